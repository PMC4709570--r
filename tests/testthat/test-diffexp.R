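test_that("wilcoxon rank-sum matches hand-enumerable cases and guards input", {
  # x = {1,2}, y = {3,4}: all four x-ranks below y; 2 of 6 assignments as extreme
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4), mode = "exact")$p, 1 / 3,
               tolerance = 1e-12)
  # complete degeneracy: no separation
  expect_equal(wilcoxon_rank_sum(c(5, 5, 5), c(5, 5, 5))$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "nonempty")
  expect_error(wilcoxon_rank_sum(c(1, 1, 2), c(2, 3), mode = "exact"), "tie")
})

test_that("exact Wilcoxon equals full enumeration for all group sizes up to 6", {
  set.seed(42)
  for (nx in 1:6) {
    for (ny in 1:6) {
      z <- sample(seq_len(50), nx + ny)  # tie-free
      x <- z[seq_len(nx)]; y <- z[-seq_len(nx)]
      expect_equal(wilcoxon_rank_sum(x, y, mode = "exact")$p,
                   enum_wilcoxon_p(x, y), tolerance = 1e-12,
                   info = sprintf("sizes %d vs %d", nx, ny))
    }
  }
})

test_that("vectorized approximate Wilcoxon matches wilcox.test including ties", {
  set.seed(7)
  m <- matrix(rpois(50 * 14, lambda = 8), nrow = 50)  # discrete => many ties
  m[1, ] <- 5  # an all-tied row
  res <- sexconn:::row_wilcoxon(m, 1:6, 7:14)
  for (i in 2:50) {
    ref <- suppressWarnings(stats::wilcox.test(m[i, 1:6], m[i, 7:14],
                                               exact = FALSE, correct = TRUE))
    expect_equal(res$p[i], ref$p.value, tolerance = 1e-12)
    expect_equal(res$statistic[i], unname(ref$statistic), tolerance = 1e-12)
  }
  expect_equal(res$p[1], 1)
})

test_that("BH adjustment reproduces the step-up rule and rejects bad input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.42), 0.42)
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), stepup_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, NA)), "\\[0, 1\\]")
  # monotonicity: raising one raw p never lowers any adjusted value
  p <- c(0.01, 0.2, 0.04, 0.6)
  p2 <- p; p2[3] <- 0.3
  expect_true(all(bh_adjust(p2) >= bh_adjust(p) - 1e-12))
})

test_that("median fold change follows its closed form", {
  expect_equal(median_fold_change(c(3, 4, 5), c(1, 2, 3), pseudocount = 1e-9),
               2, tolerance = 1e-6)
  expect_equal(median_fold_change(1:5, 1:5), 1)
  expect_equal(median_fold_change(c(9, 9, 9), c(0, 0, 0), pseudocount = 1), 10)
  expect_error(median_fold_change(1:3, 2:4, pseudocount = 0), "pseudocount")
})

test_that("sex-DE recovers planted genes and respects its contracts", {
  ds <- generate_cohort(cohort_config(
    n_genes = 500, n_x = 30, n_y = 0, n_male_tumor = 40, n_female_tumor = 40,
    n_sex_de = 50, effect_size = 4, xist_like = FALSE, seed = 7
  ))
  de <- sex_de(ds)
  truth <- ds$genes$planted_sex_de
  expect_gte(sum(de$significant[truth]), 45)
  s <- summary(de)
  expect_equal(s$n_samples, 80)
  expect_equal(s$ratio, s$n_significant / 80)
  expect_true(all(de$bh >= de$p - 1e-15))
  expect_identical(de$significant, de$bh < 0.05)
})

test_that("sex-DE is invariant under strictly monotone transforms", {
  ds <- tiny_dataset()
  de1 <- sex_de(ds, mode = "approx")
  ds_log <- ds
  ds_log$matrix <- log1p(ds$matrix)
  de2 <- sex_de(ds_log, mode = "approx")
  expect_equal(de1$p, de2$p, tolerance = 1e-12)
  expect_equal(de1$W, de2$W)
})

test_that("all-null cohort keeps the significant fraction near nominal", {
  ds <- generate_cohort(cohort_config(
    n_genes = 400, n_x = 0, n_y = 0, n_male_tumor = 25, n_female_tumor = 25,
    xist_like = FALSE, seed = 33
  ))
  de <- sex_de(ds)
  # BH at 0.05 on a global null: expect essentially no discoveries
  expect_lte(sum(de$significant), 400 * 0.05)
})

test_that("tumor-vs-normal DE is sex-stratified and enforces the arm floor", {
  ds <- small_tn_cohort()
  de_m <- tumor_vs_normal_de(ds, "male")
  de_f <- tumor_vs_normal_de(ds, "female")
  gi <- ds$genes
  male_only <- gi$gene_id[gi$tumor_de_class == "male_only"]
  expect_gte(mean(de_m$significant[de_m$gene_id %in% male_only]), 0.9)
  expect_lte(mean(de_f$significant[de_f$gene_id %in% male_only]), 0.1)
  # fc orientation: planted "up" male-only genes have fc > 1 in males
  up_m <- gi$gene_id[gi$tumor_de_class == "male_only" & gi$tumor_de_direction == "up"]
  expect_true(all(de_m$fc[de_m$gene_id %in% up_m] > 1))
  expect_error(tumor_vs_normal_de(ds, "male", min_per_arm = 20),
               "male tumor arm")
})

test_that("tumor/normal orientation swap inverts fold changes", {
  ds <- small_tn_cohort()
  de <- tumor_vs_normal_de(ds, "male", pseudocount = 1e-9)
  flipped <- ds
  flipped$samples$tissue <- ifelse(ds$samples$tissue == "tumor", "normal", "tumor")
  de2 <- tumor_vs_normal_de(flipped, "male", pseudocount = 1e-9)
  expect_equal(de2$fc, 1 / de$fc, tolerance = 1e-6)
})

test_that("sex-chromosome enrichment agrees with stats oracles", {
  ds <- generate_cohort(cohort_config(
    n_genes = 110, n_x = 8, n_y = 2, n_male_tumor = 5, n_female_tumor = 5,
    xist_like = FALSE, seed = 2
  ))
  sig <- ds$genes$gene_id[c(which(ds$genes$chromosome != "autosome")[1:8],
                            which(ds$genes$chromosome == "autosome")[1:2])]
  res <- sex_chromosome_enrichment(sig, ds)
  ref <- suppressWarnings(stats::prop.test(c(8, 10), c(10, 110), correct = TRUE))
  expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  expect_equal(res$prop_significant, 0.8)
  res_f <- sex_chromosome_enrichment(sig, ds, method = "fisher")
  ref_f <- stats::fisher.test(matrix(c(8, 2, 2, 98), nrow = 2))
  expect_equal(res_f$p, ref_f$p.value, tolerance = 1e-10)
  # all significant genes on sex chromosomes, large autosomal background
  ds2 <- generate_cohort(cohort_config(
    n_genes = 1000, n_x = 9, n_y = 1, n_male_tumor = 5, n_female_tumor = 5,
    xist_like = FALSE, seed = 3
  ))
  all_sex <- ds2$genes$gene_id[ds2$genes$chromosome != "autosome"]
  expect_lt(sex_chromosome_enrichment(all_sex, ds2)$p, 1e-6)
  expect_warning(out <- sex_chromosome_enrichment(character(0), ds), "empty")
  expect_true(is.na(out$p))
})

test_that("Fisher's method has its closed form, symmetry and monotonicity", {
  # df = 4 closed form: exp(-X/2) * (1 + X/2)
  X <- -2 * sum(log(c(0.5, 0.5)))
  expect_equal(fisher_meta(c(0.5, 0.5)), exp(-X / 2) * (1 + X / 2),
               tolerance = 1e-10)
  expect_equal(round(fisher_meta(c(0.5, 0.5)), 4), 0.5966)
  expect_equal(fisher_meta(0.123), 0.123, tolerance = 1e-12)
  expect_equal(fisher_meta(c(0.01, 0.9)), fisher_meta(c(0.9, 0.01)))
  expect_lt(fisher_meta(c(0.005, 0.9)), fisher_meta(c(0.01, 0.9)))
  expect_warning(p0 <- fisher_meta(c(0, 0.5)), "clamped")
  expect_lt(p0, 1e-10)
  expect_error(fisher_meta(c(0, 0.5), clamp_zero = FALSE), "0")
  expect_error(fisher_meta(c(0.5, 1.5)), "\\[0, 1\\]")
})
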