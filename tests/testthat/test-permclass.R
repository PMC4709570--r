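test_that("sex-label permutation preserves totals and is seeded", {
  ds <- small_tn_cohort()
  before <- table(ds$samples$sex)
  for (s in 1:20) {
    pm <- permute_sex_labels(ds, seed = s)
    expect_identical(table(pm$samples$sex), before)
    expect_identical(pm$samples$tissue, ds$samples$tissue)
  }
  expect_identical(permute_sex_labels(ds, seed = 3)$samples$sex,
                   permute_sex_labels(ds, seed = 3)$samples$sex)
})

test_that("each sample is relabeled male at the exchangeable frequency", {
  m <- matrix(rlnorm(50), nrow = 5,
              dimnames = list(paste0("G", 1:5), paste0("S", 1:10)))
  ds <- expression_dataset(m, rep(c("male", "female"), c(6, 4)),
                           rep("tumor", 10), rep("autosome", 5))
  counts <- numeric(10)
  for (s in 1:1000) {
    counts <- counts + (permute_sex_labels(ds, seed = s)$samples$sex == "male")
  }
  freq <- counts / 1000
  se <- sqrt(0.6 * 0.4 / 1000)
  expect_true(all(abs(freq - 0.6) < 3 * se + 0.02))
})

test_that("empirical p counts magnitude exceedances", {
  expect_equal(empirical_p(2.5, c(1, -2, 3, -4)), 0.5)
  expect_equal(empirical_p(0, c(1, 2, 3, 4)), 1)
  expect_equal(empirical_p(10, c(1, 2, 3, 4)), 0)
  expect_equal(empirical_p(10, c(1, 2, 3, 4), add_one = TRUE), 1 / 5)
  expect_error(empirical_p(1, numeric(0)), "empty")
})

test_that("perturbagen typing reproduces every published example row", {
  thr <- perm_thresholds()
  rows <- data.frame(
    male = c(74.26, 70.89, -79.27, -80.84, -71.30, 98.76, 98.97),
    female = c(-66.44, -86.40, 82.37, 78.58, 89.33, 99.70, 99.25),
    bh = c(9e-5, 9e-5, 9e-5, 9e-5, 9e-5, 0.9575, 0.9498),
    type = c("I", "I", "II", "II", "II", "III", "III")
  )
  expect_identical(classify_perturbagen(rows$male, rows$female, rows$bh, thr),
                   rows$type)
})

test_that("typing respects sign constraints, floors and boundaries", {
  thr <- perm_thresholds()
  # significant but same-sign scores: no sex-specific call
  expect_equal(classify_perturbagen(80, 70, 0.001, thr), "none")
  expect_equal(classify_perturbagen(-80, -70, 0.001, thr), "none")
  # boundary BH values fall to none
  expect_equal(classify_perturbagen(80, -70, 0.05, thr), "none")
  # Type III needs both scores at or above the floor
  expect_equal(classify_perturbagen(95, 89.9, 0.5, thr), "none")
  expect_equal(classify_perturbagen(90, 90, 0.5, thr), "III")
  # the stricter insignificance ceiling is available as a threshold
  strict <- perm_thresholds(bh_floor_type3 = 0.95)
  expect_equal(classify_perturbagen(98.76, 99.70, 0.9575, strict), "III")
  expect_equal(classify_perturbagen(98.97, 99.25, 0.9498, strict), "none")
  expect_equal(classify_perturbagen(95, 95, 0.95, strict), "none")
  expect_error(classify_perturbagen(120, 0, 0.5, thr), "scores")
  expect_error(classify_perturbagen(50, 0, 1.5, thr), "bh")
  expect_error(perm_thresholds(alpha_sexspec = 0), "alpha_sexspec")
  expect_error(perm_thresholds(bh_floor_type3 = 0.01), "bh_floor_type3")
  expect_error(perm_thresholds(score_floor_type3 = 0), "score_floor_type3")
})

test_that("type tallies add Type I and II into the sex-specific total", {
  expect_equal(tally_types(rep(c("I", "II", "III"), c(432, 207, 13)))[["total_sex_specific"]],
               639)
  expect_equal(tally_types(rep(c("I", "II", "III"), c(175, 243, 134)))[["total_sex_specific"]],
               418)
  expect_equal(tally_types(character(0))[["total_sex_specific"]], 0)
  expect_error(tally_types(c("I", "IV")), "I")
})

test_that("the permutation fit is deterministic and internally consistent", {
  ds <- small_tn_cohort()
  sigs <- list(
    male = build_signatures(tumor_vs_normal_de(ds, "male"), size_cap = 10,
                            quiet = TRUE),
    female = build_signatures(tumor_vs_normal_de(ds, "female"), size_cap = 10,
                              quiet = TRUE)
  )
  lib <- generate_library(
    library_config(n_perturbagens = 25, n_replicates = 1,
                   planted = data.frame(perturbagen_id = c("PERT0001", "PERT0002"),
                                        type = c("I", "III")),
                   mimic_strength = 0.95, seed = 41),
    sigs, universe = ds$genes$gene_id
  )
  thr <- perm_thresholds(n_permutations = 25, signature_cap = 10, seed = 77)
  dc1 <- suppressWarnings(differential_connectivity(ds, lib, thr))
  dc2 <- suppressWarnings(differential_connectivity(ds, lib, thr))
  expect_identical(dc1$table, dc2$table)
  expect_identical(dc1$null_diffs, dc2$null_diffs)

  tab <- dc1$table
  # p recomputes from the stored null distributions
  p_manual <- vapply(seq_len(nrow(tab)), function(i) {
    mean(abs(dc1$null_diffs[i, ]) >= abs(tab$obs_diff[i]))
  }, numeric(1))
  expect_equal(tab$p, p_manual)
  expect_equal(tab$bh, bh_adjust(tab$p))
  expect_true(all(tab$bh >= tab$p - 1e-15))
  expect_equal(tab$obs_diff, tab$male_score - tab$female_score)
  expect_identical(tab$type,
                   classify_perturbagen(tab$male_score, tab$female_score,
                                        tab$bh, thr))
  expect_equal(ncol(dc1$null_diffs), 25)
})

test_that("a cohort with no expression effects cannot seed an analysis", {
  ds <- generate_cohort(cohort_config(
    n_genes = 120, n_x = 0, n_y = 0,
    n_male_tumor = 10, n_female_tumor = 10,
    n_male_normal = 10, n_female_normal = 10,
    xist_like = FALSE, seed = 55
  ))
  universe <- ds$genes$gene_id
  lib <- generate_library(library_config(n_perturbagens = 5, n_replicates = 1,
                                         mimic_strength = 0, seed = 1),
                          signatures = NULL, universe = universe)
  thr <- perm_thresholds(n_permutations = 5, seed = 2)
  expect_error(suppressWarnings(differential_connectivity(ds, lib, thr)),
               "empty")
})

test_that("zero permutations are refused", {
  ds <- small_tn_cohort()
  lib <- generate_library(library_config(n_perturbagens = 4, n_replicates = 1,
                                         mimic_strength = 0, seed = 1),
                          signatures = NULL, universe = ds$genes$gene_id)
  expect_error(differential_connectivity(ds, lib,
                                         perm_thresholds(n_permutations = 0)),
               "n_permutations")
})
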