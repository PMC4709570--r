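test_that("cohort generation is deterministic and validated", {
  cfg <- cohort_config(n_genes = 100, n_x = 10, n_y = 5, n_male_tumor = 6,
                       n_female_tumor = 6, seed = 7)
  d1 <- generate_cohort(cfg)
  d2 <- generate_cohort(cfg)
  expect_identical(d1$matrix, d2$matrix)
  expect_identical(d1$genes, d2$genes)
  d3 <- generate_cohort(cohort_config(n_genes = 100, n_x = 10, n_y = 5,
                                      n_male_tumor = 6, n_female_tumor = 6,
                                      seed = 8))
  expect_false(identical(d1$matrix, d3$matrix))

  expect_error(cohort_config(n_genes = 10, n_x = 8, n_y = 5), "exceeds n_genes")
  expect_error(cohort_config(n_male_tumor = -1), "nonnegative")
  expect_error(cohort_config(effect_size = 1), "effect_size")
  expect_error(cohort_config(n_genes = 50, n_x = 0, n_y = 0, n_sex_de = 60),
               "planted")
})

test_that("sex-chromosome structure is planted as documented", {
  ds <- generate_cohort(cohort_config(
    n_genes = 200, n_x = 20, n_y = 10,
    n_male_tumor = 15, n_female_tumor = 15,
    n_male_normal = 15, n_female_normal = 15,
    effect_size = 4, seed = 5
  ))
  m <- ds$matrix
  female <- ds$samples$sex == "female"
  y_genes <- ds$genes$chromosome == "Y"
  # Y-linked genes near zero in females, expressed in males
  expect_lt(max(m[y_genes, female]), 1)
  expect_gt(stats::median(m[y_genes, !female]), 10)
  expect_true(all(c("ZFY_like", "EIF1AY_like", "DDX3Y_like", "RPS4Y1_like")
                  %in% ds$genes$gene_id))
  # XIST-like: female-high in tumors, sex-concordant in normals
  xi <- m["XIST_like", ]
  tum <- ds$samples$tissue == "tumor"
  fc_tumor <- stats::median(xi[female & tum]) / stats::median(xi[!female & tum])
  fc_normal <- stats::median(xi[female & !tum]) / stats::median(xi[!female & !tum])
  expect_gt(fc_tumor, 2.5)
  expect_lt(abs(log(fc_normal)), log(2))
  expect_true(all(m >= 0))
})

test_that("planted truth labels survive a write/read round trip", {
  ds <- generate_cohort(cohort_config(
    n_genes = 80, n_x = 8, n_y = 4, n_male_tumor = 5, n_female_tumor = 5,
    n_male_normal = 5, n_female_normal = 5, n_sex_de = 6,
    n_tumor_de_shared = 5, seed = 9
  ))
  stem <- file.path(withr::local_tempdir(), "cohort")
  write_expression_dataset(ds, stem)
  back <- read_expression_dataset(stem)
  expect_equal(back$matrix, ds$matrix, tolerance = 1e-8)
  expect_identical(back$genes$planted_sex_de, ds$genes$planted_sex_de)
  expect_identical(back$genes$tumor_de_class, ds$genes$tumor_de_class)
  expect_identical(back$samples, ds$samples)
  expect_identical(back$cancer_label, ds$cancer_label)
})

test_that("library generation is deterministic, valid and checks the universe", {
  ds <- small_tn_cohort()
  de <- tumor_vs_normal_de(ds, "male")
  sig <- build_signatures(de, size_cap = 10, quiet = TRUE)
  sigs <- list(male = sig, female = build_signatures(
    tumor_vs_normal_de(ds, "female"), size_cap = 10, quiet = TRUE))
  cfg <- library_config(n_perturbagens = 8, n_replicates = 2,
                        planted = data.frame(perturbagen_id = "PERT0001",
                                             type = "III"),
                        mimic_strength = 0.8, seed = 4)
  l1 <- generate_library(cfg, sigs, universe = ds$genes$gene_id)
  l2 <- generate_library(cfg, sigs, universe = ds$genes$gene_id)
  expect_identical(l1$profiles, l2$profiles)
  # every profile is a complete ranking
  expect_true(all(apply(l1$profiles, 2, function(col)
    identical(sort(unname(col)), seq_along(ds$genes$gene_id)))))
  bad_sigs <- sigs
  bad_sigs$male$sensitivity_genes <- c(bad_sigs$male$sensitivity_genes, "NOPE")
  expect_error(generate_library(cfg, bad_sigs, universe = ds$genes$gene_id),
               "NOPE")
  expect_error(library_config(mimic_strength = 1.4), "mimic_strength")
  expect_error(library_config(n_replicates = 0), "n_replicates")
})

test_that("mimic strength 0 makes planted perturbagens exchangeable with null", {
  universe <- sprintf("G%03d", 1:200)
  sigs <- list(
    male = signature_pair(universe[1:20], universe[21:40], "male"),
    female = signature_pair(universe[41:60], universe[61:80], "female")
  )
  planted <- data.frame(perturbagen_id = sprintf("PERT%04d", 1:20),
                        type = rep(c("I", "III"), 10))
  lib <- generate_library(
    library_config(n_perturbagens = 60, n_replicates = 1, planted = planted,
                   mimic_strength = 0, seed = 12),
    sigs, universe = universe
  )
  raw <- sexconn:::wtcs_profiles(lib, sigs$male$sensitivity_genes,
                                 sigs$male$resistance_genes)
  planted_raw <- raw[lib$manifest$planted_type != "null"]
  null_raw <- raw[lib$manifest$planted_type == "null"]
  # no signal at strength 0: planted scores sit inside the null spread
  expect_lt(abs(mean(planted_raw) - mean(null_raw)),
            3 * stats::sd(null_raw) / sqrt(length(planted_raw)) +
              3 * stats::sd(null_raw) / sqrt(length(null_raw)))
})

test_that("a lone Type III at full strength tops both sexes' score lists", {
  ds <- small_tn_cohort()
  sigs <- list(
    male = build_signatures(tumor_vs_normal_de(ds, "male"), size_cap = 15,
                            quiet = TRUE),
    female = build_signatures(tumor_vs_normal_de(ds, "female"), size_cap = 15,
                              quiet = TRUE)
  )
  lib <- generate_library(
    library_config(n_perturbagens = 40, n_replicates = 2,
                   planted = data.frame(perturbagen_id = "PERT0001",
                                        type = "III"),
                   mimic_strength = 1, seed = 3),
    sigs, universe = ds$genes$gene_id
  )
  sm <- score_library(lib, signature = sigs$male, quiet = TRUE)
  sf <- score_library(lib, signature = sigs$female, quiet = TRUE)
  expect_equal(sm$score[sm$perturbagen_id == "PERT0001"], 100)
  expect_equal(sf$score[sf$perturbagen_id == "PERT0001"], 100)
})
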