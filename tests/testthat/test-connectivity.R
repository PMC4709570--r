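test_that("enrichment score handles the hand-checkable extremes", {
  universe <- c("A", "B", "C", "D")
  profile <- stats::setNames(1:4, universe)
  expect_equal(enrichment_score("A", profile), 1)
  expect_equal(enrichment_score("D", profile), -1)
  expect_warning(es <- enrichment_score(universe, profile), "whole universe")
  expect_equal(es, 0)
  expect_error(enrichment_score(character(0), profile), "nonempty")
  expect_error(enrichment_score(c("A", "Z"), profile), "Z")
})

test_that("closed-form enrichment equals the explicit running-sum walk", {
  set.seed(21)
  for (i in 1:200) {
    N <- sample(10:60, 1)
    universe <- sprintf("G%02d", 1:N)
    profile <- stats::setNames(sample(N), universe)
    query <- sample(universe, sample(seq_len(N - 1), 1))
    expect_equal(enrichment_score(query, profile), walk_es(query, profile),
                 tolerance = 1e-12)
  }
})

test_that("null enrichment is symmetric around zero", {
  set.seed(5)
  N <- 100
  universe <- sprintf("G%03d", 1:N)
  es <- replicate(2000, {
    profile <- stats::setNames(sample(N), universe)
    enrichment_score(sample(universe, 10), profile)
  })
  expect_lt(abs(mean(es)), 3 * stats::sd(es) / sqrt(length(es)))
})

test_that("WTCS combines the two sides with the opposite-sign rule", {
  N <- 40
  universe <- sprintf("G%02d", 1:N)
  profile <- stats::setNames(1:N, universe)
  up <- universe[1:5]      # at the very top
  down <- universe[36:40]  # at the very bottom
  expect_gt(wtcs(up, down, profile), 0.85)
  expect_equal(wtcs(down, up, profile), -wtcs(up, down, profile))
  # both sets at the top: same-sign enrichment is not connectivity
  expect_equal(wtcs(universe[1:5], universe[6:10], profile), 0)
  expect_error(wtcs(universe[1:5], universe[5:9], profile), "disjoint")
})

test_that("raw WTCS is antisymmetric under up/down exchange on random data", {
  set.seed(9)
  N <- 80
  universe <- sprintf("G%02d", 1:N)
  for (i in 1:50) {
    profile <- stats::setNames(sample(N), universe)
    up <- sample(universe, 8)
    down <- sample(setdiff(universe, up), 8)
    expect_equal(wtcs(up, down, profile), -wtcs(down, up, profile),
                 tolerance = 1e-12)
  }
})

test_that("vectorized library scoring equals the scalar scorer", {
  set.seed(31)
  N <- 60
  universe <- sprintf("G%02d", 1:N)
  ranks <- lapply(1:12, function(i) sample(N))
  lib <- manual_library(universe, ranks)
  up <- sample(universe, 7)
  down <- sample(setdiff(universe, up), 7)
  fast <- sexconn:::wtcs_profiles(lib, up, down)
  slow <- vapply(seq_len(ncol(lib$profiles)), function(j) {
    wtcs(up, down, stats::setNames(lib$profiles[, j], universe))
  }, numeric(1))
  expect_equal(fast, slow, tolerance = 1e-12)
})

test_that("signed-percentile normalization follows its contract", {
  set.seed(2)
  N <- 30
  universe <- sprintf("G%02d", 1:N)
  lib <- manual_library(universe, lapply(1:10, function(i) sample(N)))
  raw <- c(0.9, 0.5, 0.4, 0.1, 0, -0.2, -0.3, -0.6, 0.05, -0.05)
  agg <- normalize_and_aggregate(raw, lib)
  expect_equal(agg$score[1], 100)                 # strongest positive
  expect_equal(agg$score[agg$mean_raw == 0], 0)   # exact zero stays zero
  expect_true(all(abs(agg$score) <= 100))
  expect_identical(sign(agg$score), sign(agg$mean_raw))
  # monotone within each sign class
  pos <- agg[agg$mean_raw > 0, ]
  expect_identical(order(pos$mean_raw), order(pos$score))
  # duplicating replicates leaves the mean (hence score) unchanged
  lib2 <- manual_library(universe, rep(lapply(1:10, function(i) sample(N)), 2))
  lib2$manifest$perturbagen_id <- rep(paste0("P", 1:10), 2)
  raw2 <- rep(raw, 2)
  agg2 <- normalize_and_aggregate(raw2, lib2)
  expect_equal(agg2$score[order(agg2$perturbagen_id)],
               agg$score[order(agg$perturbagen_id)])
})

test_that("single-perturbagen libraries flag the degenerate percentile", {
  universe <- sprintf("G%02d", 1:10)
  lib <- manual_library(universe, list(sample(10)))
  expect_warning(agg <- normalize_and_aggregate(0.4, lib), "degenerate")
  expect_equal(agg$score, 100)
})

test_that("exchanging a query's up and down sets negates every score exactly", {
  set.seed(13)
  N <- 120
  universe <- sprintf("G%03d", 1:N)
  lib <- manual_library(universe, lapply(1:40, function(i) sample(N)))
  up <- sample(universe, 12)
  down <- sample(setdiff(universe, up), 12)
  fwd <- score_library(lib, up_set = up, down_set = down)
  rev <- score_library(lib, up_set = down, down_set = up)
  expect_identical(fwd$perturbagen_id, rev$perturbagen_id)
  expect_equal(rev$score, -fwd$score, tolerance = 1e-12)
  expect_equal(rev$mean_raw, -fwd$mean_raw, tolerance = 1e-12)
})

test_that("scores are invariant to perturbagen relabeling", {
  set.seed(17)
  N <- 50
  universe <- sprintf("G%02d", 1:N)
  ranks <- lapply(1:10, function(i) sample(N))
  lib <- manual_library(universe, ranks)
  perm <- sample(10)
  lib_shuffled <- manual_library(universe, ranks[perm])
  up <- sample(universe, 6); down <- sample(setdiff(universe, up), 6)
  s1 <- score_library(lib, up_set = up, down_set = down)
  s2 <- score_library(lib_shuffled, up_set = up, down_set = down)
  # shuffled library's i-th perturbagen carries the original perm[i]-th profile
  expect_equal(s2$score, s1$score[perm], tolerance = 1e-12)
  expect_equal(s2$mean_raw, s1$mean_raw[perm], tolerance = 1e-12)
})

test_that("empty queries are refused", {
  universe <- sprintf("G%02d", 1:10)
  lib <- manual_library(universe, list(sample(10), sample(10)))
  expect_error(score_library(lib, up_set = character(0), down_set = universe[1:2]),
               "empty query")
})
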