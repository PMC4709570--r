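#' Thresholds for the permutation analysis and perturbagen typing
#'
#' Bundles every tunable of the differential-connectivity analysis. Type I
#' perturbagens (male-sensitive, female-resistant) and Type II (the mirror)
#' require a BH-adjusted permutation p-value below `alpha_sexspec` together
#' with the matching score signs. Type III (sensitive in both sexes)
#' requires the male-female difference to be *non*-significant
#' (BH above `bh_floor_type3`) and connectivity scores of at least
#' `score_floor_type3` in both sexes. The default `bh_floor_type3` equals
#' `alpha_sexspec`: "not sex-specific at the working threshold" — see the
#' methods vignette for why this, rather than a stricter ceiling such as
#' 0.95, is the default.
#'
#' @param alpha_sexspec BH threshold for Type I/II calls (default 0.05).
#' @param bh_floor_type3 BH floor for Type III calls (default
#'   `alpha_sexspec`; must be >= `alpha_sexspec`).
#' @param score_floor_type3 connectivity-score floor for Type III in both
#'   sexes, in (0, 100\] (default 90).
#' @param n_permutations number of sex-label permutations (default 1000).
#' @param alpha_de BH threshold of the underlying DE runs (default 0.05).
#' @param signature_cap signature size cap (default 250).
#' @param min_per_arm sample floor per tumor/normal arm (default 10).
#' @param add_one use the (r+1)/(N+1) empirical p-value instead of r/N
#'   (default `FALSE`: r/N, which can attain exact zero).
#' @param seed master seed; every permutation's seed derives from it.
#' @return A validated list of class `perm_thresholds`.
#' @export
perm_thresholds <- function(alpha_sexspec = 0.05,
                            bh_floor_type3 = alpha_sexspec,
                            score_floor_type3 = 90,
                            n_permutations = 1000L,
                            alpha_de = 0.05, signature_cap = 250L,
                            min_per_arm = 10L, add_one = FALSE,
                            seed = 1L) {
  thr <- list(alpha_sexspec = alpha_sexspec, bh_floor_type3 = bh_floor_type3,
              score_floor_type3 = score_floor_type3,
              n_permutations = as.integer(n_permutations),
              alpha_de = alpha_de, signature_cap = as.integer(signature_cap),
              min_per_arm = as.integer(min_per_arm),
              add_one = isTRUE(add_one), seed = as.integer(seed))
  if (thr$alpha_sexspec <= 0 || thr$alpha_sexspec >= 1) {
    stop("alpha_sexspec must lie in (0, 1)")
  }
  if (thr$bh_floor_type3 < thr$alpha_sexspec || thr$bh_floor_type3 >= 1) {
    stop("bh_floor_type3 must lie in [alpha_sexspec, 1)")
  }
  if (thr$score_floor_type3 <= 0 || thr$score_floor_type3 > 100) {
    stop("score_floor_type3 must lie in (0, 100]")
  }
  if (thr$n_permutations < 0L) stop("n_permutations must be nonnegative")
  structure(thr, class = "perm_thresholds")
}

#' Permute the sex labels of a dataset
#'
#' Reassigns the sex labels uniformly at random over samples while holding
#' the male/female totals constant; tumor/normal labels are untouched. This
#' is the exchangeability null of the permutation analysis: under it there
#' is no sex difference for any downstream statistic to find.
#'
#' @param dataset an [expression_dataset()].
#' @param seed optional seed; if `NULL` the current RNG stream is used (as
#'   inside the permutation loop).
#' @return The relabeled dataset.
#' @export
permute_sex_labels <- function(dataset, seed = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  sex <- dataset$samples$sex
  if (length(unique(sex)) < 2L) stop("dataset must contain both sexes")
  perm <- if (is.null(seed)) sample(sex) else with_seed(seed, sample(sex))
  set_sex_labels(dataset, perm)
}

#' Empirical permutation p-value for a connectivity difference
#'
#' Two-sided on magnitude: the fraction of permutation null differences at
#' least as large in absolute value as the observed one. With the default
#' r/N convention an exact zero is attainable (and is passed to BH
#' adjustment as-is); the (r+1)/(N+1) variant is available.
#'
#' @param obs_diff observed male-female score difference.
#' @param null_diffs numeric vector of permutation null differences.
#' @param add_one use (r+1)/(N+1).
#' @return The empirical p-value in \[0, 1\].
#' @export
empirical_p <- function(obs_diff, null_diffs, add_one = FALSE) {
  if (length(null_diffs) == 0L) stop("null distribution is empty")
  r <- sum(abs(null_diffs) >= abs(obs_diff))
  if (add_one) (r + 1) / (length(null_diffs) + 1) else r / length(null_diffs)
}

#' Classify perturbagens into Types I, II, III
#'
#' Applies the typing rules to per-perturbagen male/female connectivity
#' scores and BH-adjusted permutation p-values: Type I needs a significant
#' sex difference (`bh < alpha_sexspec`) with a positive male and negative
#' female score; Type II the mirror; Type III a non-significant difference
#' (`bh > bh_floor_type3`) with scores at or above `score_floor_type3` in
#' both sexes. Everything else is `"none"`; boundary BH values fall to
#' `"none"`.
#'
#' @param male_score,female_score numeric vectors in \[-100, 100\].
#' @param bh BH-adjusted empirical p-values in \[0, 1\].
#' @param thresholds a [perm_thresholds()].
#' @return Character vector in `c("I", "II", "III", "none")`.
#' @export
classify_perturbagen <- function(male_score, female_score, bh,
                                 thresholds = perm_thresholds()) {
  stopifnot(inherits(thresholds, "perm_thresholds"))
  if (any(abs(c(male_score, female_score)) > 100)) {
    stop("scores must lie in [-100, 100]")
  }
  if (any(bh < 0 | bh > 1)) stop("bh values must lie in [0, 1]")
  type <- rep("none", length(bh))
  sig <- bh < thresholds$alpha_sexspec
  type[sig & male_score > 0 & female_score < 0] <- "I"
  type[sig & male_score < 0 & female_score > 0] <- "II"
  type[bh > thresholds$bh_floor_type3 &
         male_score >= thresholds$score_floor_type3 &
         female_score >= thresholds$score_floor_type3] <- "III"
  type
}

#' Tally perturbagen types
#'
#' Counts Type I, II and III calls and the total number of sex-specific
#' perturbagens (Type I plus Type II), the per-cancer summary of the
#' analysis.
#'
#' @param types character vector of type calls, or a
#'   [differential_connectivity()] result.
#' @return Named integer vector: `type_I`, `type_II`, `type_III`, `none`,
#'   `total_sex_specific`.
#' @export
tally_types <- function(types) {
  if (inherits(types, "diffconn")) types <- types$table$type
  stopifnot(all(types %in% c("I", "II", "III", "none")))
  c(type_I = sum(types == "I"), type_II = sum(types == "II"),
    type_III = sum(types == "III"), none = sum(types == "none"),
    total_sex_specific = sum(types == "I") + sum(types == "II"))
}

# Per-sex connectivity scores for one (possibly relabeled) dataset:
# tumor-vs-normal DE within the sex, signature construction, library query.
# Returns NULL when a signature side comes up empty (the caller decides how
# to record that). The arm-size floor applies to the observed labels only:
# a random relabeling may shrink an arm, which is still a valid draw from
# the permutation null, so the loop passes the technical minimum of 2.
sex_scores_once <- function(dataset, library, thresholds, quiet = TRUE,
                            min_per_arm = thresholds$min_per_arm,
                            strict = FALSE) {
  out <- list()
  for (sx in c("male", "female")) {
    de <- if (strict) {
      tumor_vs_normal_de(dataset, sx, alpha = thresholds$alpha_de,
                         min_per_arm = min_per_arm, mode = "approx")
    } else {
      tryCatch(
        tumor_vs_normal_de(dataset, sx, alpha = thresholds$alpha_de,
                           min_per_arm = min_per_arm, mode = "approx"),
        error = function(e) NULL
      )
    }
    if (is.null(de)) return(NULL)
    sig <- build_signatures(de, sex = sx, size_cap = thresholds$signature_cap,
                            quiet = quiet)
    sig <- intersect_with_universe(sig, library$universe, quiet = quiet)
    if (length(sig$sensitivity_genes) == 0L || length(sig$resistance_genes) == 0L) {
      return(NULL)
    }
    out[[sx]] <- score_library(library, signature = sig, quiet = TRUE)
  }
  out
}

#' Sex-differential connectivity analysis with permutation calibration
#'
#' The package's central fit. For the observed sex labels it derives each
#' sex's tumor-versus-normal signatures and scores every perturbagen of the
#' library in both sexes; it then repeats the entire derivation under
#' `n_permutations` random relabelings of sex (male/female totals held
#' constant) to build a per-perturbagen null distribution of male-female
#' score differences, converts the observed differences to empirical
#' p-values, BH-adjusts them, and classifies each perturbagen as Type I,
#' II, III or none.
#'
#' A permutation whose relabeled data yield an empty signature side
#' contributes a zero difference for every perturbagen (recorded and
#' reported rather than aborting the run).
#'
#' @param dataset an [expression_dataset()] with at least `min_per_arm`
#'   tumor and normal samples in each sex.
#' @param library a [perturbagen_library()].
#' @param thresholds a [perm_thresholds()]; `n_permutations` and `seed`
#'   live there.
#' @param verbose print progress every 50 permutations.
#' @return An object of class `diffconn`: list with `table` (one row per
#'   perturbagen: ids, male/female scores, observed difference, empirical
#'   p, BH value, type), `null_diffs` (perturbagen x permutation matrix),
#'   `thresholds`, `n_empty_permutations`, and the observed signature
#'   sizes. Methods: `print`, `summary` (type tally), `plot` (male-female
#'   score scatter), `as.data.frame`.
#' @export
differential_connectivity <- function(dataset, library,
                                      thresholds = perm_thresholds(),
                                      verbose = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(library, "perturbagen_library"),
            inherits(thresholds, "perm_thresholds"))
  if (thresholds$n_permutations < 1L) {
    stop("n_permutations must be >= 1: no null distribution otherwise")
  }

  obs <- sex_scores_once(dataset, library, thresholds, quiet = FALSE,
                         strict = TRUE)
  if (is.null(obs)) {
    stop("observed data yield an empty signature side; nothing to test")
  }
  stopifnot(identical(obs$male$perturbagen_id, obs$female$perturbagen_id))
  pert_ids <- obs$male$perturbagen_id
  obs_diff <- obs$male$score - obs$female$score

  N <- thresholds$n_permutations
  seeds <- derive_seeds(thresholds$seed, N)
  null_diffs <- matrix(0, nrow = length(pert_ids), ncol = N,
                       dimnames = list(pert_ids, NULL))
  n_empty <- 0L
  for (b in seq_len(N)) {
    perm <- permute_sex_labels(dataset, seed = seeds[b])
    res <- sex_scores_once(perm, library, thresholds, quiet = TRUE,
                           min_per_arm = 2L)
    if (is.null(res)) {
      n_empty <- n_empty + 1L  # column stays 0
    } else {
      null_diffs[, b] <- res$male$score - res$female$score
    }
    if (verbose && b %% 50L == 0L) {
      message(sprintf("permutation %d/%d", b, N))
    }
  }
  if (n_empty > 0L) {
    warning(sprintf("%d permutation(s) yielded an empty signature; their differences were recorded as 0",
                    n_empty))
  }

  p <- vapply(seq_along(pert_ids), function(i) {
    empirical_p(obs_diff[i], null_diffs[i, ], add_one = thresholds$add_one)
  }, numeric(1))
  bh <- bh_adjust(p)
  type <- classify_perturbagen(obs$male$score, obs$female$score, bh, thresholds)

  tab <- data.frame(
    perturbagen_id = pert_ids,
    reagent_class = obs$male$reagent_class,
    planted_type = obs$male$planted_type,
    male_score = obs$male$score, female_score = obs$female$score,
    obs_diff = obs_diff, p = p, bh = bh, type = type,
    stringsAsFactors = FALSE
  )
  structure(
    list(table = tab, null_diffs = null_diffs, thresholds = thresholds,
         n_empty_permutations = n_empty,
         cancer_label = dataset$cancer_label,
         call = match.call()),
    class = "diffconn"
  )
}

#' @export
print.diffconn <- function(x, ...) {
  tt <- tally_types(x$table$type)
  cat(sprintf("<diffconn> %s: %d perturbagens, %d permutations\n",
              x$cancer_label, nrow(x$table), x$thresholds$n_permutations))
  cat(sprintf("Type I: %d  Type II: %d  Type III: %d  (total sex-specific: %d)\n",
              tt[["type_I"]], tt[["type_II"]], tt[["type_III"]],
              tt[["total_sex_specific"]]))
  ord <- order(x$table$bh, -abs(x$table$obs_diff))
  print.data.frame(utils::head(x$table[ord, ], 6L), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.diffconn <- function(object, ...) {
  tt <- tally_types(object$table$type)
  out <- data.frame(cancer_label = object$cancer_label,
                    n_perturbagens = nrow(object$table),
                    n_permutations = object$thresholds$n_permutations,
                    type_I = tt[["type_I"]], type_II = tt[["type_II"]],
                    type_III = tt[["type_III"]],
                    total_sex_specific = tt[["total_sex_specific"]],
                    n_empty_permutations = object$n_empty_permutations,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary.diffconn", "data.frame")
  out
}

#' @export
print.summary.diffconn <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.diffconn <- function(x, ...) x$table

#' @param x a `diffconn` object.
#' @param ... passed to [graphics::plot()].
#' @rdname differential_connectivity
#' @export
plot.diffconn <- function(x, ...) {
  tab <- x$table
  cols <- c(I = "#1f78b4", II = "#e31a1c", III = "#6a3d9a", none = "grey60")
  graphics::plot(tab$male_score, tab$female_score,
                 col = cols[tab$type], pch = ifelse(tab$reagent_class == "chemical", 17, 19),
                 xlab = "male connectivity score", ylab = "female connectivity score",
                 xlim = c(-100, 100), ylim = c(-100, 100),
                 main = sprintf("%s: male vs female connectivity", x$cancer_label),
                 ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  graphics::legend("bottomright", legend = names(cols), col = cols, pch = 19,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Export the male/female score scatter data
#'
#' Writes one row per perturbagen with both sexes' scores, the observed
#' difference, BH value and type call — the plain-data layer behind the
#' male-versus-female connectivity scatterplots.
#'
#' @param x a `diffconn` object.
#' @param path output TSV path.
#' @export
write_scatter_tsv <- function(x, path) {
  stopifnot(inherits(x, "diffconn"))
  tab <- x$table
  out <- data.frame(
    perturbagen_id = tab$perturbagen_id,
    reagent_class = tab$reagent_class,
    male_score = fmt_num(tab$male_score),
    female_score = fmt_num(tab$female_score),
    obs_diff = fmt_num(tab$obs_diff),
    bh = fmt_num(tab$bh), type = tab$type,
    stringsAsFactors = FALSE
  )
  write_tsv(out, path)
}
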