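#' Wilcoxon rank-sum test for two expression groups
#'
#' Thin, contract-checked wrapper around the two-sample Wilcoxon (Mann-Whitney)
#' test used for every univariate comparison in the package. In `"auto"` mode
#' the exact null distribution is enumerated when both groups have at most 10
#' observations and there are no ties; otherwise the normal approximation with
#' tie and continuity correction is used (the conventional behaviour of
#' [stats::wilcox.test()]).
#'
#' @param x,y numeric vectors of expression values for the two groups.
#' @param mode `"auto"`, `"exact"` or `"approx"`. `"exact"` requires tie-free
#'   data.
#' @return A list with `statistic` (the Mann-Whitney U for `x`, i.e. R's `W`)
#'   and `p` (two-sided p-value in (0, 1]).
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4), mode = "exact")$p  # 1/3
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  all_vals <- c(x, y)
  ties <- anyDuplicated(all_vals) > 0L
  if (length(unique(all_vals)) == 1L) {
    # complete degeneracy: no separation whatsoever
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  }
  exact <- switch(mode,
    exact = {
      if (ties) stop("exact mode requires tie-free data")
      TRUE
    },
    approx = FALSE,
    auto = length(x) <= 10L && length(y) <= 10L && !ties
  )
  res <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE,
                       alternative = "two.sided")
  )
  list(statistic = unname(res$statistic), p = min(res$p.value, 1))
}

# Vectorized normal-approximation Wilcoxon over the rows of a matrix,
# matching stats::wilcox.test(exact = FALSE, correct = TRUE) including the
# tie correction. Rows where every value is identical get p = 1. Used by the
# DE drivers and the permutation loop, where per-gene wilcox.test calls would
# dominate the run time.
row_wilcoxon <- function(mat, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  stopifnot(na > 0L, nb > 0L)
  sub <- mat[, c(idx_a, idx_b), drop = FALSE]
  n <- na + nb
  W <- numeric(nrow(sub))
  tie_term <- numeric(nrow(sub))
  for (i in seq_len(nrow(sub))) {
    r <- rank(sub[i, ])
    W[i] <- sum(r[seq_len(na)]) - na * (na + 1) / 2
    nt <- tabulate(match(sub[i, ], unique(sub[i, ])))
    tie_term[i] <- sum(nt^3 - nt)
  }
  z <- W - na * nb / 2
  sigma <- sqrt((na * nb / 12) * ((n + 1) - tie_term / (n * (n - 1))))
  zc <- (z - sign(z) * 0.5) / sigma
  p <- 2 * stats::pnorm(-abs(zc))
  p[!is.finite(zc)] <- 1  # all-tied rows: sigma == 0
  p <- pmin(p, 1)
  list(statistic = W, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts raw p-values for multiple testing by the Benjamini-Hochberg
#' procedure, yielding "BH values" that control the false discovery rate.
#' Input validation aside, this is [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Fold change of group medians
#'
#' @param x,y numeric vectors (numerator and denominator groups).
#' @param pseudocount positive constant added to both medians so that zero
#'   medians, common in nonnegative expression data, stay finite.
#' @return `(median(x) + pseudocount) / (median(y) + pseudocount)`.
#' @export
median_fold_change <- function(x, y, pseudocount = 1) {
  if (length(x) == 0L || length(y) == 0L) stop("both groups must be nonempty")
  if (!is.numeric(pseudocount) || pseudocount <= 0) stop("pseudocount must be > 0")
  (stats::median(x) + pseudocount) / (stats::median(y) + pseudocount)
}

row_median_fc <- function(mat, idx_a, idx_b, pseudocount) {
  ma <- apply(mat[, idx_a, drop = FALSE], 1L, stats::median)
  mb <- apply(mat[, idx_b, drop = FALSE], 1L, stats::median)
  (ma + pseudocount) / (mb + pseudocount)
}

# Shared builder for per-gene DE tables.
de_table <- function(dataset, idx_a, idx_b, alpha, pseudocount, mode,
                     comparison, sex = NA_character_) {
  mat <- dataset$matrix
  if (mode == "approx") {
    wt <- row_wilcoxon(mat, idx_a, idx_b)
    W <- wt$statistic
    p <- wt$p
  } else {
    res <- lapply(seq_len(nrow(mat)), function(i) {
      wilcoxon_rank_sum(mat[i, idx_a], mat[i, idx_b], mode = mode)
    })
    W <- vapply(res, `[[`, numeric(1), "statistic")
    p <- vapply(res, `[[`, numeric(1), "p")
  }
  bh <- bh_adjust(p)
  fc <- row_median_fc(mat, idx_a, idx_b, pseudocount)
  out <- data.frame(
    gene_id = rownames(mat),
    chromosome = dataset$genes$chromosome,
    W = W, p = p, bh = bh, fc = fc,
    significant = bh < alpha,
    stringsAsFactors = FALSE
  )
  structure(out,
            class = c("de_result", "data.frame"),
            comparison = comparison, sex = sex, alpha = alpha,
            pseudocount = pseudocount, mode = mode,
            n_a = length(idx_a), n_b = length(idx_b),
            cancer_label = dataset$cancer_label)
}

#' Sex-differential expression within one tissue
#'
#' Per-gene Wilcoxon rank-sum tests of male versus female expression within
#' tumor samples (or, optionally, normal samples), with BH adjustment and
#' male-over-female median fold changes. The summary reports the number of
#' significant genes and its ratio to the sample size, the sample-size
#' normalization used to compare cohorts of different size.
#'
#' @param dataset an [expression_dataset()].
#' @param alpha BH significance threshold (default 0.05).
#' @param tissue which tissue compartment to test within (default `"tumor"`).
#' @param mode Wilcoxon mode passed down; `"approx"` (default) uses the
#'   vectorized normal approximation, `"auto"`/`"exact"` per-gene exact tests.
#' @param pseudocount see [median_fold_change()].
#' @return A `de_result` data.frame (gene_id, chromosome, W, p, bh, fc,
#'   significant) with the comparison metadata in attributes; `summary()`
#'   reports `n_significant`, `n_samples` and their ratio.
#' @export
sex_de <- function(dataset, alpha = 0.05, tissue = "tumor",
                   mode = c("approx", "auto", "exact"), pseudocount = 1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  mode <- match.arg(mode)
  in_tissue <- dataset$samples$tissue == tissue
  idx_m <- which(in_tissue & dataset$samples$sex == "male")
  idx_f <- which(in_tissue & dataset$samples$sex == "female")
  if (length(idx_m) < 2L || length(idx_f) < 2L) {
    stop(sprintf("need at least 2 %s samples of each sex (male=%d, female=%d)",
                 tissue, length(idx_m), length(idx_f)))
  }
  de_table(dataset, idx_m, idx_f, alpha, pseudocount, mode,
           comparison = sprintf("male_vs_female_%s", tissue))
}

#' Tumor-versus-normal differential expression within one sex
#'
#' The sex-stratified DE that feeds signature construction: per-gene Wilcoxon
#' rank-sum tests of tumor versus normal samples restricted to one sex, with
#' fold changes oriented tumor/normal (fc > 1 means over-expressed in tumor).
#' Cohorts with fewer than `min_per_arm` samples in either arm are refused,
#' mirroring the inclusion rule for tumor atlases with sparse normal data.
#'
#' @inheritParams sex_de
#' @param sex `"male"` or `"female"`.
#' @param min_per_arm minimum samples required in each of the tumor and
#'   normal arms (default 10).
#' @return A `de_result` data.frame; see [sex_de()].
#' @export
tumor_vs_normal_de <- function(dataset, sex, alpha = 0.05, min_per_arm = 10L,
                               mode = c("approx", "auto", "exact"),
                               pseudocount = 1) {
  stopifnot(inherits(dataset, "expression_dataset"))
  sex <- match.arg(sex, c("male", "female"))
  mode <- match.arg(mode)
  of_sex <- dataset$samples$sex == sex
  idx_t <- which(of_sex & dataset$samples$tissue == "tumor")
  idx_n <- which(of_sex & dataset$samples$tissue == "normal")
  if (length(idx_t) < min_per_arm) {
    stop(sprintf("%s tumor arm has %d samples, below the floor of %d",
                 sex, length(idx_t), min_per_arm))
  }
  if (length(idx_n) < min_per_arm) {
    stop(sprintf("%s normal arm has %d samples, below the floor of %d",
                 sex, length(idx_n), min_per_arm))
  }
  de_table(dataset, idx_t, idx_n, alpha, pseudocount, mode,
           comparison = "tumor_vs_normal", sex = sex)
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %s%s, %s: %d genes, %d significant at BH < %g\n",
              attr(x, "comparison"),
              if (!is.na(attr(x, "sex"))) paste0(" [", attr(x, "sex"), "]") else "",
              attr(x, "cancer_label"), nrow(x), sum(x$significant),
              attr(x, "alpha")))
  print.data.frame(utils::head(x[order(x$bh), ], 6L), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.de_result <- function(object, ...) {
  n_samples <- attr(object, "n_a") + attr(object, "n_b")
  out <- list(
    comparison = attr(object, "comparison"),
    sex = attr(object, "sex"),
    cancer_label = attr(object, "cancer_label"),
    alpha = attr(object, "alpha"),
    n_genes = nrow(object),
    n_significant = sum(object$significant),
    n_samples = n_samples,
    ratio = sum(object$significant) / n_samples
  )
  class(out) <- "summary.de_result"
  out
}

#' @export
print.summary.de_result <- function(x, ...) {
  cat(sprintf("%s (%s): %d/%d genes significant at BH < %g\n",
              x$comparison, x$cancer_label, x$n_significant, x$n_genes, x$alpha))
  cat(sprintf("sample size %d; significant/sample-size ratio %.4f\n",
              x$n_samples, x$ratio))
  invisible(x)
}

#' Sex-chromosome enrichment among significant genes
#'
#' Tests whether the proportion of significant genes on the sex chromosomes
#' exceeds the background proportion among all measured genes, by a
#' two-proportion chi-square test with continuity correction (or Fisher's
#' exact test on the corresponding 2x2 table).
#'
#' @param significant_genes character vector of gene ids, a subset of the
#'   dataset's gene universe.
#' @param dataset an [expression_dataset()] supplying chromosome annotations.
#' @param method `"chisq"` (default) or `"fisher"`.
#' @return List with `prop_significant`, `prop_background`, `p`, `method`
#'   and the underlying counts. An empty significant set yields `NA`
#'   proportions and p with a warning.
#' @export
sex_chromosome_enrichment <- function(significant_genes, dataset,
                                      method = c("chisq", "fisher")) {
  stopifnot(inherits(dataset, "expression_dataset"))
  method <- match.arg(method)
  universe <- dataset$genes$gene_id
  if (!all(significant_genes %in% universe)) {
    stop("significant_genes must be a subset of the dataset's genes")
  }
  on_sex <- dataset$genes$chromosome %in% c("X", "Y")
  n_all <- length(universe)
  k_all <- sum(on_sex)
  if (length(significant_genes) == 0L) {
    warning("empty significant set: enrichment undefined")
    return(list(prop_significant = NA_real_, prop_background = k_all / n_all,
                p = NA_real_, method = method,
                counts = c(sig_sex = 0L, n_sig = 0L, all_sex = k_all, n_all = n_all)))
  }
  sig_sex <- sum(significant_genes %in% universe[on_sex])
  n_sig <- length(significant_genes)
  p <- if (method == "chisq") {
    suppressWarnings(
      stats::prop.test(c(sig_sex, k_all), c(n_sig, n_all), correct = TRUE)$p.value
    )
  } else {
    stats::fisher.test(matrix(c(sig_sex, n_sig - sig_sex,
                                k_all - sig_sex, (n_all - n_sig) - (k_all - sig_sex)),
                              nrow = 2L))$p.value
  }
  list(prop_significant = sig_sex / n_sig, prop_background = k_all / n_all,
       p = p, method = method,
       counts = c(sig_sex = sig_sex, n_sig = n_sig, all_sex = k_all, n_all = n_all))
}

#' Fisher's method for combining p-values across cancers
#'
#' Aggregates per-cancer p-values for one gene into a pan-cancer p-value:
#' X = -2 * sum(log p) is referred to a chi-square distribution with 2k
#' degrees of freedom.
#'
#' @param p numeric vector of p-values in (0, 1\].
#' @param clamp_zero if `TRUE` (default), exact zeros (attainable from
#'   permutation p-values) are clamped to the smallest positive double with
#'   a warning instead of erroring.
#' @return The combined p-value.
#' @export
fisher_meta <- function(p, clamp_zero = TRUE) {
  if (length(p) == 0L || anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must be a nonempty vector in [0, 1]")
  }
  if (any(p == 0)) {
    if (!clamp_zero) stop("p-value of 0 supplied to Fisher's method")
    warning("p-value(s) of 0 clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  X <- -2 * sum(log(p))
  stats::pchisq(X, df = 2 * length(p), lower.tail = FALSE)
}
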