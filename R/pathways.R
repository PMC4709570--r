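#' Hypergeometric over-representation of a pathway
#'
#' Upper-tail hypergeometric probability of observing at least the seen
#' overlap between a pathway and a significant-gene list drawn from a fixed
#' universe — the standard over-representation analysis (ORA) used in place
#' of proprietary pathway tools. Computed with [stats::phyper()].
#'
#' @param pathway_genes,significant_genes character vectors, both subsets of
#'   `universe`.
#' @param universe character vector of all measured gene ids.
#' @return The enrichment p-value; an empty pathway returns 1.
#' @export
ora <- function(pathway_genes, significant_genes, universe) {
  if (length(universe) == 0L) stop("universe must be nonempty")
  if (anyDuplicated(universe)) stop("universe gene ids must be unique")
  pathway_genes <- unique(pathway_genes)
  significant_genes <- unique(significant_genes)
  if (!all(pathway_genes %in% universe)) {
    stop("pathway genes must be a subset of the universe")
  }
  if (!all(significant_genes %in% universe)) {
    stop("significant genes must be a subset of the universe")
  }
  if (length(pathway_genes) == 0L) return(1)
  k <- length(intersect(pathway_genes, significant_genes))
  stats::phyper(k - 1, length(pathway_genes),
                length(universe) - length(pathway_genes),
                length(significant_genes), lower.tail = FALSE)
}

#' Classify a pathway's sex pattern from per-sex enrichment p-values
#'
#' A pathway is `male_only` when enriched in males (p < alpha) but not in
#' females, `female_only` for the mirror case, `both` when enriched in both
#' sexes, `neither` otherwise. Boundary values (p equal to alpha) count as
#' not significant.
#'
#' @param p_male,p_female numeric vectors of per-sex enrichment p-values in
#'   \[0, 1\] (recycled to a common length).
#' @param alpha significance threshold (default 0.05).
#' @return Character vector of categories.
#' @export
classify_pathway_sex <- function(p_male, p_female, alpha = 0.05) {
  if (anyNA(p_male) || anyNA(p_female) ||
      any(c(p_male, p_female) < 0) || any(c(p_male, p_female) > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- p_male < alpha
  f <- p_female < alpha
  ifelse(m & f, "both",
         ifelse(m, "male_only",
                ifelse(f, "female_only", "neither")))
}

#' Discordance proportion of pathway enrichment between the sexes
#'
#' Among pathways significantly enriched in at least one sex, the fraction
#' enriched in exactly one sex:
#' `(n_male_only + n_female_only) / (n_male_only + n_female_only + n_both)`.
#'
#' @param n_male_only,n_female_only,n_both nonnegative counts, not all zero.
#' @return The proportion in \[0, 1\] (full precision; display rounds to two
#'   decimals). All-zero counts yield `NA` with a warning.
#' @export
discordance_proportion <- function(n_male_only, n_female_only, n_both) {
  counts <- c(n_male_only, n_female_only, n_both)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be nonnegative")
  total <- sum(counts)
  if (total == 0) {
    warning("no significantly enriched pathways: discordance undefined")
    return(NA_real_)
  }
  (n_male_only + n_female_only) / total
}

#' Sex-stratified pathway over-representation analysis
#'
#' Runs [ora()] for every gene set against the male and the female
#' significant-gene lists (typically the BH-significant genes of the two
#' sex-stratified tumor-versus-normal DE runs), classifies each pathway with
#' [classify_pathway_sex()], and summarizes the per-sex counts and the
#' discordance proportion.
#'
#' @param genesets named list of gene-id vectors (e.g. from [read_gmt()]).
#'   Genes outside the universe are dropped per set.
#' @param significant_male,significant_female character vectors of
#'   significant gene ids.
#' @param universe character vector of all measured gene ids.
#' @param alpha significance threshold for the per-sex calls.
#' @param adjust if `TRUE`, BH-adjust the enrichment p-values within each
#'   sex before classification (off by default; raw per-sex enrichment
#'   p-values are the conventional report for this analysis).
#' @return A `pathway_result` data.frame (pathway, n_genes, p_male,
#'   p_female, category) with summary counts and the discordance proportion
#'   in attributes; see `summary()`.
#' @export
pathway_enrichment <- function(genesets, significant_male, significant_female,
                               universe, alpha = 0.05, adjust = FALSE) {
  stopifnot(is.list(genesets), !is.null(names(genesets)))
  genesets <- lapply(genesets, intersect, universe)
  p_m <- vapply(genesets, ora, numeric(1),
                significant_genes = intersect(significant_male, universe),
                universe = universe)
  p_f <- vapply(genesets, ora, numeric(1),
                significant_genes = intersect(significant_female, universe),
                universe = universe)
  if (adjust) {
    p_m <- bh_adjust(p_m)
    p_f <- bh_adjust(p_f)
  }
  category <- classify_pathway_sex(p_m, p_f, alpha = alpha)
  out <- data.frame(pathway = names(genesets),
                    n_genes = lengths(genesets),
                    p_male = unname(p_m), p_female = unname(p_f),
                    category = category, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  counts <- c(male_only = sum(category == "male_only"),
              female_only = sum(category == "female_only"),
              both = sum(category == "both"),
              neither = sum(category == "neither"))
  structure(out, class = c("pathway_result", "data.frame"),
            alpha = alpha, adjusted = adjust, counts = counts,
            discordance = if (sum(counts[1:3]) > 0) {
              discordance_proportion(counts[["male_only"]],
                                     counts[["female_only"]],
                                     counts[["both"]])
            } else NA_real_)
}

#' @export
print.pathway_result <- function(x, ...) {
  counts <- attr(x, "counts")
  cat(sprintf("<pathway_result> %d pathways at alpha %g: male_only=%d female_only=%d both=%d neither=%d\n",
              nrow(x), attr(x, "alpha"), counts[["male_only"]],
              counts[["female_only"]], counts[["both"]], counts[["neither"]]))
  d <- attr(x, "discordance")
  if (!is.na(d)) cat(sprintf("discordance proportion: %.2f\n", d))
  print.data.frame(utils::head(x[order(pmin(x$p_male, x$p_female)), ], 6L),
                   row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.pathway_result <- function(object, ...) {
  counts <- attr(object, "counts")
  data.frame(n_male_only = counts[["male_only"]],
             n_female_only = counts[["female_only"]],
             n_both = counts[["both"]],
             n_neither = counts[["neither"]],
             discordance_proportion = attr(object, "discordance"))
}
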