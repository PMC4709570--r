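#' Expression dataset with sex, tissue and chromosome annotations
#'
#' The central data container of the package: a nonnegative gene-by-sample
#' matrix of normalized expression values together with per-sample sex
#' (`"male"`/`"female"`) and tissue (`"tumor"`/`"normal"`) labels and a
#' per-gene chromosome class (`"autosome"`, `"X"` or `"Y"`). This mirrors
#' the layout of normalized RNA-seq expression tables from tumor atlases,
#' where every sample carries clinical sex and a tumor/normal flag.
#'
#' @param matrix numeric gene-by-sample matrix, nonnegative, with unique
#'   rownames (gene ids) and colnames (sample ids).
#' @param sample_sex character vector (`"male"`/`"female"`), one per column.
#' @param sample_tissue character vector (`"tumor"`/`"normal"`), one per
#'   column.
#' @param gene_chromosome character vector (`"autosome"`/`"X"`/`"Y"`), one
#'   per row.
#' @param cancer_label free-text label for the cohort (e.g. `"LIHC"`).
#' @param gene_info optional data.frame of extra per-gene columns (e.g. the
#'   planted-truth annotations written by [generate_cohort()]); row order
#'   must match the matrix.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `matrix`, `samples` (data.frame: `sample_id`, `sex`, `tissue`),
#'   `genes` (data.frame: `gene_id`, `chromosome`, plus any extra columns)
#'   and `cancer_label`.
#' @seealso [generate_cohort()], [read_expression_dataset()],
#'   [write_expression_dataset()]
#' @export
expression_dataset <- function(matrix, sample_sex, sample_tissue,
                               gene_chromosome, cancer_label = "synthetic",
                               gene_info = NULL) {
  matrix <- as.matrix(matrix)
  if (!is.numeric(matrix)) stop("expression matrix must be numeric")
  if (anyNA(matrix)) stop("expression matrix contains missing values")
  if (any(matrix < 0)) stop("expression values must be nonnegative")
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(matrix))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(matrix))) stop("sample ids must be unique")

  sample_sex <- match_label(sample_sex, c("male", "female"), ncol(matrix), "sample_sex")
  sample_tissue <- match_label(sample_tissue, c("tumor", "normal"), ncol(matrix), "sample_tissue")
  gene_chromosome <- match_label(gene_chromosome, c("autosome", "X", "Y"),
                                 nrow(matrix), "gene_chromosome")

  genes <- data.frame(gene_id = rownames(matrix), chromosome = gene_chromosome,
                      stringsAsFactors = FALSE)
  if (!is.null(gene_info)) {
    stopifnot(nrow(gene_info) == nrow(matrix))
    extra <- gene_info[, setdiff(names(gene_info), names(genes)), drop = FALSE]
    genes <- cbind(genes, extra)
  }
  structure(
    list(
      matrix = matrix,
      samples = data.frame(sample_id = colnames(matrix), sex = sample_sex,
                           tissue = sample_tissue, stringsAsFactors = FALSE),
      genes = genes,
      cancer_label = as.character(cancer_label)
    ),
    class = "expression_dataset"
  )
}

match_label <- function(x, levels, n, what) {
  x <- as.character(x)
  if (length(x) != n) stop(sprintf("%s must have length %d", what, n))
  if (anyNA(x) || !all(x %in% levels)) {
    stop(sprintf("%s must be one of: %s (no missing values)",
                 what, paste(levels, collapse = ", ")))
  }
  x
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("<expression_dataset> %s: %d genes x %d samples\n",
              x$cancer_label, nrow(x$matrix), ncol(x$matrix)))
  tab <- table(sex = x$samples$sex, tissue = x$samples$tissue)
  print(tab)
  cat("chromosomes:",
      paste(sprintf("%s=%d", names(table(x$genes$chromosome)),
                    as.integer(table(x$genes$chromosome))), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
summary.expression_dataset <- function(object, ...) {
  out <- list(
    cancer_label = object$cancer_label,
    n_genes = nrow(object$matrix),
    n_samples = ncol(object$matrix),
    arms = table(object$samples$sex, object$samples$tissue),
    chromosome = table(object$genes$chromosome),
    expression_range = range(object$matrix)
  )
  class(out) <- "summary.expression_dataset"
  out
}

#' @export
print.summary.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset '%s': %d genes, %d samples\n",
              x$cancer_label, x$n_genes, x$n_samples))
  print(x$arms)
  cat(sprintf("expression range: [%.3g, %.3g]\n",
              x$expression_range[1], x$expression_range[2]))
  invisible(x)
}

#' Subset an expression dataset by samples and/or genes
#'
#' @param x an `expression_dataset`.
#' @param genes gene ids or logical/integer index over rows.
#' @param samples sample ids or logical/integer index over columns.
#' @param sex,tissue optional convenience filters applied on top of
#'   `samples`.
#' @return A new `expression_dataset`.
#' @export
subset_dataset <- function(x, genes = NULL, samples = NULL,
                           sex = NULL, tissue = NULL) {
  stopifnot(inherits(x, "expression_dataset"))
  keep_s <- rep(TRUE, ncol(x$matrix))
  if (!is.null(samples)) {
    if (is.character(samples)) {
      keep_s <- colnames(x$matrix) %in% samples
    } else {
      tmp <- rep(FALSE, ncol(x$matrix)); tmp[samples] <- TRUE; keep_s <- tmp
    }
  }
  if (!is.null(sex)) keep_s <- keep_s & x$samples$sex %in% sex
  if (!is.null(tissue)) keep_s <- keep_s & x$samples$tissue %in% tissue
  keep_g <- rep(TRUE, nrow(x$matrix))
  if (!is.null(genes)) {
    if (is.character(genes)) {
      keep_g <- rownames(x$matrix) %in% genes
    } else {
      tmp <- rep(FALSE, nrow(x$matrix)); tmp[genes] <- TRUE; keep_g <- tmp
    }
  }
  expression_dataset(
    x$matrix[keep_g, keep_s, drop = FALSE],
    x$samples$sex[keep_s], x$samples$tissue[keep_s],
    x$genes$chromosome[keep_g], x$cancer_label,
    gene_info = x$genes[keep_g, , drop = FALSE]
  )
}

#' Replace the sex labels of a dataset
#'
#' Used by the permutation machinery; validates that the multiset of labels
#' is unchanged so that male/female totals are held constant.
#'
#' @param x an `expression_dataset`.
#' @param sex new character vector of labels, a permutation of the old one.
#' @return The relabeled dataset.
#' @export
set_sex_labels <- function(x, sex) {
  stopifnot(inherits(x, "expression_dataset"))
  sex <- match_label(sex, c("male", "female"), ncol(x$matrix), "sex")
  lv <- c("male", "female")
  if (!all(table(factor(sex, lv)) == table(factor(x$samples$sex, lv)))) {
    stop("new sex labels must preserve the male/female totals")
  }
  x$samples$sex <- sex
  x
}
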