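#' Read and write GCT expression matrices
#'
#' Minimal reader/writer for the tab-delimited GCT v1.2 format used for
#' gene-by-sample matrices: a `#1.2` version line, a dimensions line, then a
#' header row (`Name`, `Description`, sample ids) and one row per gene.
#'
#' @param path file path.
#' @return `read_gct()` returns a list with `matrix` (numeric, gene ids as
#'   rownames, sample ids as colnames) and `description` (character vector,
#'   one entry per gene).
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || !startsWith(lines[[1L]], "#1.")) {
    stop("not a GCT file: ", path)
  }
  dims <- as.integer(strsplit(lines[[2L]], "\t")[[1L]][1:2])
  body <- utils::read.delim(text = lines[-(1:2)], check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (nrow(body) != dims[1L] || ncol(body) - 2L != dims[2L]) {
    stop("GCT dimension line disagrees with table body")
  }
  m <- as.matrix(body[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(body[[1L]])
  list(matrix = m, description = as.character(body[[2L]]))
}

#' @param matrix numeric matrix with row and column names.
#' @param description optional per-gene description column (defaults to the
#'   gene ids).
#' @rdname read_gct
#' @export
write_gct <- function(matrix, path, description = NULL) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)), !is.null(colnames(matrix)))
  description <- description %||% rownames(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(matrix), ncol(matrix), sep = "\t")), con)
  header <- paste(c("Name", "Description", colnames(matrix)), collapse = "\t")
  writeLines(header, con)
  body <- cbind(rownames(matrix), description,
                format(matrix, trim = TRUE, scientific = FALSE, digits = 10))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read and write GMT gene-set collections
#'
#' GMT is the standard one-set-per-line format: set name, description, then
#' member gene ids, tab-separated. Reading delegates to
#' [fgsea::gmtPathways()].
#'
#' @param path file path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional character vector parallel to `sets`.
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write / read an expression dataset as GCT plus TSV sidecars
#'
#' The matrix is written as `<stem>.gct`; sample annotations (id, sex,
#' tissue) as `<stem>.samples.tsv`; gene annotations (id, chromosome, and
#' any planted-truth columns from the synthetic generator) as
#' `<stem>.genes.tsv`.
#'
#' @param x an `expression_dataset`.
#' @param stem path stem (no extension).
#' @return `write_expression_dataset()` returns the stem invisibly;
#'   `read_expression_dataset()` returns the reconstructed
#'   `expression_dataset`.
#' @export
write_expression_dataset <- function(x, stem) {
  stopifnot(inherits(x, "expression_dataset"))
  write_gct(x$matrix, paste0(stem, ".gct"))
  write_tsv(x$samples, paste0(stem, ".samples.tsv"))
  genes <- x$genes
  genes$cancer_label <- NULL
  write_tsv(genes, paste0(stem, ".genes.tsv"))
  writeLines(x$cancer_label, paste0(stem, ".label.txt"))
  invisible(stem)
}

#' @rdname write_expression_dataset
#' @export
read_expression_dataset <- function(stem) {
  g <- read_gct(paste0(stem, ".gct"))
  samples <- read_tsv(paste0(stem, ".samples.tsv"))
  genes <- read_tsv(paste0(stem, ".genes.tsv"))
  label_path <- paste0(stem, ".label.txt")
  label <- if (file.exists(label_path)) readLines(label_path)[1L] else "unknown"
  stopifnot(identical(samples$sample_id, colnames(g$matrix)),
            identical(genes$gene_id, rownames(g$matrix)))
  # read.delim may coerce logical truth columns; normalize them back
  for (col in intersect(c("planted_sex_de"), names(genes))) {
    genes[[col]] <- as.logical(genes[[col]])
  }
  expression_dataset(g$matrix, samples$sex, samples$tissue, genes$chromosome,
                     cancer_label = label, gene_info = genes)
}
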