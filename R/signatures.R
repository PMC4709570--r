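#' Sensitivity/resistance signature pair
#'
#' A pair of ordered gene lists for one sex: the resistance signature (genes
#' over-expressed in tumor relative to normal, fc > 1) and the sensitivity
#' signature (genes over-expressed in normal tissue, fc < 1). These are the
#' down- and up-regulated query sets, respectively, for connectivity-map
#' scoring: a perturbagen that up-regulates the sensitivity set and
#' down-regulates the resistance set pushes the tumor profile back toward
#' normal.
#'
#' @param sensitivity_genes,resistance_genes ordered character vectors of
#'   gene ids (most extreme fold change first), disjoint, each at most
#'   `size_cap` long.
#' @param sex `"male"` or `"female"`.
#' @param cancer_label cohort label.
#' @param size_cap the cap applied at construction (default 250).
#' @return An object of class `signature_pair`.
#' @export
signature_pair <- function(sensitivity_genes, resistance_genes, sex,
                           cancer_label = "unknown", size_cap = 250L) {
  sensitivity_genes <- as.character(sensitivity_genes)
  resistance_genes <- as.character(resistance_genes)
  if (length(intersect(sensitivity_genes, resistance_genes)) > 0L) {
    stop("sensitivity and resistance signatures must be disjoint")
  }
  if (length(sensitivity_genes) > size_cap || length(resistance_genes) > size_cap) {
    stop("signature exceeds size_cap")
  }
  structure(
    list(sensitivity_genes = sensitivity_genes,
         resistance_genes = resistance_genes,
         sex = match.arg(sex, c("male", "female")),
         cancer_label = as.character(cancer_label),
         size_cap = as.integer(size_cap)),
    class = "signature_pair"
  )
}

#' @export
print.signature_pair <- function(x, ...) {
  cat(sprintf("<signature_pair> %s %s: %d sensitivity / %d resistance genes (cap %d)\n",
              x$cancer_label, x$sex, length(x$sensitivity_genes),
              length(x$resistance_genes), x$size_cap))
  invisible(x)
}

# Ranking used on both sides: extreme fold change first, ties broken by
# smaller BH value, then lexicographic gene id.
rank_side <- function(tab, decreasing) {
  key <- if (decreasing) -tab$fc else tab$fc
  tab[order(key, tab$bh, tab$gene_id), , drop = FALSE]
}

#' Build sensitivity/resistance signatures from a DE table
#'
#' From a tumor-versus-normal `de_result`, selects the significant genes
#' (BH < alpha) and takes the `size_cap` genes with the largest tumor/normal
#' fold change as the resistance signature and the `size_cap` genes with the
#' largest normal/tumor fold change (i.e. smallest tumor/normal fc, fc < 1)
#' as the sensitivity signature. Genes with fc exactly 1 favour neither
#' tissue and are never selected. If fewer than `size_cap` genes qualify on
#' a side, all qualifying genes are taken and a warning is emitted.
#'
#' @param de_table a `de_result` from [tumor_vs_normal_de()] (fold changes
#'   oriented tumor/normal).
#' @param sex sex of the signature; defaults to the DE table's.
#' @param size_cap maximum genes per side (default 250).
#' @param alpha significance threshold; defaults to the DE table's.
#' @param quiet suppress the under-cap/empty warnings (used inside the
#'   permutation loop, where shallow signatures are expected and recorded).
#' @return A [signature_pair()].
#' @export
build_signatures <- function(de_table, sex = attr(de_table, "sex"),
                             size_cap = 250L, alpha = attr(de_table, "alpha"),
                             quiet = FALSE) {
  stopifnot(inherits(de_table, "de_result"))
  if (is.null(sex) || is.na(sex)) stop("sex must be supplied")
  sig <- de_table[de_table$bh < alpha, , drop = FALSE]
  res_tab <- rank_side(sig[sig$fc > 1, , drop = FALSE], decreasing = TRUE)
  sens_tab <- rank_side(sig[sig$fc < 1, , drop = FALSE], decreasing = FALSE)
  res <- utils::head(res_tab$gene_id, size_cap)
  sens <- utils::head(sens_tab$gene_id, size_cap)
  if (!quiet) {
    if (nrow(sig) == 0L) {
      warning("no significant genes: empty signature pair")
    } else {
      if (length(res) < size_cap) {
        warning(sprintf("resistance signature has only %d genes (cap %d)",
                        length(res), size_cap))
      }
      if (length(sens) < size_cap) {
        warning(sprintf("sensitivity signature has only %d genes (cap %d)",
                        length(sens), size_cap))
      }
    }
  }
  signature_pair(sens, res, sex = sex,
                 cancer_label = attr(de_table, "cancer_label") %||% "unknown",
                 size_cap = size_cap)
}

#' Pan-cancer signatures from several per-cancer DE tables
#'
#' Combines per-cancer tumor-versus-normal DE tables over a shared gene
#' universe: per-gene significance comes from Fisher-combined p-values
#' (BH-adjusted), and ranking uses the geometric mean of the per-cancer
#' tumor/normal fold changes. With a single table this reduces exactly to
#' [build_signatures()].
#'
#' @param de_tables list of `de_result` objects for one sex over identical
#'   gene universes.
#' @inheritParams build_signatures
#' @return A [signature_pair()] labelled `"pan-cancer"`.
#' @export
build_pan_cancer_signatures <- function(de_tables, sex = NULL,
                                        size_cap = 250L, alpha = 0.05,
                                        quiet = FALSE) {
  stopifnot(is.list(de_tables), length(de_tables) > 0L)
  genes <- de_tables[[1L]]$gene_id
  for (d in de_tables) {
    if (!identical(d$gene_id, genes)) {
      stop("all DE tables must share one gene universe (same genes, same order)")
    }
  }
  sex <- sex %||% attr(de_tables[[1L]], "sex")
  pmat <- vapply(de_tables, `[[`, numeric(length(genes)), "p")
  fmat <- vapply(de_tables, `[[`, numeric(length(genes)), "fc")
  pmat <- matrix(pmat, nrow = length(genes))
  fmat <- matrix(fmat, nrow = length(genes))
  combined_p <- apply(pmat, 1L, fisher_meta)
  bh <- bh_adjust(combined_p)
  gm_fc <- exp(rowMeans(log(fmat)))
  combined <- structure(
    data.frame(gene_id = genes,
               chromosome = de_tables[[1L]]$chromosome,
               W = NA_real_, p = combined_p, bh = bh, fc = gm_fc,
               significant = bh < alpha, stringsAsFactors = FALSE),
    class = c("de_result", "data.frame"),
    comparison = "tumor_vs_normal_pan_cancer", sex = sex, alpha = alpha,
    n_a = sum(vapply(de_tables, attr, numeric(1), "n_a")),
    n_b = sum(vapply(de_tables, attr, numeric(1), "n_b")),
    cancer_label = "pan-cancer"
  )
  build_signatures(combined, sex = sex, size_cap = size_cap, alpha = alpha,
                   quiet = quiet)
}

#' Write a pair of signature pairs (both sexes) as GMT
#'
#' Emits the four query sets (`<label>_<sex>_SENS` / `<label>_<sex>_RES`)
#' in GMT format.
#'
#' @param signatures list with elements `male` and `female`, each a
#'   [signature_pair()].
#' @param path output GMT path.
#' @export
write_signatures_gmt <- function(signatures, path) {
  stopifnot(all(c("male", "female") %in% names(signatures)))
  sets <- list()
  for (sx in c("male", "female")) {
    sp <- signatures[[sx]]
    stopifnot(inherits(sp, "signature_pair"))
    sets[[sprintf("%s_%s_SENS", sp$cancer_label, sx)]] <- sp$sensitivity_genes
    sets[[sprintf("%s_%s_RES", sp$cancer_label, sx)]] <- sp$resistance_genes
  }
  write_gmt(sets, path)
}

# Drop signature genes absent from a perturbagen library's universe,
# reporting what was dropped. Returns the filtered pair.
intersect_with_universe <- function(pair, universe, quiet = FALSE) {
  missing <- setdiff(c(pair$sensitivity_genes, pair$resistance_genes), universe)
  if (length(missing) > 0L && !quiet) {
    warning(sprintf("%d signature gene(s) absent from the library universe dropped: %s",
                    length(missing),
                    paste(utils::head(missing, 5L), collapse = ", ")))
  }
  pair$sensitivity_genes <- intersect(pair$sensitivity_genes, universe)
  pair$resistance_genes <- intersect(pair$resistance_genes, universe)
  pair
}
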