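#' Perturbagen reference library of rank profiles
#'
#' A connectivity-map reference library: for every perturbagen replicate, a
#' complete ranking of a fixed gene universe (rank 1 = the gene most
#' up-regulated by the perturbagen). Profiles are stored as an integer
#' matrix (genes x replicate-profiles) of ranks; the manifest maps profile
#' columns to perturbagens, replicates, reagent class, and (for synthetic
#' libraries) the planted perturbagen type.
#'
#' @param universe character vector of gene ids (row order of `profiles`).
#' @param profiles integer matrix, one column per replicate profile; every
#'   column must be a permutation of `1:length(universe)`.
#' @param manifest data.frame with columns `profile_id`, `perturbagen_id`,
#'   `replicate`, `reagent_class` and optionally `planted_type`.
#' @return An object of class `perturbagen_library`.
#' @export
perturbagen_library <- function(universe, profiles, manifest) {
  universe <- as.character(universe)
  profiles <- as.matrix(profiles)
  storage.mode(profiles) <- "integer"
  n <- length(universe)
  if (nrow(profiles) != n) stop("profiles must have one row per universe gene")
  if (anyDuplicated(universe)) stop("universe gene ids must be unique")
  ok <- apply(profiles, 2L, function(col) identical(sort(unname(col)), seq_len(n)))
  if (!all(ok)) stop("every profile must be a complete ranking (permutation) of the universe")
  need <- c("profile_id", "perturbagen_id", "replicate", "reagent_class")
  if (!all(need %in% names(manifest))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "))
  }
  if (nrow(manifest) != ncol(profiles)) {
    stop("manifest must have one row per profile column")
  }
  if (!("planted_type" %in% names(manifest))) manifest$planted_type <- "null"
  rownames(profiles) <- universe
  colnames(profiles) <- manifest$profile_id
  structure(list(universe = universe, profiles = profiles,
                 manifest = manifest),
            class = "perturbagen_library")
}

#' @export
print.perturbagen_library <- function(x, ...) {
  n_pert <- length(unique(x$manifest$perturbagen_id))
  cat(sprintf("<perturbagen_library> %d perturbagens, %d profiles, %d-gene universe\n",
              n_pert, ncol(x$profiles), length(x$universe)))
  if (any(x$manifest$planted_type != "null")) {
    tt <- table(x$manifest$planted_type[!duplicated(x$manifest$perturbagen_id)])
    cat("planted types:", paste(sprintf("%s=%d", names(tt), as.integer(tt)),
                                collapse = " "), "\n")
  }
  invisible(x)
}

#' Write / read a perturbagen library as GCT plus a TSV manifest
#'
#' Rank profiles go to `<stem>.gct` (values are integer ranks), the manifest
#' to `<stem>.manifest.tsv`.
#'
#' @param library a [perturbagen_library()].
#' @param stem path stem.
#' @export
write_perturbagen_library <- function(library, stem) {
  stopifnot(inherits(library, "perturbagen_library"))
  write_gct(library$profiles + 0, paste0(stem, ".gct"))
  write_tsv(library$manifest, paste0(stem, ".manifest.tsv"))
  invisible(stem)
}

#' @rdname write_perturbagen_library
#' @export
read_perturbagen_library <- function(stem) {
  g <- read_gct(paste0(stem, ".gct"))
  manifest <- read_tsv(paste0(stem, ".manifest.tsv"))
  perturbagen_library(rownames(g$matrix), g$matrix, manifest)
}

#' Kolmogorov-Smirnov enrichment of a gene set in a rank profile
#'
#' The classic connectivity-map running-sum statistic: walking down the
#' ranking, the sum steps up by 1/n at each query ("hit") gene and down by
#' 1/(N-n) at each non-query gene; the enrichment score is the signed
#' extreme deviation of the walk. ES near +1 means the set sits at the top
#' of the ranking (up-regulated by the perturbagen), near -1 at the bottom.
#'
#' @param query_set character vector of gene ids, nonempty, a subset of the
#'   profile's universe.
#' @param profile named integer rank vector over the universe (rank 1 =
#'   most up-regulated), e.g. a column of a library's `profiles` matrix
#'   combined with its rownames.
#' @return The enrichment score in \[-1, 1\]. A query equal to the whole
#'   universe is degenerate and returns 0 with a warning.
#' @export
enrichment_score <- function(query_set, profile) {
  if (length(query_set) == 0L) stop("query set must be nonempty")
  if (is.null(names(profile))) stop("profile must be a named rank vector")
  absent <- setdiff(query_set, names(profile))
  if (length(absent) > 0L) {
    stop("query genes absent from universe: ",
         paste(utils::head(absent, 10L), collapse = ", "))
  }
  N <- length(profile)
  pos <- sort(unname(profile[query_set]))
  es_from_positions(pos, N)
}

# Closed-form extremes of the hit/miss walk given sorted hit positions.
# The walk's maximum is attained just after some hit, its minimum just
# before some hit.
es_from_positions <- function(pos, N) {
  n <- length(pos)
  if (n == N) {
    warning("query equals the whole universe: enrichment undefined, returning 0")
    return(0)
  }
  i <- seq_len(n)
  after <- i / n - (pos - i) / (N - n)
  before <- (i - 1) / n - (pos - 1 - (i - 1)) / (N - n)
  up <- max(after)
  down <- min(before)
  if (up >= -down) up else down
}

#' Weighted two-sided connectivity score (WTCS) of an up/down query pair
#'
#' Combines the enrichment of the up set and the down set in one profile:
#' `raw = (ES(up) - ES(down)) / 2` when the two component scores have
#' opposite signs, and 0 otherwise (a profile that moves both sets the same
#' way is not connective). A perturbagen that places the up set at the top
#' and the down set at the bottom of its ranking scores near +1.
#'
#' @param up_set,down_set disjoint nonempty gene sets within the universe.
#' @inheritParams enrichment_score
#' @return The raw connectivity score in \[-1, 1\].
#' @export
wtcs <- function(up_set, down_set, profile) {
  if (length(intersect(up_set, down_set)) > 0L) {
    stop("up and down query sets must be disjoint")
  }
  es_up <- enrichment_score(up_set, profile)
  es_down <- enrichment_score(down_set, profile)
  if (es_up * es_down < 0) (es_up - es_down) / 2 else 0
}

# Raw WTCS for every profile column of a library. up/down are gene id
# vectors already guaranteed inside the universe. Matrix-vectorized: the
# walk extremes have a closed form in the sorted hit positions, so each
# query set is handled as one genes-x-profiles slice.
wtcs_profiles <- function(library, up_set, down_set) {
  if (length(intersect(up_set, down_set)) > 0L) {
    stop("up and down query sets must be disjoint")
  }
  absent <- setdiff(c(up_set, down_set), library$universe)
  if (length(absent) > 0L) {
    stop("query genes absent from universe: ",
         paste(utils::head(absent, 10L), collapse = ", "))
  }
  N <- length(library$universe)
  eu <- es_columns(library$profiles[match(up_set, library$universe), ,
                                    drop = FALSE], N)
  ed <- es_columns(library$profiles[match(down_set, library$universe), ,
                                    drop = FALSE], N)
  unname(ifelse(eu * ed < 0, (eu - ed) / 2, 0))
}

# Signed walk extremes for one query set across all profile columns.
# pos_mat: hit positions (rows = query genes, cols = profiles), unsorted.
es_columns <- function(pos_mat, N) {
  n <- nrow(pos_mat)
  if (n == N) {
    warning("query equals the whole universe: enrichment undefined, returning 0")
    return(numeric(ncol(pos_mat)))
  }
  P <- apply(pos_mat, 2L, sort)
  if (is.null(dim(P))) P <- matrix(P, nrow = n)
  i <- seq_len(n)
  after <- i / n - (P - i) / (N - n)     # walk just after each hit
  before <- (i - 1) / n - (P - 1 - (i - 1)) / (N - n)  # just before
  up <- apply(after, 2L, max)
  down <- apply(before, 2L, min)
  ifelse(up >= -down, up, down)
}

#' Normalize and aggregate raw connectivity scores over replicates
#'
#' Averages raw WTCS over each perturbagen's replicates, then maps the means
#' onto the \[-100, 100\] connectivity-score scale by a signed percentile
#' transform: within each sign class, `score = sign * 100 * percentile of
#' |mean raw|` (ties share the mean rank); a mean of exactly 0 scores 0.
#' The transform is monotone in the mean raw score within each sign class,
#' and the library's strongest positive perturbagen scores exactly 100.
#'
#' @param raw named numeric vector of raw scores, one per profile, in
#'   manifest order.
#' @param library the [perturbagen_library()] the scores were computed on.
#' @return data.frame with one row per perturbagen: `perturbagen_id`,
#'   `reagent_class`, `planted_type`, `n_replicates`, `mean_raw`, `score`.
#' @export
normalize_and_aggregate <- function(raw, library) {
  stopifnot(inherits(library, "perturbagen_library"),
            length(raw) == nrow(library$manifest))
  mono <- library$manifest[!duplicated(library$manifest$perturbagen_id),
                           c("perturbagen_id", "reagent_class", "planted_type")]
  mean_raw <- tapply(raw, library$manifest$perturbagen_id, mean)
  n_rep <- tapply(raw, library$manifest$perturbagen_id, length)
  mono$mean_raw <- as.numeric(mean_raw[mono$perturbagen_id])
  mono$n_replicates <- as.integer(n_rep[mono$perturbagen_id])
  if (nrow(mono) == 1L) {
    warning("single-perturbagen library: percentile normalization is degenerate")
  }
  mono$score <- signed_percentile_score(mono$mean_raw)
  rownames(mono) <- NULL
  mono[, c("perturbagen_id", "reagent_class", "planted_type",
           "n_replicates", "mean_raw", "score")]
}

signed_percentile_score <- function(mean_raw) {
  score <- numeric(length(mean_raw))
  for (s in c(-1, 1)) {
    idx <- which(sign(mean_raw) == s)
    if (length(idx) > 0L) {
      pct <- rank(abs(mean_raw[idx]), ties.method = "average") / length(idx)
      score[idx] <- s * 100 * pct
    }
  }
  score
}

#' Score a whole library against one up/down query
#'
#' Computes the raw WTCS of every replicate profile for the query defined by
#' a signature pair (sensitivity genes as the up set, resistance genes as
#' the down set), then aggregates and normalizes per perturbagen. Signature
#' genes missing from the library universe are dropped with a warning
#' before querying.
#'
#' @param library a [perturbagen_library()].
#' @param signature a [signature_pair()]; alternatively supply `up_set` and
#'   `down_set` directly.
#' @param up_set,down_set explicit query sets (used when `signature` is
#'   NULL).
#' @param quiet suppress the universe-intersection warning.
#' @return A `connectivity_result` data.frame (see
#'   [normalize_and_aggregate()]) with the query metadata in attributes.
#' @export
score_library <- function(library, signature = NULL, up_set = NULL,
                          down_set = NULL, quiet = FALSE) {
  stopifnot(inherits(library, "perturbagen_library"))
  if (!is.null(signature)) {
    stopifnot(inherits(signature, "signature_pair"))
    signature <- intersect_with_universe(signature, library$universe, quiet = quiet)
    up_set <- signature$sensitivity_genes
    down_set <- signature$resistance_genes
  }
  if (length(up_set) == 0L || length(down_set) == 0L) {
    stop("empty query: both up and down sets must be nonempty")
  }
  raw <- wtcs_profiles(library, up_set, down_set)
  out <- normalize_and_aggregate(raw, library)
  structure(out, class = c("connectivity_result", "data.frame"),
            sex = if (!is.null(signature)) signature$sex else NA_character_,
            cancer_label = if (!is.null(signature)) signature$cancer_label else NA_character_,
            n_up = length(up_set), n_down = length(down_set))
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("<connectivity_result>%s %d perturbagens (query: %d up / %d down genes)\n",
              if (!is.na(attr(x, "sex"))) paste0(" ", attr(x, "sex")) else "",
              nrow(x), attr(x, "n_up"), attr(x, "n_down")))
  ord <- order(-x$score)
  print.data.frame(utils::head(x[ord, ], 6L), row.names = FALSE, digits = 4)
  invisible(x)
}
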