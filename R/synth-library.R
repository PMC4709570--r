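#' Configuration for the synthetic perturbagen library generator
#'
#' Describes a reference library of ranked perturbagen profiles with
#' optional planted perturbagens engineered to reverse one or both sexes'
#' tumor signatures. `mimic_strength` is a continuous dial from pure noise
#' (0: every perturbagen, planted or not, is an exchangeable uniform random
#' ranking) to perfect reversal (1: the targeted signature genes occupy the
#' exact extremes of the ranking).
#'
#' @param n_perturbagens total number of perturbagens.
#' @param n_replicates replicate profiles per perturbagen (>= 1), standing
#'   in for the cell-line/dose replicates a real connectivity-map library
#'   averages over.
#' @param planted data.frame with columns `perturbagen_id` and `type`
#'   (`"I"`, `"II"`, `"III"` or `"null"`), or `NULL` for an all-null
#'   library. Ids must be among `sprintf("PERT%04d", 1:n_perturbagens)`.
#'   An optional `mimic` column overrides `mimic_strength` per perturbagen
#'   (e.g. to model reagents of different potency).
#' @param mimic_strength fraction in \[0, 1\].
#' @param prop_chemical fraction of perturbagens labelled `"chemical"` in
#'   the manifest (the rest are `"genetic"`).
#' @param seed integer seed.
#' @return A validated list of class `library_config`.
#' @export
library_config <- function(n_perturbagens = 100L, n_replicates = 3L,
                           planted = NULL, mimic_strength = 0.9,
                           prop_chemical = 0.5, seed = 1L) {
  cfg <- list(n_perturbagens = as.integer(n_perturbagens),
              n_replicates = as.integer(n_replicates),
              planted = planted, mimic_strength = mimic_strength,
              prop_chemical = prop_chemical, seed = as.integer(seed))
  if (cfg$n_perturbagens < 1L) stop("library configuration error: need >= 1 perturbagen")
  if (cfg$n_replicates < 1L) stop("library configuration error: n_replicates must be >= 1")
  if (!is.numeric(cfg$mimic_strength) || cfg$mimic_strength < 0 || cfg$mimic_strength > 1) {
    stop("library configuration error: mimic_strength must lie in [0, 1]")
  }
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("perturbagen_id", "type") %in% names(planted)))
    if (!all(planted$type %in% c("I", "II", "III", "null"))) {
      stop("library configuration error: planted types must be I, II, III or null")
    }
    ids <- sprintf("PERT%04d", seq_len(cfg$n_perturbagens))
    if (!all(planted$perturbagen_id %in% ids)) {
      stop("library configuration error: planted ids outside PERT0001..",
           sprintf("PERT%04d", cfg$n_perturbagens))
    }
    if (anyDuplicated(planted$perturbagen_id)) {
      stop("library configuration error: duplicated planted ids")
    }
    if ("mimic" %in% names(planted) &&
        (any(planted$mimic < 0) || any(planted$mimic > 1))) {
      stop("library configuration error: per-perturbagen mimic must lie in [0, 1]")
    }
  }
  structure(cfg, class = "library_config")
}

#' Generate a seeded synthetic perturbagen library
#'
#' Builds a [perturbagen_library()] over a gene universe. Null perturbagens
#' are uniform random rankings. A planted Type I perturbagen reverses the
#' male tumor signature (male sensitivity genes driven toward the top of
#' the ranking, male resistance genes toward the bottom) while
#' anti-reversing the female signature (female sensitivity at the bottom,
#' female resistance at the top); Type II is the mirror image; Type III
#' reverses both sexes' signatures. Rankings are produced by interpolating
#' between a target ranking with the signature genes at the extremes and an
#' independent uniform random ranking, with weight `mimic_strength` on the
#' target — so strength 0 is exchangeable with null and strength 1 places
#' the target sets at the exact extremes.
#'
#' @param config a [library_config()].
#' @param signatures list with elements `male` and `female`, each a
#'   [signature_pair()] over `universe` (required when any non-null
#'   perturbagen is planted).
#' @param universe character vector of gene ids.
#' @return A [perturbagen_library()].
#' @export
generate_library <- function(config, signatures = NULL, universe) {
  stopifnot(inherits(config, "library_config"))
  universe <- as.character(universe)
  n <- length(universe)
  if (n < 2L) stop("universe must contain at least 2 genes")

  planted <- config$planted
  types <- stats::setNames(rep("null", config$n_perturbagens),
                           sprintf("PERT%04d", seq_len(config$n_perturbagens)))
  mimics <- stats::setNames(rep(config$mimic_strength, config$n_perturbagens),
                            names(types))
  if (!is.null(planted)) {
    types[planted$perturbagen_id] <- planted$type
    if ("mimic" %in% names(planted)) {
      mimics[planted$perturbagen_id] <- planted$mimic
    }
  }
  if (any(types != "null")) {
    if (is.null(signatures) || !all(c("male", "female") %in% names(signatures))) {
      stop("planted perturbagens need male and female target signatures")
    }
    sig_genes <- unlist(lapply(signatures, function(s) {
      c(s$sensitivity_genes, s$resistance_genes)
    }), use.names = FALSE)
    absent <- setdiff(sig_genes, universe)
    if (length(absent) > 0L) {
      stop("signature genes absent from universe: ",
           paste(utils::head(absent, 10L), collapse = ", "))
    }
  }

  # additive top(+1)/bottom(-1) bias per gene for each planted type
  bias_for <- function(type) {
    b <- numeric(n)
    if (type == "null") return(b)
    add <- function(genes, delta) {
      idx <- match(genes, universe)
      b[idx] <<- b[idx] + delta
    }
    ms <- signatures$male; fs <- signatures$female
    switch(type,
      I = { add(ms$sensitivity_genes, 1); add(ms$resistance_genes, -1)
            add(fs$sensitivity_genes, -1); add(fs$resistance_genes, 1) },
      II = { add(ms$sensitivity_genes, -1); add(ms$resistance_genes, 1)
             add(fs$sensitivity_genes, 1); add(fs$resistance_genes, -1) },
      III = { add(ms$sensitivity_genes, 1); add(ms$resistance_genes, -1)
              add(fs$sensitivity_genes, 1); add(fs$resistance_genes, -1) }
    )
    b
  }

  with_seed(config$seed, {
    pert_ids <- names(types)
    n_chem <- round(config$prop_chemical * config$n_perturbagens)
    reagent <- rep("genetic", config$n_perturbagens)
    if (n_chem > 0) reagent[sample.int(config$n_perturbagens, n_chem)] <- "chemical"

    n_prof <- config$n_perturbagens * config$n_replicates
    profiles <- matrix(0L, nrow = n, ncol = n_prof)
    manifest <- data.frame(
      profile_id = character(n_prof), perturbagen_id = character(n_prof),
      replicate = integer(n_prof), reagent_class = character(n_prof),
      planted_type = character(n_prof), stringsAsFactors = FALSE
    )
    col <- 0L
    for (k in seq_len(config$n_perturbagens)) {
      b <- bias_for(types[[k]])
      m <- mimics[[k]]
      for (r in seq_len(config$n_replicates)) {
        col <- col + 1L
        # target ranking: top-band genes first, random order within bands
        target_rank <- order(order(-b, stats::runif(n)))
        random_rank <- sample.int(n)
        latent <- m * target_rank + (1 - m) * random_rank
        profiles[, col] <- rank(latent, ties.method = "random")
        manifest$profile_id[col] <- sprintf("%s_r%d", pert_ids[k], r)
        manifest$perturbagen_id[col] <- pert_ids[k]
        manifest$replicate[col] <- r
        manifest$reagent_class[col] <- reagent[k]
        manifest$planted_type[col] <- types[[k]]
      }
    }
    perturbagen_library(universe, profiles, manifest)
  })
}
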