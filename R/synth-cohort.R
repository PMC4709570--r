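#' Configuration for the synthetic cohort generator
#'
#' Describes a four-arm (sex x tissue) expression cohort with planted
#' effects. Genes are partitioned into autosomal, X and Y classes; planted
#' sex-differential genes are drawn preferentially from the X chromosome
#' (sex-linked expression in real tumors concentrates on the sex
#' chromosomes), and planted tumor-versus-normal genes from the autosomes.
#' All planted effects are multiplicative fold changes on a log-normal
#' expression model, which keeps values nonnegative like normalized RNA-seq
#' counts and is the natural noise model for the rank-based tests downstream.
#'
#' @param n_genes total number of genes.
#' @param n_x,n_y number of X- and Y-linked genes; the remainder is
#'   autosomal.
#' @param n_male_tumor,n_female_tumor,n_male_normal,n_female_normal sample
#'   counts per arm (normal arms may be 0 for tumor-only cohorts).
#' @param n_sex_de number of planted sex-differential genes (beyond the
#'   intrinsic Y-linked and XIST-like markers).
#' @param n_tumor_de_shared,n_tumor_de_male_only,n_tumor_de_female_only
#'   numbers of planted tumor-vs-normal genes affected in both sexes, males
#'   only, or females only.
#' @param effect_size multiplicative fold change of planted sex-DE and
#'   sex-specific tumor effects (> 1); planted genes alternate up/down
#'   directions.
#' @param effect_size_shared fold change of the shared (both-sex) tumor
#'   effects; defaults to `effect_size`. Setting it below `effect_size`
#'   emulates cohorts where the sex-specific component of the tumor program
#'   is the strongest signal.
#' @param dispersion standard deviation of the log-normal noise on the log
#'   scale (default 0.5, a realistic biological coefficient of variation for
#'   bulk expression).
#' @param xist_like if `TRUE` (default) one designated X gene behaves like
#'   XIST: strongly female-high in tumors but sex-concordant in normal
#'   tissue, reproducing the qualitative tumor/normal contrast in which XIST
#'   separates the sexes in tumors only.
#' @param y_female_level expression level of Y-linked genes in females
#'   (near zero; default 0.05 versus a median baseline around 100).
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 2000L, n_x = 60L, n_y = 20L,
                          n_male_tumor = 50L, n_female_tumor = 50L,
                          n_male_normal = 0L, n_female_normal = 0L,
                          n_sex_de = 0L,
                          n_tumor_de_shared = 0L,
                          n_tumor_de_male_only = 0L,
                          n_tumor_de_female_only = 0L,
                          effect_size = 4, effect_size_shared = NULL,
                          dispersion = 0.5,
                          xist_like = TRUE, y_female_level = 0.05,
                          seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_x = as.integer(n_x),
              n_y = as.integer(n_y),
              n_male_tumor = as.integer(n_male_tumor),
              n_female_tumor = as.integer(n_female_tumor),
              n_male_normal = as.integer(n_male_normal),
              n_female_normal = as.integer(n_female_normal),
              n_sex_de = as.integer(n_sex_de),
              n_tumor_de_shared = as.integer(n_tumor_de_shared),
              n_tumor_de_male_only = as.integer(n_tumor_de_male_only),
              n_tumor_de_female_only = as.integer(n_tumor_de_female_only),
              effect_size = effect_size,
              effect_size_shared = effect_size_shared %||% effect_size,
              dispersion = dispersion,
              xist_like = isTRUE(xist_like),
              y_female_level = y_female_level, seed = as.integer(seed))
  counts <- unlist(cfg[c("n_genes", "n_x", "n_y", "n_male_tumor",
                         "n_female_tumor", "n_male_normal", "n_female_normal",
                         "n_sex_de", "n_tumor_de_shared",
                         "n_tumor_de_male_only", "n_tumor_de_female_only")])
  if (anyNA(counts) || any(counts < 0)) {
    stop("cohort configuration error: all counts must be nonnegative")
  }
  cfg$n_autosomal <- cfg$n_genes - cfg$n_x - cfg$n_y
  if (cfg$n_autosomal < 0) {
    stop("cohort configuration error: n_x + n_y exceeds n_genes")
  }
  n_planted <- cfg$n_sex_de + cfg$n_tumor_de_shared +
    cfg$n_tumor_de_male_only + cfg$n_tumor_de_female_only
  if (n_planted > cfg$n_genes) {
    stop("cohort configuration error: planted gene counts exceed n_genes")
  }
  if (!is.numeric(cfg$effect_size) || cfg$effect_size <= 1) {
    stop("cohort configuration error: effect_size must be > 1")
  }
  if (!is.numeric(cfg$effect_size_shared) || cfg$effect_size_shared <= 1) {
    stop("cohort configuration error: effect_size_shared must be > 1")
  }
  if (cfg$dispersion <= 0) stop("cohort configuration error: dispersion must be > 0")
  if (cfg$y_female_level <= 0) stop("cohort configuration error: y_female_level must be > 0")
  structure(cfg, class = "cohort_config")
}

#' Generate a seeded synthetic expression cohort
#'
#' Simulates a gene-by-sample matrix with the statistical structure the
#' downstream analyses assume: nonnegative log-normal expression; Y-linked
#' genes near zero in females; an optional XIST-like gene high in female
#' tumors but concordant between sexes in normal tissue; planted
#' sex-differential and (sex-stratified) tumor-versus-normal effects at a
#' configured multiplicative fold change. The gene annotation table records
#' the chromosome class and every planted truth so recovery can be scored.
#'
#' @param config a [cohort_config()].
#' @param cancer_label label stored on the dataset (default `"SYN"`).
#' @return An [expression_dataset()] whose `genes` table carries the columns
#'   `marker` (`""`, `"xist_like"` or `"y_marker"`), `planted_sex_de`,
#'   `sex_de_direction`, `tumor_de_class` and `tumor_de_direction`.
#' @export
generate_cohort <- function(config, cancer_label = "SYN") {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    gene_ids <- character(0)
    chrom <- character(0)
    if (config$n_autosomal > 0) {
      gene_ids <- c(gene_ids, sprintf("A%05d", seq_len(config$n_autosomal)))
      chrom <- c(chrom, rep("autosome", config$n_autosomal))
    }
    x_ids <- if (config$n_x > 0) sprintf("X%04d", seq_len(config$n_x)) else character(0)
    if (config$xist_like && config$n_x > 0) x_ids[1L] <- "XIST_like"
    y_ids <- if (config$n_y > 0) sprintf("Y%03d", seq_len(config$n_y)) else character(0)
    y_marker_names <- c("ZFY_like", "EIF1AY_like", "DDX3Y_like", "RPS4Y1_like")
    if (config$n_y > 0) {
      k <- min(config$n_y, length(y_marker_names))
      y_ids[seq_len(k)] <- y_marker_names[seq_len(k)]
    }
    gene_ids <- c(gene_ids, x_ids, y_ids)
    chrom <- c(chrom, rep("X", config$n_x), rep("Y", config$n_y))

    arms <- list(
      c("male", "tumor", config$n_male_tumor, "MT"),
      c("female", "tumor", config$n_female_tumor, "FT"),
      c("male", "normal", config$n_male_normal, "MN"),
      c("female", "normal", config$n_female_normal, "FN")
    )
    sex <- tissue <- sample_ids <- character(0)
    for (a in arms) {
      n <- as.integer(a[[3]])
      if (n > 0) {
        sex <- c(sex, rep(a[[1]], n))
        tissue <- c(tissue, rep(a[[2]], n))
        sample_ids <- c(sample_ids, sprintf("%s%03d", a[[4]], seq_len(n)))
      }
    }
    n_samples <- length(sample_ids)
    if (n_samples == 0L) stop("cohort configuration error: no samples")

    is_female <- sex == "female"
    is_tumor <- tissue == "tumor"

    # per-gene baseline on the log scale (median expression ~ 100)
    base_mu <- stats::rnorm(config$n_genes, mean = log(100), sd = 1)
    log_mu <- matrix(base_mu, nrow = config$n_genes, ncol = n_samples)

    marker <- rep("", config$n_genes)
    is_y <- chrom == "Y"
    if (any(is_y)) {
      marker[which(is_y)[gene_ids[is_y] %in% y_marker_names]] <- "y_marker"
      # Y-linked genes: near-zero expression in females
      log_mu[is_y, is_female] <- log(config$y_female_level)
    }
    if (config$xist_like && config$n_x > 0) {
      xi <- match("XIST_like", gene_ids)
      marker[xi] <- "xist_like"
      # female-high in tumors only; sex-concordant in normals by default
      log_mu[xi, is_female & is_tumor] <- base_mu[xi] + log(config$effect_size)
    }

    # planted sex-DE genes: X chromosome first (excluding the XIST-like
    # marker), then autosomes
    planted_sex_de <- logical(config$n_genes)
    sex_de_direction <- rep("", config$n_genes)
    x_pool <- which(chrom == "X" & marker == "")
    a_pool <- which(chrom == "autosome")
    sexde_pool <- c(x_pool, a_pool)
    if (config$n_sex_de > length(sexde_pool)) {
      stop("cohort configuration error: not enough X/autosomal genes for n_sex_de")
    }
    sexde_idx <- sexde_pool[seq_len(config$n_sex_de)]
    if (config$n_sex_de > 0) {
      planted_sex_de[sexde_idx] <- TRUE
      dirs <- rep(c(1, -1), length.out = config$n_sex_de)
      sex_de_direction[sexde_idx] <- ifelse(dirs > 0, "up_in_female", "up_in_male")
      shift <- outer(dirs * log(config$effect_size), as.numeric(is_female))
      log_mu[sexde_idx, ] <- log_mu[sexde_idx, , drop = FALSE] + shift
    }

    # planted tumor-vs-normal genes: autosomal, disjoint from sex-DE picks
    tumor_de_class <- rep("none", config$n_genes)
    tumor_de_direction <- rep("", config$n_genes)
    tde_pool <- setdiff(a_pool, sexde_idx)
    n_tde <- config$n_tumor_de_shared + config$n_tumor_de_male_only +
      config$n_tumor_de_female_only
    if (n_tde > length(tde_pool)) {
      stop("cohort configuration error: not enough autosomal genes for tumor-DE plants")
    }
    tde_idx <- tde_pool[seq_len(n_tde)]
    tde_class <- rep(c("shared", "male_only", "female_only"),
                     times = c(config$n_tumor_de_shared,
                               config$n_tumor_de_male_only,
                               config$n_tumor_de_female_only))
    if (n_tde > 0) {
      tumor_de_class[tde_idx] <- tde_class
      dirs <- rep(c(1, -1), length.out = n_tde)
      tumor_de_direction[tde_idx] <- ifelse(dirs > 0, "up", "down")
      affected <- rbind(
        shared = is_tumor,
        male_only = is_tumor & !is_female,
        female_only = is_tumor & is_female
      )
      eff <- ifelse(tde_class == "shared", config$effect_size_shared,
                    config$effect_size)
      for (j in seq_len(n_tde)) {
        cols <- affected[tde_class[j], ]
        log_mu[tde_idx[j], cols] <- log_mu[tde_idx[j], cols] +
          dirs[j] * log(eff[j])
      }
    }

    expr <- exp(log_mu + matrix(stats::rnorm(config$n_genes * n_samples,
                                             sd = config$dispersion),
                                nrow = config$n_genes))
    rownames(expr) <- gene_ids
    colnames(expr) <- sample_ids

    gene_info <- data.frame(
      gene_id = gene_ids, chromosome = chrom, marker = marker,
      planted_sex_de = planted_sex_de, sex_de_direction = sex_de_direction,
      tumor_de_class = tumor_de_class, tumor_de_direction = tumor_de_direction,
      stringsAsFactors = FALSE
    )
    expression_dataset(expr, sex, tissue, chrom, cancer_label = cancer_label,
                       gene_info = gene_info)
  })
}
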