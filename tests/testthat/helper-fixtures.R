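# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# A fully hand-specified dataset: 2 genes x 8 samples, no randomness.
tiny_dataset <- function() {
  m <- rbind(
    G1 = c(10, 12, 11, 13, 2, 3, 2.5, 3.5),
    G2 = c(5, 5.5, 6, 5.2, 5.1, 5.3, 5.6, 5.4)
  )
  colnames(m) <- paste0("S", 1:8)
  expression_dataset(
    m,
    sample_sex = rep(c("male", "female"), each = 4),
    sample_tissue = rep("tumor", 8),
    gene_chromosome = c("autosome", "X"),
    cancer_label = "TINY"
  )
}

# Small four-arm cohort with planted tumor effects, used across DE and
# signature tests.
small_tn_cohort <- function(seed = 101) {
  generate_cohort(cohort_config(
    n_genes = 300, n_x = 0, n_y = 0,
    n_male_tumor = 12, n_female_tumor = 12,
    n_male_normal = 12, n_female_normal = 12,
    n_tumor_de_shared = 20, n_tumor_de_male_only = 20,
    n_tumor_de_female_only = 20,
    effect_size = 5, xist_like = FALSE, seed = seed
  ))
}

# A de_result built directly from vectors, for signature-selection tests
# that need exact fold changes.
fake_de_result <- function(gene_id, p, fc, alpha = 0.05, sex = "male") {
  bh <- bh_adjust(p)
  structure(
    data.frame(gene_id = gene_id,
               chromosome = rep("autosome", length(gene_id)),
               W = NA_real_, p = p, bh = bh, fc = fc,
               significant = bh < alpha, stringsAsFactors = FALSE),
    class = c("de_result", "data.frame"),
    comparison = "tumor_vs_normal", sex = sex, alpha = alpha,
    n_a = 10L, n_b = 10L, cancer_label = "FAKE"
  )
}

# Independent brute-force oracles ------------------------------------------

# Two-sided exact Wilcoxon p by full enumeration of group assignments.
enum_wilcoxon_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  z <- c(x, y)
  r <- rank(z)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  us <- apply(combos, 2L, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  if (u_obs >= mu) {
    p <- 2 * mean(us >= u_obs)
  } else {
    p <- 2 * mean(us <= u_obs)
  }
  min(p, 1)
}

# Step-up BH oracle written independently of p.adjust.
stepup_bh <- function(p) {
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  ro <- order(ord)
  adj <- cummin(p[ord] * m / rev(seq_len(m)))
  pmin(1, adj)[ro]
}

# Hypergeometric upper-tail oracle by direct summation of binomials.
enum_ora_p <- function(n_pathway, n_sig, n_universe, overlap) {
  ks <- overlap:min(n_pathway, n_sig)
  sum(choose(n_pathway, ks) * choose(n_universe - n_pathway, n_sig - ks)) /
    choose(n_universe, n_sig)
}

# Running-sum enrichment-score oracle: explicit walk over the ranking.
walk_es <- function(query, profile) {
  ord <- names(profile)[order(profile)]
  hit <- ord %in% query
  n <- sum(hit); N <- length(profile)
  steps <- ifelse(hit, 1 / n, -1 / (N - n))
  walk <- cumsum(steps)
  i <- which.max(abs(walk))
  # deviations of equal magnitude resolve toward the positive extreme
  if (max(walk) >= -min(walk)) max(walk) else min(walk)
}

# Tiny perturbagen library built directly from explicit rankings.
manual_library <- function(universe, rank_list, types = NULL) {
  profiles <- do.call(cbind, rank_list)
  n <- length(rank_list)
  manifest <- data.frame(
    profile_id = paste0("P", seq_len(n), "_r1"),
    perturbagen_id = paste0("P", seq_len(n)),
    replicate = 1L,
    reagent_class = rep("chemical", n),
    planted_type = types %||% rep("null", n),
    stringsAsFactors = FALSE
  )
  perturbagen_library(universe, profiles, manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
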