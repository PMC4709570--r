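# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never clobbers the
# user's RNG stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Rank-based AUC of `score` against binary `truth` (TRUE/1 = positive class).
# Equivalent to the Mann-Whitney U statistic scaled to [0, 1], with ties
# sharing average ranks.
rank_auc <- function(score, truth) {
  truth <- as.logical(truth)
  stopifnot(length(score) == length(truth), !anyNA(score), !anyNA(truth))
  n1 <- sum(truth)
  n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Consistent float formatting for TSV exports (4 decimals per the package's
# reporting convention).
fmt_num <- function(x, digits = 4L) {
  ifelse(is.na(x), NA_character_, formatC(x, format = "f", digits = digits))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
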