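# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. seed = NULL means "use the current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# sample() without the length-1 surprise.
sample_one <- function(x, prob = NULL) {
  if (length(x) == 1L) return(x)
  x[sample.int(length(x), 1L, prob = prob)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Standard error of the mean; 0 for a single observation (reported with the
# caller's n so the degenerate case is visible).
se_mean <- function(x) {
  n <- length(x)
  if (n <= 1L) return(0)
  sd(x) / sqrt(n)
}

# Deterministic TSV writers used for all reports.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

#' Welch two-sample t-test utility
#'
#' Thin wrapper around [stats::t.test()] (Welch variant, unequal variances)
#' returning just the statistic, degrees of freedom and p-value. Used for
#' mutant-versus-control rate comparisons.
#'
#' @param x,y Numeric vectors of per-plant values for the two groups.
#' @return A list with elements `statistic`, `df` and `p.value`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 7))
welch_t <- function(x, y) {
  res <- t.test(x, y, var.equal = FALSE)
  list(statistic = unname(res$statistic),
       df = unname(res$parameter),
       p.value = res$p.value)
}
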