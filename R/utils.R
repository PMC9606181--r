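# Internal helpers shared across modules.

#' Deterministic 31-bit hash of a character string
#'
#' Polynomial rolling hash over UTF-8 bytes, reduced modulo 2^31 - 1.
#' Used to derive per-group child seeds from a master seed so that adding
#' or removing a group never perturbs the draws of the others.
#' @param x single character string
#' @return integer in [0, 2^31 - 2]
#' @keywords internal
string_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(utf8ToInt(enc2utf8(x)))
  h <- 0
  m <- 2147483647  # 2^31 - 1, prime
  for (b in bytes) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

#' Derive a child seed from a master seed and a label
#' @keywords internal
child_seed <- function(master_seed, label) {
  m <- 2147483647
  as.integer((as.numeric(master_seed) %% m * 48271 + string_hash(label)) %% m)
}

# Nearest-rank percentile cutoff: smallest value v in x such that at least
# p% of the n values are <= v. Ties at the cutoff qualify downstream.
nearest_rank_cutoff <- function(x, percentile) {
  stopifnot(percentile > 0, percentile < 100)
  n <- length(x)
  unname(sort(x)[max(1L, ceiling(percentile / 100 * n))])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
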