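# shared internal helpers

# round-half-away-from-zero; base round() is banker's and would turn 2.5 into 2
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' @importFrom stats runif rnorm rbeta quantile sd cor
#' @importFrom utils write.csv read.csv
#' @importFrom Rcpp evalCpp
#' @useDynLib cultnet, .registration = TRUE
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# derive a reproducible 32-bit substream seed from a master seed and labels
derive_seed <- function(master, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  }, numeric(1))
  s <- as.numeric(master)
  for (p in parts) s <- (s * 69069 + p * 101 + 1) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(seed)
  expr
}
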