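#' @useDynLib adaptrt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm sd pt qnorm quantile
#' @importFrom utils read.csv write.csv
NULL

# Deterministic 32-bit sub-seed derivation: the whole cohort is a pure
# function of (master_seed, indices). Splitmix-style integer mixing done in
# doubles; every intermediate stays below 2^53 and the result below 2^31.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.numeric(master) %% 2147483647
  for (k in seq_along(idx)) {
    v <- as.numeric(idx[k])
    if (is.character(idx[k])) v <- sum(utf8ToInt(idx[k]) * seq_len(nchar(idx[k])))
    h <- (h * 69621 + v * 1013904 + 5040953 * k) %% 2147483647
    h <- (h * 30269 + 171717) %% 2147483647
  }
  as.integer(h %% 2147483629 + 1)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
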