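sigmoid <- function(x) 1 / (1 + exp(-x))

#' @useDynLib sleepstates, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif fft mvfft pt sd var lm poly predict
#'   prcomp setNames aggregate
#' @importFrom utils read.csv write.csv head
NULL

# Row-normalisation used by the covariance energy: v_hat = v / (||v||/sqrt(D) + eps)
normalize_rows <- function(V, eps = 1e-8) {
  nrm <- sqrt(rowSums(V^2) / ncol(V)) + eps
  V / nrm
}

stage_levels <- c("W", "NR", "R")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pack a binary latent configuration into its integer key
#'
#' The latent-state identity is the concatenated (h_c, h_m) bit vector read
#' as a big-endian integer (h_c bits most significant). Packing is bijective
#' for up to 30 bits.
#'
#' @param h_c binary vector of covariance-unit states
#' @param h_m binary vector of mean-unit states
#' @return a single integer key
#' @export
config_to_key <- function(h_c, h_m) {
  bits <- c(h_c, h_m)
  stopifnot(all(bits %in% c(0, 1)), length(bits) <= 30)
  as.integer(sum(bits * 2^(rev(seq_along(bits)) - 1)))
}

#' Unpack an integer key into its binary latent configuration
#'
#' @param key integer key produced by [config_to_key()]
#' @param n_cov number of covariance units (h_c bits)
#' @param n_mean number of mean units (h_m bits)
#' @return list with binary vectors `h_c` and `h_m`
#' @export
key_to_config <- function(key, n_cov, n_mean) {
  n <- n_cov + n_mean
  stopifnot(n <= 30, key >= 0, key < 2^n)
  bits <- as.integer(bitwAnd(bitwShiftR(as.integer(key), (n - 1):0), 1L))
  list(h_c = bits[seq_len(n_cov)], h_m = bits[n_cov + seq_len(n_mean)])
}
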