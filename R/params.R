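#' Seed length and coprime sampling-step selection
#'
#' Only every k1-th reference position is indexed and every k2-th query
#' position is probed. If gcd(k1, k2) = 1 and k1*k2 <= L - K + 1, every exact
#' match of length >= L contains an aligned position pair sampled on both
#' sides with at least K characters remaining (a Chinese-remainder argument
#' over the alignment shift), so sparse sampling loses no MEM.
#'
#' @name params
NULL

MIN_MEM_LENGTH <- 37L

#' Select the seed length K for a minimum MEM length
#'
#' Policy: K = 36 for L < 80, K = 44 for 80 <= L < 200, K = 56 for L >= 200;
#' memory-frugal mode caps K at 44 (a shorter seed means a smaller hash
#' table). The thresholds are a documented policy, overridable via
#' `seed_length` in [mem_params()].
#'
#' @param L minimum MEM length, in bases (L >= 37).
#' @param mode `"default"` or `"memory-frugal"`.
#' @return Seed length K, in bases.
#' @export
select_seed_length <- function(L, mode = c("default", "memory-frugal")) {
  mode <- match.arg(mode)
  if (L < MIN_MEM_LENGTH)
    stop(sprintf("minimum MEM length L = %d is below the minimum supported (%d)",
                 L, MIN_MEM_LENGTH))
  K <- if (L < 80) 36L else if (L < 200) 44L else 56L
  if (mode == "memory-frugal") K <- min(K, 44L)
  K
}

#' Select the coprime sampling steps (k1, k2)
#'
#' With budget B = L - K + 1: the base step k is the largest integer with
#' k*(k-1) <= B and k2 = k - 1 (steps differing by 1 are always coprime);
#' then k1 is relaxed upward to the largest j >= k with j*k2 <= B and
#' gcd(j, k2) = 1. A larger k1 means fewer indexed reference positions at no
#' loss of sensitivity.
#'
#' @param L minimum MEM length, in bases.
#' @param K seed length, in bases (K <= L - 1).
#' @return Integer vector `c(k1, k2)` with k1 >= k2 >= 1, gcd(k1, k2) = 1 and
#'   k1*k2 <= L - K + 1.
#' @export
select_sampling_steps <- function(L, K) {
  B <- L - K + 1L
  if (B < 2L)
    stop(sprintf("L - K + 1 = %d must be at least 2 (got L = %d, K = %d)",
                 B, L, K))
  k <- floor((1 + sqrt(1 + 4 * B)) / 2)     # max k with k*(k-1) <= B
  while (k * (k - 1L) > B) k <- k - 1L
  while ((k + 1L) * k <= B) k <- k + 1L
  k2 <- k - 1L
  k1 <- B %/% k2
  while (gcd_int(k1, k2) != 1L) k1 <- k1 - 1L
  c(k1 = as.integer(k1), k2 = as.integer(k2))
}

gcd_int <- function(a, b) {
  while (b != 0L) { t <- a %% b; a <- b; b <- t }
  a
}

#' Assemble the full parameter set for a run
#'
#' @param L minimum MEM length (L >= 37).
#' @param mode `"default"` or `"memory-frugal"`.
#' @param seed_length optional explicit seed length K, overriding the
#'   automatic policy.
#' @return An object of class `mem_params` with fields `L`, `K`, `k1`, `k2`,
#'   `mode`.
#' @export
mem_params <- function(L, mode = c("default", "memory-frugal"),
                       seed_length = NULL) {
  mode <- match.arg(mode)
  L <- as.integer(L)
  K <- if (is.null(seed_length)) select_seed_length(L, mode)
       else as.integer(seed_length)
  if (K > L - 1L)
    stop(sprintf("seed length K = %d leaves no sampling budget for L = %d", K, L))
  ks <- select_sampling_steps(L, K)
  p <- list(L = L, K = K, k1 = ks[["k1"]], k2 = ks[["k2"]], mode = mode)
  class(p) <- "mem_params"
  p
}

#' @export
print.mem_params <- function(x, ...) {
  cat(sprintf("<mem_params> L=%d K=%d k1=%d k2=%d mode=%s\n",
              x$L, x$K, x$k1, x$k2, x$mode))
  invisible(x)
}
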