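#' Derive a stage-specific random seed from a master seed
#'
#' Every stochastic stage of the package (region building, respondent
#' sampling, response generation, bootstrap, replicate experiments) draws its
#' seed from a single master seed through this map, so that one integer
#' reproduces a whole run while stages remain independently re-runnable.
#' The derivation is `(seed * 48271 + stage) mod (2^31 - 1)`, i.e. one step
#' of a Lehmer generator offset by the stage index; results always fit in a
#' 32-bit integer.
#'
#' @param seed master seed (single non-negative integer).
#' @param stage stage offset (single non-negative integer).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 1)
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stage),
            length(stage) == 1L, seed >= 0, stage >= 0)
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + as.numeric(stage)) %% m)
}

# Wilson score interval for a binomial proportion; returns c(lower, upper).
wilson_ci <- function(x, n, level = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

# t-based confidence interval for a mean across groups.
t_ci <- function(x, level = 0.95) {
  x <- x[is.finite(x)]
  k <- length(x)
  if (k < 2) return(c(lower = NA_real_, upper = NA_real_))
  se <- stats::sd(x) / sqrt(k)
  hw <- stats::qt(1 - (1 - level) / 2, df = k - 1) * se
  c(lower = mean(x) - hw, upper = mean(x) + hw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
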