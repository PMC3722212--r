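# Shared fixtures: a scaled-down survey configuration for fast unit tests,
# and brute-force oracles for the conflict indices and rank correlation.

small_config <- function(seed = 1L, ...) {
  generator_config(n_municipalities = c(Norway = 12L, Sweden = 9L),
                   n_counties = c(Norway = 4L, Sweden = 3L),
                   seed = seed, ...)
}

small_sim <- function(seed = 1L, ...) simulate_survey(small_config(seed, ...))

# PCI2 by literal enumeration of all unordered pairs.
pci2_brute <- function(scores, m = 2) {
  n <- length(scores)
  D <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sign(scores[i]) * sign(scores[j]) < 0)
      D <- D + abs(scores[i] - scores[j])
  }
  D / (floor(n / 2) * ceiling(n / 2) * 2 * m)
}

# PCI1 by direct evaluation of the published formula.
pci1_brute <- function(scores, m = 2) {
  X_a <- sum(scores[scores > 0])
  X_u <- sum(abs(scores[scores < 0]))
  X <- X_a + X_u
  Z <- length(scores) * m
  if (X == 0) return(0)
  (1 - abs(X_a - X_u) / X) * (X / Z)
}

# Spearman correlation from first principles: midranks, then the
# sum-of-products Pearson formula.
spearman_brute <- function(x, y) {
  midrank <- function(v) {
    sapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2)
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# All score multisets of size n over {-m..m}, as a list of vectors.
score_multisets <- function(n, m = 2) {
  grid <- do.call(expand.grid, rep(list(seq(-m, m)), n))
  keep <- apply(grid, 1, function(r) !is.unsorted(r))
  lapply(which(keep), function(i) as.numeric(grid[i, ]))
}
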