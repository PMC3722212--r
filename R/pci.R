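#' Second-generation Potential Conflict Index (PCI2)
#'
#' Quantifies divergence of opinion in a group of centered Likert scores
#' (`-m..+m`). PCI2 totals the distances between every pair of respondents
#' on strictly opposite sides of neutral — a respondent scoring +1 and one
#' scoring -2 contribute |1 - (-2)| = 3; neutral (0) respondents pair with
#' nobody — and divides by the largest total any group of the same size
#' could produce, attained when the group splits half and half between the
#' two extremes: \eqn{\delta = \lfloor n/2 \rfloor \lceil n/2 \rceil (2m)}.
#' The index is 0 when everyone is on one side (full consensus) and 1 for
#' the maximal even split (full polarization).
#'
#' @param scores integer vector of centered scores in `{-m..+m}`.
#' @param m extreme score of the scale (default 2).
#' @return an object of class `"pci_result"`: list with `value`, `variant`,
#'   `n`, `n_a` (positive responses), `n_u` (negative responses),
#'   `n_neutral`, `numerator` (D, the total opposite-sign pairwise
#'   distance), `maximum` (delta).
#' @seealso [pci1()] for the first-generation index.
#' @export
#' @examples
#' pci2(c(2, 2, -2, -2))$value   # 1: maximal split
#' pci2(c(1, -1, 0, 0))$value    # 0.125
pci2 <- function(scores, m = 2L) {
  scores <- check_scores(scores, m)
  n <- length(scores)
  n_a <- sum(scores > 0)
  n_u <- sum(scores < 0)
  # D = sum over opposite-sign pairs of |x_i - x_j|, via level counts
  pos <- scores[scores > 0]
  neg <- scores[scores < 0]
  D <- 0
  if (n_a > 0 && n_u > 0) {
    ta <- table(pos)
    tu <- table(neg)
    av <- as.integer(names(ta))
    uv <- as.integer(names(tu))
    D <- sum(outer(as.vector(ta), as.vector(tu)) * outer(av, uv, function(a, u) a - u))
  }
  delta <- floor(n / 2) * ceiling(n / 2) * (2 * m)
  if (n_a == 0 && n_u == 0)
    message("pci2: all responses neutral; index is 0 by convention")
  value <- if (n_a == 0 || n_u == 0) 0 else D / delta
  new_pci_result(value, "pci2", n, n_a, n_u, D, delta)
}

#' First-generation Potential Conflict Index (PCI1)
#'
#' Compares the summed magnitudes of the accepting and rejecting sides:
#' with \eqn{X_a = \sum |positive|}, \eqn{X_u = \sum |negative|} and
#' \eqn{Z = n m} the maximum possible sum of scores, the index is
#' \eqn{2 \min(X_a, X_u) / Z} — algebraically
#' \eqn{(1 - |X_a - X_u| / X) (X / Z)} with \eqn{X = X_a + X_u} — scaled so
#' the half-at-each-extreme split yields 1.
#'
#' @inheritParams pci2
#' @return a `"pci_result"` (see [pci2()]); `numerator` holds
#'   \eqn{X - |X_a - X_u|} and `maximum` holds Z.
#' @export
#' @examples
#' pci1(c(1, -1, 0, 0))$value  # 0.25
pci1 <- function(scores, m = 2L) {
  scores <- check_scores(scores, m)
  n <- length(scores)
  X_a <- sum(scores[scores > 0])
  X_u <- sum(-scores[scores < 0])
  Z <- n * m
  value <- 2 * min(X_a, X_u) / Z
  new_pci_result(value, "pci1", n, sum(scores > 0), sum(scores < 0),
                 (X_a + X_u) - abs(X_a - X_u), Z)
}

check_scores <- function(scores, m) {
  stopifnot(m >= 1)
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2)
    stop("PCI is undefined for fewer than 2 scores", call. = FALSE)
  if (any(abs(scores) > m))
    stop(sprintf("score outside [-%d, %d]: %s", m, m,
                 paste(unique(scores[abs(scores) > m]), collapse = ", ")),
         call. = FALSE)
  scores
}

new_pci_result <- function(value, variant, n, n_a, n_u, numerator, maximum) {
  structure(list(value = value, variant = variant, n = n, n_a = n_a,
                 n_u = n_u, n_neutral = n - n_a - n_u,
                 numerator = numerator, maximum = maximum),
            class = "pci_result")
}

#' @export
print.pci_result <- function(x, ...) {
  cat(sprintf("%s = %.4f  (n = %d: %d accept / %d neutral / %d reject)\n",
              toupper(x$variant), x$value, x$n, x$n_a, x$n_neutral, x$n_u))
  invisible(x)
}

pci_fun <- function(variant) {
  switch(match.arg(variant, c("pci2", "pci1")), pci2 = pci2, pci1 = pci1)
}

#' PCI per geographic group
#'
#' Computes the conflict index for one or more poaching-acceptance items,
#' pooling all respondents of each county or municipality. Groups with
#' fewer than 2 respondents get a missing value (with a warning); groups
#' with fewer than 8 are flagged as small, since the index is unstable in
#' tiny groups such as single municipalities sampled with 4-5 respondents.
#'
#' @param survey a survey table with `county_id`, `municipality_id`,
#'   `country` and item columns (see [generate_responses()]).
#' @param grouping `"county"` or `"municipality"`.
#' @param items item columns to index; defaults to the four
#'   species-specific poaching items ([poaching_items()]).
#' @param variant `"pci2"` (default) or `"pci1"`.
#' @param m extreme score of the centered scale.
#' @return a `data.frame` with one row per group x item: group id, country,
#'   item, species (where applicable), variant, value, n, n_a, n_u,
#'   n_neutral, flag_small.
#' @export
pci_by_group <- function(survey, grouping = c("county", "municipality"),
                         items = poaching_items(),
                         variant = c("pci2", "pci1"), m = 2L) {
  grouping <- match.arg(grouping)
  variant <- match.arg(variant)
  fun <- pci_fun(variant)
  missing_items <- setdiff(items, colnames(survey))
  if (length(missing_items))
    stop(sprintf("unknown item column(s): %s",
                 paste(missing_items, collapse = ", ")), call. = FALSE)
  key <- if (grouping == "county") "county_id" else "municipality_id"
  species_of <- names(poaching_items())[match(items, poaching_items())]
  groups <- unique(survey[, c(key, "country")])
  groups <- groups[order(groups[[key]]), , drop = FALSE]
  small <- character(0)
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    sub <- survey[survey[[key]] == groups[[key]][g], , drop = FALSE]
    do.call(rbind, lapply(seq_along(items), function(j) {
      sc <- recode_centered(sub[[items[j]]], m)
      sc <- sc[!is.na(sc)]
      if (length(sc) < 2) {
        small <<- c(small, groups[[key]][g])
        return(data.frame(group_id = groups[[key]][g],
                          country = groups$country[g], item = items[j],
                          species = species_of[j], variant = variant,
                          value = NA_real_, n = length(sc), n_a = NA_integer_,
                          n_u = NA_integer_, n_neutral = NA_integer_,
                          flag_small = TRUE, stringsAsFactors = FALSE))
      }
      r <- fun(sc, m)
      data.frame(group_id = groups[[key]][g], country = groups$country[g],
                 item = items[j], species = species_of[j], variant = variant,
                 value = r$value, n = r$n, n_a = r$n_a, n_u = r$n_u,
                 n_neutral = r$n_neutral, flag_small = r$n < 8,
                 stringsAsFactors = FALSE)
    }))
  })
  if (length(small))
    warning(sprintf("PCI undefined (n < 2) for group(s): %s",
                    paste(unique(small), collapse = ", ")), call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percentile bootstrap confidence interval for a PCI value
#'
#' Resamples respondents with replacement and returns the percentile
#' interval of the index across `B` bootstrap replicates.
#'
#' @param scores centered scores in `{-m..+m}`.
#' @param B number of bootstrap replicates (>= 100).
#' @param level confidence level in (0, 1).
#' @param seed seed for the resampling stream.
#' @param variant `"pci2"` or `"pci1"`.
#' @param m extreme score.
#' @return list with `value` (point estimate), `lower`, `upper`, `B`,
#'   `level`.
#' @export
pci_bootstrap_ci <- function(scores, B = 1000L, level = 0.95, seed = 1L,
                             variant = c("pci2", "pci1"), m = 2L) {
  variant <- match.arg(variant)
  stopifnot(B >= 100, level > 0, level < 1)
  fun <- pci_fun(variant)
  scores <- check_scores(scores, m)
  point <- fun(scores, m)$value
  if (length(unique(scores)) == 1L)
    return(list(value = point, lower = point, upper = point,
                B = as.integer(B), level = level))
  set.seed(seed)
  n <- length(scores)
  reps <- vapply(seq_len(B), function(b) {
    fun(scores[sample.int(n, n, replace = TRUE)], m)$value
  }, numeric(1))
  qs <- stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(value = point, lower = qs[1], upper = qs[2], B = as.integer(B),
       level = level)
}
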