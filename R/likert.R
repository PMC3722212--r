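#' Recode a Likert response to a centered score
#'
#' Maps a 5-point Likert response to the centered `-m..+m` scale used by the
#' Potential Conflict Index: "strongly disagree" becomes -2, the neutral
#' midpoint 0, and "strongly agree" +2 (for the default `m = 2`).
#'
#' @param likert integer vector of responses in `1..(2m+1)`.
#' @param m the extreme score of the centered scale (2 for 5-point items).
#' @return integer vector in `{-m, ..., +m}`.
#' @export
#' @examples
#' recode_centered(c(1, 3, 5))  # -2 0 2
recode_centered <- function(likert, m = 2L) {
  stopifnot(m >= 1, m == round(m))
  bad <- !is.na(likert) & (likert < 1 | likert > 2 * m + 1 | likert != round(likert))
  if (any(bad))
    stop(sprintf("Likert value out of range 1..%d: %s", 2 * m + 1,
                 paste(unique(likert[bad]), collapse = ", ")), call. = FALSE)
  as.integer(likert) - as.integer(m + 1L)
}

#' Binarize a Likert response into acceptance
#'
#' "Agree" and "strongly agree" (4, 5) are coded 1; every other response —
#' including the neutral midpoint — is coded 0. This is the binomial
#' response used by the respondent-level acceptance models.
#'
#' @param likert integer vector of responses in 1..5.
#' @return integer vector of 0/1.
#' @export
#' @examples
#' binarize_acceptance(1:5)  # 0 0 0 1 1
binarize_acceptance <- function(likert) {
  bad <- !is.na(likert) & !(likert %in% 1:5)
  if (any(bad))
    stop(sprintf("Likert value out of range 1..5: %s",
                 paste(unique(likert[bad]), collapse = ", ")), call. = FALSE)
  as.integer(likert >= 4L)
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item battery. The raw variant
#' is \eqn{\alpha = k/(k-1) (1 - \sum_i s_i^2 / s_T^2)} where \eqn{s_i^2}
#' are item variances and \eqn{s_T^2} the variance of the row total; the
#' standardized variant is \eqn{k \bar r / (1 + (k-1)\bar r)} with
#' \eqn{\bar r} the mean pairwise inter-item correlation. Rows with any
#' missing item are dropped (listwise deletion) with a message.
#'
#' @param items a numeric matrix or data frame, respondents in rows, items
#'   in columns.
#' @param variant `"raw"` (default) or `"standardized"`.
#' @return an object of class `"reliability_result"`: a list with `alpha`,
#'   `n_items`, `n_respondents`, `variant`, `n_dropped`.
#' @export
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(100), 50, 2)
#' cronbach_alpha(cbind(x, x))$alpha
cronbach_alpha <- function(items, variant = c("raw", "standardized")) {
  variant <- match.arg(variant)
  items <- as.matrix(items)
  storage.mode(items) <- "double"
  k <- ncol(items)
  if (k < 2) stop("Cronbach's alpha needs at least 2 items", call. = FALSE)
  complete <- stats::complete.cases(items)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(sprintf("cronbach_alpha: dropped %d incomplete row(s)", n_dropped))
    items <- items[complete, , drop = FALSE]
  }
  n <- nrow(items)
  if (n < 2) stop("Cronbach's alpha needs at least 2 complete respondents",
                  call. = FALSE)
  if (variant == "raw") {
    total_var <- stats::var(rowSums(items))
    if (total_var <= 0)
      stop("total score has zero variance; alpha undefined", call. = FALSE)
    alpha <- k / (k - 1) * (1 - sum(apply(items, 2, stats::var)) / total_var)
  } else {
    sds <- apply(items, 2, stats::sd)
    if (any(sds == 0))
      stop("constant item column; standardized alpha undefined", call. = FALSE)
    r <- stats::cor(items)
    rbar <- mean(r[lower.tri(r)])
    alpha <- k * rbar / (1 + (k - 1) * rbar)
  }
  structure(list(alpha = alpha, n_items = k, n_respondents = n,
                 variant = variant, n_dropped = n_dropped),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Cronbach's alpha (%s): %.3f  [%d items, %d respondents]\n",
              x$variant, x$alpha, x$n_items, x$n_respondents))
  invisible(x)
}

#' Simulate an equicorrelated continuous item battery
#'
#' Draws `n` respondents by `k` items from a multivariate normal with unit
#' variances and a common inter-item correlation `rho` (compound symmetry),
#' via the one-factor representation. Used to study the closed-form
#' behaviour of Cronbach's alpha: the standardized alpha of such a battery
#' converges to `k * rho / (1 + (k - 1) * rho)`.
#'
#' @param n respondents.
#' @param k items.
#' @param rho common inter-item correlation in `[0, 1)`.
#' @param seed optional seed.
#' @return an `n x k` numeric matrix.
#' @export
simulate_equicorrelated <- function(n, k, rho, seed = NULL) {
  stopifnot(n >= 1, k >= 2, rho >= 0, rho < 1)
  if (!is.null(seed)) set.seed(seed)
  equicorr_normal(n, k, rho)
}
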