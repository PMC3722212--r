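#' Specify a mixed model
#'
#' A declarative description of a (generalized) linear mixed model: the
#' response column, its family, the fixed-effect terms, an optional random
#' intercept grouping, and the subset of fixed terms exempt from backward
#' elimination (typically the individual covariates sex, age and education,
#' which are kept as adjustment terms).
#'
#' @param response response column name (binary 0/1 for binomial family).
#' @param family `"binomial"` (logit link) or `"gaussian"` (identity).
#' @param fixed character vector of fixed-effect terms; each entry is an R
#'   model term, e.g. `"country"`, `"age"`, or
#'   `"poly(log_human_density, 2)"` for a second-order component. A
#'   categorical term expands to its dummy block and is always dropped or
#'   retained as a whole.
#' @param random grouping column for the random intercept
#'   (`"municipality_id"`, `"county_id"`, ...), or `NULL` for an ordinary
#'   fixed-effects fit.
#' @param forced subset of `fixed` never eliminated.
#' @return a list of class `"model_spec"`.
#' @export
#' @examples
#' model_spec("accept", "binomial",
#'            fixed = c("sex", "age", "education", "country"),
#'            random = "municipality_id",
#'            forced = c("sex", "age", "education"))
model_spec <- function(response, family = c("binomial", "gaussian"),
                       fixed = character(), random = NULL,
                       forced = character()) {
  family <- match.arg(family)
  if (!all(forced %in% fixed))
    stop("forced terms must be a subset of fixed terms", call. = FALSE)
  structure(list(response = response, family = family,
                 fixed = unname(fixed), random = random,
                 forced = unname(forced)),
            class = "model_spec")
}

spec_formula <- function(spec) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  if (!is.null(spec$random))
    rhs <- paste0(rhs, " + (1 | ", spec$random, ")")
  stats::as.formula(paste(spec$response, "~", rhs))
}

#' Fit a mixed (or ordinary) model from a spec
#'
#' Binomial-logit models with a random intercept are fitted by maximum
#' likelihood with the Laplace approximation ([lme4::glmer()]); Gaussian
#' models by ML ([lme4::lmer()] with `REML = FALSE`, so log-likelihoods are
#' comparable across nested fixed-effect structures); specs without a
#' random term fall back to [stats::glm()] / [stats::lm()]. With a
#' between-group variance of zero the mixed fit collapses to the ordinary
#' fit.
#'
#' @param data a data frame containing all spec columns.
#' @param spec a [model_spec()].
#' @return an object of class `"model_fit"`: list with `coefficients`
#'   (data frame: term, estimate, se, z), `sigma_u`, `loglik`, `df`,
#'   `n_obs`, `n_groups`, `converged`, `spec`, and the underlying `fit`.
#' @export
fit_glmm <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (!is.null(spec$random) && !spec$random %in% colnames(data))
    stop(sprintf("grouping column '%s' not in data", spec$random), call. = FALSE)
  if (spec$family == "binomial") {
    y <- data[[spec$response]]
    if (!all(stats::na.omit(y) %in% c(0, 1)))
      stop("binomial family requires a 0/1 response", call. = FALSE)
  }
  form <- spec_formula(spec)
  mixed <- !is.null(spec$random)
  converged <- TRUE
  if (mixed) {
    if (length(unique(data[[spec$random]])) < 2)
      stop("random intercept needs at least 2 groups", call. = FALSE)
    fit <- if (spec$family == "binomial") {
      lme4::glmer(form, data = data, family = stats::binomial(),
                  control = lme4::glmerControl(optimizer = "bobyqa"))
    } else {
      lme4::lmer(form, data = data, REML = FALSE)
    }
    converged <- length(fit@optinfo$conv$lme4$messages) == 0 &&
      (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0)
    vc <- lme4::VarCorr(fit)[[spec$random]]
    sigma_u <- sqrt(vc[1, 1])
    co <- summary(fit)$coefficients
    n_groups <- lme4::ngrps(fit)[[spec$random]]
    n_obs <- stats::nobs(fit)
  } else {
    fit <- if (spec$family == "binomial") {
      stats::glm(form, data = data, family = stats::binomial())
    } else {
      stats::lm(form, data = data)
    }
    if (spec$family == "binomial") converged <- fit$converged
    sigma_u <- 0
    co <- summary(fit)$coefficients
    n_groups <- NA_integer_
    n_obs <- stats::nobs(fit)
  }
  ll <- stats::logLik(fit)
  est <- co[, 1]
  if (spec$family == "binomial" && any(abs(est) > 10))
    warning(sprintf("possible separation: |coefficient| > 10 for %s",
                    paste(rownames(co)[abs(est) > 10], collapse = ", ")),
            call. = FALSE)
  coefs <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                      z = co[, 1] / co[, 2], row.names = NULL,
                      stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, sigma_u = sigma_u,
                 loglik = as.numeric(ll), df = attr(ll, "df"),
                 n_obs = n_obs, n_groups = n_groups, converged = converged,
                 spec = spec, fit = fit, elimination_trace = NULL),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s model: %s\n", x$spec$family,
              deparse(spec_formula(x$spec))))
  print(x$coefficients, digits = 3)
  cat(sprintf("sigma_u = %.3f, logLik = %.2f (df %d), n = %d",
              x$sigma_u, x$loglik, x$df, x$n_obs))
  if (!is.na(x$n_groups)) cat(sprintf(", groups = %d", x$n_groups))
  cat(if (x$converged) "\n" else "  [NOT CONVERGED]\n")
  invisible(x)
}

#' Build the county x species mean-acceptance table
#'
#' Aggregates the survey to one row per county and species with the mean
#' Likert acceptance (1-5 scale) and the county PCI for that species, plus
#' county-level covariates (log human density, big-game tradition
#' prevalence, mean sheep density, carnivore densities). This is the input
#' for the county-level Gaussian mixed models, where each county
#' contributes four observations (one per species) and county is the
#' random intercept.
#'
#' @param survey a survey table.
#' @param regions the matching region table.
#' @param variant PCI variant for the `pci` column.
#' @return a `data.frame`, one row per county x species.
#' @export
build_county_table <- function(survey, regions, variant = c("pci2", "pci1")) {
  variant <- match.arg(variant)
  items <- poaching_items()
  pci_tab <- pci_by_group(survey, "county", variant = variant)
  agg <- stats::aggregate(regions[c("human_density", "big_game_tradition",
                                    "sheep_density", "wolf_zone")],
                          by = list(county_id = regions$county_id), FUN = mean)
  dens_cols <- grep("_density_(current|historical)$", colnames(regions),
                    value = TRUE)
  dens <- regions[!duplicated(regions$county_id),
                  c("county_id", "country", dens_cols)]
  out <- do.call(rbind, lapply(names(items), function(sp) {
    m_acc <- tapply(survey[[items[[sp]]]], survey$county_id,
                    function(v) mean(v, na.rm = TRUE))
    ptab <- pci_tab[pci_tab$species == sp, ]
    data.frame(county_id = names(m_acc), species = sp,
               mean_acceptance = as.numeric(m_acc),
               pci = ptab$value[match(names(m_acc), ptab$group_id)],
               stringsAsFactors = FALSE)
  }))
  out <- merge(merge(out, dens, by = "county_id"), agg, by = "county_id")
  out$log_human_density <- log(out$human_density)
  out$species <- factor(out$species, levels = names(items))
  rownames(out) <- NULL
  out
}

#' County-level Gaussian mixed model
#'
#' Thin wrapper over [fit_glmm()] asserting the Gaussian family and a
#' county random intercept, for models of county mean acceptance or county
#' PCI with four species rows per county.
#'
#' @param county_table output of [build_county_table()].
#' @param spec a [model_spec()] with `family = "gaussian"` and
#'   `random = "county_id"`.
#' @return a `"model_fit"`.
#' @export
fit_county_lmm <- function(county_table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$family != "gaussian")
    stop("county-level model uses the gaussian family", call. = FALSE)
  fit_glmm(county_table, spec)
}

#' Likelihood-ratio test between nested fits
#'
#' \eqn{\chi^2 = 2(\ell_{full} - \ell_{reduced})} (clipped at 0), degrees
#' of freedom equal to the difference in parameter counts, upper-tail
#' chi-square p-value. Both fits must share response, family, grouping and
#' data size, and the reduced fixed terms must nest in the full ones.
#'
#' @param full,reduced `"model_fit"` objects.
#' @return list with `chisq`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  stopifnot(inherits(full, "model_fit"), inherits(reduced, "model_fit"))
  fs <- full$spec; rs <- reduced$spec
  if (!identical(fs$response, rs$response) || !identical(fs$family, rs$family) ||
      !identical(fs$random, rs$random) ||
      !all(rs$fixed %in% fs$fixed) ||
      full$n_obs != reduced$n_obs)
    stop("models are not nested on the same data", call. = FALSE)
  chisq <- max(0, 2 * (full$loglik - reduced$loglik))
  df <- full$df - reduced$df
  if (df < 0) stop("reduced model has more parameters than full", call. = FALSE)
  p <- if (df == 0) 1 else stats::pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p_value = p)
}

#' Backward elimination by likelihood-ratio tests
#'
#' Starting from the full spec, repeatedly refits the model without each
#' non-forced term, removes the single term with the largest LRT p-value
#' among those exceeding the threshold (ties broken alphabetically by term
#' name), and stops when every retained non-forced term is significant at
#' the threshold. Categorical terms leave as whole blocks. The returned fit
#' carries the full elimination trace, including the final LRT of every
#' retained term.
#'
#' @param data model data.
#' @param spec a [model_spec()].
#' @param threshold retention p-value threshold (default 0.05).
#' @return the final `"model_fit"`, with `elimination_trace` set: a data
#'   frame of step, term, chisq, df, p_value, action ("dropped"/"retained").
#' @export
backward_eliminate <- function(data, spec, threshold = 0.05) {
  stopifnot(inherits(spec, "model_spec"), threshold > 0, threshold < 1)
  trace <- list()
  step <- 0L
  repeat {
    full <- fit_glmm(data, spec)
    candidates <- sort(setdiff(spec$fixed, spec$forced))
    if (!length(candidates)) break
    tests <- lapply(candidates, function(tm) {
      red_spec <- model_spec(spec$response, spec$family,
                             fixed = setdiff(spec$fixed, tm),
                             random = spec$random, forced = spec$forced)
      likelihood_ratio_test(full, fit_glmm(data, red_spec))
    })
    ps <- vapply(tests, `[[`, numeric(1), "p_value")
    worst <- which.max(ps)  # ties: first in alphabetical candidate order
    if (ps[worst] <= threshold) {
      step <- step + 1L
      for (j in seq_along(candidates))
        trace[[length(trace) + 1L]] <- data.frame(
          step = step, term = candidates[j], chisq = tests[[j]]$chisq,
          df = tests[[j]]$df, p_value = ps[j], action = "retained",
          stringsAsFactors = FALSE)
      break
    }
    step <- step + 1L
    trace[[length(trace) + 1L]] <- data.frame(
      step = step, term = candidates[worst], chisq = tests[[worst]]$chisq,
      df = tests[[worst]]$df, p_value = ps[worst], action = "dropped",
      stringsAsFactors = FALSE)
    spec <- model_spec(spec$response, spec$family,
                       fixed = setdiff(spec$fixed, candidates[worst]),
                       random = spec$random, forced = spec$forced)
  }
  final <- fit_glmm(data, spec)
  final$elimination_trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), term = character(), chisq = numeric(),
               df = numeric(), p_value = numeric(), action = character(),
               stringsAsFactors = FALSE)
  final
}

#' Odds ratio for a binomial-model coefficient
#'
#' Exponentiates a log-odds estimate and its Wald interval:
#' \eqn{OR = e^{\hat\beta}}, CI \eqn{e^{\hat\beta \pm 1.96 SE}}.
#'
#' @param fit a binomial `"model_fit"`.
#' @param term coefficient name, matched exactly or as a prefix (so
#'   `"country"` finds `"countrySweden"` if unique).
#' @param level confidence level.
#' @return list with `term`, `OR`, `ci_low`, `ci_high`.
#' @export
odds_ratio <- function(fit, term, level = 0.95) {
  stopifnot(inherits(fit, "model_fit"))
  if (fit$spec$family != "binomial")
    stop("odds ratio is undefined for a gaussian model", call. = FALSE)
  co <- fit$coefficients
  i <- which(co$term == term)
  if (!length(i)) i <- which(startsWith(co$term, term))
  if (length(i) != 1)
    stop(sprintf("term '%s' does not identify a single coefficient", term),
         call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- co$estimate[i]; se <- co$se[i]
  list(term = co$term[i], OR = exp(est), ci_low = exp(est - z * se),
       ci_high = exp(est + z * se))
}

#' Stack the survey into respondent x species long format
#'
#' The respondent-level acceptance analysis treats carnivore species as a
#' predictor, so each respondent contributes one row per species with the
#' binarized acceptance of that species' poaching item. Factors are coded
#' with the conventional reference levels (male, secondary school, Norway,
#' bear) unless `country_ref` overrides the country baseline.
#'
#' @param survey a survey table.
#' @param regions optional region table to merge municipality covariates
#'   (human density, big-game tradition, wolf zone, carnivore densities).
#' @param species subset of species to stack (default all four).
#' @param country_ref reference level for the country factor.
#' @return a long `data.frame` with an `accept` 0/1 column.
#' @export
respondent_model_data <- function(survey, regions = NULL,
                                  species = names(poaching_items()),
                                  country_ref = "Norway") {
  items <- poaching_items()[species]
  long <- do.call(rbind, lapply(names(items), function(sp) {
    d <- survey[c("respondent_id", "municipality_id", "county_id", "country",
                  "sex", "age", "education")]
    d$species <- sp
    d$accept <- binarize_acceptance(survey[[items[[sp]]]])
    d
  }))
  long$sex <- factor(long$sex, levels = c("male", "female"))
  long$education <- factor(long$education, levels = education_levels())
  long$country <- stats::relevel(factor(long$country), ref = country_ref)
  long$species <- factor(long$species, levels = names(poaching_items())[
    names(poaching_items()) %in% species])
  if (!is.null(regions)) {
    keep <- setdiff(colnames(regions), c("county_id", "country"))
    long <- merge(long, regions[keep], by = "municipality_id", sort = FALSE)
    long$log_human_density <- log(long$human_density)
  }
  long[order(long$respondent_id, long$species), , drop = FALSE]
}
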