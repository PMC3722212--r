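#' Configuration for the synthetic survey generator
#'
#' Builds and validates the configuration driving the geographically
#' stratified survey simulator. The defaults emulate the design of the
#' Scandinavian carnivore-poaching attitude study this package models:
#' every municipality in Norway (429) and Sweden (280) is surveyed with 4-5
#' telephone respondents, municipalities nest in 18 (Norway) and 19 (Sweden)
#' counties, and the species-specific poaching-acceptance items follow a
#' logistic model on the respondent's country, age, sex and education with a
#' municipality random intercept.
#'
#' @details
#' The acceptance process works on the log-odds scale. A respondent's linear
#' predictor is
#' \deqn{\eta = \beta_0 + \beta_{country} I(\mathrm{Norway}) + \beta_{age} \cdot age +
#'   \beta_{sex} I(\mathrm{female}) + \beta_{edu}(level) + u_{municipality}}
#' with \eqn{u \sim N(0, \sigma_u^2)}. Each of the four species items (6-9) is
#' produced by thresholding \eqn{\eta + e_s} at the ordinal cut points, where
#' the noise copies \eqn{e_s} share a respondent factor (equicorrelation
#' `species_latent_correlation` across species) and are marginally standard
#' logistic via a Gaussian copula. Because the third cut point is fixed at 0,
#' the binarized item (category 4 or 5) is exactly a Bernoulli draw with
#' probability `plogis(eta)` — the generator's ordinal responses and its
#' logistic "truth" coefficients are consistent by construction.
#' `beta_country` is the magnitude of the Norway-Sweden log-odds gap, applied
#' to Norway (the high-acceptance country).
#'
#' The remaining 12 items come from an equicorrelated Gaussian battery
#' (`item_equicorrelation`) sharing the same respondent factor, cut into five
#' equiprobable categories, so the 16-item internal consistency (Cronbach's
#' alpha) is tunable.
#'
#' @param n_municipalities named integer vector, municipalities per country.
#' @param n_counties named integer vector, counties per country.
#' @param respondents_range integer length-2, inclusive range of respondents
#'   drawn per municipality.
#' @param intercept baseline log-odds of accepting poaching (reference:
#'   Swedish male respondent, secondary school, age 0).
#' @param beta_country Norway-Sweden log-odds gap (applied to Norway).
#' @param beta_age log-odds change per year of age.
#' @param beta_sex_female log-odds change for female vs male respondents.
#' @param beta_education named vector of log-odds offsets by education level
#'   (reference level first, at 0).
#' @param sigma_municipality standard deviation of the municipality random
#'   intercept (log-odds scale).
#' @param species_latent_correlation equicorrelation of the four species
#'   latent noise copies, in `[0, 1]`.
#' @param item_equicorrelation latent equicorrelation of the 12-item general
#'   attitude battery, in `[0, 1)`.
#' @param ordinal_cuts increasing cut points (latent logistic scale) between
#'   the five response categories; the third must be 0 so that binarized
#'   acceptance matches the logistic model.
#' @param age_range inclusive integer range for respondent age.
#' @param p_female probability a respondent is female.
#' @param education_probs probabilities of the four education levels.
#' @param big_game_tradition_prob named per-country probability that a
#'   municipality reports strong big-game hunting traditions.
#' @param human_density_meanlog,human_density_sdlog log-normal parameters for
#'   municipality human density (persons/km^2).
#' @param sheep_density_meanlog,sheep_density_sdlog log-normal parameters for
#'   Norwegian municipality free-ranging sheep density (sheep/km^2); Swedish
#'   sheep density is structurally 0 (fenced flocks are not modelled).
#' @param carnivore_density_meanlog,carnivore_density_sdlog log-normal
#'   parameters for county-level carnivore densities.
#' @param cross_species_correlation latent correlation between the four
#'   species' county densities, in `[0, 1]`.
#' @param wolf_zone_fraction fraction of Norwegian municipalities inside the
#'   wolf management zone (Sweden has no wolf zone).
#' @param missingness probability an item response is missing (default 0: the
#'   generator emits completed interviews).
#' @param seed master seed for the generator's random streams.
#' @return a validated list of class `"generator_config"`.
#' @export
#' @examples
#' cfg <- generator_config(seed = 1)
#' cfg$n_municipalities
generator_config <- function(n_municipalities = c(Norway = 429L, Sweden = 280L),
                             n_counties = c(Norway = 18L, Sweden = 19L),
                             respondents_range = c(4L, 5L),
                             intercept = -4.8,
                             beta_country = 1.35,
                             beta_age = 0.016,
                             beta_sex_female = -0.18,
                             beta_education = c(secondary = 0, high_school = 0.41,
                                                undergraduate = 0.79, graduate = 1.36),
                             sigma_municipality = 0.5,
                             species_latent_correlation = 0.90,
                             item_equicorrelation = 0.28,
                             ordinal_cuts = c(-3, -1.5, 0, 1.5),
                             age_range = c(18L, 80L),
                             p_female = 0.5,
                             education_probs = rep(0.25, 4),
                             big_game_tradition_prob = c(Norway = 0.63, Sweden = 0.23),
                             human_density_meanlog = 2.3,
                             human_density_sdlog = 1.3,
                             sheep_density_meanlog = 1.0,
                             sheep_density_sdlog = 1.0,
                             carnivore_density_meanlog = -3,
                             carnivore_density_sdlog = 1,
                             cross_species_correlation = 0.75,
                             wolf_zone_fraction = 0.1,
                             missingness = 0,
                             seed = 1L) {
  cfg <- list(
    n_municipalities = n_municipalities, n_counties = n_counties,
    respondents_range = as.integer(respondents_range),
    intercept = intercept, beta_country = beta_country, beta_age = beta_age,
    beta_sex_female = beta_sex_female, beta_education = beta_education,
    sigma_municipality = sigma_municipality,
    species_latent_correlation = species_latent_correlation,
    item_equicorrelation = item_equicorrelation,
    ordinal_cuts = ordinal_cuts,
    age_range = as.integer(age_range), p_female = p_female,
    education_probs = education_probs,
    big_game_tradition_prob = big_game_tradition_prob,
    human_density_meanlog = human_density_meanlog,
    human_density_sdlog = human_density_sdlog,
    sheep_density_meanlog = sheep_density_meanlog,
    sheep_density_sdlog = sheep_density_sdlog,
    carnivore_density_meanlog = carnivore_density_meanlog,
    carnivore_density_sdlog = carnivore_density_sdlog,
    cross_species_correlation = cross_species_correlation,
    wolf_zone_fraction = wolf_zone_fraction,
    missingness = missingness,
    seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid generator config: field '%s' %s", field, why),
         call. = FALSE)
  }
  chk_prob <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      fail(field, "must be a probability in [0, 1]")
  }
  for (f in c("n_municipalities", "n_counties")) {
    x <- cfg[[f]]
    if (length(x) != 2L || is.null(names(x)) ||
        !setequal(names(x), c("Norway", "Sweden")))
      fail(f, "must be named with 'Norway' and 'Sweden'")
    if (any(x < 1) || any(x != round(x))) fail(f, "must be positive integers")
  }
  if (any(cfg$n_counties[c("Norway", "Sweden")] >
          cfg$n_municipalities[c("Norway", "Sweden")]))
    fail("n_counties", "cannot exceed n_municipalities in either country")
  if (length(cfg$respondents_range) != 2L ||
      cfg$respondents_range[1] > cfg$respondents_range[2] ||
      cfg$respondents_range[1] < 1)
    fail("respondents_range", "must be an increasing positive integer pair")
  if (cfg$sigma_municipality < 0) fail("sigma_municipality", "must be >= 0")
  chk_prob(cfg$species_latent_correlation, "species_latent_correlation")
  if (cfg$item_equicorrelation < 0 || cfg$item_equicorrelation >= 1)
    fail("item_equicorrelation", "must be in [0, 1)")
  if (length(cfg$ordinal_cuts) != 4L || is.unsorted(cfg$ordinal_cuts, strictly = TRUE))
    fail("ordinal_cuts", "must be 4 strictly increasing values")
  if (cfg$ordinal_cuts[3] != 0)
    fail("ordinal_cuts", "must have its third cut at 0 (acceptance threshold)")
  chk_prob(cfg$p_female, "p_female")
  if (length(cfg$education_probs) != 4L || abs(sum(cfg$education_probs) - 1) > 1e-8)
    fail("education_probs", "must be 4 probabilities summing to 1")
  chk_prob(cfg$education_probs, "education_probs")
  chk_prob(cfg$big_game_tradition_prob, "big_game_tradition_prob")
  if (!setequal(names(cfg$big_game_tradition_prob), c("Norway", "Sweden")))
    fail("big_game_tradition_prob", "must be named with 'Norway' and 'Sweden'")
  for (f in c("human_density_sdlog", "sheep_density_sdlog",
              "carnivore_density_sdlog"))
    if (cfg[[f]] < 0) fail(f, "must be >= 0")
  chk_prob(cfg$cross_species_correlation, "cross_species_correlation")
  chk_prob(cfg$wolf_zone_fraction, "wolf_zone_fraction")
  chk_prob(cfg$missingness, "missingness")
  if (length(cfg$beta_education) != 4L)
    fail("beta_education", "must give 4 education-level coefficients")
  if (cfg$age_range[1] > cfg$age_range[2]) fail("age_range", "must be increasing")
  cfg
}

#' Species covered by the poaching-acceptance items
#'
#' Items 6-9 of the questionnaire ask whether poaching of each large
#' carnivore is acceptable; this maps species names to item columns.
#'
#' @return named character vector `c(bear = "item_6", ...)`.
#' @export
poaching_items <- function() {
  c(bear = "item_6", wolf = "item_7", wolverine = "item_8", lynx = "item_9")
}

education_levels <- function() {
  c("secondary", "high_school", "undergraduate", "graduate")
}

carnivore_species <- function() c("bear", "wolf", "wolverine", "lynx")

# Equicorrelated standard-normal matrix via the one-factor construction
# x = sqrt(rho) f + sqrt(1 - rho) e.
equicorr_normal <- function(n, k, rho) {
  f <- stats::rnorm(n)
  sqrt(rho) * matrix(f, n, k) + sqrt(1 - rho) * matrix(stats::rnorm(n * k), n, k)
}

#' Build the municipality/county region table
#'
#' Generates one record per municipality with its county and country ids and
#' the region covariates the analysis uses: human density, big-game-hunting
#' tradition, free-ranging sheep density (Norway only), wolf-zone membership
#' (Norway only) and current plus historical (1856-1860 bounty era analogue)
#' county-level densities of bear, wolf, wolverine and lynx. Carnivore
#' densities are drawn from a log-normal with a configurable latent
#' cross-species correlation, emulating the strong co-occurrence of species
#' (bear-wolverine rank correlation near 0.75) seen in registry data.
#'
#' @param config a [generator_config()].
#' @param seed optional override of the region-stage seed (defaults to a
#'   stream derived from `config$seed`).
#' @return a `data.frame` with one row per municipality; county-level
#'   covariates are replicated across a county's municipalities.
#' @export
#' @examples
#' head(build_regions(generator_config(
#'   n_municipalities = c(Norway = 6, Sweden = 4),
#'   n_counties = c(Norway = 2, Sweden = 2))))
build_regions <- function(config, seed = NULL) {
  config <- validate_generator_config(config)
  set.seed(seed %||% derive_seed(config$seed, 1L))
  sp <- carnivore_species()
  one_country <- function(country) {
    code <- c(Norway = "NO", Sweden = "SE")[[country]]
    n_m <- config$n_municipalities[[country]]
    n_c <- config$n_counties[[country]]
    county_of <- sort(rep_len(seq_len(n_c), n_m))
    # county-level carnivore densities, current and historical, with
    # cross-species latent correlation
    dens <- lapply(c("current", "historical"), function(period) {
      z <- equicorr_normal(n_c, length(sp), config$cross_species_correlation)
      q <- stats::qlnorm(stats::pnorm(z), config$carnivore_density_meanlog,
                         config$carnivore_density_sdlog)
      colnames(q) <- paste0(sp, "_density_", period)
      q
    })
    dens <- do.call(cbind, dens)
    is_no <- country == "Norway"
    df <- data.frame(
      municipality_id = sprintf("%s-M%03d", code, seq_len(n_m)),
      county_id = sprintf("%s-C%02d", code, county_of),
      country = country,
      human_density = stats::rlnorm(n_m, config$human_density_meanlog,
                                    config$human_density_sdlog),
      big_game_tradition = stats::rbinom(
        n_m, 1L, config$big_game_tradition_prob[[country]]),
      sheep_density = if (is_no)
        stats::rlnorm(n_m, config$sheep_density_meanlog,
                      config$sheep_density_sdlog) else 0,
      wolf_zone = if (is_no)
        stats::rbinom(n_m, 1L, config$wolf_zone_fraction) else 0L,
      stringsAsFactors = FALSE)
    cbind(df, as.data.frame(dens[county_of, , drop = FALSE], row.names = FALSE))
  }
  out <- rbind(one_country("Norway"), one_country("Sweden"))
  rownames(out) <- NULL
  out
}

#' Draw the respondent skeleton (demographics only)
#'
#' Samples 4-5 respondents (configurable) per municipality — the
#' geographically stratified design that gives rural areas the same weight
#' as cities — with sex, age and education drawn from the configured
#' marginals.
#'
#' @param regions a region table from [build_regions()].
#' @param config a [generator_config()].
#' @param seed optional override of the sampling-stage seed.
#' @return a `data.frame` with respondent_id, municipality_id, county_id,
#'   country, sex, age, education.
#' @export
sample_respondents <- function(regions, config, seed = NULL) {
  config <- validate_generator_config(config)
  if (!NROW(regions)) stop("regions table is empty", call. = FALSE)
  set.seed(seed %||% derive_seed(config$seed, 2L))
  rng <- config$respondents_range
  n_per <- if (rng[1] == rng[2]) rep(rng[1], nrow(regions))
           else sample(rng[1]:rng[2], nrow(regions), replace = TRUE)
  idx <- rep(seq_len(nrow(regions)), n_per)
  n <- length(idx)
  data.frame(
    respondent_id = sprintf("R%05d", seq_len(n)),
    municipality_id = regions$municipality_id[idx],
    county_id = regions$county_id[idx],
    country = regions$country[idx],
    sex = ifelse(stats::runif(n) < config$p_female, "female", "male"),
    age = sample(config$age_range[1]:config$age_range[2], n, replace = TRUE),
    education = sample(education_levels(), n, replace = TRUE,
                       prob = config$education_probs),
    stringsAsFactors = FALSE)
}

#' Generate the 16-item Likert responses
#'
#' Fills in items 1-16 for a respondent skeleton. Items 6-9 (poaching
#' acceptance per species) follow the thresholded latent-logistic model
#' described in [generator_config()]; by construction their binarized form
#' (response 4 or 5) is Bernoulli with the logistic probability implied by
#' the configured fixed effects and municipality random intercept. The other
#' 12 items come from an equicorrelated latent battery sharing the
#' respondent factor.
#'
#' @param skeleton output of [sample_respondents()].
#' @param regions the region table the skeleton was drawn from.
#' @param config a [generator_config()].
#' @param seed optional override of the response-stage seed.
#' @return the skeleton with columns `item_1` ... `item_16` appended
#'   (integers 1-5; 1 = strongly disagree, 5 = strongly agree).
#' @export
generate_responses <- function(skeleton, regions, config, seed = NULL) {
  config <- validate_generator_config(config)
  unknown <- !(skeleton$municipality_id %in% regions$municipality_id)
  if (any(unknown))
    stop(sprintf("unknown municipality id in skeleton row(s) %s: %s",
                 paste(utils::head(which(unknown), 5), collapse = ", "),
                 paste(utils::head(unique(skeleton$municipality_id[unknown]), 5),
                       collapse = ", ")), call. = FALSE)
  set.seed(seed %||% derive_seed(config$seed, 3L))
  n <- nrow(skeleton)
  country <- regions$country[match(skeleton$municipality_id,
                                   regions$municipality_id)]

  mun <- unique(skeleton$municipality_id)
  u <- stats::rnorm(length(mun), 0, config$sigma_municipality)
  names(u) <- mun

  beta_edu <- config$beta_education
  names(beta_edu) <- education_levels()
  eta <- config$intercept +
    config$beta_country * (country == "Norway") +
    config$beta_age * skeleton$age +
    config$beta_sex_female * (skeleton$sex == "female") +
    beta_edu[skeleton$education] +
    u[skeleton$municipality_id]

  f <- stats::rnorm(n)  # respondent factor shared across all 16 items
  rho <- config$species_latent_correlation
  cuts <- config$ordinal_cuts
  species_item <- function() {
    z <- sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(n)
    e <- stats::qlogis(stats::pnorm(z))  # marginally standard logistic
    findInterval(eta + e, cuts) + 1L
  }
  items <- matrix(NA_integer_, n, 16,
                  dimnames = list(NULL, paste0("item_", 1:16)))
  for (col in poaching_items()) items[, col] <- species_item()

  lam <- config$item_equicorrelation
  battery_cuts <- stats::qnorm(c(0.2, 0.4, 0.6, 0.8))
  for (col in setdiff(colnames(items), poaching_items())) {
    g <- sqrt(lam) * f + sqrt(1 - lam) * stats::rnorm(n)
    items[, col] <- findInterval(g, battery_cuts) + 1L
  }
  if (config$missingness > 0) {
    drop <- matrix(stats::runif(n * 16) < config$missingness, n, 16)
    items[drop] <- NA_integer_
  }
  cbind(skeleton, as.data.frame(items))
}

#' Run the full survey simulation
#'
#' Convenience wrapper chaining [build_regions()], [sample_respondents()]
#' and [generate_responses()] under the config's derived seed streams.
#'
#' @param config a [generator_config()].
#' @return `list(regions = <region table>, survey = <survey table>)`.
#' @export
#' @examples
#' sim <- simulate_survey(generator_config(
#'   n_municipalities = c(Norway = 8, Sweden = 6),
#'   n_counties = c(Norway = 2, Sweden = 2), seed = 42))
#' dim(sim$survey)
simulate_survey <- function(config) {
  regions <- build_regions(config)
  skeleton <- sample_respondents(regions, config)
  survey <- generate_responses(skeleton, regions, config)
  list(regions = regions, survey = survey)
}
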