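#' Write the survey and region tables to CSV
#'
#' Runs the generator end-to-end and writes `survey.csv`, `regions.csv`
#' and a sidecar `config_echo.txt` (one `name = value` line per scalar or
#' comma-separated vector field, documenting exactly the configuration and
#' master seed that produced the files).
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
run_simulate <- function(config, out_dir) {
  config <- validate_generator_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_survey(config)
  paths <- list(survey = file.path(out_dir, "survey.csv"),
                regions = file.path(out_dir, "regions.csv"),
                config = file.path(out_dir, "config_echo.txt"))
  utils::write.csv(sim$survey, paths$survey, row.names = FALSE)
  utils::write.csv(sim$regions, paths$regions, row.names = FALSE)
  echo <- vapply(names(unclass(config)), function(nm) {
    v <- config[[nm]]
    sprintf("%s = %s", nm, paste(
      if (is.numeric(v)) format(v, digits = 15, trim = TRUE) else as.character(v),
      collapse = ", "))
  }, character(1))
  writeLines(echo, paths$config)
  invisible(paths)
}

#' Read a survey or region CSV written by [run_simulate()]
#'
#' @param path CSV path.
#' @return a `data.frame`.
#' @export
read_survey_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

check_survey_schema <- function(survey) {
  need <- c("respondent_id", "municipality_id", "county_id", "country",
            "sex", "age", "education", paste0("item_", 1:16))
  missing <- setdiff(need, colnames(survey))
  if (length(missing))
    stop(sprintf("survey table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (it in paste0("item_", 1:16)) {
    bad <- which(!is.na(survey[[it]]) & !(survey[[it]] %in% 1:5))
    if (length(bad))
      stop(sprintf("survey column %s has out-of-range value(s) at row(s) %s",
                   it, paste(utils::head(bad, 5), collapse = ", ")),
           call. = FALSE)
  }
  invisible(survey)
}

#' Default candidate terms for the respondent acceptance model
#'
#' Country, species, big-game tradition, log human density and the current
#' and historical carnivore densities. For Norway-only input the country
#' term is dropped (constant) and the Norway-specific predictors — wolf
#' zone and log sheep density — enter; these analyses are only meaningful
#' for Norway, where sheep range freely and a wolf zone exists.
#'
#' @param survey survey table (used to detect a single-country input).
#' @param regions region table (supplies the density column names).
#' @return character vector of model terms.
#' @export
default_model_terms <- function(survey, regions) {
  norway_only <- identical(unique(survey$country), "Norway")
  dens_terms <- grep("_density_(current|historical)$", colnames(regions),
                     value = TRUE)
  c(if (!norway_only) "country", "species",
    "big_game_tradition", "log_human_density", dens_terms,
    if (norway_only) c("wolf_zone", "I(log(sheep_density))"))
}

#' Run the full analysis and write the report tables
#'
#' Produces the package's standard set of result tables from a survey and
#' region table (in memory or as CSV paths):
#' * `acceptance_by_country.csv` — percentage accepting poaching per
#'   species and country, with Wilson 95% score intervals;
#' * `pci_by_county.csv` — the conflict index per county and species, with
#'   percentile bootstrap intervals;
#' * `pci_summary.csv` — mean county PCI per species and country with a
#'   t-interval across counties;
#' * `correlations_county.csv` / `correlations_municipality.csv` — rank
#'   correlations between group mean acceptance and group PCI;
#' * `species_correlations.csv` — individual-level rank correlations
#'   between the four species items;
#' * `model_respondent.csv` and `elimination_trace.csv` — the backward-
#'   eliminated respondent-level binomial mixed model;
#' * `reliability.csv` — Cronbach's alpha for all 16 items, the 4 poaching
#'   items and the 12 remaining items.
#'
#' When the input contains only Norway, the wolf-zone and (log) sheep
#' density terms enter the candidate model terms and the country term is
#' dropped (it would be constant); this mirrors analyses that are only
#' valid for Norway.
#'
#' @param survey survey table or CSV path.
#' @param regions region table or CSV path.
#' @param out_dir output directory.
#' @param pci_variant `"pci2"` (default) or `"pci1"`.
#' @param model_terms candidate (non-forced) fixed terms for the
#'   respondent model; `NULL` selects the default set (country, species,
#'   big-game tradition, log human density, current and historical
#'   carnivore densities, plus wolf zone and log sheep density for
#'   Norway-only input).
#' @param forced_terms fixed terms exempt from elimination (default the
#'   individual covariates sex, age, education).
#' @param bootstrap_B bootstrap replicates per county PCI interval.
#' @param ci_level confidence level for all intervals.
#' @param threshold backward-elimination retention threshold.
#' @param seed seed for bootstrap resampling.
#' @return invisibly, a named list of the output data frames.
#' @export
run_analyze <- function(survey, regions, out_dir, pci_variant = c("pci2", "pci1"),
                        model_terms = NULL,
                        forced_terms = c("sex", "age", "education"),
                        bootstrap_B = 500L, ci_level = 0.95,
                        threshold = 0.05, seed = 1L) {
  pci_variant <- match.arg(pci_variant)
  if (is.character(survey)) survey <- read_survey_csv(survey)
  if (is.character(regions)) regions <- read_survey_csv(regions)
  check_survey_schema(survey)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  items <- poaching_items()
  countries <- unique(survey$country)

  # Table-4 left block analogue: % accepting, Wilson interval
  acceptance <- do.call(rbind, lapply(names(items), function(sp) {
    do.call(rbind, lapply(countries, function(ct) {
      v <- binarize_acceptance(
        survey[[items[[sp]]]][survey$country == ct])
      v <- v[!is.na(v)]
      ci <- wilson_ci(sum(v), length(v), ci_level)
      data.frame(species = sp, country = ct, n = length(v),
                 percent = 100 * mean(v), ci_low = 100 * ci[["lower"]],
                 ci_high = 100 * ci[["upper"]], stringsAsFactors = FALSE)
    }))
  }))

  pci_county <- pci_by_group(survey, "county", variant = pci_variant)
  boot <- t(vapply(seq_len(nrow(pci_county)), function(i) {
    row <- pci_county[i, ]
    if (is.na(row$value)) return(c(NA_real_, NA_real_))
    sc <- recode_centered(survey[[row$item]][survey$county_id == row$group_id])
    ci <- pci_bootstrap_ci(sc[!is.na(sc)], B = bootstrap_B, level = ci_level,
                           seed = derive_seed(seed, 10L + i),
                           variant = pci_variant)
    c(ci$lower, ci$upper)
  }, numeric(2)))
  pci_county$ci_low <- boot[, 1]
  pci_county$ci_high <- boot[, 2]

  pci_summary <- do.call(rbind, lapply(names(items), function(sp) {
    do.call(rbind, lapply(countries, function(ct) {
      v <- pci_county$value[pci_county$species == sp &
                              pci_county$country == ct]
      ci <- t_ci(v, ci_level)
      data.frame(species = sp, country = ct, n_counties = sum(is.finite(v)),
                 mean_pci = mean(v, na.rm = TRUE), ci_low = ci[["lower"]],
                 ci_high = ci[["upper"]], stringsAsFactors = FALSE)
    }))
  }))

  corr_county <- acceptance_pci_correlations(survey, "county",
                                             variant = pci_variant,
                                             on_degenerate = "na")
  corr_mun <- acceptance_pci_correlations(survey, "municipality",
                                          variant = pci_variant,
                                          on_degenerate = "na")
  species_corr <- species_item_correlations(survey)

  long <- respondent_model_data(survey, regions)
  if (is.null(model_terms)) model_terms <- default_model_terms(survey, regions)
  spec <- model_spec("accept", "binomial",
                     fixed = c(forced_terms, model_terms),
                     random = "municipality_id", forced = forced_terms)
  fit <- backward_eliminate(long, spec, threshold = threshold)
  model_tab <- fit$coefficients
  model_tab$sigma_u <- fit$sigma_u
  model_tab$n_obs <- fit$n_obs
  model_tab$n_groups <- fit$n_groups
  model_tab$converged <- fit$converged

  item_mat <- survey[paste0("item_", 1:16)]
  alpha_row <- function(label, cols) {
    a_raw <- cronbach_alpha(item_mat[cols], "raw")
    a_std <- cronbach_alpha(item_mat[cols], "standardized")
    data.frame(scale = label, n_items = length(cols),
               alpha_raw = a_raw$alpha, alpha_standardized = a_std$alpha,
               n_respondents = a_raw$n_respondents, stringsAsFactors = FALSE)
  }
  reliability <- rbind(
    alpha_row("all_16_items", seq_len(16)),
    alpha_row("poaching_items_6_9", match(items, paste0("item_", 1:16))),
    alpha_row("other_12_items",
              setdiff(seq_len(16), match(items, paste0("item_", 1:16)))))

  out <- list(acceptance_by_country = acceptance,
              pci_by_county = pci_county,
              pci_summary = pci_summary,
              correlations_county = corr_county,
              correlations_municipality = corr_mun,
              species_correlations = species_corr,
              model_respondent = model_tab,
              elimination_trace = fit$elimination_trace,
              reliability = reliability)
  for (nm in names(out))
    utils::write.csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  invisible(out)
}

#' Render a plain-text summary of an analysis run
#'
#' Reads the tables written by [run_analyze()] and prints the headline
#' numbers: acceptance percentages by country, the Norway-vs-Sweden odds
#' ratio implied by the retained country coefficient, the county-level
#' acceptance-PCI correlation range, and the reliability coefficients.
#'
#' @param out_dir directory holding the [run_analyze()] outputs.
#' @return the summary text, invisibly; the text is also printed.
#' @export
run_report <- function(out_dir) {
  need <- function(name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    if (!file.exists(p))
      stop(sprintf("missing analysis output: %s (run the analyze step first)",
                   p), call. = FALSE)
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  acc <- need("acceptance_by_country")
  corr <- need("correlations_county")
  model <- need("model_respondent")
  rel <- need("reliability")
  lines <- c("=== Survey analysis summary ===", "",
             "Acceptance of poaching (% agree or strongly agree):")
  for (ct in unique(acc$country)) {
    sub <- acc[acc$country == ct, ]
    lines <- c(lines, sprintf("  %s: %.1f-%.1f%% across species", ct,
                              min(sub$percent), max(sub$percent)))
  }
  crow <- model[grep("^country", model$term), , drop = FALSE]
  if (nrow(crow) == 1) {
    # coefficient is printed against the Norway reference; the Norway-vs-
    # Sweden odds ratio is exp(-estimate)
    gap <- -crow$estimate
    z <- stats::qnorm(0.975)
    lines <- c(lines, "", sprintf(
      "Country effect retained: Norway-Sweden log-odds gap %.2f;", gap),
      sprintf("  odds ratio Norway vs Sweden %.2f (95%% CI %.2f, %.2f)",
              exp(gap), exp(gap - z * crow$se), exp(gap + z * crow$se)))
  } else {
    lines <- c(lines, "", "Country effect not retained in the final model.")
  }
  lines <- c(lines, "", if (all(is.na(corr$r_sp))) {
    "County-level acceptance-PCI rank correlations: undefined (degenerate groups)"
  } else sprintf(
    "County-level acceptance-PCI rank correlations: %.2f to %.2f (n groups %d-%d)",
    min(corr$r_sp, na.rm = TRUE), max(corr$r_sp, na.rm = TRUE),
    min(corr$n), max(corr$n)))
  lines <- c(lines, "", "Internal consistency (Cronbach's alpha, raw):")
  for (i in seq_len(nrow(rel)))
    lines <- c(lines, sprintf("  %-20s alpha = %.2f (%d items)",
                              rel$scale[i], rel$alpha_raw[i], rel$n_items[i]))
  txt <- paste(lines, collapse = "\n")
  cat(txt, "\n")
  invisible(txt)
}
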