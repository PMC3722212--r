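# simulate a simple grouped binomial data set with known coefficients
sim_binary <- function(n_groups = 30, per_group = 40, beta_x = 1,
                       sigma_u = 0.5, seed = 1) {
  set.seed(seed)
  g <- rep(sprintf("g%02d", seq_len(n_groups)), each = per_group)
  u <- rnorm(n_groups, 0, sigma_u)
  names(u) <- unique(g)
  d <- data.frame(group = g,
                  x = rnorm(n_groups * per_group),
                  z1 = rnorm(n_groups * per_group),
                  z2 = rnorm(n_groups * per_group))
  d$y <- rbinom(nrow(d), 1, plogis(-1 + beta_x * d$x + u[d$group]))
  d
}

test_that("model specs validate their invariants", {
  expect_error(model_spec("y", "binomial", fixed = "x", forced = "w"),
               "subset")
  s <- model_spec("y", "binomial", fixed = c("x", "z1"), random = "group")
  expect_s3_class(s, "model_spec")
  expect_error(fit_glmm(sim_binary(), model_spec("y", "binomial",
                                                 fixed = "x",
                                                 random = "nope")),
               "nope")
  d <- sim_binary()
  d$y <- d$y + 1
  expect_error(fit_glmm(d, model_spec("y", "binomial", fixed = "x",
                                      random = "group")),
               "0/1")
})

test_that("with no true group variance the mixed fit matches the plain glm", {
  d <- sim_binary(sigma_u = 0, seed = 4, n_groups = 40, per_group = 50)
  mixed <- fit_glmm(d, model_spec("y", "binomial", fixed = "x",
                                  random = "group"))
  plain <- fit_glmm(d, model_spec("y", "binomial", fixed = "x"))
  expect_lt(mixed$sigma_u, 0.05)
  expect_equal(mixed$coefficients$estimate, plain$coefficients$estimate,
               tolerance = 1e-3)
})

test_that("mixed fits recover generating fixed effects and variance", {
  d <- sim_binary(beta_x = 1, sigma_u = 0.8, seed = 7, n_groups = 60,
                  per_group = 60)
  fit <- fit_glmm(d, model_spec("y", "binomial", fixed = "x",
                                random = "group"))
  co <- fit$coefficients
  est <- co$estimate[co$term == "x"]
  se <- co$se[co$term == "x"]
  expect_lt(abs(est - 1), 3 * se)
  expect_gt(fit$sigma_u, 0.4)
  expect_lt(fit$sigma_u, 1.2)
  expect_true(fit$converged)
  expect_equal(fit$n_groups, 60)
})

test_that("likelihood-ratio tests behave on identical and nested fits", {
  d <- sim_binary(seed = 2)
  spec_full <- model_spec("y", "binomial", fixed = c("x", "z1"),
                          random = "group")
  spec_red <- model_spec("y", "binomial", fixed = "x", random = "group")
  full <- fit_glmm(d, spec_full)
  red <- fit_glmm(d, spec_red)
  same <- likelihood_ratio_test(full, fit_glmm(d, spec_full))
  expect_equal(same$chisq, 0, tolerance = 1e-6)
  expect_equal(same$p_value, 1)
  lrt <- likelihood_ratio_test(full, red)
  expect_equal(lrt$df, 1)
  expect_gte(lrt$chisq, 0)
  expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
  # strong true effect is detected decisively
  strong <- likelihood_ratio_test(
    full, fit_glmm(d, model_spec("y", "binomial", fixed = "z1",
                                 random = "group")))
  expect_lt(strong$p_value, 1e-10)
  # non-nested pairs are refused
  other <- fit_glmm(d, model_spec("y", "binomial", fixed = "z2",
                                  random = "group"))
  expect_error(likelihood_ratio_test(full, other), "nested")
})

test_that("adding a term never decreases the log-likelihood", {
  d <- sim_binary(seed = 9)
  base <- fit_glmm(d, model_spec("y", "binomial", fixed = "x",
                                 random = "group"))
  bigger <- fit_glmm(d, model_spec("y", "binomial", fixed = c("x", "z1", "z2"),
                                   random = "group"))
  expect_gte(bigger$loglik, base$loglik - 1e-6)
})

test_that("backward elimination drops noise and keeps the real effect", {
  d <- sim_binary(beta_x = 1.2, seed = 11, n_groups = 40, per_group = 40)
  spec <- model_spec("y", "binomial", fixed = c("x", "z1", "z2"),
                     random = "group")
  fit <- backward_eliminate(d, spec)
  expect_true("x" %in% fit$spec$fixed)
  expect_false(any(c("z1", "z2") %in% fit$spec$fixed))
  tr <- fit$elimination_trace
  expect_equal(sum(tr$action == "dropped"), 2)
  expect_true(all(tr$p_value >= 0 & tr$p_value <= 1))
  expect_true(all(tr$p_value[tr$action == "retained"] <= 0.05))
})

test_that("forced terms are never eliminated", {
  d <- sim_binary(seed = 12)
  spec <- model_spec("y", "binomial", fixed = c("x", "z1"),
                     random = "group", forced = c("x", "z1"))
  fit <- backward_eliminate(d, spec)
  expect_setequal(fit$spec$fixed, c("x", "z1"))
  expect_equal(nrow(fit$elimination_trace), 0)
})

test_that("the county table has four species rows per county", {
  sim <- simulate_survey(generator_config(seed = 8))
  ct <- build_county_table(sim$survey, sim$regions)
  expect_equal(nrow(ct), (18 + 19) * 4)
  expect_equal(length(unique(ct$county_id)), 37)
  spec <- model_spec("mean_acceptance", "gaussian",
                     fixed = c("species", "country"), random = "county_id")
  fit <- fit_county_lmm(ct, spec)
  expect_equal(fit$n_obs, 148)
  expect_equal(fit$n_groups, 37)
  # Norway's mean acceptance is generated higher than Sweden's
  co <- fit$coefficients
  expect_lt(co$estimate[co$term == "countrySweden"], 0)
  expect_error(fit_county_lmm(ct, model_spec("accept", "binomial")),
               "gaussian")
})

test_that("a quadratic conflict-density relationship is recovered with a negative curvature", {
  # county PCI peaking at intermediate log human density
  set.seed(15)
  counties <- sprintf("c%02d", 1:37)
  d <- expand.grid(county_id = counties,
                   species = c("bear", "wolf", "wolverine", "lynx"))
  lhd <- rnorm(37, 3, 1.2)
  names(lhd) <- counties
  d$log_human_density <- lhd[d$county_id]
  u <- rnorm(37, 0, 0.02)
  names(u) <- counties
  d$pci <- 0.1 + 0.08 * d$log_human_density - 0.012 * d$log_human_density^2 +
    u[d$county_id] + rnorm(nrow(d), 0, 0.03)
  spec <- model_spec("pci", "gaussian",
                     fixed = c("species", "log_human_density",
                               "I(log_human_density^2)"),
                     random = "county_id")
  fit <- fit_glmm(d, spec)
  co <- fit$coefficients
  expect_lt(co$estimate[co$term == "I(log_human_density^2)"], 0)
})

test_that("odds ratios exponentiate the logit estimates", {
  fake <- structure(list(
    coefficients = data.frame(term = c("(Intercept)", "countrySweden"),
                              estimate = c(-3, 1.435), se = c(0.2, 0.158)),
    spec = model_spec("accept", "binomial", fixed = "country")),
    class = "model_fit")
  or <- odds_ratio(fake, "country")
  expect_equal(or$OR, exp(1.435), tolerance = 1e-8)
  expect_equal(round(or$OR, 1), 4.2)
  expect_equal(round(or$ci_low, 1), 3.1)
  expect_gt(or$ci_high, 5.7)
  expect_lt(or$ci_high, 5.76)
  fake$coefficients$estimate[2] <- 1.35
  expect_equal(round(odds_ratio(fake, "country")$OR, 2), 3.86)
  fake$coefficients$estimate[2] <- 0
  or0 <- odds_ratio(fake, "countrySweden")
  expect_equal(or0$OR, 1)
  expect_equal(or0$ci_low * or0$ci_high, 1, tolerance = 1e-10)
  gfake <- fake
  gfake$spec$family <- "gaussian"
  expect_error(odds_ratio(gfake, "country"), "gaussian")
  expect_error(odds_ratio(fake, "bogus"), "bogus")
})
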