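test_that("default region table covers every municipality with valid structure", {
  regions <- build_regions(generator_config(seed = 3))
  expect_equal(nrow(regions), 429 + 280)
  expect_equal(sum(regions$country == "Norway"), 429)
  expect_equal(sum(regions$country == "Sweden"), 280)
  expect_equal(length(unique(regions$county_id[regions$country == "Norway"])), 18)
  expect_equal(length(unique(regions$county_id[regions$country == "Sweden"])), 19)
  # every municipality in exactly one county, every county in one country
  expect_false(any(duplicated(regions$municipality_id)))
  cc <- unique(regions[c("county_id", "country")])
  expect_false(any(duplicated(cc$county_id)))
  # no wolf zone and no free-ranging sheep outside Norway
  expect_true(all(regions$wolf_zone[regions$country == "Sweden"] == 0))
  expect_true(all(regions$sheep_density[regions$country == "Sweden"] == 0))
  # carnivore densities are county-level: constant within county
  for (col in grep("_density_", colnames(regions), value = TRUE)) {
    per_county <- tapply(regions[[col]], regions$county_id,
                         function(v) length(unique(v)))
    expect_true(all(per_county == 1))
  }
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(generator_config(n_municipalities = c(Norway = -1, Sweden = 5)),
               "n_municipalities")
  expect_error(generator_config(wolf_zone_fraction = 1.5), "wolf_zone_fraction")
  expect_error(generator_config(sigma_municipality = -0.1), "sigma_municipality")
  expect_error(generator_config(n_municipalities = c(Norway = 5, Sweden = 5),
                                n_counties = c(Norway = 6, Sweden = 2)),
               "n_counties")
  expect_error(generator_config(education_probs = c(0.5, 0.5, 0.5, 0.5)),
               "education_probs")
  expect_error(generator_config(ordinal_cuts = c(-1, -0.5, 0.2, 1)),
               "ordinal_cuts")
})

test_that("degenerate covariate settings behave as documented", {
  r0 <- build_regions(small_config(wolf_zone_fraction = 0))
  expect_true(all(r0$wolf_zone == 0))
  # perfect cross-species correlation with equal marginals: identical ranks
  r1 <- build_regions(generator_config(
    n_municipalities = c(Norway = 40, Sweden = 40),
    n_counties = c(Norway = 20, Sweden = 20),
    cross_species_correlation = 1, seed = 5))
  for (ct in c("Norway", "Sweden")) {
    sub <- r1[r1$country == ct & !duplicated(r1$county_id), ]
    cur <- sub[grep("_density_current$", colnames(sub))]
    ranks <- apply(as.matrix(cur), 2, rank)
    expect_true(all(ranks == ranks[, 1]))
  }
})

test_that("respondent sampling honours the per-municipality range", {
  regions <- build_regions(generator_config(seed = 2))
  cfg <- generator_config(seed = 2)
  sk <- sample_respondents(regions, cfg)
  counts <- table(sk$municipality_id)
  expect_true(all(counts >= 4 & counts <= 5))
  expect_gte(nrow(sk), 4 * 709)
  expect_lte(nrow(sk), 5 * 709)
  # degenerate range: exactly 4 everywhere
  sk4 <- sample_respondents(regions, generator_config(
    respondents_range = c(4, 4), seed = 2))
  expect_true(all(table(sk4$municipality_id) == 4))
  expect_error(sample_respondents(regions[0, ], cfg), "empty")
})

test_that("the generator is deterministic given config and seed", {
  s1 <- small_sim(seed = 11)
  s2 <- small_sim(seed = 11)
  expect_identical(s1, s2)
  s3 <- small_sim(seed = 12)
  expect_false(identical(s1$survey, s3$survey))
})

test_that("survey items are complete Likert responses in 1..5", {
  s <- small_sim(seed = 4)$survey
  items <- as.matrix(s[paste0("item_", 1:16)])
  expect_false(anyNA(items))
  expect_true(all(items %in% 1:5))
})

test_that("unknown municipality ids are reported by row", {
  sim <- small_sim(seed = 1)
  cfg <- small_config(seed = 1)
  sk <- sample_respondents(sim$regions, cfg)
  sk$municipality_id[3] <- "XX-M999"
  expect_error(generate_responses(sk, sim$regions, cfg), "XX-M999")
})

test_that("perfect species correlation collapses items 6-9 to one response", {
  sim <- small_sim(seed = 9, species_latent_correlation = 1)
  it <- as.matrix(sim$survey[poaching_items()])
  expect_true(all(it == it[, 1]))
})

test_that("with no effects the binarized rate matches the intercept logit", {
  # closed form: P(item >= 4) = plogis(beta0) when all betas and sigma are 0
  cfg <- generator_config(
    n_municipalities = c(Norway = 30, Sweden = 30),
    n_counties = c(Norway = 5, Sweden = 5),
    respondents_range = c(40, 40),
    intercept = qlogis(0.3), beta_country = 0, beta_age = 0,
    beta_sex_female = 0, beta_education = rep(0, 4),
    sigma_municipality = 0, seed = 21)
  s <- simulate_survey(cfg)$survey
  rate <- mean(binarize_acceptance(s$item_7))
  expect_equal(rate, 0.3, tolerance = 0.05)
})

test_that("respondent order does not affect group statistics", {
  s <- small_sim(seed = 6)$survey
  set.seed(1)
  shuffled <- s[sample(nrow(s)), ]
  a <- pci_by_group(s, "county")
  b <- pci_by_group(shuffled, "county")
  expect_equal(a, b)
})
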