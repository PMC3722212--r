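test_that("PCI2 worked examples decompose correctly", {
  r <- pci2(c(1, -1, 0, 0))
  expect_equal(r$numerator, 2)   # one opposite-sign pair at distance 2
  expect_equal(r$maximum, 16)    # 2 * 2 * (2 * 2)
  expect_equal(r$value, 0.125)
  expect_equal(r$n_neutral, 2)
  r2 <- pci2(c(2, -2, 0))
  expect_equal(r2$numerator, 4)
  expect_equal(r2$maximum, 8)
  expect_equal(r2$value, 0.5)
  expect_equal(r2$n, r2$n_a + r2$n_u + r2$n_neutral)
})

test_that("PCI1 matches its direct formula", {
  expect_equal(pci1(c(2, 2, -2, -2))$value, 1)
  expect_equal(pci1(c(2, 2, 2, 2))$value, 0)
  expect_equal(pci1(c(1, -1, 0, 0))$value, 0.25)
})

test_that("degenerate PCI inputs are handled as documented", {
  expect_error(pci2(c(1)), "fewer than 2")
  expect_error(pci2(c(1, 3)), "3")
  expect_message(r <- pci2(c(0, 0, 0)), "neutral")
  expect_equal(r$value, 0)
  expect_equal(r$n_a, 0)
  expect_equal(r$n_u, 0)
})

test_that("both indices agree with brute-force oracles on random draws", {
  set.seed(14)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    sc <- sample(-2:2, n, replace = TRUE)
    expect_equal(pci2(sc)$value, pci2_brute(sc))
    expect_equal(pci1(sc)$value, pci1_brute(sc))
    # sign symmetry and permutation invariance
    expect_equal(pci2(-sc)$value, pci2(sc)$value)
    expect_equal(pci1(-sc)$value, pci1(sc)$value)
    expect_equal(pci2(sample(sc))$value, pci2(sc)$value)
  }
})

test_that("grouped PCI is a pure function of the group's response multiset", {
  s <- small_sim(seed = 2)$survey
  tab <- pci_by_group(s, "municipality", items = "item_6")
  # rebuild one group by hand
  g <- tab$group_id[5]
  sc <- recode_centered(s$item_6[s$municipality_id == g])
  expect_equal(tab$value[tab$group_id == g], pci2(sc)$value)
  # two municipalities with identical response multisets -> identical PCI
  toy <- data.frame(
    municipality_id = rep(c("A", "B"), each = 5),
    county_id = rep(c("CA", "CB"), each = 5),
    country = "Norway",
    item_6 = c(1, 5, 3, 4, 2, 2, 3, 1, 5, 4))  # same multiset, reordered
  t2 <- pci_by_group(toy, "municipality", items = "item_6")
  expect_equal(t2$value[t2$group_id == "A"], t2$value[t2$group_id == "B"])
})

test_that("municipality grouping on the Norway subset yields one row per municipality", {
  s <- simulate_survey(generator_config(seed = 5))$survey
  tab <- pci_by_group(s[s$country == "Norway", ], "municipality",
                      items = "item_6")
  expect_equal(nrow(tab), 429)
  expect_true(all(tab$flag_small))  # 4-5 respondents per municipality
})

test_that("grouped PCI flags small and undefined groups", {
  s <- small_sim(seed = 3)$survey
  one <- s[1, ]
  one$municipality_id <- "NO-M999"
  one$county_id <- "NO-C99"
  expect_warning(tab <- pci_by_group(rbind(s, one), "municipality",
                                     items = "item_7"),
                 "NO-M999")
  expect_true(is.na(tab$value[tab$group_id == "NO-M999"]))
  expect_error(pci_by_group(s, "county", items = "item_99"), "item_99")
})

test_that("between-county PCI spread shrinks as county samples grow", {
  # no between-group heterogeneity: spread across counties is pure noise
  base <- list(respondents_range = c(6, 6), sigma_municipality = 0,
               n_municipalities = c(Norway = 40, Sweden = 40),
               n_counties = c(Norway = 10, Sweden = 10))
  spread <- sapply(c(6, 60), function(k) {
    cfg <- do.call(generator_config, c(base, list(seed = 17)))
    cfg$respondents_range <- c(k, k)
    s <- simulate_survey(cfg)$survey
    tab <- pci_by_group(s, "county", items = "item_6")
    sd(tab$value)
  })
  expect_lt(spread[2], spread[1])
})

test_that("bootstrap intervals are reproducible and respect degeneracy", {
  sc <- recode_centered(c(1, 1, 2, 4, 5, 5, 3, 2, 4, 1))
  a <- pci_bootstrap_ci(sc, B = 500, seed = 99)
  b <- pci_bootstrap_ci(sc, B = 500, seed = 99)
  expect_identical(a, b)
  cons <- pci_bootstrap_ci(rep(2L, 10), B = 200, seed = 1)
  expect_equal(c(cons$lower, cons$upper), c(0, 0))
  split <- pci_bootstrap_ci(c(rep(2L, 5), rep(-2L, 5)), B = 1000, seed = 1)
  expect_equal(split$value, 1)
  expect_lt(split$lower, 1)  # resampling breaks the exact split
})
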