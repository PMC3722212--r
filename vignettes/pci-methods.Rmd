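---
title: "Conflict indices and mixed models for stratified attitude surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conflict indices and mixed models for stratified attitude surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Public acceptance of illegal hunting (poaching) of large carnivores — brown
bear, wolf, wolverine and lynx — varies geographically. Surveys drawn
proportionally to population measure mostly urban opinion, while the conflict
plays out in thinly populated rural areas. A geographically stratified design
instead interviews a fixed handful of residents (4–5) in *every*
municipality, giving each place equal weight. `pcisurvey` provides the full
toolchain for this kind of study: a synthetic survey generator with the
municipality/county/country structure, Likert coding utilities, the
Potential Conflict Index, rank-correlation and reliability statistics, and
binomial/Gaussian mixed models with likelihood-ratio backward elimination.

Because no respondent-level data from such telephone surveys are
redistributable, the generator is a first-class, tested component: it
defines the statistical conditions under which every downstream method is
validated.

## The Potential Conflict Index

Respondents rate "poaching of species X is acceptable" on a 5-point Likert
scale, recoded to centered scores $x_i \in \{-2,-1,0,+1,+2\}$
(`recode_centered()`). For a group of $n$ respondents:

* **PCI$_2$** (`pci2()`, the default) totals the pairwise distances between
  respondents on strictly opposite sides of neutral,
  $D = \sum_{i<j,\; x_i x_j < 0} |x_i - x_j|$, and divides by the maximum
  any $n$-sized group can attain, the half-at-each-extreme split
  $\delta = \lfloor n/2\rfloor \lceil n/2\rceil \cdot 2m$ (with $m = 2$ the
  extreme score). Neutral respondents enter $n$ (and hence $\delta$) but
  pair with nobody.
* **PCI$_1$** (`pci1()`) compares the summed magnitudes of the two sides:
  with $X_a = \sum_{x_i>0} x_i$, $X_u = \sum_{x_i<0} |x_i|$ and $Z = nm$
  the maximum possible sum of scores, the index is $2\min(X_a, X_u)/Z$,
  algebraically $(1 - |X_a - X_u|/X)\,(X/Z)$ for $X = X_a + X_u$.

Both live on $[0,1]$: 0 is complete consensus (one side empty), 1 maximal
polarization. Published descriptions of the index family are not always
internally consistent — verbal accounts built from side sums and
$Z = n\cdot\text{extreme}$ describe the first generation, while the second
generation is the pairwise-distance form — so the package implements both,
defaults to PCI$_2$, and exposes the variant as a flag everywhere
(`pci_by_group()`, `run_analyze(pci_variant =)`).

Numerical choices: for odd $n$ the maximal split is
$\lfloor n/2\rfloor\lceil n/2\rceil$ opposite pairs; an all-neutral group
returns 0 with a note (there is no disagreement to measure); groups with
$n < 2$ yield `NA`, and groups with $n < 8$ are flagged `flag_small` because
a 4–5 person municipality estimates the index very noisily. The test suite
checks both indices against brute-force pair enumeration on *every* score
multiset of size $\le 6$, plus bound, sign-symmetry and
minority-growth monotonicity properties.

Confidence intervals for a single group use a percentile bootstrap over
respondents (`pci_bootstrap_ci()`, default $B = 1000$); the per-species,
per-country summary of county PCI values uses a $t$-interval across
counties. Neither interval method is canonical in the literature; both are
stated choices here.

## The synthetic survey generator

`generator_config()` fixes the study conditions; the defaults are the
package's reference design:

| Parameter | Default | Meaning |
|---|---|---|
| municipalities | 429 Norway, 280 Sweden | one record each |
| counties | 18 / 19 | random-effect grouping for county analyses |
| respondents per municipality | 4–5 | stratified telephone design |
| intercept $\beta_0$ | $-4.8$ | baseline log-odds (Swedish male, secondary school) |
| country gap | $+1.35$ | Norway–Sweden log-odds gap, Norway high |
| age | $0.016$/yr | acceptance rises with age |
| sex (female) | $-0.18$ | |
| education (HS / BSc / grad) | $0.41 / 0.79 / 1.36$ | vs secondary school |
| municipality random SD $\sigma_u$ | 0.5 | spatial heterogeneity |
| species latent correlation | 0.90 | inter-item agreement of items 6–9 |
| battery equicorrelation | 0.28 | drives 16-item alpha |

A respondent's acceptance propensity is
$\eta = \beta_0 + \beta^\top x + u_{municipality}$. Each species item is
generated by thresholding $\eta + e_s$ at ordinal cut points
$(-3, -1.5, 0, 1.5)$, where the four noise copies $e_s$ share a respondent
factor (Gaussian copula with equicorrelation 0.90) and are marginally
standard logistic. Fixing the third cut at 0 makes the binarized item
("agree"/"strongly agree") *exactly* Bernoulli$(\mathrm{logit}^{-1}(\eta))$,
so the generator simultaneously produces realistic ordinal data for the PCI
and an exact binomial-GLMM truth for parameter-recovery experiments — the
reason a thresholded-latent design was chosen over, say, independent ordinal
draws. The remaining 12 attitude items come from an equicorrelated Gaussian
battery sharing the same respondent factor, cut into five equiprobable
categories.

Calibration of the free scale parameters was done once, against the
reference design, and is not revisited: the intercept $-4.8$ puts country
acceptance rates near 13% (Norway) and 4% (Sweden); the species latent
correlation 0.90 puts the mean pairwise inter-item rank correlation of
items 6–9 near 0.82; the battery equicorrelation 0.28 puts the 16-item raw
alpha near 0.88 (with the four strongly-correlated poaching items pulling it
above the 12-item battery alone). Sex is Bernoulli(0.5), age uniform on
18–80 and education uniform over four levels — neutral, configurable
defaults, since the design gives no reason to prefer anything else.
Demographic covariates are drawn independently of country, so the country
coefficient is not confounded in recovery experiments.

Region covariates are synthetic stand-ins with the right *structure*, not
reconstructions of any registry: log-normal human and sheep densities,
Bernoulli big-game-tradition flags (0.63 Norway / 0.23 Sweden), a wolf-zone
flag for a fraction of Norwegian municipalities only, and county-level
carnivore densities drawn with a cross-species latent correlation of 0.75 so
that the multicollinearity screen has something real to find. Swedish sheep
density is structurally zero: fenced flocks are not part of the free-ranging
depredation problem the sheep analyses address.

All randomness flows from one master seed through `derive_seed()` (a single
Lehmer step plus a stage offset), so a run is reproducible end-to-end and
individual stages can be re-drawn independently.

What the generator does *not* emulate: non-response and its geography (it
emits completed interviews directly), item non-response beyond an optional
uniform missingness rate, reverse-coded items, spatial autocorrelation
between neighbouring municipalities beyond the county random intercept, and
any dependence of acceptance on the region covariates other than country.
Passing tests therefore demonstrate that the estimators recover the truth
under this model, not that the model captures every feature of real survey
data.

## Reliability and correlation conventions

`cronbach_alpha()` implements the raw variant
$\frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)$ (the default — it is
what "Cronbach's alpha" means unqualified) and the standardized variant
$k\bar r / (1 + (k-1)\bar r)$; rows with missing items are dropped listwise
with a logged count. `spearman_with_se()` uses midranks for ties and reports
$SE_r = \sqrt{(1-r^2)/(n-2)}$ with a two-sided $t$ p-value — the convention
that reproduces printed county-level values such as $r = 0.84$, $n = 18
\Rightarrow SE = 0.14$. The collinearity screen flags pairs with
$|r_s| > 0.7$ by default, the region where carnivore-density predictors
start to overlap too much to enter a model together.

## Mixed models and elimination

`fit_glmm()` delegates to `lme4`: binomial-logit with a random intercept via
the Laplace approximation (`glmer`, bobyqa optimizer), Gaussian via `lmer`
with `REML = FALSE` so that log-likelihoods are comparable across nested
fixed structures, and plain `glm`/`lm` when no random term is given. The
respondent-level acceptance model treats species as a predictor by stacking
one row per respondent × species (`respondent_model_data()`), keeping
municipality — and only municipality — as the random intercept; the
within-respondent correlation this leaves unmodelled is a documented
limitation, accepted to stay within the one-random-intercept design. County
models take four rows per county (one per species) with a county random
intercept, and human density enters its conflict model as a second-order
term in log density, where a negative curvature corresponds to conflict
peaking at intermediate (mixed rural–urban) densities.

`backward_eliminate()` removes, one at a time, the non-forced term with the
largest likelihood-ratio p-value above the threshold (default 0.05),
refitting after each removal; categorical terms leave as whole blocks, ties
break alphabetically (making the procedure deterministic), and the full
trace — including final tests of the retained terms — is returned. Sex, age
and education are forced by default in the respondent model: they are
adjustment covariates, not hypotheses under test. Reference levels default
to male / secondary school / Norway / bear.

On the sign convention: the package generates Norway as the high-acceptance
country with a gap of 1.35 log-odds, and its recovery experiment
(`recover_acceptance_effects()`) fits with Sweden as the reference so the
reported coefficient is that positive gap. `odds_ratio()` is pure
exponentiation of a coefficient and its Wald interval; $e^{1.35} = 3.86$.

## Problem sizes used by the test suite

The oracle-equivalence suite enumerates all 456 score multisets of size
2–6. Alpha calibration uses 20 batteries of 2 522 × 16. Parameter recovery
runs 10 replicates of the full 709-municipality design (≈3 200 respondents,
single-species response). The elimination-behaviour study runs 10
replicates at 250 municipalities — the full design makes the same decisions
but each replicate costs minutes rather than seconds, and the property
being checked (null terms leave, the real country effect stays) does not
depend on the larger n. The likelihood-ratio calibration study uses 500
null replicates of an ordinary logistic model at $n = 400$.

## Known limitations

* The generator's acceptance process depends on region covariates only
  through country; effects of sheep density, traditions or zoning must be
  injected by the user via config coefficients of a custom response model.
* PCI group comparisons come with no formal between-group test.
* The bootstrap interval for PCI in 4–5 person groups is honest but very
  wide; county-level grouping is the intended scale of inference.
* Mixed-model p-values rely on the asymptotic $\chi^2$ distribution of the
  LRT; with 37 county groups this is an approximation, which the
  calibration test bounds only for the fixed-effects case.
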