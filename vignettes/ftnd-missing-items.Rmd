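---
title: "Comparing methods for missing FTND items by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing methods for missing FTND items by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ftndmiss)
```

## The problem

The Fagerström Test for Nicotine Dependence (FTND) is a six-item
questionnaire scored by summing the items: items 1 and 4 score 0--3, the
other four items score 0/1, so totals run 0--10.  Respondents sometimes
skip individual items, and practice varies widely in how a total is then
computed: dropping the subject entirely (complete case analysis), ignoring
a single missing item, or imputing it.  `ftndmiss` implements a Monte
Carlo framework that quantifies what each choice does to the accuracy
(bias) and precision (standard-error bias) of two downstream quantities:
the mean total score, and the slope of a simple regression of the total on
a binary covariate ("Is smoking allowed in your home?").

Because the quitline dataset that motivates the framework is restricted,
the package ships a synthetic-population generator calibrated to that
sample's published descriptive statistics.  Every analysis in the package
runs end to end on synthetic data.

## The synthetic population

`ftnd_generator()` encodes a single-factor latent-trait model: subject
$i$ has a latent nicotine-dependence trait
$T_i = \gamma_g\,\mathrm{gender}_i + \gamma_{w(i)} + Z_i$, with
$Z_i \sim N(0,1)$, and item $j$ is an ordinal discretisation

$$ X_{ij} = \#\{c : \lambda_j T_i + \varepsilon_{ij} > \tau_{jc}\},
   \qquad \varepsilon_{ij} \sim N(0,1), $$

with three cut-points for items 1 and 4 and one for the binary items.
One knob per item (the loading $\lambda_j$) controls the dependence
structure, while the cut-points $\tau_{jc}$ control the marginals: because
the marginal distribution of $\lambda_j T + \varepsilon$ is a six-component
normal mixture over the gender-by-smoke-where combinations, the cut-points
that reproduce any target category probabilities can be solved exactly.
This separation is what makes calibration fast and stable.

### Calibration

`calibrate_generator()` fits the generator to `ftnd_targets()`: item means
(2.0, 0.3, 0.6, 0.9, 0.4, 0.5), item SDs (1.0, 0.4, 0.5, 0.8, 0.5, 0.5),
total mean 4.7 and SD 2.3, Cronbach's $\alpha$ = 0.59, and item-rest
Spearman correlations (0.48, 0.26, 0.35, 0.36, 0.31, 0.31).  Three facts
shape the algorithm:

* Published values are rounded to one decimal, and taken literally they
  are not mutually consistent.  A binary item's SD is
  $\sqrt{m(1-m)}$: a mean of 0.30 forces SD 0.458, which is incompatible
  with a printed SD of 0.4.  Likewise $\alpha$ ties the item variances to
  the total variance through
  $\sum_j \sigma_j^2 = \sigma_{tot}^2(1 - \tfrac{5}{6}\alpha)$, and the
  printed SDs taken exactly would push the total SD to 2.25.  The
  calibrator therefore treats each printed value as the centre of a
  rounding band: binary means are nudged minimally (item 2 becomes
  0.2775), ordinal means are re-centred so the six means sum to 4.7, and
  the ordinal item variances absorb the variance required by the
  $\alpha$/total-SD identity.  All adjustments stay inside the stated
  tolerances (0.05 for moments, 0.02 for $\alpha$).
* Given any loadings, thresholds are solved analytically from the mixture
  CDF, so marginals never drift during the search.  Category probabilities
  for the two 0--3 items come from a normal discretised at 0.5/1.5/2.5,
  fitted to the (band-resolved) mean and SD.
* The dependence side is a short coordinate search: simulate 50,000
  subjects, update each loading multiplicatively towards its item-rest
  correlation target, apply a global scale correction towards the
  $\alpha$ target, and stop when everything is inside its band.  From the
  package defaults this converges in one or two rounds.

The frozen defaults (`ftnd_calibrated_defaults()`) come from one such run;
a 100,000-subject verification population achieved total mean 4.70, SD
2.29, $\alpha$ = 0.588, and a dependence-category split
(19.0/26.9/15.5/26.8/11.8% across very low/low/medium/high/very high)
within three percentage points of the published 18.0/24.4/16.8/28.7/11.0.

```{r calibration-demo}
cfg <- ftnd_generator(seed = 1)
pop <- generate_population(cfg, n = 20000)
c(mean = mean(ftnd_total(pop)), sd = sd(ftnd_total(pop)),
  alpha = cronbach_alpha(pop))
```

### Covariates

Three covariates are generated: gender (57% female), the three-level "If
you smoke at home, where?" variable, and the binary "Is smoking allowed in
your home?" variable.  Two design choices deserve comment.

* The smoke-where category probabilities are not published; the defaults
  0.45/0.35/0.20 (no / outside / inside) give the MAR mechanism real
  covariate variation and are configurable.
* The trait shifts attached to gender and smoke-where are tiny
  ($|\gamma| \le 0.02$ trait SD, with non-home-smokers lowest).  This is
  deliberate: in a sample of nearly forty thousand, associations of this
  size are statistically significant yet practically negligible — and the
  reported MAR results (every method except drop one biased by at most
  0.2%) are only possible if the eligibility covariates carry almost no
  information about the total score.  Smoking-allowed, by contrast, is
  drawn from a logistic model on the trait with slope chosen so the true
  regression coefficient of the total on it is about 0.7 points, the
  magnitude implied by the reported absolute and percent biases of that
  coefficient.  Since no true value of this coefficient is published, the
  package's regression-bias checks are interpreted in percent terms only.

## Missingness mechanisms

Item nonresponse is injected in two stages.  First a subject becomes
*eligible* with probability from a logistic model:

$$\mathrm{MAR:}\quad \mathrm{logit}\,\Pr(\text{eligible}) =
  \beta_0 + 0.20\,\mathrm{gender} - 2.12\,\mathrm{outside}
  - 1.99\,\mathrm{inside},$$
$$\mathrm{MNAR:}\quad \mathrm{logit}\,\Pr(\text{eligible}) =
  \beta_0 + 0.2\,\mathrm{FTND},$$

so under MNAR more dependent smokers are more likely to lose items.  Then
each of an eligible subject's six items is independently deleted with
probability `p_item`.  The intercept $\beta_0$ is solved by bracketing
bisection on $[-50, 50]$ so the *mean* eligibility probability equals
`p_sub` to within $10^{-8}$ — the mean is strictly increasing in
$\beta_0$, so the root is unique.  Realised eligible counts then vary
binomially around `p_sub`, which is how we read "approximately `p_sub`
subjects eligible".  Whether the original study re-solved the intercept
per simulated dataset or once overall is not stated; the package re-solves
per dataset by default (`beta0_scope = "dataset"`), which keeps every
replication's eligibility rate on target.

All six items share one `p_item` (an explicit simplifying assumption of
the design), covariates are never deleted, and MCAR is deliberately not
implemented — its only effect on these estimands is sample-size loss.

```{r mechanism-demo}
cfg_m <- missingness_config("MNAR", p_sub = 0.3, p_item = 0.5)
res <- draw_missingness(pop[1:2000, ], cfg_m, seed = 42)
mean(res$mask$deleted)  # about p_sub * p_item = 0.15
```

## The six scoring methods

* **CCA** — total only for fully observed subjects.
* **Drop one** — one missing item scored as zero; two or more give a
  missing total.
* **Item mean** — a missing item takes the mean of its observed values in
  the *current* dataset (post-missingness), so totals can be fractional.
* **HR item mean** — item mean gated by the half rule: at least 3 of 6
  items must be observed.
* **Proration** — a missing item is imputed from the subject's own
  answered items, weighted by the item's maximum score:
  $\hat x_{ij} = \mathrm{max}_j \times (\text{answered total} /
  \text{answered possible total})$, applied under the half rule.
  Fractional totals are kept; nothing in the scoring rule calls for
  rounding, and rounding would add quantisation bias.
* **Hot deck** — k-nearest-neighbour donor imputation under Gower's
  distance over gender, smoking-allowed, and the recipient's observed
  items; one donor drawn uniformly from the k = 5 nearest candidates
  donates *all* of the recipient's missing items, so totals stay integer
  and intra-subject item dependence is preserved.

Three hot-deck details are worth making explicit.  Candidates are any
subjects observing all of the recipient's missing items *and* all distance
variables — partially missing subjects can donate what they do observe.
Distance ties at the k-th rank are all included before the uniform draw,
which removes any dependence on row order.  And if fewer than k candidates
exist the pool shrinks with a warning (strict mode turns this into an
error); with n = 52 and 35% missing cells this fallback does occur.

The matching set follows the reading that the recipient's *observed* items
are the distance variables; matching all items via pairwise-available
comparisons is the other defensible reading of the source description, but
it makes distances across recipients incommensurable.

```{r scoring-demo}
sc <- score_all_methods(res$observed[1:500, ], seed = 7)
vapply(sc, function(r) sum(!is.na(r$total)), integer(1))
```

## Performance measures

For each replication the truth $\theta$ is computed on the *same* sampled
dataset before deletion; bias is $\hat\theta - \theta$ and percent bias is
$100(\hat\theta - \theta)/\theta$ (guarded for $|\theta| < 10^{-8}$).
Cell summaries report the mean and a Monte Carlo 95% interval of the
per-replication percent biases.  The interval is the 2.5th/97.5th
percentile of the replication values (linear interpolation between order
statistics): the published intervals — e.g. (−36%, 27%) around a −4% mean
— are far too wide to be $\bar x \pm 1.96\,s/\sqrt{1000}$, so they must
summarise the replication distribution itself.  A normal-theory variant
($\bar x \pm 1.96 s$) is selectable via `ci_type`.

Precision is measured as SE bias: the cell's empirical SE is the SD of the
estimates over its replications, each replication's percent SE bias is
$100(\widehat{SE} - SE_{emp})/SE_{emp}$, and the mean of those
per-replication values is reported (not the ratio of averages).  Each
cell uses its own empirical SE.  Replications where a method leaves fewer
than two usable totals are recorded as undefined and excluded.

A mean-FTND bias of 1 point (10% of the scale, enough to cross a
dependence category) is flagged as clinically important.

The two design sample sizes come from an exact noncentral-t power
calculation: `power_sample_size(0.8)` = 52 and `power_sample_size(0.2)` =
788 subjects in total for 80% power at two-sided $\alpha$ = 0.05.

## The simulation driver

`run_grid()` implements the full design: for each cell of (mechanism,
`p_sub` in {0.1, 0.3, 0.5}, `p_item` in {0.1, 0.3, 0.5, 0.7}, `n_obs` in
{52, 788}) it repeatedly samples with replacement from the population,
records truths, solves $\beta_0$, injects missingness once, and scores the
identical observed dataset with every method — the method comparison is
paired within replication.  Seeds follow a master → cell → replication
hierarchy (`derive_seed`), so any replication is reproducible in isolation
and results are independent of execution order.

```{r driver-demo}
grid <- ftnd_grid(n_obs = 100, mechanisms = "MNAR", p_sub = 0.5,
                  p_item = 0.5, replications = 50,
                  methods = c("cca", "proration"), seed = 9)
sim <- run_grid(pop, grid)
sim$summary[sim$summary$estimand == "mean_ftnd",
            c("method", "mean_percent_bias", "se_percent_bias")]
```

## Problem sizes and what the tests show

The package's test suite exercises the framework at sizes chosen to keep a
full run inside a few minutes while leaving Monte Carlo noise well below
the assertion bands: calibration checks use populations of 20,000--40,000,
mechanism and scoring properties use 150--2,000 subjects, and the
headline simulation checks run 500 replications at `n_obs` = 788 for the
four most informative cells, asserting that each summary lands inside the
published Monte Carlo interval for that quantity.  At 500 replications the
Monte Carlo SE of a cell's mean percent bias is a few tenths of a percent,
small against bands several points wide.

Passing these checks shows that the *mechanisms and estimators* behave as
specified on a population whose first two moments, reliability and rank
correlations match the published sample.  It does not show that the
synthetic items reproduce every feature of real FTND responses: the
latent-trait model is an artifact choice (nothing about the joint
modelling of items and covariates in the source sample is published),
higher-order dependence beyond $\alpha$ and the item-rest correlations is
not targeted, all items share one deletion probability, and the education
and race/ethnicity covariates of the source sample are not modelled at
all.

## Known limitations

* Single imputation only; multiple imputation and likelihood-based
  approaches are out of scope by design.
* The regression-coefficient truth is the complete-sample OLS slope of the
  same replication, so its percent-bias distribution at small `n_obs` is
  heavy-tailed (the truth can sit near zero); interpret those cells via
  their intervals, not their means.
* The hot deck is the slowest method (pairwise Gower distances per
  missingness pattern); grids that include it cost roughly 40--50 ms per
  replication at `n_obs` = 788 versus ~4 ms without it.
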