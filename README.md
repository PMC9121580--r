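# ftndmiss

Simulation framework for comparing methods of managing missing items on
the Fagerström Test for Nicotine Dependence (FTND).

## The problem

The FTND is a six-item questionnaire measuring nicotine dependence; items
1 and 4 score 0–3, items 2, 3, 5 and 6 score 0/1, and the total (0–10) is
the sum.  When respondents skip items, analysts variously drop the
subject (complete case analysis), ignore a single missing item, or impute
it — and the choice affects both the estimated mean dependence of a
sample and regression analyses that use the total as outcome.  This
package quantifies those effects by Monte Carlo simulation for six
scoring rules:

| method | rule |
|---|---|
| `cca` | total only if all 6 items observed |
| `drop_one` | 1 missing item scored as 0; ≥ 2 missing → total missing |
| `item_mean` | missing item ← mean of that item's observed values |
| `hr_item_mean` | item mean, but only if ≥ 3 items observed (half rule) |
| `proration` | missing item ← max_score × answered total / answered possible total, under the half rule |
| `hot_deck` | k-NN donor (Gower distance on gender, smoking-allowed and observed items), one donor fills all gaps |

Missingness is injected by a two-level mechanism: subjects become
eligible through a logistic model — on covariates (MAR,
`logit Pr = β₀ + 0.20·gender − 2.12·smoke_outside − 1.99·smoke_inside`)
or on the true total itself (MNAR, `logit Pr = β₀ + 0.2·FTND`) — with the
intercept solved so the mean eligibility probability equals `p_sub`; each
item of an eligible subject is then deleted with probability `p_item`.
Performance per cell of the design grid is summarised by the bias
`θ̂ − θ` and percent bias of the mean FTND score and of the slope of a
regression of the total on a binary covariate, plus the percent bias of
their standard errors against the empirical SE across replications.

Because the motivating quitline dataset is restricted, the package ships
a calibrated synthetic-population generator (latent-trait model with
exact threshold calibration) reproducing that sample's published
descriptives: total mean 4.7, SD 2.3, Cronbach's α 0.59, the item
means/SDs and item-rest Spearman correlations.  See the vignette
(`vignettes/ftnd-missing-items.Rmd`) for the model and every calibration
decision.

## Worked example

```r
library(ftndmiss)

cfg <- ftnd_generator(seed = 1)          # calibrated defaults
pop <- generate_population(cfg, n = 38334)
c(mean(ftnd_total(pop)), sd(ftnd_total(pop)), cronbach_alpha(pop))
#> 4.70  2.29  0.59

grid <- ftnd_grid(n_obs = 788, mechanisms = "MNAR", p_sub = 0.5,
                  p_item = c(0.3, 0.7), replications = 200,
                  methods = c("cca", "drop_one", "proration", "hot_deck"),
                  seed = 20)
sim <- run_grid(pop, grid)
sim$summary[sim$summary$estimand == "mean_ftnd",
            c("p_item", "method", "mean_bias", "mean_percent_bias",
              "pct_ci_low", "pct_ci_high", "se_percent_bias")]
#>  p_item    method mean_bias mean_percent_bias pct_ci_low pct_ci_high se_percent_bias
#>     0.3       cca    -0.406             -8.65      -11.7       -5.52            0.78
#>     0.3  drop_one    -0.398             -8.47      -10.7       -6.11           -0.60
#>     0.3 proration    -0.021             -0.45       -1.8        0.78           -1.01
#>     0.3  hot_deck    -0.080             -1.70       -3.0       -0.53          -11.00
#>     0.7       cca    -0.503            -10.69      -14.0       -7.16           -4.16
#>     0.7  drop_one    -0.502            -10.67      -13.9       -6.76           -4.16
#>     0.7 proration    -0.304             -6.47       -9.4       -3.80            1.22
#>     0.7  hot_deck    -0.273             -5.81       -8.6       -2.90          -22.97
```

Reading the table: under MNAR missingness (more dependent smokers lose
more items), complete case analysis underestimates the mean dependence by
about half a point (−9 to −11%) because it discards exactly the subjects
the mechanism targets, while proration stays within −0.5% at moderate
missingness and −6.5% even when half the subjects lose 70% of their
items.  No method reaches the clinically important bias of 1 FTND point.
`summary(sim)` pivots all four measures into method-by-cell tables and
ranks methods per cell; `plot(sim)` draws the measure against `p_item`.

A command-line front end with `generate` / `simulate` / `summarize`
subcommands is in `inst/scripts/ftndsim.R`.

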