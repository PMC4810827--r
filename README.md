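# foodwebERGM

Exponential random graph models (ERGMs) for directed, binary food webs.

Food webs — species linked by who-eats-whom arcs, oriented prey →
predator — carry the imprint of the micro-level interaction processes that
assembled them: generalist predators accumulating prey, heavily exploited
prey species, tri-trophic chains, omnivory, and competition for shared
resources or shared enemies. Classical motif analysis scores each of these
substructures against a null model one at a time and stays descriptive.
The ERGM approach modelled here instead asks which *minimal set* of
processes jointly explains the whole web:

$$P(G) = \frac{1}{c}\,\exp\Big(\sum_s \theta_s\, z_s(G)\Big)$$

where each network statistic $z_s$ counts (with geometric down-weighting,
weight $\lambda$) one configuration — alternating in-/out-/mixed stars,
alternating two-paths and shared-partner terms, alternating triangles —
and $\theta_s$ measures whether that process drives ($>0$) or inhibits
($<0$) web formation. Fitted parameters for webs observed before and after
an ecological regime shift can then be compared directly, turning "did the
system change?" into "which assembly processes changed, and by how much?"

The package is aimed at community ecologists and network scientists who
want that workflow end to end on ~30-species webs: configuration
statistics with exact change statistics, Metropolis–Hastings simulation,
Monte-Carlo maximum-likelihood fitting (Robbins–Monro stochastic
approximation with convergence t-ratios and standard errors),
simulation-based goodness of fit over a 32-statistic suite, descriptive
triad/motif baselines, niche-model synthetic webs, and before/after
regime comparison.

## Worked example

Fit a three-process model to the bundled 30-species synthetic web:

```r
library(foodwebERGM)

web <- fixture_web("baltic_like_30")
web
#> <foodweb> 30 species, 180 arcs (connectance 0.207)

fit <- fit_ergm(web, model_spec("arc", "generalist", "tri_trophic"),
                settings = sampler_settings(30, seed = 1))
fit
#> <ergm_fit> 3 configurations, converged (max |t| = 0.016, 2 restarts)
#>             estimate     se t_conv sig
#> arc          -4.1089 0.5022 -0.004   *
#> generalist    2.1306 0.2493 -0.007   *
#> tri_trophic  -0.1834 0.0240  0.016   *
```

All three parameters are significant (`|estimate| >= 2 SE`): ties are
intrinsically rare (negative arc baseline), generalist predators strongly
drive structure, and food chains are slightly inhibited once the star
process is accounted for. Convergence t-ratios near zero say networks
simulated at these parameters reproduce the observed statistics.
`goodness_of_fit(web, fit)` then checks 32 statistics the model never
targeted.

Comparing the bundled published estimates for the coastal Baltic webs
before (1980s) and after (2000s) the reported regime shift:

```r
cmp <- compare_fits(baltic_estimates("coast_1980s"),
                    baltic_estimates("coast_2000s"))
cmp$table[, c("configuration", "theta_before", "theta_after", "pct_change")]
#>         configuration theta_before theta_after pct_change
#>                   arc     -11.3957    -12.0156  -5.439771
#>            generalist       4.0303      4.5274  12.334069
#>       highly_predated       2.1640      2.0822  -3.780037
#>              keystone       2.8967      3.6722  26.771844
#>              omnivory      -0.1033     -0.1157 -12.003872
#>           tri_trophic      -0.3501     -0.4182 -19.451585
#>  apparent_competition      -0.1779     -0.2373 -33.389545
```

The tri-trophic chain process weakened by ~19.5% ("nearly 20%") and
apparent competition by ~33%, while keystone and generalist processes
strengthened — changes in magnitude, not in the identity of the driving
processes. Configurations present in only one period (here exploitative
competition, coastal 2000s only) are reported separately, never dropped.

A full two-period study (fit both webs, GoF each, compare, emit
Table-style CSVs and JSON) is one call: `run_pipeline()`, or from a shell
via the thin wrapper `inst/cli/foodweb-ergm.R` with subcommands `fit`,
`gof`, `compare`, `simulate`, `census`, `pipeline`.

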