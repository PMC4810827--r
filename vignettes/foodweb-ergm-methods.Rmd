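---
title: "Modelling food-web structure with exponential random graph models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling food-web structure with exponential random graph models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodwebERGM)
```

## The model

A food web is represented as a directed, binary, loop-free graph on `n`
species: the arc `i -> j` records energy transfer from prey `i` to predator
`j`, and cannibalistic self-links are excluded. An exponential random graph
model (ERGM) places a probability on every such graph,

$$P(G) = \frac{1}{c}\exp\Big(\sum_s \theta_s\, z_s(G)\Big),$$

where each `z_s` is a *configuration statistic* - a count (or geometrically
down-weighted count) of a small subgraph with an ecological reading - and
`theta_s` is its parameter. A positive `theta_s` means the corresponding
interaction process *drives* web formation (webs rich in that configuration
are more probable, all else equal); a negative value means it is inhibited.
The normalizing constant `c` sums over all `2^{n(n-1)}` webs and is never
computed; all inference is simulation-based.

This is a fundamentally different exercise from the classical motif census
(also provided, see `motif_zscores()`): rather than scoring each motif
against a null model independently, the ERGM seeks the *minimal set* of
processes that jointly reproduce the whole structure, so an excess of, say,
transitive triangles may be explained away as a by-product of strong
star-forming processes rather than a process of its own.

## The configuration catalogue

With `x_{ij}` the arc indicator, in-degree counting a predator's prey and
out-degree a prey's predators, the model-capable statistics are:

| name | form | ecological reading |
|---|---|---|
| `arc` | $\sum x_{ij}$ | baseline tie propensity (density control) |
| `reciprocity` | $\sum_{i<j} x_{ij}x_{ji}$ | mutual predation |
| `generalist` | $\sum_j \lambda^2[(1-\tfrac1\lambda)^{d^{in}_j} + d^{in}_j/\lambda - 1]$ | predators with many prey |
| `highly_predated` | same form on $d^{out}$ | prey with many predators |
| `keystone` | $\sum_i g_\lambda(d^{in}_i)\,g_\lambda(d^{out}_i)$ | species with many prey *and* many predators |
| `tri_trophic` | $\sum_{i\ne j} g_\lambda(L_2(i,j))$ | food chains (mixed two-paths) |
| `apparent_competition` | $\sum_{\{i,j\}} g_\lambda(\#\text{shared predators})$ | two prey sharing predators |
| `exploitative_competition` | $\sum_{\{i,j\}} g_\lambda(\#\text{shared prey})$ | two predators sharing prey |
| `omnivory` | $\sum_{x_{ij}=1} g_\lambda(L_2(i,j))$ | chains closed by a direct link |
| `cyclic_triangle` | $\sum_{x_{ij}=1} g_\lambda(\#\text{cyclic partners})$ | directed 3-cycles |

plus raw 2-/3-star, two-path and triangle counts. Here
$g_\lambda(d) = \lambda(1-(1-1/\lambda)^d)$ and $L_2(i,j)$ counts two-paths
`i -> k -> j`. The *alternating* (geometrically weighted) forms are used for
everything star- or partner-shaped: they saturate as counts grow, which is
what lets a single parameter describe heterogeneous degrees without the
notorious ERGM degeneracy of raw star counts.

Conventions fixed here: mixed two-paths are counted over ordered pairs
(chain direction matters), shared-partner competition terms over unordered
pairs (competition is symmetric); all statistics ignore self-loops by
construction. The keystone term uses the product form above - species
scoring high on both margins - which is one of several reasonable
mixed-star operationalizations; the catalogue registry makes it easy to
swap in an alternative without touching the estimator.

**The smoothing weight.** `lambda` defaults to 2 throughout, the
conventional choice in the ERGM literature for alternating statistics. It
is a setting, not an estimated parameter: fits at a handful of values
(e.g. 1.5-4) can be compared by goodness of fit if there is doubt.

## Change statistics and simulation

Everything rests on the change statistic
$\delta_s(i,j) = z_s(G+ij) - z_s(G-ij)$, computed in `O(n)` per dyad by
maintaining the two-path and shared-partner matrices incrementally
(compiled code). `change_statistics()` exposes it; a randomized test
verifies it against brute-force recomputation of both graph variants.

`sample_networks()` runs single-arc-toggle Metropolis-Hastings: a uniform
random ordered dyad is proposed for toggling and accepted with probability
$\min(1, e^{\pm\sum_s\theta_s\delta_s})$. Burn-in and thinning default to
`50 n^2` and `10 n^2` proposals (multiples of the dyad count); the
chain for a 30-species web then decorrelates essentially completely between
retained samples (lag-1 autocorrelation of the statistics trace is
indistinguishable from zero). A chain whose retained density is pinned at 0
or 1 more than 90% of the time is flagged degenerate with a warning, not an
error - the estimator needs to be able to observe and react to degeneracy.
Fresh cold-start simulation (as in `simulate_study()`) uses a much longer
default burn-in of `500 n^2`, because equilibrating from the empty graph is
slower than moving within the stationary distribution; with the shorter
default we observed cold-start ensembles measurably out of equilibrium.

All randomness flows through R's RNG, so every sampling function is exactly
reproducible given its `seed`, and seeded calls restore the caller's RNG
state.

## Estimation

`fit_ergm()` implements Monte-Carlo maximum likelihood by stochastic
approximation, in the classic three-phase tradition of stochastic
approximation ERGM estimators:

1. **Phase 1** - a short run at the warm start (arc parameter at
   `logit(density)`, the exact Bernoulli sub-model MLE; all else 0)
   estimates the statistic covariance, used as a Newton-type
   preconditioner. A diagonal scaling was tried first and converges
   poorly here because arc and the alternating stars are strongly
   correlated statistics.
2. **Phase 2** - Robbins-Monro subphases of `(2, 4, 8, 16) p` iterations
   with gain halving from 0.1, each iteration advancing the chain `10 n^2`
   proposals and updating
   $\theta \leftarrow \theta - a\,\hat V^{-1}(z(G_{sim}) - z_{obs})$.
   The subphase output is the *average* of the final subphase's iterates
   (Polyak averaging), which removes most of the stochastic-approximation
   jitter at no extra simulation cost.
3. **Phase 3** - a long run (1000 networks by default) at the candidate
   estimate yields the convergence t-ratios
   $t_s = (\bar z_s^{sim} - z_s^{obs})/sd^{sim}_s$, and standard errors
   from the inverse covariance of the sampled statistics (the Fisher
   information of an exponential family). If `max |t| > 0.1` the fit is
   re-centred by a damped Fisher-scoring step
   $\theta \mathrel{+}= \hat I^{-1}(z_{obs} - \bar z)$ and phase 3 is
   repeated, up to 3 times by default; the attempt with the smallest
   `max |t|` is reported. Polishing continues while attempts remain until
   `max |t|` is *half* the threshold, so reported t-ratios are not left
   sitting on the pass/fail boundary at the mercy of Monte-Carlo noise.

Convergence is declared at `max |t| <= 0.1` and a configuration is starred
significant when `|estimate| >= 2 SE` - both the conventions of the
software lineage this estimator follows. Non-convergence is a reported
state (`converged = FALSE`), never an exception. On tiny graphs the
likelihood can be nearly flat (near-singular information), in which case a
loose t-ratio tolerates visible parameter error; `exact_fit_small()`
provides an enumeration oracle for `n <= 4`, and matching it to 0.05
requires tightened settings (`t_threshold = 0.02`, 20000 phase-3 samples),
as the tests do.

## Goodness of fit

`goodness_of_fit()` simulates an ensemble at the fitted parameters and
compares the observed web on a 32-statistic suite: the 10 catalogue
configurations at `lambda = 2`, raw 2-/3-in/out-stars, raw two-path,
transitive and cyclic triangle counts, all 13 connected triad classes, and
the in-/out-degree standard deviations. The suite size is canonical; its
membership is this package's choice (degree skewness was a candidate and
was left out to keep the count at 32) and any 32 statistics can be passed
instead. Modelled statistics must satisfy `|t| <= 0.1` - the moment
condition again - and non-modelled ones `|t| < 2`; a statistic with zero
ensemble variance is reported with `t = NA` and excluded from the verdict.

A caveat worth stating plainly: for rare discrete statistics (triad classes
involving mutual dyads in a sparse, largely acyclic web, with ensemble
means well below 1) the t-ratio is a crude screen - a single observed
instance of a configuration whose ensemble mean is 0.1 already scores
`|t| > 2`. Such failures should be read alongside the absolute counts
before condemning a model.

## Regime comparison

`compare_fits()` reports, per shared configuration,
$100(\theta_{after} - \theta_{before})/|\theta_{before}|$. The absolute
value in the denominator means the sign of the change is the sign of the
raw difference, which reproduces the published Baltic coastal tri-trophic
decline of 19.45% ("nearly 20%") from the bundled estimates
(`baltic_estimates()`). The comparison refuses to cross systems (offshore
vs coastal) unless forced, lists one-sided configurations separately, and
flags sign flips and joint significance. Swapping the roles of the two
fits rebaselines the percentage rather than negating it.

```{r regime}
cmp <- compare_fits(baltic_estimates("coast_1980s"),
                    baltic_estimates("coast_2000s"))
cmp$table[, c("configuration", "theta_before", "theta_after", "pct_change")]
```

## Synthetic data

The package generates all of its own test inputs:

* `fixture_web()` - tiny canonical webs (chain, omnivory triangle,
  predator star, prey fan) with hand-checkable statistics, plus
  `baltic_like_30`, a frozen 30-species, 180-arc niche-model web shipped
  as a data file so numbers attached to it are stable. The scale matches
  the webs that motivated the package: circa 30 species, connectance
  near 0.2.
* `niche_model_web()` - the classic niche model: niche values uniform on
  [0, 1], diet ranges `u * Beta(1, 1/(2C) - 1)` centred below the
  consumer's niche value. It produces the triangular trophic structure
  (many basal, few top species) typical of real webs; realized
  connectance at `n = 30, C = 0.2` averages within 0.02 of target across
  replicates. Cannibalistic self-links are deleted, not redrawn. The
  default `C = 0.2` stands in for the empirical webs' (unpublished)
  connectance.
* `simulate_study()` - replicate webs from a known `theta` with derived
  per-replicate sub-seeds, for parameter-recovery scoring. The recovery
  conditions used in the tests are `n = 30` with
  `theta = (arc -2, generalist +0.5, tri_trophic -0.3)`, giving sparse
  webs (density ~0.09) with pronounced star and chain structure and no
  degeneracy.

What the synthetic generators deliberately do not emulate: trophic-level
ordering constraints beyond the niche hierarchy, body-size or biomass
covariates, sampling effort artefacts, and the expert-assembly process
behind real webs. Passing tests therefore demonstrate that the machinery
recovers known generating processes at realistic scale - not that any
particular empirical web satisfies the model's assumptions.

## Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to run on
a single CPU in a few minutes per property: 50 replicate fits for
coverage, 20 fit-plus-GoF cycles for self-consistency, ensembles of
500-1000 networks, detailed-balance checks over all 64 three-node digraphs
against exact enumeration. Every stochastic result is tied to an explicit
seed; pipeline runs derive per-stage sub-seeds from one global seed and
log them, so any stage can be reproduced in isolation.

## Known limitations

* No covariate (node- or dyad-attribute) terms, no curved-ERGM estimation
  of `lambda`, no weighted or dynamic extensions.
* The t-ratio GoF screen is conservative-to-erratic for rare discrete
  statistics, as discussed above.
* Stochastic-approximation fitting is Monte-Carlo noisy by nature;
  near-flat likelihoods (tiny webs, boundary statistics) need tightened
  settings or the enumeration oracle.
* The regime comparison is descriptive - percentage changes carry no
  formal test of parameter equality, matching the practice it mirrors.
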