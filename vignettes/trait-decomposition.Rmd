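---
title: "Partitioning community trait change into species turnover and intraspecific variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning community trait change into species turnover and intraspecific variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitflux)
```

## The scientific problem

When the environment changes along a gradient — here, the decades-long
closing of a tropical dry forest canopy after land abandonment — the mean
functional trait value of a community can change through two distinct
mechanisms: **species turnover** (different species, with different mean
traits, replace each other) and **intraspecific trait variation** (ITV: the
individuals of a given species express different trait values under
different conditions). The two mechanisms have very different ecological
interpretations, and most trait-based studies quantify only the first.
`traitflux` implements, as a reusable and tested pipeline, the standard
machinery for separating them at the community scale (single-trait
sum-of-squares partition, multi-trait partial RLQ) and for dissecting ITV
itself at the individual scale (mixed models of ontogeny and light).

## The single-trait partition

For a quantitative trait and plot $p$, with $w_{sp}$ the relative abundance
of species $s$ in the plot (counts of surveyed saplings),

* the **specific** community-weighted mean uses species means computed *per
  plot*: $\mathrm{CWM}^{spec}_p = \sum_s w_{sp}\,\bar{x}_{sp}$ — it responds
  to turnover *and* ITV;
* the **fixed** mean uses species means computed *across all plots of the
  forest type*: $\mathrm{CWM}^{fix}_p = \sum_s w_{sp}\,\bar{x}_{s}$ — it can
  respond only to turnover;
* their difference is the ITV component,
  $\mathrm{CWM}^{itv}_p = \mathrm{CWM}^{spec}_p - \mathrm{CWM}^{fix}_p$,
  and the identity $spec = fix + itv$ holds exactly by construction.

Two decompositions are provided. In **total-variation mode**
(`decompose_total()`) the among-plot sums of squared deviations from the
forest-type mean of the three series give
$SS_{spec} = SS_{fix} + SS_{itv} + SS_{cov}$, with the covariation term
obtained by subtraction — positive when turnover and ITV push community
values the same way, negative when they oppose. In **gradient mode**
(`decompose_vs_gradient()`) each series is regressed on successional age by
ordinary least squares and the *explained* SS of the fixed and ITV
regressions are expressed as percentages of the total SS of the specific
regression; slopes and two-sided p-values of all three regressions are
reported (p from the t distribution of the OLS slope, no multiple-testing
correction, per-forest-type analysis throughout).

Numerical choices:

* the fixed species mean is the *individual-weighted* mean over all plots of
  the forest type, not the mean of per-plot means — it uses all measured
  individuals; the alternative is a one-line change in `compute_cwm()`;
* when all plots are identical ($SS_{spec} = 0$) contributions are
  undefined: the result row is flagged `degenerate` with `NA` percentages
  instead of propagating `NaN`;
* total-variation mode uses deviations from the forest-type grand mean (the
  natural ANOVA framing for a balanced chronosequence).

## Multi-trait analyses

`hill_smith()` ordinates tables mixing quantitative and categorical
variables. Quantitative columns are standardized under the row weights;
categorical columns are indicator-coded and scaled by
$1/\sqrt{f_l\,(m-1)}$ ($f_l$ the level frequency, $m$ the number of levels),
so that **every variable contributes total inertia exactly 1** and the total
inertia equals the number of variables. For binary variables this is exactly
the correspondence-analysis inverse-square-root-of-frequency scaling; for
$m > 2$ the extra $1/(m-1)$ factor is this package's normalisation choice
(the classical mixed-variable ordination instead lets an $m$-level factor
contribute $m - 1$), chosen so that quantitative and categorical variables
are exchangeable in the inertia budget. On an all-quantitative table the
procedure reduces *exactly* to PCA of the weighted correlation matrix, which
is the oracle used in the tests. Eigen-signs are fixed by making the
largest-magnitude loading positive; eigenvalues below $10^{-10}$ of the
leading one are reported as 0.

`rlq()` links plot environments (R), a non-negative plot × observation
table (L), and observation traits (Q). L is converted to relative
frequencies; its margins provide the row weights under which R and Q are
scaled as above; the doubly-centred frequency table $P_0$ mediates the
cross-covariance matrix $M = X^\top P_0 Y$, whose singular value
decomposition yields axes maximizing the squared cross-covariance of linear
combinations of the two sides (eigenvalue = squared singular value; the
trace identity $\sum_k \lambda_k = \lVert M\rVert_F^2$ is asserted on every
run). This construction reproduces the classical three-table implementation
to machine precision on shared test instances.

`partial_rlq()` separates the trait–environment relationship into an
**among-species** part (each individual's trait row replaced by its species
mean) and a **within-species** part (deviations from species means). The
split is applied to the *scaled* individual-level trait table, so the two
parts sum to the scaled raw table exactly and their eigenvalues are
comparable on one scale. Categorical traits are species attributes with no
recorded intraspecific variation: they enter the among-species table only.
L is the plots × individuals incidence table (each individual occurs in
exactly one plot); species means are computed within the analysed forest
type, consistent with the fixed means of the single-trait partition.
Environment variables are standardized per variable; a species represented
by a single individual contributes an exactly-zero row to the
within-species table and is flagged, not dropped.

## The individual-scale models

For categorical traits the community response is the change in the
proportion of saplings carrying a level, modelled per plot with a
quasi-binomial logit GLM (dispersion estimated, F-tests) with age, forest
type and their interaction, then backward elimination at $\alpha = 0.05$
(interaction before main effects; an NA p-value from a saturated fit counts
as no evidence and the term is dropped). The reported pseudo-$R^2$ is
$1 - D_{res}/D_{null}$; the deviance-ratio definition was chosen because the
alternative (squared correlation) is not well defined for proportions at the
boundary.

For quantitative traits, `fit_itv_lmm()` models the natural log of each
sapling's trait value as a function of relative height $H/H_{max}$ (the
ontogeny proxy; height-class midpoint over species maximum height), forest
type, their interaction, and the crown illumination index (an ordinal 1–5
score used as a numeric covariate). Species enters as a random factor, on
the intercept and optionally on the $H/H_{max}$ slope. The random structure
is chosen by AIC between restricted-likelihood fits sharing the full fixed
part; fixed terms are then selected backward by AIC on full-likelihood
fits (respecting marginality, ties resolved toward dropping the
higher-order term); the final model is refitted by restricted likelihood —
the standard REML/ML bookkeeping for mixed-model selection. Marginal and
conditional $R^2$ follow the variance-components convention
($R^2_M = \sigma^2_f / (\sigma^2_f + \sigma^2_r + \sigma^2_e)$, $R^2_C$
adding $\sigma^2_r$ to the numerator), with the random-slope contribution
averaged over the observed $H/H_{max}$ design:
$\sigma^2_r = \sigma^2_{00} + 2\sigma_{01}\overline{h} +
\sigma^2_{11}\overline{h^2}$. Wald t p-values use residual degrees of
freedom $n - p$, documented as an approximation. A fit at the variance
boundary (zero species variance) is flagged `singular` and coincides with
ordinary least squares, which the tests assert exactly.

Eligibility follows the field protocol: only species with at least one
individual in two different height classes of the same forest type enter
(otherwise the within-species ontogeny contrast is empty).

## The synthetic world

`generate_study()` draws studies with known ground truth so that every
stage has a parameter-recovery test without any external download. The
stated world mirrors a two-chronosequence sapling survey:

| parameter | default | meaning |
|---|---|---|
| plots | 6 per forest type | OAK ages 12–37 y, MIX 19–67 y, evenly spaced |
| `n_species` | 60 | regional pool |
| `mean_abundance` | 2.5 | expected saplings / species / plot at niche optimum (≈ 950 saplings per study, the scale of an intensive survey) |
| `niche_width` | 15 y | Gaussian abundance niches on the age axis (species turnover); `Inf` = flat |
| `trait_correlation` | 0.7 | species-mean correlation of the leaf-economics traits |
| `species_sd` | 1 | among-species trait spread (model scale) |
| `turnover_strength` | 0.02 /y | species-mean shift per year of niche optimum |
| `itv_strength` | 0.01 /y | within-species shift per year of plot age |
| `ontogeny_slope` | −0.3 | shift per unit $H/H_{max}$ |
| `cii_slope` | 0.05 | shift per illumination unit |
| `noise_sd` | 0.3 | residual s.d. |

Traits flagged for log transformation (SLA, leaf area, petiole length) are
generated as the exponential of the linear model, so they are strictly
positive and the mixed-model layer recovers slopes on its native scale;
the remaining traits are linear with base mean 10, far enough from zero
that values stay positive. Heights are uniform over the six 50-cm classes
(midpoints 1.25–3.75 m); the illumination score tracks plot canopy openness
only weakly, so that the $H/H_{max}$–CII rank correlation stays small and
both can enter one model, as in the motivating sampling design. Environment
columns are monotone in age (openness and temperature decreasing) plus
noise; soil variables separate the forest types but not the gradient.
Deciduousness, pubescence and legume status are assigned with probabilities
sliding along each species' niche optimum, giving the GLM stage signal.

`truth_expected_decomposition()` is the independent oracle: it evaluates
the generating model directly on the realized design (expected value per
individual, lognormal correction $e^{\sigma^2/2}$ for log-scale traits) and
aggregates expected CWM series with its own arithmetic, never calling the
pipeline code path.

Two canonical recovery worlds deserve a note. The *turnover-only* world
switches off every within-species effect, so specific and fixed means agree
up to (tiny) noise and the ITV share is 0 by construction. The *ITV-only*
world needs more care: even with `turnover_strength = 0`, Poisson sampling
of which plots a species occupies makes that species' forest-type mean
absorb part of the gradient signal, so the fixed series is not automatically
flat. The ITV-only configuration therefore also sets `species_sd = 0`
(identical species means) and uses flat niches with high abundance, which
bounds the remaining "sampling turnover" well below the 1% recovery
tolerance. This is a property of the *estimand*, not an implementation
artefact: with few individuals per species, part of an ITV response is
genuinely indistinguishable from turnover.

What a green synthetic test does **not** establish: the generator has no
spatial structure, no phylogenetic signal, no trait-dependent sampling
effort, balanced chronosequences, Gaussian noise, and linear (log-linear)
responses throughout. Field data violate all of these to some degree; the
tests establish correctness of the arithmetic and estimators under the
stated model, not robustness to its violations.

## Missing values

Community-weighted means need a value for every retained individual.
Missing quantitative values are filled by the first available unweighted
mean in the hierarchy *species × plot* → *species × forest type* → *forest
type*, with a per-cell log of the rule used. The original study extrapolated
unmeasured leaves with a scheme described only in its supplementary
material; this hierarchical-mean rule is a deliberately simple, auditable
stand-in and is documented as such. Imputation is idempotent and never
alters a measured value. Whether abundance weights should count all surveyed
saplings or only measured ones is ambiguous in the motivating design; this
package retains unmeasured individuals in the weights (they are real
occurrences) and fills their traits.

## Known limitations

* The GLM backward selection uses F-tests at a fixed threshold, not
  quasi-AIC; with very few plots the tests have little power.
* LMM p-values use the $n - p$ degrees-of-freedom approximation rather than
  Satterthwaite/Kenward–Roger corrections.
* The within-species RLQ excludes categorical traits entirely; rare
  within-species categorical variation, if recorded, would be ignored.
* Height is a class midpoint, so $H/H_{max}$ is piecewise-constant; the
  models treat it as exact.
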