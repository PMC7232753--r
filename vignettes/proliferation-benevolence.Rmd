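---
title: "Decomposing microbial health effects into proliferation and benevolence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing microbial health effects into proliferation and benevolence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probene)
```

## The model

An experimental infection yields, for each host, a microbial density $c$
(colony-forming units) and a health outcome. The workhorse of this package is
the linear regression

$$\mathrm{Health} = a + b\,c$$

fitted within groups of hosts (host genotypes) or groups of microbes
(strains). The intercept $a$ is the baseline health of uninfected hosts
(*vigour*). The slope $b$ measures how much health changes per unit density.
The group mean density is written $\bar c$.

The same two numbers carry different names depending on which side of the
interaction varies:

* When **host types** vary and the microbe is fixed, $\bar c$ measures
  (inverse) *resistance* — a more resistant host keeps densities low — and
  $b$ measures *tolerance*: a shallow slope means the host's health barely
  deteriorates as density rises.
* When **strains** vary and the host is fixed, $\bar c$ is the strain's
  *proliferation* and $b$ its *benevolence*. A strain is *benevolent* if
  $b > 0$ over the observed density range, *malevolent* if $b < 0$.

*Virulence* is the signed product $v = b\,\bar c$: the per-density harm (or
benefit) times the density actually attained. The package reports $v$ signed
(negative = net harm) and enforces the identity $v = b\bar c$ exactly in
every `group_summary`.

## The tests

Each study design maps to one model, fitted with ordinary least squares
(`stats::lm`) or, for 0/1 survival outcomes, a binomial GLM with logit link
(`stats::glm`):

| design | model | significant term means |
|---|---|---|
| hosts vary | `density = host_type` | variation in resistance |
| hosts vary | `health = host_type * density` | interaction: variation in tolerance |
| strains vary | `density = strain` | variation in proliferation |
| strains vary | `health = strain * density` | interaction: variation in benevolence |
| both vary | `density = host_type + strain` | resistance and proliferation |
| both vary | `health = host_type + strain + density + host_type:density + strain:density` | tolerance and benevolence |

Interaction (slope-heterogeneity) evidence is an extra-sum-of-squares $F$
comparison of the full against the additive model for continuous outcomes,
and a likelihood-ratio $\chi^2$ for binary outcomes. The named term is what
matters scientifically; the comparison-of-nested-models form was chosen
because it is well defined in unbalanced designs, where classical
sequential ANOVA tables depend on term order. Per-term tables for the
factorial design use Type-II tests (`car::Anova`) for the same reason.

Group levels are coded with treatment contrasts against the alphabetically
first level, but all interpretation goes through *per-group* intercepts and
slopes obtained from the saturated nested parameterisation
`outcome ~ 0 + group + group:density`; these equal independent per-group
least-squares fits, so nothing depends on the contrast coding. Density is
not mean-centred: main effects are never interpreted directly.

In the combined factorial design the host-by-strain interaction is screened
first in the density model at the configured $\alpha$; if significant it is
retained and the result is flagged as cell-specific, otherwise the additive
model is reported.

### Density scale

Cfu counts span orders of magnitude, so the default analysis scale is
$\log_{10}(\mathrm{cfu} + 1)$ (`scale = "log10p1"`); `scale = "raw"` is
available for outcomes already on a linear scale. Every result object
records the scale used, and $\bar c$, $b$ and $v$ are all reported on it.
Uninfected hosts (density 0) are retained by default — they inform the
vigour intercept — and can be dropped with `include_uninfected = FALSE`.

### Degenerate fits

Zero residual variance makes the usual $F$ undefined. Two cases are
distinguished, both flagged in the result:

* residual SS ≈ 0 **and** extra SS ≈ 0: nothing to test, `p = NaN`
  (`degenerate_zero_residual`);
* the full model fits exactly but the reduced model does not: the data are
  perfectly explained by separate group lines, `p = 0` (`exact_fit`).

The thresholds are relative ($10^{-10}$ of the total SS), so affine changes
of units do not move fits across the boundary.

### Separation in the binomial model

With small samples or strong effects, a 0/1 outcome can be perfectly
predicted (monotone likelihood); ordinary ML estimates then diverge. This is
detected from `glm` warnings and runaway coefficients, and the fit is
repeated with Firth's bias-reduced (Jeffreys-prior-penalized) logistic
regression, implemented in-package by modified-score Newton iteration; the
interaction is then tested by a penalized likelihood ratio and the result
carries the flags `separation` and `firth_penalized`.

## Factor classification

A molecular factor is studied by comparing a wild type with its isogenic
factor-negative knockout. Two tests are run on the pooled data: slope
heterogeneity and mean-density difference. For a microbial factor,

* slope difference significant and $b_{wt} > b_{ko}$: **benevolence factor**;
* slope difference significant and $b_{wt} < b_{ko}$: **malevolence factor**;
* density difference significant and $\bar c_{wt} > \bar c_{ko}$:
  **proliferation factor**.

A host factor mirrors this: $\bar c_{wt} < \bar c_{ko}$ gives a resistance
factor and $b_{wt} > b_{ko}$ (shallower toward harm) a tolerance factor.
When the two host slopes straddle zero, "shallower" is ill-defined and the
call is flagged `ambiguous_slope_signs` instead of being made.

A factor is *pure* when exactly one of the two tests is significant. Because
non-significance is weak evidence of absence, every purity claim is
accompanied by the non-significant p-value and a minimum detectable effect
at roughly 80% power, $(z_{1-\alpha/2} + z_{0.8}) \cdot \mathrm{se}$, so the
reader can judge what "no effect on the other axis" could have been missed.

The two hypotheses are treated as distinct — no multiplicity correction by
default, matching how the two questions are posed; `bonferroni = TRUE`
halves $\alpha$ for users who prefer a familywise guarantee, and
`point_estimate = TRUE` classifies by sign alone. A significant density
effect in the *unexpected* direction (knockout denser than wild type) is
reported as the flag `density_effect_reversed` rather than a label, keeping
each label's direction meaningful.

## The synthetic-data generator

`simulation_scenario()` describes a factorial experiment: one row per
host-type-by-strain cell with vigour `a`, slope `b`, optional curvature
`quad`, a density distribution (`mu_density`, `sd_density` on the analysis
scale) and cell size `n`, plus a residual health standard deviation
`sigma_health` and a mandatory seed. Densities are normal on the log10
scale — i.e. roughly lognormal cfu, the usual shape of plate counts — and
truncated at zero raw density by redraw; the truncated fraction is logged
when it exceeds 0.1% (it is $\approx\Phi(-4) \approx 3\times10^{-5}$ for
the default mean of 4 log units, but ~2% for preset cells placed at 2 log
units). Continuous health is $a + b d + \mathrm{quad}\,d^2 + N(0, \sigma)$;
binary survival is Bernoulli with the same linear predictor on the log-odds
scale, matching the binomial analysis path.

Default conditions emulate a typical rodent or insect infection assay:
vigour 10 (an arbitrary health score), residual health SD 1, densities
centred at 4 log10 cfu with SD 1 log unit, 50 hosts per cell, and knockout
effect sizes of one slope unit or one log unit of density. Binary-outcome
calibration checks use 100 hosts per group, since a 0/1 outcome carries
less information per host. These sizes were fixed once as realistic
study conditions; simulation-based checks in the test suite (type-I error
at 2000 replicates, recovery at 1000, classification at 500) use them
unchanged.

What the generator does **not** emulate: correlated errors between health
and density measurements, time-course (within-host dynamic) data, overdispersed
or zero-inflated counts, and measurement error in cfu itself. Passing tests
therefore demonstrate the statistical machinery under the stated generative
model, not robustness to those features of real data.

## Diagnostics

Two caveats of slope-based inference are implemented as pre-fit checks:

* **Density overlap.** Slopes compared between groups whose observed density
  ranges barely overlap can be spurious — each slope is estimated over a
  different stretch of the axis. `density_overlap()` reports, per group
  pair, `length(range intersection) / length(range union)` on observed
  min–max ranges (assumption-free, unlike distributional overlap measures).
  Pairs below the threshold — 0.5 by default, a declared convention, not an
  empirical constant — are flagged, and the flag propagates into any slope
  fit on the same data (`low_density_overlap`) and downgrades factor
  classifications to unreliable rather than suppressing them.
* **Linearity.** `linearity_check()` compares the linear model against the
  quadratic extension (`density` and `density^2`, each interacting with the
  grouping) and advises switching to the quadratic fit when curvature is
  detected. Quadratic per-group coefficients come from the same nested
  parameterisation as the lines.

## Worked example

```{r example}
scenario <- make_preset("knockout_pure_benevolence", seed = 42)
records <- simulate_experiment(scenario)
fit <- test_slope_variation(records, grouping = "strain")
fit
classify_microbial_factor(records[records$strain == "wt", ],
                          records[records$strain == "ko", ])
```

The wild type was generated with slope 0 and the knockout with slope $-1$
at identical densities, so the contrast is called a pure benevolence
factor: knocking the gene out steepens harm per unit density without
changing proliferation.

## Numerical and design choices

* Monte-Carlo utilities (`power_sweep`, and the simulation-based tests)
  derive one sub-seed per replicate from the scenario seed, so every result
  is reproducible and independent replicates do not share streams; seeds
  stay below $2^{31}$.
* Estimator standard errors use the pooled residual variance of the
  saturated model; with two groups the interaction $F$ is then exactly the
  square of the pooled-variance slope-contrast $t$.
* Whether virulence should be reported signed or as a positive "harm
  magnitude" is a convention; the package reports it signed (negative =
  harm) and documents this, since the sign is what separates benevolent
  from malevolent microbes.
* Direction calls (`classify_direction`) require a two-sided test of
  $b \neq 0$ at $\alpha = 0.05$ by default; the "relevant range of
  densities" is taken to be the observed per-group range.

## Limitations

* Density is a single endpoint per host; microbial fitness has aspects
  (transmission, persistence) that density does not capture, and none of
  the epidemiological consequences are modelled here.
* Heritability of benevolence or proliferation across related strains
  requires phylogenetic comparative methods, which are out of scope.
* The overlap diagnostic flags but does not correct; formal corrections for
  overlap-induced bias are not implemented.
* Purity calls rest on a non-rejection and should be read together with the
  reported minimum detectable effect.
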