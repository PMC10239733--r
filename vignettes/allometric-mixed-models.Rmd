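---
title: "Allometric mixed models for aquatic and terrestrial mammals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allometric mixed models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allomm)
```

## The scientific problem

Basal metabolic rate (BMR) scales with body mass as a power law,
$Y = c\,M_b^{\,n}$, and a long-standing question in comparative physiology is
whether this scaling differs between aquatic and terrestrial mammals — and, if
it does, whether the oxygen-delivery pathway (cardiac output, minute
ventilation) shows matching differences. Comparing species directly violates
the independence assumption of ordinary regression because species share
evolutionary history: closely related species resemble each other. This
package fits the comparison on the $\log_{10}$ scale with nested taxonomic
random intercepts as a practical proxy for phylogeny.

## The model

For species $s$ in genus $g$, family $f$, order $o$:

$$
\log_{10} Y_s \;=\; \beta_0 + \beta_m \log_{10} M_s
  + \left(\beta_h + \beta_i \log_{10} M_s\right) \mathrm{I}(\text{terrestrial})
  + u_o + u_f + u_g + \varepsilon_s,
$$

with $u_o \sim N(0, \sigma^2_{order})$, $u_f \sim N(0, \sigma^2_{family})$,
$u_g \sim N(0, \sigma^2_{genus})$, $\varepsilon_s \sim N(0, \sigma^2)$, all
independent. Aquatic is the reference level, so $(\beta_0, \beta_m)$ is the
aquatic line and $(\beta_0 + \beta_h, \beta_m + \beta_i)$ the terrestrial one;
on the natural scale the fitted line is the power law
$Y = 10^{\beta_0} M_b^{\beta_m}$. `habitat_equations()` performs this
composition and `percent_difference()` evaluates the signed aquatic-relative
difference $100\,(10^{L_{aq}(m) - L_{terr}(m)} - 1)$ at any mass. When
$\beta_i \neq 0$ the two lines cross at exactly one mass,
$\log_{10} m^* = -\beta_h / \beta_i$ (`crossover_mass()`).

Model assumptions worth keeping in mind: linearity on the log–log scale
(a single power law per habitat, no curvature), Gaussian residuals with
constant variance, and exchangeability of taxa within each nesting level.
Taxonomic nesting is a coarser representation of shared ancestry than a full
phylogenetic covariance with branch lengths; the latter is deliberately out
of scope.

## Estimation

Variance components are estimated by REML, the standard choice for
variance-component inference because it profiles out the fixed effects and
reduces the downward bias of maximum likelihood; fixed effects are the GLS
solution at the REML optimum with covariance $(X'V^{-1}X)^{-1}$. The
criterion is the restricted log-likelihood normalised as the Gaussian log
density of $Q_2'y$, where $Q_2$ spans the orthogonal complement of the fixed
design — the implementation evaluates it block-wise in compiled code (rows
are sorted hierarchically, so $V$ is block diagonal by the coarsest retained
taxonomic group), and the test suite checks it against an independent dense
orthonormal-contrast evaluation.

Numerical choices:

* Variance components are optimised on the log scale, so non-negativity is
  automatic. Optimisation uses a derivative-free Nelder–Mead start followed
  by a BFGS polish (relative tolerance $10^{-10}$, at most 500 simplex
  iterations). Estimates below $10^{-10}$ are mapped to exactly zero and
  flagged as boundary (singular) fits rather than treated as errors.
* Starting values split the OLS residual variance equally across components.
  Bootstrap refits warm-start at the parent fit's estimates with a lighter
  stopping rule ($10^{-8}$, no polish), which matters because the bootstrap
  refits the model hundreds of times.
* "Where possible" nesting is made operational by an incidence check: a
  level whose grouping partition coincides with the next finer retained
  partition (or with the observations) has no identifiable variance — e.g.
  one species per genus aliases $\sigma^2_{genus}$ with the residual — and is
  dropped with a warning. Levels with a single group are likewise dropped.
* Degenerate inputs fail loudly: identical masses give a rank-deficiency
  error; a single habitat reduces the fixed design to intercept and slope and
  marks the habitat terms unestimable.

Inference uses Wald z intervals ($\hat\beta \pm z_{0.975}\,SE$) and Type II
Wald chi-square tests. The Type II construction respects marginality: each
main effect is tested by a linear hypothesis adjusted for the other main
effect and ignoring the interaction; the interaction is tested last (for its
single degree of freedom the statistic is exactly $(\hat\beta_i/SE_i)^2$).
The hypothesis matrices are built by complementing the term's rows against
its higher-order relatives under the coefficient-covariance inner product,
which reproduces the standard Type II Wald chi-square table; the tests are
checked against `car::Anova()` on an `lme4` fit of the identical model. No
Satterthwaite or Kenward–Roger degrees-of-freedom correction is applied —
the tests are asymptotic chi-square by design, and the size simulation below
quantifies the finite-sample consequence.

## The synthetic-data generator

`simulate_traits()` draws species tables from exactly the generative model
above, so every downstream stage can be validated with known truth. The
built-in `trait_scenario()` conditions reproduce the published study designs
for the five traits: the reduced-model fixed effects, the taxonomic
composition at all four levels (e.g. BMR: 63 species, 20 aquatic, in 55
genera, 32 families, 13 orders), and the per-habitat mass ranges.

* **Habitat is assigned at the order level** by default — whole orders are
  aquatic or terrestrial, as in real mammalian phylogeny (cetaceans;
  pinniped-dominated carnivoran families). This is the realistic, and harder,
  setting for separating habitat effects from taxonomic variance because
  habitat is confounded with order membership. `habitat_level = "species"`
  scrambles habitat for stress tests.
* **Masses are log-uniform** within each habitat's range, matching the
  2.5+ orders of magnitude spanned by allometric datasets and giving the
  log-scale leverage the regression assumes.
* **Variance components default** to $\sigma^2_{order} = 0.01$,
  $\sigma^2_{family} = 0.005$, $\sigma^2_{genus} = 0.0025$,
  $\sigma^2 = 0.01$ on the $\log_{10}$ scale. The original analyses do not
  report their estimated components, so these are an arbitrary, documented
  choice — plausible in magnitude (taxonomic signal comparable to residual
  scatter) and overridable everywhere.
* One master seed drives three independent sub-streams (taxonomy, masses,
  noise), so the taxonomy can be held fixed while noise varies.

What the generator does *not* emulate: measurement error correlated with
mass (heteroscedasticity), non-Gaussian residuals, curvature in the
allometry, unequal within-taxon sampling effort, or any real phylogenetic
branch-length structure. Passing recovery and coverage tests therefore shows
the estimator is correct *under its own assumptions*, not that real data
satisfy them.

```{r example, eval = FALSE}
dat <- simulate_traits(trait_scenario("BMR"), seed = 1)
fit <- allom_fit(dat)
summary(fit)
percent_difference(fit, c(10, 5000))
```

## Bootstrap propagation

Cardiac output ($CO = SV \cdot f_H$) and minute ventilation
($MV = V_T \cdot f_R$) are products of traits fitted on different species
sets, so their uncertainty is propagated by parametric bootstrap
(`allom_boot()`): simulate a new response from the fitted model (fresh random
intercepts and residuals), refit, and record predictions — per species
including the replicate's conditional modes, or at population level (random
effects zero) on a mass grid. Refitting per replicate is the default because
it is what propagates parameter uncertainty; a no-refit mode (random-effect
and residual draws only) is provided for fast tests. Replicates that fail to
converge are redrawn, up to ten times the requested count.

`boot_product()` multiplies two ensembles by adding paired samples on the
$\log_{10}$ scale. Pairing is by replicate index with an independent RNG
sub-stream per trait: the two traits' sampling uncertainties are treated as
independent, which is an explicit assumption (the species sets differ, and
no cross-trait covariance is estimable from separate fits). Species-level
products are formed on the intersection of the species sets; curve products
use a common mass grid (default 50 log-spaced points, 10–6650 kg).

`boot_ci()` reports the ensemble mean and percentile bounds at the
$(1 \pm 0.95)/2$ empirical quantiles. The quantile rule is fixed to the
Hazen convention (linear interpolation with $h = np + 1/2$; R's `type = 5`)
for reproducibility — with replicates $\{1, \dots, 100\}$ a 90% interval is
exactly $(5.5, 95.5)$. Percentile bounds are not forced to bracket the
plug-in estimate; only $lo \le hi$ is guaranteed. The default
`n_boot = 100` follows the original procedure; calibration checks use 200
for stabler tails.

`habitat_difference()` evaluates the aquatic-minus-terrestrial difference of
a (product) quantity for hypothetical species on a mass grid, at population
level with all random effects set to zero, using the same replicate fit for
both habitats so the difference is paired, and reports whether each CI spans
zero. Within a replicate the difference is taken on the natural (linear)
scale, where "no habitat effect" corresponds to a difference of zero.

## What the validation computes

The test suite and `scripts/acceptance.R` recompute, at fixed seeds:

* exact arithmetic identities from the published reduced-model coefficient
  tables (habitat equation composition and percent differences, the
  reference power laws);
* REML-criterion equivalence with the independent dense oracle on 20 random
  instances of up to 50 species, and superiority over a coarse
  variance-component grid;
* bias and 95% Wald-interval coverage of the fixed effects over 200
  simulated datasets of the 63-species BMR design; size of the Type II
  interaction test over 1000 null simulations;
* bootstrap propagation: with no habitat effect injected into stroke volume
  and heart rate, the population-level CO difference CI spans zero across the
  mass grid, and a large injected offset is detected everywhere; percentile
  CI coverage of the true population CO and MV at 100 kg over 200 replicates
  with `n_boot = 200`.

These problem sizes (200 replicate fits for calibration, 1000 for test size,
200×200 for bootstrap coverage) are chosen to keep Monte-Carlo error small
relative to the acceptance bands while remaining comfortable to re-run on a
laptop.

## Known limitations

* Taxonomic nesting is a proxy; with branch-length phylogenies available, a
  PGLS-type covariance would use more information. Out of scope here.
* Wald inference is asymptotic, and no small-sample degrees-of-freedom
  correction is attempted. At these sample sizes the tests run liberal: the
  size simulation measures a true size of about 0.08 (nominal 0.05) for the
  interaction test under the 63-species BMR design with habitat assigned at
  the order level — an identical rate is obtained from `car::Anova()` on an
  `lme4` fit of the same model, so this is a property of the Wald chi-square
  test in this confounded design, not of the implementation. Habitat varies
  only between the 13 orders, so the effective replication for habitat terms
  is far smaller than the species count.
* The cardiac oxygen output formula is implemented exactly as printed,
  $f_H \cdot SV \cdot Hb \cdot 1.34 \cdot 0.01$; a units audit shows the
  result is mL O$_2$·min$^{-1}$ for $f_H$ in min$^{-1}$, SV in mL and Hb in
  g·dL$^{-1}$, so outputs are labelled accordingly (the source's
  L O$_2$·min$^{-1}$ label appears to be a typographical inconsistency). No
  silent rescaling is applied.
* Alveolar ventilation uses fractional dead space of tidal volume,
  $\dot V_A = V_T (1 - f_{DS}) f_R$ with defaults 0.07 (aquatic) and 0.03
  (terrestrial) — the only reading consistent with dead space quoted as a
  percentage — and is labelled exploratory in pipeline outputs.
* Trait condition flags (juvenile, sedated) are taken as supplied by the
  user; the package does not attempt to verify measurement conditions.
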