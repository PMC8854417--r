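---
title: "Methods: adaptive evolution of fly visual and antennal systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive evolution of fly visual and antennal systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flyvis)
```

# The scientific question

Miltogrammine flesh flies find the nests of their aculeate hosts in two
qualitatively different ways: *satellite* (SAT) species trail a returning
host in flight at a fixed distance, a pursuit that demands precise visual
tracking, while *non-satellite* (NON-SAT) species reach nests by
necrophagy, hole searching or stalking/lurking. `flyvis` implements the
comparative analysis that asks whether this behavioural dichotomy is
associated with differential investment in the peripheral visual system
(compound eyes, ocelli) versus the antennal system, over and above body
size and shared ancestry.

# Morphometric derivations

All lengths are micrometres internally; areas are squared micrometres.

**Eye area.** The compound eye is approximated as a spherical shell of
height `W = E_widthA` cut from a sphere whose radius is set by the mean
lateral chord `L = (E_height + E_widthL)/2`. The shell-area formula
`2 pi W ((L^2 + W^2) / (2W))` simplifies algebraically to
`pi (L^2 + W^2)`; the implementation uses the simplified form and the
test suite asserts the equivalence to a relative 1e-12 on random chords.
When all three chords equal `L` the formula returns `2 pi L^2`, a
hemisphere of radius `L`, which is the geometric sanity check.

**Facet area and count.** Ommatidial facets are regular hexagons measured
by their apex-to-apex diameter; with circumradius `r = diameter/2` the
area is `2.598 r^2`. The coefficient is deliberately the conventional
printed constant rather than the exact `3 sqrt(3)/2 = 2.59808...`
(relative difference 3e-5), to stay bit-compatible with published
derivations. The ommatidium count is the unrounded ratio
`E_area / mean(OM_area)`.

**Interommatidial angle.** For a hemispheric, hexagonally packed eye the
mean angle between neighbouring optical axes is
`delta_gamma = sqrt(K / OM_number)` degrees. Published accounts sometimes
print `K = 23.818`, but that scale yields sub-degree angles for eyes with
a thousand facets, which is off by a factor ~sqrt(1000) from every
tabulated species value; back-calculation from the packaged species table
(counts of 1100-2600 against printed angles of 3.0-4.6 degrees) forces
`K = 23818 deg^2`, the value used as the default. The calibration is a
standing test: across all 18 species the median absolute difference
between back-calculated and printed angles is 0.010 degrees. The
small-scale constant remains available as an argument.

**Aggregation order.** Traits are derived per specimen and then averaged
within species (mean and `sd/sqrt(n)`), not derived from species-mean
chords. The two orders differ by a Jensen gap of order CV^2 of the
specimen noise; the tests quantify this on synthetic specimens. A species
represented by a single specimen reports a missing standard error rather
than zero. The packaged species tables already contain the derived traits
as published, so no re-derivation is applied to them.

**Body mass.** The brachyceran allometry `mass = 0.655 H^2.526` (H in mm,
mass in mg) is exposed for completeness; head width itself is the
body-size proxy used in the models.

# Regime mapping by maximum parsimony

The binary host-finding character is mapped onto the tree with unit-cost
(Fitch) parsimony, implemented as a Sankoff dynamic program plus complete
backtracking, so the package returns *every* minimum-change labelling,
in a deterministic lexicographic order. Each labelling is converted to a
branch painting in which a branch carries the state of its child node and
the root's own state feeds the weight-matrix root term — the standard
convention for Hansen-type models. Downstream model fits can be repeated
per reconstruction to check robustness of conclusions to reconstruction
ambiguity (the package supports this comparison; it does not assume the
reconstructions agree). Exactness is tested against exhaustive
enumeration of all internal labelings on trees of up to 12 tips.
Multistate or weighted parsimony and likelihood-based ancestral
reconstruction are out of scope.

# The Ornstein-Uhlenbeck adaptive regression

Trait evolution follows `dy = -alpha (y - theta) dt + sigma dB`:
a deterministic pull toward a primary optimum `theta` at rate `alpha`
plus white-noise perturbation. The reported parametrization is the
phylogenetic half-life `t_half = ln(2)/alpha` — the expected time to
close half the distance to a new optimum, in units of the tree depth
(trees are validated ultrametric and rescaled to depth 1) — and the
stationary variance `v_y = sigma^2/(2 alpha)`.

**Covariance.** With the process started at the ancestral optimum, tips
i and j covary as `v_y (1 - e^{-2 alpha s_ij}) e^{-alpha d_ij}` with
`s_ij` the shared root-ward time and `d_ij` the patristic distance. At
`alpha = 0` this degenerates; the implementation switches analytically to
the Brownian form `sigma^2 s_ij` with `sigma^2` as the free parameter,
and at `alpha = Inf` to `v_y I`. The covariance is verified against the
Monte-Carlo covariance of one million exact-transition simulations on a
five-tip tree.

**Design matrices.** Four variants: intercept only; a Brownian body-size
predictor `[1, x]`; regime optima via the weight matrix whose entry
(i, k) integrates `e^{-alpha (T - t)}` over the segments of lineage i
painted with regime k (rows sum to one identically); and regime + body
size. For the continuous predictor the GLS slope on the observed values
is the *evolutionary* slope; dividing by
`rho(alpha T) = 1 - (1 - e^{-alpha T})/(alpha T)` gives the inertia-free
*optimal* slope, so the evolutionary slope is never steeper than the
optimal one and the two coincide only under instantaneous adaptation.
The predictor's own Brownian variance is *not* propagated into the
residual covariance — a documented simplification relative to the fullest
treatment of random predictors; the parameter-recovery simulations bound
its practical effect under study-like conditions.

**Estimation.** Without an observation-error term, `v_y` scales the
covariance, so its maximum-likelihood value at a given half-life is
available in closed form; the likelihood is therefore profiled over a
fixed half-life grid `{0} U logspace(-3, 1, 60) x depth U {Inf}` with the
scale maximized analytically at each point, followed by 1-D refinement
around the best cell. Both endpoints are first-class: `t_half = 0` is
exactly white-noise GLS (equals ordinary least squares, verified to
1e-10) and `t_half = Inf` is exactly Brownian-motion GLS (verified
against an independent phylogenetic GLS to 1e-4 log-units). With
measurement error on, squared standard errors of the species means join
the covariance diagonal (delta-method rescaled on the log scale), the
scale is no longer separable, and the surface is explored on a
(t_half, v_y) grid with Nelder-Mead refinement. A grid-adequacy test
checks that a 4x finer grid moves the maximized log-likelihood by less
than 0.01 on study-sized problems.

**Uncertainty and model choice.** The half-life support region is the set
of grid half-lives whose profile log-likelihood is within 2 units of the
maximum (log-linear interpolation at the crossings; endpoints may be 0 or
infinity). Model fit is summarized by the phylogenetic R^2
(one minus the ratio of GLS quadratic forms against the intercept-only
residuals under the same covariance) and compared across variants by
AICc with `k` counting the half-life, the scale and every regression
coefficient (3, 4, 4, 5 for the four variants); models within
`delta < 4` of the best are flagged equally supported. Responses and the
body-size predictor are natural-log transformed by default, the standard
scale for size traits; a flag disables it. The interommatidial angle is
excluded from OU fitting by default since it is a deterministic inverse
transform of the ommatidium count and would mirror its results.

# Non-phylogenetic statistics

Group contrasts use unweighted species means per regime: pooled
(equal-variance) two-sample t-tests with `df = n1 + n2 - 2` (Welch is
available behind a flag), ratios reported in the direction that makes
them at least 1 with an explicit direction label, and plain OLS for the
angle-on-head-width regression. The eye-antenna trade-off is assessed by
Pearson correlations of size-relative values (trait / head width x 100);
a flag switches to ln-transformed relative values. No multiplicity
correction is applied — the tests are descriptive companions to the
phylogenetic models, not a family of confirmatory hypotheses.

On the packaged tables these statistics give: head width 2.13 vs 1.89 mm
(t = 1.56, n.s.), eye area ratio 1.74, ommatidium count ratio 1.48,
facet area ratio 1.17, ocellar ratio 1.30 (t = 2.94), angle contrast
t = 3.96, arista ratio 1.54 (NON-SAT longer), pedicel ratio 0.95, angle
regression intercept 5.88 with R^2 = 0.52, and all six size-relative
eye-antenna correlations negative (r between -0.75 and -0.48, all
p < 0.05). Two small transcription-level caveats are worth knowing: the
total antennal length of *C. tabaniformis* as published exceeds the sum
of its printed parts by ~11% (the table validator warns rather than
errors for exactly this reason), and the funiculus and total-antenna
group ratios recompute as 1.25 and 1.29 from the published species
means, not the 1.24 sometimes quoted.

# What the synthetic generator emulates — and what it does not

The generator produces pure-birth trees rescaled to depth 1, a regime
painting (single derived clade, or a symmetric Markov walk whose
realized change counts are tested against their branch-length
expectation), a Brownian log-size predictor, and OU responses by exact
per-branch Gaussian transitions started at the root regime's optimum.
A measurement layer mimics the data shape of the study: each species is
"measured" on 7 specimens (the study median) with multiplicative
lognormal noise of 5% CV on the natural scale (the packaged tables show
relative standard errors of roughly 2-8%), and species means, standard
errors and sample sizes are tabulated. Default generating parameters are
fixed once to study-like values: half-life 0.1, stationary variance 0.05
and a regime contrast of 0.5 on the log scale.

An Euler-Maruyama path (step 1e-3 by default) integrates the variant in
which the optimum tracks the Brownian predictor,
`theta(x) = b0 + b1 x`; with slope zero it reduces to a single-optimum
OU and is cross-checked against the exact simulator.

The generator does **not** emulate: non-ultrametric rate variation,
regime-dependent `alpha` or `sigma`, correlated measurement error across
traits, missing specimens, or tree-estimation uncertainty. Passing
recovery tests therefore demonstrate correctness of the estimator under
the model's own assumptions, not robustness to their violation on real
data.

Under those study-like conditions (200 replicates, 50-tip trees) the
2-logL support region covers the generating half-life in ~95% of
replicates and the regime contrast is recovered with a median relative
bias under 1% — both computed afresh by the test suite and by
`scripts/acceptance.R`, not quoted from anywhere.

# Numerical and design choices

* Trees with polytomies or root-to-tip spread beyond 1e-6 of depth are
  rejected, never silently repaired; species matching between tree,
  traits and regimes is exact string matching after whitespace
  normalization.
* Problem sizes in the tests — 18-tip fixture runs, 50-tip recovery
  replicates, 1e6-replicate Monte-Carlo covariance on 5 tips, exhaustive
  parsimony up to 12 tips — were chosen as the smallest sizes at which
  each property is sharply testable.
* All randomness is driven by explicit integer seeds; seeded runs are
  bit-reproducible, and the pipeline writes byte-identical outputs on
  reruns.
* `t_half = 0` ties in model comparison are broken by input order
  (first minimum wins); AICc requires `n - k - 1 > 0` and refuses to fit
  otherwise.
* Known limitations: two regimes only; no regime-specific OU parameters
  (OUwie-style); no Bayesian machinery; the random-predictor
  simplification above.
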