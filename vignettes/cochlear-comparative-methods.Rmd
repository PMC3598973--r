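---
title: "Comparative methods for cochlear trait evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative methods for cochlear trait evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cochlevol)
```

This vignette explains the models behind `cochlevol`, the choices made
where the design was genuinely open, and what the package's simulations do
and do not establish about real data.

## The measurement layer

**Membrane arc length.** The basilar membrane's path is digitised as an
ordered series of 3D landmarks (mm) from base to apex, and its length is
the sum of consecutive Euclidean distances (`polyline_length()`). Chords
always underestimate a smooth curve, so the estimate rises monotonically
with landmark density; at 86 roughly equidistant points the shortfall on a
cochlea-like tapered helix is below 0.5%, while halving to 43 points costs
on the order of a few percent. This motivates the 86-point convention as a
practical accuracy/effort compromise.

**Turn counting.** `count_turns()` reports revolutions to the nearest
quarter turn, the resolution used in the descriptive literature. The
primary estimator is the cumulative winding angle of the apical-view
projection about the spiral centre. Because no anatomical landmark marks
the centre, it is estimated: candidate centres (path end points, a
least-squares circle fit, the centroid) are scored by how smoothly radius
varies with winding angle — quadratic in angle for circular arcs and
Archimedean spirals, log-linear for tapered spirals — and the best
candidate is refined numerically under each metric. A secondary
line-crossing estimate mimics the manual convention (count crossings of
the line from the round-window landmark through the centre, divide by
two); a path that starts on that line contributes boundary touches that
are counted as half crossings, without which the manual rule is biased
low by up to half a turn. The two estimators agree to within a quarter
turn on noise-free spirals across the 0.5–4.25-turn range seen in
mammals. The projection axis is caller-supplied (default `c(0, 0, 1)`)
because the apical viewing direction is a property of how the specimen
was digitised, not of the algorithm.

**Relative membrane length** divides length by `mass^(1/3)` (cube root by
default; 0.33 is accepted as a parameter and differs by well under 1%
over the relevant mass range). All downstream work is in `log10`, the
scale on which published regression coefficients of this kind are
consistent.

## Allometry and outlier classification

`fit_ols()` stores, besides the coefficients, everything required to
reproduce predictions and intervals without the data: residual standard
error, residual degrees of freedom, predictor means and the unscaled
inverse cross-product matrix. Prediction (not confidence) intervals are
used for classifying species against a reference allometry, because the
scientific question is whether a *species* (a new observation) lies off
the reference distribution, not whether the mean does. The reference set
is always selected by a caller-supplied mask; no taxon lists are built
in. A point exactly on an interval boundary counts as `within`, with a
machine-precision tolerance so that degenerate (zero-residual) reference
fits classify their own points as `within` rather than by floating-point
accident.

## Brownian-motion machinery

The tree covariance `C` has `C[i, j]` equal to the shared root-to-MRCA
path length (My) and tip depths on the diagonal. Pagel's lambda scales
only the off-diagonal entries — equivalently, internal branches are
multiplied by lambda and terminal branches stretched to preserve tip
depths — leaving tip variances untouched, the standard construction.

Ancestral states are GLS/ML conditional expectations under BM; the root
estimate coincides algebraically with the independent-contrasts root on
the same binary tree, and this equivalence is exercised as a test oracle
across random trees. Standard errors include the uncertainty from
estimating the root state. Polytomies are resolved arbitrarily with
zero-length branches (with a warning) before the contrasts recursion; on
a dated, essentially binary phylogeny this only formalises ties.

`fit_lambda()` profiles the BM likelihood over `lambda in [0, 1]`
(`sigma^2` and the root maximised analytically at each `lambda`), using a
21-point grid to bracket the optimum followed by bounded scalar search at
tolerance 1e-6 — cheap, derivative-free and robust to the flat profiles
that small trees produce. Likelihood-ratio tests against 0 and 1 use
chi-square with 1 df even at the `lambda = 1` boundary, matching the
behaviour of the widely used tooling; at the boundary this is
conservative, which is the safer direction for claiming departures from
BM. Estimation below roughly 10 tips triggers a warning rather than an
error. Lambda is constrained to `[0, 1]`; implementations that allow
`lambda` slightly above 1 can report marginally higher likelihoods when
the optimum sits at the boundary.

Two independent likelihood evaluations — a dense multivariate normal and
the pruning (contrast) factorisation — are kept in the package and
checked against each other to 1e-8; the pruning form is the one the
compiled rate-shift kernel uses.

## Phylogenetic regression

`pgls_fit()` whitens by the Cholesky factor of the (lambda-scaled) BM
covariance; with `lambda = 0` on an ultrametric tree it reduces exactly
to OLS. `lambda = "ml"` profiles lambda for the regression residuals.

`bpmm_sample()` is a pure Gibbs sampler for the phylogenetic mixed model:
flat priors on fixed effects and inverse-gamma(0.001, 0.001) on both
variance components — the weak, customary choice for this model family,
exposed as arguments. The phylogenetic effect is sampled in the
eigenbasis of `C` (scaled to unit mean diagonal so the variance
components share the trait's scale), where its full conditional is
diagonal; one iteration costs two `n x n` rotations. Defaults (13,000
iterations, 3,000 burn-in, thinning 10) give 1,000 draws in about a
second at `n = 200`. DIC is computed as
`2 * mean(deviance) - deviance(posterior means)` with the conditional
Gaussian deviance, and model comparison treats `|dDIC| >= 2` as
significant. pMCMC is twice the smaller posterior tail about zero,
clamped below at `2 / n_draws` because a tail is never estimated as
exactly zero from finitely many draws. A split-chain Rhat above 1.1
triggers a warning (never an error): the intercept and the phylogenetic
effect are weakly identified against each other, and slow mixing there is
common and benign for inference about slopes.

## Rate-shift detection

`rjmcmc_rates()` samples over partitions of branches into BM rate
classes. A shift lives at a node and re-rates the node's own branch and
its whole descendant clade until overridden by a nested shift — the
clade-wise semantics that node-centred shift-probability plots assume.
The shift count has a truncated Poisson(1) prior, uniform over which
nodes carry the shifts; rates have a log-normal prior (sd 1.5 on the log
scale) centred on the contrasts-based rate estimate, a scale-free
empirical centring. Moves are a log-scale random walk on one rate, shift
birth/death and shift relocation. Birth proposes the new log-rate from
its prior, so the Hastings ratio collapses to likelihood ratio times
`pois_mean / (k + 1)` (death: `k / pois_mean`); the birth and death move
probabilities must be equal, and the acceptance arithmetic is exposed
(`rj_log_alpha`) so its reversibility is directly testable. The
likelihood is the REML (contrast) BM likelihood, so no root state is
sampled. The kernel is compiled (Rcpp) and uses R's RNG, making chains
bit-reproducible from `set.seed()`; 200,000 generations on a 64-tip tree
take a few seconds. Model-averaged branch rates are reported relative to
each sample's median branch rate, and `shift_summary()` calls shifts
significant above 0.95 posterior probability, classifying direction by
the clade's model-averaged rate against the tree-wide median.

Desk-scale defaults are 200,000 generations sampled every 200 with 25%
burn-in; full-scale analyses of the kind this models typically use
4,000,000 generations sampled every 4,000, and those settings are plain
arguments.

A property worth understanding before interpreting output: when a clade's
rate is elevated, the posterior can legitimately split between "shift at
the clade's stem" and "shift at one of its children", because the
evidence separating these lives only in the stem branch and the smaller
child's few contrasts, whose realised variance scatters widely. In
simulations with a 10-fold rate increase on a ~16-tip clade of a 64-tip
tree, the stem-exact posterior probability exceeds 0.95 in only roughly
half of trait realisations, even for chains long enough to be at
equilibrium — verified both by running 15x longer chains and by direct
profile-likelihood comparison of the competing placements. This is a
property of the inference problem, not of the sampler; null data, by
contrast, essentially never produce spurious 0.95 calls (posterior shift
counts match the Poisson prior). Practical reading: treat the *clade
region* with elevated model-averaged rates as the finding, and the exact
stem placement as approximate.

## Hearing and call-frequency calibration

Call-frequency models are `log10(kHz)` regressions on `log10` membrane
length (absolute, mm) and `log10` turns; two published coefficient sets
(phylogenetically corrected and ordinary stepwise) ship as data files and
load by name. Membrane length enters these models in absolute terms:
evaluating the shipped phylogenetic set at an 11.75 mm / 2.45-turn
cochlea yields ~38 / ~52 / ~65 kHz (minimum / peak / maximum), whereas a
mass-relative reading produces frequencies near 92 kHz for the minimum,
inconsistent with the magnitudes these models are known to produce — this
fixes the interpretation. Since the per-parameter regressions are fitted
independently, a predicted minimum can exceed a predicted maximum at
extreme morphologies; this is reported as a warning, not an error.

Hearing-limit calibrations are four OLS fits on `log10(kHz)`:
high-frequency limits (30 and 60 dB) on `log10` *relative* membrane
length, and low-frequency limits on the product
`log10(membrane mm) x turns`. The product's functional form is stated
only loosely in the literature it follows; taking turns unlogged is this
package's documented choice and is configurable by pre-transforming the
inputs. Responses are fitted and predicted on the `log10` scale and
anti-logged, so predictions are always positive; prediction intervals
propagate calibration uncertainty.

## The synthetic-data generator

`generate_study_dataset()` builds a joint dataset with the statistical
structure the analyses assume, so every stage is testable without any
download. Defaults, chosen once to emulate a bat-and-mammal cochlear
study: 100 species on a Yule chronogram (birth rate 0.065/My, giving
root heights around 60–70 My, the age scale of the bat crown group);
`log10` body mass by BM from a 19.22 g root (rate 0.01 per My);
`log10` membrane length on the mammalian allometry (slope 0.498,
intercept 0.717 against `log10 mass^(1/3)`) plus a +0.2 echolocator
clade offset, a lambda-0.9 BM deviation (rate 4e-5) and iid measurement
noise (sd 0.05); `log10` turns from relative membrane length (slope
0.123, intercept 0.342, residual sd 0.122); call frequencies from the
phylogenetic coefficient set with sd-0.05 noise; and a 38-species
audiogram calibration (noise sd 0.1) whose generative curves give a
11.75 mm / 2.45-turn / 19.22 g cochlea limits near 60 kHz (30 dB) and
100 kHz (60 dB) at the high end and ~1 kHz at the low end. The
echolocator group is the clade nearest half the species, because
ecological traits are phylogenetically clustered. Every latent quantity
(node states, clade identity, all parameters) is returned for recovery
tests.

The Yule simulator is written forward from the process definition
(exponential waiting times at rate `birth_rate * k`), so its expected
root height has the closed form `sum(1 / (birth_rate * k))`, `k = 2..n`
— the exact identity its tests check.

What passing tests on these data do **not** show: the generator draws
Gaussian, homoscedastic deviations on a correctly specified tree, with no
measurement asymmetries, no missing data, no fossil signal, and
echolocation as a single clean clade. Real datasets violate all of these
to some degree; the simulations validate the estimators' correctness, not
their robustness to misspecification.

## Numerical choices and degenerate inputs

Exact-fit regressions snap the residual sum of squares to zero and return
zero-width prediction intervals with a warning. Zero-length branches are
tolerated (they arise from polytomy resolution) except where a contrast's
combined branch length vanishes, which is an error. The BM covariance is
Cholesky-verified positive definite on construction, with eigenvalue
diagnostics on failure. Optimisations are derivative-free with fixed
tolerances (1e-6 for lambda); ties in nearest-quarter rounding follow
`round()`'s banker's rule. Tests and simulations in the package use
problem sizes of 8–200 species, 20,000–200,000 MCMC generations and
50–100 replicates, sizes at which every property checked stabilises.

## Known limitations

* OU, early-burst and multivariate models are out of scope; lambda is the
  only covariance transformation.
* The rate-shift model places shifts at nodes with clade-wise
  inheritance; branch-local (non-inherited) shifts are not represented,
  and exact stem placement is approximate (see above).
* BPMM supports a single Gaussian response; no multi-response or
  non-Gaussian families.
* The built-in call-frequency coefficients are point estimates; their
  estimation uncertainty is not propagated into predictions.
* Turn counting assumes the projected path is a roughly monotone spiral;
  strongly non-planar or self-crossing paths need a caller-supplied axis.
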