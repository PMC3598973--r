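# cochlevol

Comparative phylogenetics of cochlear morphology, hearing limits and
echolocation.

Mammalian hearing ranges are tightly linked to inner-ear geometry: basilar
membrane length scales with body size, high-frequency limits fall as the
membrane lengthens, and the number of cochlear spiral turns relates to
low-frequency sensitivity. Laryngeal echolocating bats push these
relationships to extremes. `cochlevol` is an R toolkit for asking, on a
time-calibrated phylogeny, how such traits evolved: it measures cochlear
morphometrics from 3D landmark paths, flags allometric outliers with
prediction intervals, reconstructs ancestral states under Brownian motion,
quantifies phylogenetic signal, fits phylogenetic regressions (deterministic
and Bayesian), locates branch-specific shifts in evolutionary rate, and
converts reconstructed morphology into predicted hearing limits and
echolocation call frequencies. It is aimed at comparative morphologists and
evolutionary biologists working with chronograms and per-species trait
tables.

## Models at the core

* **Brownian motion (BM).** A trait `x` evolves so that
  `Cov(x_i, x_j) = sigma^2 * t_ij`, where `t_ij` is the shared root-to-MRCA
  path length (My). Ancestral states come from generalized least squares,
  with the root state `(1' C^-1 x) / (1' C^-1 1)`; the independent-contrasts
  recursion gives the same root and an unbiased `sigma^2` estimate
  `sum(c_k^2) / (n - 1)`.
* **Pagel's lambda.** Off-diagonal covariances are scaled by
  `lambda in [0, 1]` and `lambda` is estimated by profile maximum
  likelihood, with likelihood-ratio tests against `lambda = 0` (star
  phylogeny) and `lambda = 1` (pure BM).
* **Phylogenetic regression.** PGLS under the (lambda-scaled) BM
  covariance, and a Gibbs-sampled Bayesian phylogenetic mixed model
  `y = X b + u + e`, `u ~ N(0, sigma2_p C)`, `e ~ N(0, sigma2_e I)`,
  reporting pMCMC (twice the smaller posterior tail about zero) and DIC,
  with `|dDIC| >= 2` as the significance convention.
* **Rate shifts.** A reversible-jump MCMC over clade-wise BM rate classes:
  a shift at a node re-rates its branch and all descendants; the prior on
  the number of shifts is Poisson(1), and per-node posterior shift
  probabilities above 0.95 are called significant.
* **Allometry and calibration.** OLS of `log10` membrane length on
  `log10 mass^(1/3)` with 95% prediction intervals for outlier
  classification, and log-log calibration regressions that map morphology
  to hearing limits (30/60 dB) and echolocation call frequencies.

## Worked example

```r
library(cochlevol)

## a synthetic 100-species study with bat-like generative structure
ds <- generate_study_dataset(study_config(n_species = 100, seed = 42))
log_rel <- setNames(
  log10(relative_membrane_length(ds$traits$membrane_length, ds$traits$mass)),
  ds$traits$species)

## ancestral state of log10 relative membrane length at the root
anc <- ancestral_states(ds$tree, log_rel, method = "ML")
anc[anc$node == 101, ]
#>   node estimate    se
#> 1  101    0.547 0.114

## phylogenetic signal
fit_lambda(ds$tree, log_rel)
#> Pagel's lambda: 0.9031 (logL 84.907, sigma2 0.0004406, root 0.5464, n = 100)
#>   vs lambda = 0: LR = 126.841, p = 2.01e-29
#>   vs lambda = 1: LR = 90.988, p = 1.45e-21

## call frequencies implied by an ancestral morphology of
## 11.75 mm membrane and 2.45 turns, using the built-in
## phylogenetically corrected coefficient set
round(predict_call_frequencies(11.75, 2.45), 1)
#>  min peak  max
#> 38.3 52.1 65.4
```

The root estimate (0.547 with SE 0.114, on log10 mm/g^0.33) is the
reconstructed relative membrane length of the synthetic clade's common
ancestor; the lambda fit says the trait carries strong but imperfect
phylogenetic signal (0.90, distinguishable from both 0 and 1); and the
final call shows how a reconstructed morphology converts to predicted
minimum / peak-energy / maximum echolocation call frequencies in kHz.

The full pipeline (simulation or file input, morphometrics, allometry,
signal, ancestral states, Bayesian regression, rate shifts, hearing
prediction) runs from one configuration:

```r
run_pipeline(list(seed = 7, out_dir = "run1",
                  stages = list(simulate = TRUE, allometry = TRUE,
                                lambda = TRUE, ancestral = TRUE,
                                rateshift = TRUE, hearing = TRUE)))
```

Every output file is hashed into `run1/manifest.json`; reruns with the same
configuration and seed are bit-identical.

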