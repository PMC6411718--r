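---
title: "Methods: morphometric trait construction and phylogenetic comparative inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometric trait construction and phylogenetic comparative inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosense)
```

`phylosense` analyses how fly species divide sensory investment between
vision and olfaction, and whether that division is structured by the
phylogeny. This vignette documents the models, the conventions behind every
derived trait, the numerical choices, and what the synthetic-data generators
do and do not emulate.

## Derived traits from raw morphometrics

All lengths are in µm, areas in µm², volumes in µm³; ratios are
dimensionless. There is no unit autodetection: the input CSVs are assumed to
be in these units.

**Eye surface area.** The compound eye is treated as a half ellipsoid and
its surface approximated by a half-sphere, `2πr²`. The default radius
convention is `r = (eye_width + eye_height/2)/2` — the eye width combined
with half the eye height. The phrase "average eye width and half eye height
as the radius" admits a second reading in which both axes are halved,
`r = (eye_width/2 + eye_height/2)/2`; this is exposed as
`convention = "halfwidth-halfheight"` so users can match either convention.
Both run low relative to integration of a true ellipsoid surface, but they
are internally consistent across species, which is what a ratio trait needs.

**Funiculus surface area.** The funiculus (third antennal segment, the main
olfactory surface) is a complete ovoid, so the default is the full-sphere
surface `4πr²` with `r = (length/2 + width/2)/2`, minus the circular base
`π(width/2)²` where it joins the pedicel. A half-surface alternative
(`surface = "half"`) is provided. Note that the full ovoid minus its base is
provably positive for any positive length and width, while the half surface
can go negative when width exceeds ~2.4× the length; that case raises a
geometry error rather than returning a nonsensical area.

**EF ratio.** Eye area divided by funiculus area: the central
sensory-allocation trait. Large values mean relatively large eyes
(visually-biased species), small values relatively large antennae
(olfactory-biased).

**Sensillum density.** Counts made on one face of the antenna are divided by
half the funiculus surface: `density = count / (½ · funiculus surface)`.

**Replicate aggregation.** Species values are the arithmetic means of the
raw linear measurements across replicates (typically 3–8 females), with the
derived areas computed *from the means*, not averaged over per-replicate
areas. This matches the convention of averaging widths and heights first, is
order-invariant in the replicates, and avoids a Jensen-gap dependence on
replicate noise.

**Neuropil ratios and disc ratios.** Optic lobe (OL), antennal lobe (AL) and
central-brain volumes give `OL:AL`, `OL:central` and `AL:central`; the
central brain excludes the AL, so `OL:AL = (OL:central)/(AL:central)`
exactly. The larval eye–antennal imaginal disc contributes the ratio of its
eye portion to its antennal portion, the proposed developmental origin of
the adult allocation.

**Attraction index.** The two-trap behavioural assay is summarized by the
symmetric preference index `(n_test − n_control)/(n_test + n_control)`,
bounded in [−1, 1] and undefined (an error) when no fly was captured.

## Phylogenetic comparative model

Under Brownian trait evolution on a rooted tree with branch lengths, the
trait covariance of two species equals the branch length their root-to-tip
paths share, giving the matrix **V** (`vcv_from_tree()`). Pagel's λ
multiplies the off-diagonal of **V**: λ = 1 is strict Brownian motion, λ = 0
removes all phylogenetic covariance.

The profiled Brownian log-likelihood (`bm_loglik()`) uses the GLS root state
`â = (1ᵀV⁻¹1)⁻¹1ᵀV⁻¹x` and ML rate `σ̂² = (x−â1)ᵀV⁻¹(x−â1)/n`. ML rather
than REML is used throughout, for a single transparent profile; at the
sample sizes involved (≈60 species) the λ estimate is essentially
unaffected, and the choice is recorded here because comparative packages
differ on it.

**λ estimation** (`fit_lambda_ml()`): a 101-point grid on [0, 1] followed by
golden-section refinement around the grid argmax, ties broken toward smaller
λ, tolerance 1e−8. The boundaries 0 and 1 are always kept as candidates, and
the returned optimum is verified in the tests against a 1001-point grid. The
two boundary hypotheses are tested by likelihood ratio with the 50:50
mixture correction (halved χ²₁ p-value) appropriate when the null value lies
on the boundary of [0, 1]; both `p_vs_zero` and `p_vs_one` are reported
because published analyses are often ambiguous about which null their single
"p" refers to.

**Blomberg's K** (`blomberg_k()`): the observed ratio of the ordinary mean
squared error around `â` to the GLS mean squared error, divided by its
Brownian expectation `[tr(V) − n/(1ᵀV⁻¹1)]/(n−1)`. K = 1 under Brownian
motion on the given tree — exactly 1 on a star phylogeny for *any* trait —
K < 1 indicates less resemblance among relatives than Brownian motion
predicts (variation within subgroups), K > 1 more. Significance comes from a
permutation test (`k_permutation_test()`): trait values are shuffled across
tips, the statistic is the GLS MSE (smaller = more signal), and
`p = (1 + #{MSE_perm ≤ MSE_obs})/(n_perm + 1)` with `n_perm = 999` by
default and a mandatory seed, so every p-value is reproducible.

**PGLS** (`pgls_fit()`): generalized least squares with error covariance
`σ²V(λ)`. The default mode re-estimates λ from the regression residual
profile by the same grid-plus-golden-section optimizer (`ml_lambda`,
matching the behaviour of the comparative packages most analyses cite); a
fixed strict-Brownian structure is available as `mode = "brownian"`.
Standard errors use `σ̂² = RSS_V/(n−p)` and t-based two-sided p-values on
`n−p` degrees of freedom. With an identity covariance the fit reproduces OLS
to machine precision, which the tests assert. Binary species traits (wing
pigmentation, light-dependent courtship) enter as 0/1 predictors of the EF
ratio; phylogenetic logistic regression is deliberately out of scope.

**Numerical choices.** All solves and log-determinants go through Cholesky
factorization; a raw determinant is never formed. Zero-length branches are
permitted; if a factorization fails, a 1e−10 diagonal jitter is added once,
with a warning. Tip alignment (`align_traits_to_tree()`) is strict and
case-sensitive: labels differing only in case raise an error, and pruning is
always reported, never silent. A constant trait makes σ̂² = 0; `bm_loglik()`
flags this as degenerate rather than crashing, and the signal statistics
refuse constant traits with a clear error.

## Synthetic data: what it emulates, and what it does not

The generators (`simulate_*`) are pure functions of their seed: a master
seed plus fixed per-generator offsets select independent substreams, so
adding a generator never changes the output of the others.

* `simulate_tree()` draws pure-birth (Yule) trees — exponential waiting
  times, uniform lineage choice — rescaled to unit root-to-tip depth so a
  Brownian rate of 1 means one unit of variance root-to-tip. Real molecular
  phylogenies are neither ultrametric in branch-length units nor Yule-like
  in shape; the calibration claims in the tests are about the estimators on
  trees of the study's size (~59–62 tips), not about any particular tree.
* `simulate_bm_trait()` draws from `MVN(root·1, σ²V(λ))` via the Cholesky
  factor of the transformed covariance.
* `simulate_binary_trait()` thresholds a latent Brownian trait at its
  `(1 − prevalence)` quantile. The latent-threshold construction gives the
  binary column tunable phylogenetic signal, which iid Bernoulli draws would
  not.
* `simulate_morphometric_table()` builds specimen-level measurement tables
  with the analysis's assumed structure baked in: log body length is
  Brownian on the tree (root 2500 µm, SD 0.25 over unit depth); head width
  is 0.36 × body length; log eye and funiculus areas both scale as
  `isometry_slope × log(head width)` (default slope 2 — isometry of an area
  on a length) with baseline coefficients 0.74 and 0.10 of head width
  squared; and a latent allocation axis `z` (SD `ef_log_sd`, default 0.4)
  shifts log eye area by `+z/2` and log funiculus area by `−z/2`, making the
  EF ratio equal to `exp(z)` up to a constant and hence independent of size
  by construction. The baselines are *Drosophila melanogaster*-scale values
  chosen once (body ≈ 2.5 mm, head ≈ 0.9 mm, eye area ≈ 0.6 mm²,
  funiculus ≈ 0.08 mm², EF ≈ 7.4). Linear measurements are back-solved
  through the exact inverses of the two surface-area formulas at fixed
  aspect ratios (eye height = 1.5 × width; funiculus length = 2.5 × width),
  and replicates get multiplicative lognormal noise with CV
  `measurement_cv` (default 0.05).
* The allocation axis defaults to `ef_lambda = 0` (no phylogenetic signal in
  the EF ratio), which is both what the real trait shows and what makes the
  generator's advertised independence between size and EF hold for ordinary
  least squares checks; `lambda_true` continues to govern the generic trait
  simulators so signal-recovery experiments can dial signal up and down. A
  Brownian allocation axis can be requested via `ef_lambda = 1`, in which
  case OLS confidence intervals on the EF-vs-size slope are anticonservative
  (phylogenetically correlated residuals) and PGLS should be used instead.
* `simulate_disc_data()` draws a two-group (olfactory- vs visually-biased)
  mixture of disc ratios and pairs them with adult EF ratios through a
  Gaussian copula on the log scale, so the population log-log correlation
  equals `rho_adult` regardless of the group separation. When given a named
  `adult_ef` vector it conditions on those values instead, which is how
  `simulate_study()` makes the disc file coherent with the specimen file for
  the same species.

What passing the simulation suite shows: the estimators are calibrated and
the pipeline recovers known generating parameters *under the generating
models* — Brownian or λ-transformed traits on ultrametric trees, lognormal
measurement error, isometric scaling. What it does not show: robustness to
model misspecification in real data (non-Brownian evolution, measurement
error correlated with size, tree estimation error), which no desk-scale
simulation can establish.

## Problem sizes used by the test suite

The calibration experiments run at the study's scale: a 59-tip tree with
200 replicate traits for λ recovery, 500 for K calibration, 100 shuffled
traits for the no-signal check, 200 datasets × 199 permutations for the
permutation-test type-I rate, and 200 replicates for PGLS interval
coverage. The permutation count for the type-I experiment (199) is smaller
than the package default (999) because the add-one estimator is unbiased at
any count and the experiment repeats the test 200 times; single analyses
should keep 999 or more.

## Known limitations

* λ is estimated on [0, 1] only; values slightly above 1 that some packages
  allow on some trees are not searched.
* No Ornstein–Uhlenbeck or multi-rate models; no ancestral-state
  reconstruction; trees are consumed, never inferred.
* Binary traits are predictors, not responses: no phylogenetic
  logistic/threshold regression.
* The permutation test conditions on the tree; it tests the exchangeability
  of trait values across tips, not the adequacy of the Brownian model.
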