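---
title: "Scale invariance, coarse-graining and criticality in whole-brain activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scale invariance, coarse-graining and criticality in whole-brain activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoRG)
```

## The problem

Spontaneous large-scale brain activity shows power-law (scale-free)
statistics across recording modalities. In statistical physics, scale
invariance arises at critical points of phase transitions, which has
motivated the hypothesis that healthy resting-state dynamics operate near
criticality. phenoRG implements a pipeline that quantifies scale
invariance in multivariate binary activity with four exponents and then
asks, through a connectome-coupled spin model, which dynamical regime
(ordered, disordered, critical) best reproduces them.

The pipeline works on three ingredients:

* an N x T matrix of region-of-interest (ROI) signals, binarized at a
  z-score threshold;
* the 3D positions of the ROI centers (for distances);
* optionally a symmetric structural coupling matrix C (e.g. from
  tractography) or its exponential-distance-rule (EDR) surrogate
  `C_ij = exp(-gamma r_ij)`.

## The four exponents

**Correlation function.** `correlationFunction()` averages pairwise
Pearson correlations of the binarized signals over half-open distance
bins `[r, r + dr)` and `fitCorrelationExponent()` fits
`g(r) ~ r^(-eta)` by least squares on log-log coordinates.

**Phenomenological renormalization group (PRG).** `runPRG()` iteratively
groups the two most correlated variables and replaces them by their sum
(`pairGreedy()` + `coarseGrainRaster()`), producing clusters of size
K = 2^k. Three observables are tracked:

* `varianceCurve()`: the mean variance of coarse variables, `V ~ K^alpha`.
  Independent signals give alpha = 1 (variances add), perfectly shared
  signals give alpha = 2 (amplitudes add); intermediate values signal
  nontrivial correlation across scales.
* `silenceCurve()`: `F(K) = ln P_silence(K)`, the log-probability that a
  cluster is fully silent in a frame, interpretable as a free energy
  `-ln Z_K` under a Boltzmann ansatz with null silence energy;
  `F ~ -K^beta` with beta = 1 for independent signals.
* `eigenspectrumCurve()`: eigenvalues of the within-cluster covariance of
  the member level-0 signals, rank-averaged across clusters of equal K;
  at a renormalization fixed point the spectra collapse in the relative
  rank and decay as `lambda ~ (rank/K)^(-mu)`.

**Connectivity-based PRG.** The same coarse-graining driven by structural
couplings instead of correlations: pairs maximize `C^(k)` and the
couplings themselves are coarse-grained by `coarseGrainConnectivity()`,
the mean of the four cross-pair weights, so a level-k weight is the mean
of 4^k original cross-weights. The grouping depends only on the
connectivity, never on the activity.

Every power-law fit is ordinary least squares on log-log coordinates,
with an exponential alternative fitted to the identical point set on
semilog coordinates and the ratio of coefficients of determination
`R_EV = R2_PL / R2_Exp` reported (`fitPowerLaw()`). Values above 1 favor
the power law. Distribution-tail MLE machinery
(Clauset-style, Kolmogorov-Smirnov) is deliberately absent: these
quantities are not probability densities, so likelihood-based tail
fitting does not apply.

## The spin model

`metropolisSample()` samples the pairwise model
`P(sigma) = exp(beta * sum_ij C_ij sigma_i sigma_j) / Z`, with
`sigma_i = +/-1`, by single-spin-flip Metropolis dynamics. Two
conventions matter and are fixed throughout:

* the energy uses an *ordered double sum*, so each undirected pair is
  counted twice; the two-spin correlation is `tanh(2 beta c)` and the
  exact 2D nearest-neighbor critical point becomes
  `beta_c = ln(1 + sqrt(2)) / 4 ~ 0.2203`;
* beta is part of the energy, so the acceptance probability is
  `exp(-dE)` with `dE = 4 beta sigma_i h_i`. Writing the acceptance as
  `exp(-beta dE)` with beta *also* in E would apply the temperature
  twice; the implementation applies it exactly once.

Local fields are cached and updated incrementally; every 10^4 attempts
they are recomputed from scratch and the largest deviation is reported
on the trace (`fieldCheckError`), which the test-suite requires to stay
below 1e-10.

`betaScan()` runs several independent chains per beta (5 by default,
matching standard practice of 50,000 stored sweeps after a 500,000-step
burn-in at production scale) and `locateCriticalBeta()` places the
critical point at the susceptibility peak
`chi = N (<M^2> - <|M|>^2)`, refined by quadratic interpolation through
the three points around the peak. `<|M|>` rather than `<M>` is the order
parameter because the two ordered branches cancel in sign across
realizations. The silence observable is undefined for spin data (the
+/-1 symmetry admits no silent state), so model activity is compared to
data through eta, alpha and mu only.

## Synthetic study conditions

The generators in this package are first-class, tested code and define
the conditions under which every claim is checked:

* `generatePositions()`: uniform points in a 140 x 170 x 100 mm box, a
  human-cortex bounding scale giving pairwise distances of the same
  order as parcellation centroids (a few to ~200 mm).
* `generateEDRConnectivity()` with gamma = 0.106 / mm, the decay rate of
  short-range (< 50 mm) structural connectivity at whole-brain scale.
* `generateIndependentRaster()` / `generateFullyCorrelatedRaster()` with
  p = 0.2, near the activation rate produced by theta = 1 binarization;
  these realize the two analytic PRG limits (alpha of 1 and 2).
* `generatePowerLawRaster()`: a dichotomized Gaussian whose latent
  correlation is `min(1, (r/r0)^(-eta))`, projected to the nearest
  correlation matrix by eigenvalue clipping when needed. This fixture is
  our construction: it produces binary data with a controllable,
  monotonically distance-decaying correlation function whose expected
  shape follows from the bivariate-normal orthant probability, which is
  exactly how the test suite validates the recovered eta (numeric
  tetrachoric oracle, 15% band).
* `shuffleTimeFrames()` and `shuffleConnectivity()`: the two negative
  controls -- per-row frame permutation (destroys correlations, keeps
  marginals; PRG exponents revert to 1) and weight-multiset-preserving
  connectivity shuffling (destroys the weight-distance relation).

What these surrogates do *not* emulate: hemodynamics, measurement noise
spectra, spatially inhomogeneous activation rates, subject-to-subject
variability, and the long-range tail by which real tractography departs
from a pure EDR. Passing tests on surrogates therefore validate the
*method* (estimators, conventions, bookkeeping), not any empirical claim
about recordings, which require user-supplied data.

## Defaults and numerical choices

| parameter | default | why |
|---|---|---|
| binarization theta | 1 z-unit | standard point-process reduction of ROI signals; ~16% activation on Gaussian signals |
| g(r) bin width dr | 0.43 mm | resolves centroid distances at 1000-ROI scale; coarser bins advised for small synthetic geometries |
| g(r) fit window | [10, 90] mm | below ~10 mm sampling is sparse, above ~90 mm bins mix hemispheres; configurable, and `scanFitWindow()` maps the stability region |
| PRG depth kMax | 6 (K = 64) | covariance spectra need >10 samples per variable; 1200-frame scans admit K <= 64 |
| eigen fit window | 1/K < rank/K < 0.4 | drops the rank-1 collective mode and the finite-size truncation tail |
| EDR fit cutoff | 50 mm | exponential decay holds at short range; long-range couplings depart from it |
| Metropolis | store every N attempts, 500k burn-in, 5 realizations | one stored configuration per sweep; burn-in removes initial-condition dependence |

Further conventions, each forced or chosen once and kept:

* **Bins are half-open** `[r, r + dr)` so no pair is double-counted; the
  edge rule is otherwise immaterial.
* **Bins or levels with non-positive values are excluded from log fits**
  (log undefined), with counts reported; the silence curve additionally
  excludes levels whose empirical silence probability is exactly zero
  (unobservable at the available T) and warns.
* **Greedy pairing uses signed correlations.** Summing anti-correlated
  variables would cancel amplitudes and break the variance-growth
  interpretation of coarse-graining; "most similar" means largest signed
  value. Ties break to the smallest first index, then the second, making
  runs bit-reproducible.
* **Odd variable counts:** the leftover variable is discarded from
  deeper levels so every cluster has exactly 2^k members (the observables
  assume equal cluster sizes); discards are logged on the hierarchy. From
  1000 nodes, 7 nodes' worth of leftovers accumulate by K = 64.
* **Silence is per-cluster, averaged, then logged.** The alternative
  reading (whole-population silence) would be K-independent and could
  not scale as `-K^beta` with beta < 1, so the mean-then-log convention
  is the one consistent with the free-energy interpretation.
* **Pairing correlations are recomputed at every level** from the coarse
  variables, i.e. the renormalization acts on the current system, not on
  level-0 statistics.
* **EDR fits use raw per-pair log-weights** (unbiased under the
  multiplicative-noise model); distance-binned fitting is exposed as an
  option (`binWidth`).
* **PSD projection** of the power-law kernel clips negative eigenvalues
  at zero and renormalizes the diagonal; the projection is rejected if
  the result is still not positive semidefinite to 1e-8.
* **Degenerate inputs fail loudly**: zero-variance rows, all-zero or
  asymmetric couplings, all-silent rasters, starved fit windows and
  boundary susceptibility peaks are all errors or warnings, never silent
  mangling.

## Problem sizes used by the checks

The analytic-limit checks run 512 series of 20,000 frames (K up to 64).
The sampler-vs-enumeration check uses ten random systems of 5-10 spins
with 200,000 stored configurations each, compared through batch-means
Monte-Carlo errors. The lattice benchmark uses a 32 x 32 torus, 13
temperatures, 3 chains each. The spin-model phase-pattern check uses a
256-node EDR surrogate with 10,000 stored sweeps per temperature: at the
located critical point the correlation exponent is nearest 0.5 and the
eigen-spectrum is power-law (R_EV > 1), while deep in the ordered phase
(1.5 beta_c) the spectrum decays exponentially (R_EV < 1). Reproducing
whole-brain critical exponents at full protocol scale (1000 nodes,
50,000 sweeps, 5 realizations, a fine beta grid) takes hours on one CPU
and real centroid coordinates, and is left to the user; the package's
defaults are exactly that protocol.

## Limitations

* Greedy max-correlation pairing is a heuristic, not a maximum-weight
  matching; it is the standard definition for this coarse-graining and
  is implemented exactly as stated (globally maximal remaining pair).
* Least-squares exponents on log-log coordinates carry the usual caveats
  of regression-based power-law estimation; R_EV quantifies relative,
  not absolute, adequacy of the power law.
* The susceptibility-peak estimate of beta_c has a finite-size bias of
  order a few percent at the system sizes used here.
* The dichotomized-Gaussian surrogate has no dynamics; it validates
  spatial-correlation estimators only.
* Exponents estimated from T ~ 10 * 2^kMax frames sit at the edge of the
  sample-size rule; the rule is enforced, but more data always helps.
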