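# phenoRG

Scale-invariance diagnostics for large-scale neural activity, and a
connectome spin model that maps them onto the phases of a second-order
phase transition.

## What it does, for whom

Resting-state brain recordings (e.g. parcellated fMRI) show power-law
statistics that are suggestive of critical dynamics. phenoRG is for
researchers who want to quantify that claim on their own multivariate
recordings. It implements:

* **Binarization** of ROI signals at a z-score threshold θ
  (`zscoreBinarize`, default θ = 1).
* **Correlation function** g(r): the mean pairwise Pearson correlation of
  nodes separated by distance in [r, r + Δr), fitted as g(r) ~ r^(−η̃) by
  least squares on log–log coordinates (`correlationFunction`,
  `fitCorrelationExponent`, `scanFitWindow`).
* **Phenomenological renormalization group (PRG)**: iteratively sum the
  two most correlated variables, σ′^(k+1) = σ_i*^(k) + σ_j*^(k), building
  clusters of size K = 2^k, and track three observables (`runPRG`):
  - variance V(K) ~ K^α̃ (`varianceCurve`; α̃ = 1 uncorrelated, 2 fully
    correlated),
  - silence free energy F(K) = ln P_silence ~ −K^β̃ (`silenceCurve`),
  - within-cluster covariance eigen-spectra λ ~ (rank/K)^(−μ)
    (`eigenspectrumCurve`).
* **Connectivity-based PRG**: the same coarse-graining driven by a
  structural coupling matrix, which is itself renormalized as the mean of
  the four cross-pair weights, C^(1)_{m′n′} = ¼[C_ik + C_il + C_jk + C_jl]
  (`coarseGrainConnectivity`).
* **Power-law vs exponential model comparison**: both models fitted by
  least squares to the identical point set; R_EV = R²_PL / R²_Exp > 1
  favors the power law (`fitPowerLaw`).
* **EDR connectomics**: fit of the exponential distance rule
  C_ij ∝ exp(−γ r_ij) (`fitEDR`), node strength, and linear signal
  prediction X_pred = CX scored per node (`linearPredictionScores`).
* **Spin model**: P(σ⃗) = Z⁻¹ exp(β Σ_ij C_ij σ_i σ_j) on a weighted
  connectome, sampled with Metropolis dynamics (`metropolisSample`, Rcpp),
  validated against exact enumeration (`exactBoltzmannMoments`), scanned
  over β (`betaScan`) with the critical point located at the
  susceptibility peak (`locateCriticalBeta`).
* **Synthetic data** for every stage: box geometries, EDR couplings,
  independent / fully correlated / dichotomized-Gaussian rasters, and the
  frame- and connectivity-shuffling controls.

The methods vignette (`vignettes/prg-criticality.Rmd`) documents the
model, conventions, defaults and limitations.

## Worked example

All four exponents on a synthetic raster with power-law spatial
correlations:

```r
library(phenoRG)

geo <- generatePositions(128, seed = 2)             # 3D box, mm
ras <- generatePowerLawRaster(geo, eta = 0.5, theta = 1,
                              nFrames = 2500, seed = 3)
C   <- generateEDRConnectivity(geo, gamma = 0.106)  # exp(-0.106 r)

cfg <- analysisConfig(raster = ras, geometry = geo, connectivity = C,
                      dr = 6, fitWindow = c(15, 120), kMax = 5, seed = 4)
rep <- runFullAnalysis(cfg)

rep$stages$corrfunc$eta$exponent          # 0.5154  g(r) decay exponent
rep$stages$prg_correlation$alpha$exponent # 1.2278  variance scaling
rep$stages$prg_correlation$beta$exponent  # 0.8818  silence free energy
rep$stages$prg_correlation$mu$exponent    # 0.1591  eigen-spectrum decay
```

Read: the recovered η̃ ≈ 0.52 matches the generator's latent exponent
after dichotomization; α̃ between 1 and 2 indicates correlation across
scales (away from both the independent and the fully shared limits); β̃
just below 1 shows the silence probability is close to, but not at, the
independent prediction; μ is the decay rate of the rank-ordered
covariance spectrum inside clusters.

A spin-model phase scan on a denser EDR surrogate (256 nodes):

```r
geo256 <- generatePositions(256, seed = 31)
C256   <- generateEDRConnectivity(geo256, gamma = 0.106)
scan <- betaScan(C256, betas = seq(0.15, 0.55, 0.04), realizations = 3,
                 nSamples = 4000, burnInAttempts = 4e5, seed = 112)
scan <- locateCriticalBeta(scan)
criticalBeta(scan)                        # 0.3093  susceptibility peak
```

At β_c the sampled activity reproduces the critical phenomenology:
g(r) is closest to a ~0.5 exponent, and the eigen-spectrum is power-law
(R_EV > 1), turning exponential in the ordered phase.

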