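---
title: "Multi-echo denoising: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-echo denoising: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models the package implements, the parameters
that matter (with units and defaults), what the synthetic phantom does and
does not emulate, and the design choices made where the design was
genuinely open.

## Signal model

A multi-echo acquisition samples each volume at E echo times. The package
models the voxelwise signal as monoexponential decay,

$$Y(t, v, e) \approx S_0(v)\,\exp(-T\!E_e / T_2^*(v)),$$

with BOLD fluctuations entering through the decay *rate*
($\Delta R_2^*(v,t)$, TE-dependent) and most artifacts entering through the
*amplitude* (TE-independent). This asymmetry is what every stage exploits.
The decay exponent is negative — the physical convention for transverse
relaxation — and all echo times are handled internally in milliseconds,
converted from BIDS seconds only at the I/O boundary.

## Decay fitting and optimal combination

`fit_monoexponential()` fits one $(S_0, T_2^*)$ pair per voxel by ordinary
least squares of $\log \bar S_e$ on $T\!E_e$, where $\bar S_e$ is the
temporal mean of echo $e$. A static whole-run fit is the only reading
consistent with a single $(S_0, T_2^*)$ per voxel entering the RMSE
metric, which evaluates residuals over *all* time points and echoes:

$$\mathrm{RMSE}(v) = \sqrt{\tfrac{1}{TE}\textstyle\sum_{t,e}
  \left[Y(t,v,e) - S_0 e^{-T\!E_e/T_2^*}\right]^2}.$$

Log-linear least squares (rather than iterative nonlinear fitting) is
deterministic and fast; the test suite validates it against a dense
grid-search nonlinear least-squares oracle (median relative $T_2^*$ error
below 5% at SNR 20, and below $10^{-6}$ noise-free). $T_2^*$ is clipped to
[1, 300] ms — bounds wide enough for tissue at 3T — and voxels with any
nonpositive mean echo signal, or estimates at the bounds, are flagged out
of `fit_mask`. `optimal_combine()` weights echo $e$ by
$T\!E_e\,e^{-T\!E_e/T_2^*}$ (normalized); outside `fit_mask` the
infinite-$T_2^*$ limit (weights proportional to TE) is used, so weights
always exist, are nonnegative, and sum to one.

## The preICA stage

`preica_denoise()` removes motion-like structure *before* combination,
when it is still coherent across echoes:

1. **Z-concatenation.** The E echo volumes are stacked along Z, so one
   decomposition yields a single time course per component with an
   extended spatial map; slab $e$ of the map is that component's
   expression in echo $e$.
2. **Decomposition.** PCA whitening followed by symmetric fixed-point ICA
   (tanh contrast) on the variance-normalized voxel-by-time matrix, with a
   fixed seed, up to 10 restarts on non-convergence, and restart
   abandonment once fresh initializations stop improving the final
   rotation increment (the typical situation when K exceeds the
   non-Gaussian subspace, where leftover directions are
   rotation-indeterminate and harmless).
3. **Automatic dimensionality.** K defaults to the number of covariance
   eigenvalues above the Marchenko–Pastur upper edge
   $\hat\sigma^2 (1+\sqrt{T/V})^2$, with $\hat\sigma^2$ the median
   eigenvalue, clipped to $[2, \min(T-1, 100)]$. An explained-variance
   rule (e.g., smallest K reaching 95% EV) was considered and rejected:
   after per-voxel variance normalization, i.i.d. thermal noise carries
   most of the eigenvalue mass, such a rule saturates at its ceiling
   (K near T), and planted-source recovery collapses (matched correlations
   fall from ~0.99 to ~0.35 in our experiments). The random-matrix edge
   adapts K to the signal subspace and recovers exactly the injected
   component count on phantoms.
4. **Features.** Per component: `max_rp_corr()` — the mean over 1,000
   random 90% subsamples of the maximum absolute Pearson correlation
   between the component time course and 36 realignment regressors (6
   parameters, their backward first differences, and both shifted one TR
   forward and backward; shift edges repeat the boundary value) *and*
   between the squared time course and the squared regressors — 72 values
   per subsample. `high_freq_content()` — the normalized spectral position
   (0 at 0.01 Hz, 1 at Nyquist) where cumulative power reaches 50%.
   `spatial_fractions()` — edge and CSF fractions of the suprathreshold
   ($|Z| \ge 2.3$) first-echo map, the echo with the highest SNR.
5. **Classification.** Motion if any of: the pretrained LDA decision
   function on (maxRPcorr, edgeFraction) is positive (`aroma_hyperplane`,
   imported verbatim as published constants, not retrained); HFC > 0.35;
   csfFraction > 0.10. All three thresholds are configurable; the defaults
   are the original single-echo classifier's. A plain $|Z|$ threshold
   (default 2.3) stands in for mixture-model map thresholding.
6. **Removal.** Non-aggressive regression: the full mixing matrix is fit
   to every voxel and only the motion components' contributions are
   subtracted — slab by slab, so each echo is cleaned with the *same*
   component set.

## The TE-dependence stage

`meica_denoise()` decomposes the combined series, then scores each
component: per voxel, the per-echo regression coefficients
$\beta_{v,e}$ of the echo data on the component time course are fitted
across echoes with a one-parameter $R_2^*$ model
($\beta_{v,e} \propto -\bar S_{v,e} T\!E_e$) and a one-parameter $S_0$
model ($\beta_{v,e} \propto \bar S_{v,e}$); the per-voxel F statistics are
averaged with the squared suprathreshold component Z-map as weights,
giving $\kappa$ (TE-dependence) and $\rho$ (TE-independence). This is a
deliberately minimal formulation — a two-model F contrast with elbow
selection — not a re-implementation of any full decision tree, and it is
documented as such.

**Elbow convention.** Components are accepted when $\kappa$ exceeds the
$\kappa$ elbow and $\rho$ falls below the $\rho$ elbow. The elbow of a
sorted score curve is its maximum-distance-to-chord point; the *threshold*
is the midpoint between that point and its predecessor, which keeps both
natural readings consistent: on $\kappa = \{100, 95, 5, 4\}$ the first two
components pass, and on $\rho = \{50, 1, 1, 1\}$ the tied low scores pass.
A curve spanning less than a 3x dynamic range has no elbow — a cluster of
comparable scores (e.g., all components genuinely BOLD) yields no cutoff
and every component passes that criterion, generalizing the degenerate
all-equal rule. Without this guard the elbow manufactures a cutoff inside
a homogeneous cluster and rejects valid signal.

## Quality metrics

* **DVARS**: RMS over in-mask voxels of the frame-to-frame difference,
  reported in raw intensity units (comparisons are within-dataset, so
  units cancel; a percent-of-mean mode is available). Its summary AUC uses
  trapezoid integration over the volume index (unit spacing). The first
  frame's DVARS and FD are 0 in confound tables (undefined differences).
* **Framewise displacement**: Power convention, backward differences,
  rotations converted at a 50 mm radius.
* **tSNR**: temporal mean over temporal SD (unbiased, $n-1$); zero-SD
  voxels are flagged NA and excluded from means.
* **Shannon entropy**: 20 equal-width bins over the observed range,
  $-\sum p_i \log_2 p_i$; constant series have zero entropy. Bin count and
  base are conventions, declared and configurable, and tested for
  internal consistency only.
* **Carpet matrix**: in-mask voxel rows ordered by correlation with the
  global signal, demeaned per row; rendering is left to `plot_carpet()`.

## Reliability metrics

`seed_fc_map()` correlates the seed-mean time series with every in-brain
voxel; `spatial_reliability()` is the Pearson correlation of that map with
a binary network template, and `cronbach_alpha()` summarizes consistency
across networks (items = networks, cases = subjects). `icc_curve()`
quantifies temporal reliability: for window lengths 5%..100% of the run in
5% steps (20 points), windows slide with stride `max(1, window/2)`, each
windowed connectome's upper-triangle pattern is compared with the
full-run pattern by ICC, and positions are averaged. Choices made here,
all configurable:

* **ICC flavor**: ICC(3,1) — two-way mixed, consistency, single measure —
  because an additive offset between a windowed and a full-run pattern
  should not count as unreliability.
* **Windows**: sliding with half-window stride, averaged; a start-anchored
  single-window mode exists for speed. Windows below 10 volumes are
  clamped up with a warning (correlations on fewer frames are too noisy
  to order).
* **MP** (minimum data percentage reaching ICC $\ge$ 0.95) is reported on
  the 5% grid without interpolation; means across runs land off-grid.
* Edge vectorization excludes the diagonal; ICC is computed on r values
  (Fisher-z is available but off by default, as patterns are compared, not
  pooled).

The final grid point compares the full run with itself, so the curve ends
at exactly 1 and AUC is at most 19.

## The synthetic phantom

`generate_phantom()` builds an ellipsoidal head: brain interior, a 1-voxel
edge shell (morphological erosion), a central CSF compartment, and
out-of-brain background — the minimal geometry supporting all classifier
masks. Within it:

* $S_0 \sim U(800, 1200)$, tissue $T_2^* \sim U(20, 60)$ ms, CSF
  $T_2^* \sim U(100, 200)$ ms — representative 3T values.
* **BOLD**: disjoint spherical networks with band-limited (0.01–0.1 Hz)
  unit-SD time courses entering through $\Delta R_2^*$ with SD
  0.0007 /ms (about a 2% signal change at TE 30 ms).
* **Motion**: realignment parameters are a slow random walk plus abrupt
  jerks (dominantly z-translation); the artifact time course is the
  rescaled framewise displacement plus its square (spike-locked to the
  parameters, as a realignment-locked classifier expects), applied
  multiplicatively with voxelwise heterogeneous gain on the edge shell
  (rim voxels gain or lose signal with displacement depending on the local
  spatial gradient — a flat-gain shell would be spatially featureless
  after Z-scoring). Default fractional amplitude 3%.
* **CSF**: additive band-limited fluctuations (SD 15) confined to the CSF
  compartment; **drift**: a linear trend of 1% of baseline per run;
  **thermal noise**: i.i.d. Gaussian, SD 10 (in-brain tSNR near 70),
  TE-independent by default so tSNR ordering across echoes stays
  interpretable.
* Defaults mirror a 4-echo 3T protocol — TEs 12/28/44/60 ms, TR 2.47 s —
  on a 24×24×12 grid with 120 volumes, sized so a full 4-variant run
  takes seconds and a 10-seed study a few minutes on one CPU; these sizes
  are also what the test suite and the acceptance script use.

**What it does not emulate** — and hence what passing tests do not show
about real data: EPI/k-space physics, susceptibility dropout,
cardiac/respiratory waveforms, spatial autocorrelation of thermal noise,
spin-history effects, and interactions between motion and the decay
parameters. The phantom encodes exactly the TE-dependent-signal /
TE-independent-noise dichotomy the method targets; real-data artifacts are
richer, and the desk-scale effect sizes here are deliberately modest (the
injected artifact, not broadband noise, is what denoising removes).

## Numerical conventions and degenerate inputs

* Seeds: every stochastic stage (phantom, ICA initialization, maxRPcorr
  subsampling) takes an explicit seed; identical seeds give bit-identical
  results. Pipeline stages derive distinct fixed offsets from the base
  seed, so enabling more variants never changes an earlier variant's
  output.
* ICA sign indeterminacy is fixed by making each spatial map's skewness
  positive; map Z-scoring and unit-variance time courses remove scale
  indeterminacy.
* Components with numerically zero loadings are flagged degenerate
  (relative tolerance $10^{-12}$) and rejected rather than scored.
* Constant regressors contribute r = 0 in maxRPcorr; constant voxels are
  excluded from tSNR means and zeroed before ICA.
* Masks are strictly binary on disk; nonzero values are coerced to 1 with
  a warning.

## Known limitations

The kappa/rho stage is a minimal surrogate and its elbow rule, while
deterministic and tested, is cruder than a multi-stage decision tree;
group-level statistics across subjects are out of scope (the test suite's
multi-seed sign tests stand in for them at desk scale); only volumetric
NIfTI is supported; and the automatic K rule, though robust on phantom
data, inherits the usual fragility of eigenvalue thresholds when noise is
strongly spatially correlated.
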