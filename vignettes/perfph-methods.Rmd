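---
title: "Methods: pH-weighted mapping from DSC-MRI perfusion time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pH-weighted mapping from DSC-MRI perfusion time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfph)
```

## The problem

Glioblastoma acidifies its microenvironment: hypoxia and the Warburg shift
toward glycolysis raise extracellular lactate and lower pH, particularly in
and around hypercellular, poorly perfused regions. Amine CEST-EPI measures
this acidity voxel-wise through the magnetization-transfer-ratio asymmetry at
3 ppm (`MTR_asym`), but CEST is not part of routine clinical protocols. DSC
perfusion MRI is. Because perfusion governs the washout of protons and
lactate, the temporal shape of the DSC signal carries information about local
acidity that conventional summary maps (rCBV, CBF) discard.

`perfph` implements the full inference chain: quantify `MTR_asym` from a CEST
acquisition (the target), compress each voxel's DSC signal–time curve into
seven temporal principal-component scores (the features), and learn a
per-subregion mapping from scores to `MTR_asym` with Gaussian-kernel support
vector regression, validated leave-one-subject-out. Because no patient data
ship with the package, a digital phantom generator with known ground truth
stands in for the cohort; every stage is exercised and audited against that
truth.

## The phantom generator

The generator defines the study conditions; it is configured once through
`phantom_config()` and not tuned per experiment.

**Geometry.** Each subject is an ellipsoidal "brain" on a regular grid
(default 20 × 20 × 12 voxels) containing a concentric-ellipsoid tumor in one
hemisphere: necrotic core (NC, label 1), enhancing tumor rim (ET, label 4),
and a peritumoral edema shell (ED, label 2), with small per-subject jitter in
position and size. Concentric ellipsoids guarantee that all three subregions
are non-empty and connected. All volumes share one grid; no registration is
simulated.

**DSC curves.** Each in-brain voxel carries latent hemodynamics
(L, D, R, t0, k): baseline signal level, fractional drop depth, recovery
fraction, bolus arrival time, and sharpness. The noise-free curve is

    S(t) = L * [1 - D * g(t) - D * (1 - R) * c(t)]

with `g` a unit-peak gamma-variate bolus, `g(t) = x^k * exp(k*(1-x))` for
`x = (t-t0)/(tp-t0)`, peaking at `tp = t0 + 20/k` seconds, and
`c(t) = (1 - exp(-(t-tp)/8)) * (1 - g(t))` a smoothed recovery step gated off
at the bolus peak. The gating factor `(1 - g)` matters: without it the
leakage term begins rising exactly where the bolus term is flat, pushing the
curve minimum below `L(1-D)` and off the peak. With it the curve attains its
three anchors exactly — baseline `L`, minimum `L(1-D)` at `tp`, late plateau
`L(1 - D(1-R))` — which is what the generator's unit tests pin at 1e-9
relative error. Tissue classes draw latents from distinct distributions (ET
high level and deep drop with poor recovery; NC low level and shallow drop;
ED intermediate; normal brain in between), reflecting the perfusion contrast
between subregions.

**The acidity link.** True acidity is a deterministic monotone function of
the hemodynamics,

    f(L, D, R) = 0.09 * clamp01(0.40 * clamp01(L/200) + 0.35 * D + 0.25 * (1-R))

plus optional Gaussian scatter (`link_noise_sd`), clamped to the fractional
`MTR_asym` scale [0, 0.1]. Direction and weighting mirror the reported
associations: higher signal level (PC1), deeper drop (PC2), and poorer
recovery (PC3) all accompany higher acidity. The scatter term models
biological decoupling between hemodynamics and pH; it is the knob that
degrades the recoverable correlation, and the recovery acceptance test
verifies that the cohort-mean union Spearman correlation falls monotonically
as it grows.

**CEST spectra.** Each voxel's z-spectrum is a three-pool Lorentzian model:
direct water saturation (amplitude 0.75, FWHM 1.2 ppm at 0 ppm), a broad
symmetric MT-like background (amplitude 0.10, FWHM 30 ppm at 0 ppm), and the
amine pool at +3.0 ppm (FWHM 1.0 ppm) whose amplitude is
`true_acidity / cest_w_cal()`. The calibration constant is computed in closed
form from the amine line shape over the ±3 ppm windows, so that noise-free,
shift-free window asymmetry returns the true acidity exactly; no NOE pool is
included, which keeps the acidity-free spectrum exactly symmetric (the null
tests exploit this). The sampled offsets are the 29-point schedule
`offset_schedule()`: -3.5..-2.5, -0.3..+0.3 and +2.5..+3.5 ppm in 0.1 ppm
steps. The middle range densely samples the water dip for B0 estimation; the
outer ranges bracket the ±3 ppm integration windows. (The printed source for
this schedule lists a third range that overlaps the others and cannot total
29 points; +2.5..+3.5 is the unique reading consistent with the stated
count.)

**B0 field.** The per-subject field is a signed global offset plus a random
low-order 3D polynomial, scaled so its maximum magnitude equals
`b0_amplitude_ppm` (default 0.2 ppm) and its magnitude never falls below 20%
of that. This models the dominant structure of real shim residuals — a
center-frequency offset modulated by smooth spatial terms — and avoids
degenerate zero-shift voxels for which correction is a no-op.

**Noise.** Defaults: DSC noise SD 1% of baseline signal (baseline SNR 100,
typical of smoothed clinical gradient-echo EPI), CEST noise SD 0.5% of S0,
link scatter 0.01. These were fixed from the variance-budget argument that
white acquisition noise spreads evenly over all temporal components, so the
noise share of total curve variance (≈ 0.3% at these settings) must stay
below the 1% head-room of the seven-component variance claim.

**What the phantom does not emulate** (so what passing tests do *not* show):
MR physics (relaxation, coil sensitivity, EPI distortion), motion,
registration error, partial-volume mixtures at tissue boundaries,
segmentation error, arterial input variability, and non-Lorentzian
(Henkelman-type) MT lineshapes. Results on the phantom demonstrate that the
pipeline recovers a recoverable signal faithfully; they do not certify
performance on patient data.

## CEST quantification

**B0 estimation** (`estimate_b0`). S0-normalized spectra of in-mask voxels
are clustered by K-means (default 8 clusters, seeded); a water-dip model is
fitted to each cluster centroid and then to each voxel, initialized from its
cluster's fit, with failed voxel fits falling back to the cluster center and
flagged. The dip model is a narrow Lorentzian plus a broad symmetric
Lorentzian background sharing one center on a flat baseline, fitted by
bounded Levenberg–Marquardt least squares; the shared center, bounded to
[-0.3, 0.3] ppm, is the B0 shift. Two design points deserve note:

* *Fit support.* The residual covers the water window (-0.3..+0.3 ppm) plus
  the -3.5..-2.5 ppm shoulder, which anchors the baseline. The +2.5..+3.5
  shoulder is deliberately excluded: it contains the amine resonance, which a
  symmetric dip model cannot represent, and including it drags the fitted
  center toward +3 ppm by up to 0.1 ppm at high acidity.
* *The broad component.* With a single Lorentzian the symmetric MT
  background biases the fitted center by ~2e-5 ppm even at zero shift; the
  two-component model contains the acidity-free spectrum exactly, so the
  center is recovered to machine precision noise-free and to well under
  0.01 ppm across conditions.

**Correction and asymmetry.** `correct_spectrum` resamples each spectrum at
`offset + B0` (cubic interpolation inside the densely sampled water window,
linear in the shoulders; FMM end conditions, which keep the round-trip error
of a generator-shifted spectrum under 1e-3). Offsets whose shifted position
leaves their contiguous sampled segment are marked missing. The 0.4 ppm
"integral" around ±3 ppm is the mean of the (up to five) non-missing samples
in the closed window — on a uniform grid a trapezoidal integral differs only
by a factor common to both windows, and the mean keeps values on the
conventional scale. Finally

    MTR_asym = (W(-3.0) - W(+3.0)) / S0

per voxel, a dimensionless fraction (any percent display is presentation
only). Voxels with nonpositive S0, non-finite spectra, or empty windows are
excluded from the validity mask.

## Temporal PCA of perfusion curves

**Alignment and normalization** (`normalize_and_align`). Per voxel, the
baseline is the mean of the pre-bolus frames (auto-detected from the mask
mean curve as the steepest-drop frame minus 2, floor 3, overridable); curves
whose relative drop is below `margin` (default 5%) are flagged bolus-free and
excluded; remaining curves are shifted integer frames so their minimum lands
on a common target index (the cohort median), with edge replication —
sub-frame interpolation would smooth the curves and is avoided.

Normalization "for baseline and maximum drop" pins two points affinely:
baseline to 1 and minimum to 0. The open design choice is *whose* baseline
and minimum. The default (`mode = "subject"`) pins the subject's mean-curve
baseline and minimum and applies that one affine map to all of the subject's
voxels: curves become comparable across subjects while within-subject
contrast in level and depth — precisely what PC1 and PC2 encode, and what the
acidity link depends on — survives. The alternative (`mode = "voxel"`) pins
every row individually; it enforces the per-row invariants exactly but erases
per-voxel amplitude, leaving only shape. Both are implemented and tested; the
subject mode is the default because the component interpretation (PC1 ≈
signal level, PC2 ≈ drop depth, PC3 ≈ drop/recovery shape) and the
hemodynamics-to-acidity recovery are only possible under it.

**Decomposition** (`fit_pca`). Mean-centered PCA via SVD of the pooled
stratified sample (up to 1000 voxels per subregion per subject across the
cohort — one cohort-level basis), components ordered by decreasing variance
with each component's largest-magnitude loading forced positive, making the
basis deterministic across platforms. The test suite checks the decomposition
against an independent `eigen(cov(x))` oracle at 1e-8. On the default cohort
the first seven components capture ≥ 99% of the variance (about 99.7% in
practice); the pipeline records the full cumulative-variance profile and the
smallest component count reaching the configured target.

## Regression and validation

Features are the 7 PC scores, standardized by training-fold mean/SD (the
same transform applied to test voxels; fold-internal, so no leakage through
the scaler). One epsilon-SVR with radial kernel is trained per subregion on
the pooled stratified samples of the training subjects (SMO via libsvm). The
kernel scale is the median pairwise Euclidean distance among ≤ 2000
standardized training rows (seeded subsample), `gamma = 1/(2*scale^2)` — a
deterministic stand-in for proprietary "automatic" scale heuristics. Box
constraint defaults to 1 and epsilon to `IQR(targets)/13.49` (an SD-consistent
tube width); both are recorded in the fitted object and overridable.

Leave-one-subject-out: each fold trains the three subregion models on all
other subjects and predicts every valid voxel of the held-out subject with
its own subregion's model; the stitched result over ET ∪ NC ∪ ED is the
constructed `MTR_asym` map. Training provenance (subject IDs per fold per
subregion) is retained and asserted empty of the held-out subject.

Evaluation is the Spearman rank correlation between constructed and actual
maps over paired valid voxels, per subregion and over the union, per subject;
the cohort summary is the unweighted mean of per-subject correlations (not
pooled-voxel correlation). P-values use the large-sample t approximation at
n ≥ 10 and the exact permutation distribution below that.

## Numerical choices and degenerate inputs

* Constant (or entirely within-tube) SVR targets leave libsvm with no
  support vectors; the model degenerates to its bias, the mean target.
* All-identical curves have zero total variance: `fit_pca` errors in strict
  mode and returns a flagged zero-component model otherwise; rank-deficient
  input reduces the usable component count.
* K-means degeneracy (fewer distinct spectra than clusters) degrades to a
  single global cluster; fewer in-mask voxels than clusters is an error.
* Voxels pinned at the ±0.3 ppm center bound, failed per-voxel fits, and
  non-finite spectra are flagged in the B0 map.
* Exact permutation p-values enumerate n! orderings and are used only below
  10 pairs (≤ 362 880 permutations).
* Ties in Spearman ranks use average ranks; correlations of identical maps
  are 1 up to a few ulps, so tests compare at 1e-12 rather than exactly.

## Problem sizes

The reference conditions used throughout the tests and the reproduction
script: 12 subjects on a 20 × 20 × 12 grid (~1860 brain voxels per subject),
60 DSC frames at TR 2 s, 29 CEST offsets, 1000 sampled voxels per subregion
per subject (clamped by subregion size; ~4400 pooled training curves).
Smaller grids (down to 12 × 12 × 8) and cohorts (3–6 subjects) are used for
unit tests and the noise-sweep experiments; all sizes are configuration, not
code.

## Known limitations

The B0 scheme is one faithful reading of a clustering-plus-Lorentzian-fitting
algorithm that is cited rather than specified in the source literature;
cluster count, fit support, and per-voxel initialization are isolated behind
`estimate_b0`'s interface. Whether curve normalization should be per-voxel or
per-subject, and whether regression should train on sampled or all voxels,
are likewise unstated upstream; both are exposed as configuration with the
defaults argued above. The cohort-level correlations attainable on real
patients depend on the true biological coupling between hemodynamics and pH,
which the phantom parameterizes but cannot validate.
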