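---
title: "Methods: simulating and quantifying hyperpolarized 13C CSI treatment-response studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying hyperpolarized 13C CSI treatment-response studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hpcsi)
```

## What this package models

Hyperpolarized [1-13C]pyruvate MRSI measures the cerebral conversion of
pyruvate to lactate in vivo. In neuroinflammation, activated innate immune
cells up-regulate glycolysis (high PDK1, low PDH activity), routing
pyruvate towards lactate; the time-integrated lactate/pyruvate signal
ratio therefore rises with inflammatory burden and falls under effective
immunomodulatory therapy. Co-injected [13C]urea is metabolically inert and
serves as a perfusion/delivery control, and pre/post-gadolinium
T1-weighted imaging provides the conventional blood-brain-barrier
endpoint.

`hpcsi` implements this whole measurement chain twice over: a forward
model (kinetics, spectral synthesis, k-space encoding, noise, cohort
structure) and the analysis pipeline a study would apply to real data
(reconstruction, Lorentzian peak quantification, ratio and normalization
maps, group statistics). Because the forward model has closed-form
ground truth, every stage of the analysis is verifiable without animal
data.

## Two-site exchange model

Longitudinal magnetization of pyruvate (P), lactate (L) and urea (U) in a
voxel follows

$$\frac{dP}{dt} = u_p(t) - (R_{1,pyr} + \lambda_{RF} + k_{PL})\,P, \qquad
\frac{dL}{dt} = k_{PL} P - (R_{1,lac} + \lambda_{RF})\,L,$$
$$\frac{dU}{dt} = u_u(t) - (R_{1,urea} + \lambda_{RF})\,U,$$

with a boxcar delivery input $u(t)$ over the 12 s intravenous injection
(optionally delayed). Back-conversion $k_{LP}$ is available but defaults
to zero — the unidirectional model is the standard reading of
hyperpolarized pyruvate experiments. RF sampling losses are folded into a
continuous rate $\lambda_{RF} = -\log(\cos\theta)/TR$; with 64 phase
encodes per 4 s frame the excitations are dense enough that the
continuous approximation is excellent, and it keeps the system autonomous
(`rf_depletion_rate()` is about 0.255 1/s at the default 10° / 60 ms).
`simulate_magnetization()` integrates the system with an adaptive solver
(lsoda, rtol 1e-8); the test suite checks it against an independently
coded fixed-step RK4 oracle and against the exact closed-form solution of
the unidirectional model.

Integrating the lactate equation from injection to infinity gives the
precursor-product identity

$$\frac{\int L\,dt}{\int P\,dt} = \frac{k_{PL}}{R_{1,lac} + \lambda_{RF}},$$

independent of the delivery shape (`auc_ratio_theory()`). This is the
analytic oracle for the pipeline's model-free AUC-ratio readout, and the
forward map used to calibrate the cohort preset. `fit_kpl()` additionally
provides a model-based estimator (closed-form model, profiled amplitude,
golden-section search over $k_{PL}$, optional inverse-variance weighting
when per-series noise levels are known) used purely for
parameter-recovery validation.

## Acquisition model and parameters

`acq_params()` fixes the acquisition constants: 14.1 T (carbon frequency
$\approx$ 151.0 MHz), 8x8 matrix over 24x24 mm², 5 mm slice, 2500 Hz
spectral width over 128 points, TR 60 ms, flip angle 10°, one frame every
4 s, 15 frames (one minute of dynamic data; the frame count is
configurable). The three resonances — urea 162.5 ppm, pyruvate 171 ppm,
lactate 183.5 ppm — span about 21 ppm ($>$ 3100 Hz), which cannot fit in
the 2500 Hz window, so with the carrier at 173 ppm the urea and lactate
lines alias to apparent offsets of ±915 Hz (`ppm_to_offset_hz()`
documents the wrap-around). The apparent positions remain separated by
more than five linewidths, which the tests guard as a fit-identifiability
invariant.

Each voxel and frame yields a Lorentzian-line FID
(`synthesize_voxel_fid()`); frames are phase-encoded by a normalized 2D
spatial DFT with a centred k-space layout (`encode_kspace()`), and i.i.d.
complex Gaussian noise is added in k-space. One FID represents each
frame; the 64 individual phase encodes are not simulated (their RF cost
lives in $\lambda_{RF}$), keeping the dataset exactly the shape the
pipeline consumes. Echo-time and first-order phase effects are not
simulated (TE 1.2 ms treated as zero-phase). Coil sensitivity, $B_0$
inhomogeneity and chemical-shift displacement are out of scope.

The default k-space noise, $\sigma = 5\times10^{-4}$ per component, gives
time-summed-spectrum SNR of roughly 300 for pyruvate and 20 for lactate
at the control conversion rate — the clean-summed-spectrum regime in
which hyperpolarized studies quantify ratio maps. At substantially lower
SNR the bounded Lorentzian fit acquires a positive bias on weak lactate
lines (amplitudes cannot go negative, and noise-level peaks fit at
maximal width); the pipeline flags and excludes such bound-saturated
voxels, but the generator default deliberately stays in the
well-quantifiable regime.

## Quantification chain

Per dataset, `analyze_csi()` applies, in order:

1. **Spatial zero-filling** by a factor 2 (8x8 to 16x16), zeros split
   symmetrically around the k-space centre. Under the centred, normalized
   DFT convention this is exact Fourier interpolation: reconstructed
   values at the original voxel centres are unchanged (frozen by a
   round-trip test at 1e-8).
2. **Reconstruction** by the inverse spatial DFT (`reconstruct_voxels()`),
   the exact inverse of the encoder (1e-10 round trip).
3. **Time-summed spectra** per voxel: each frame's FID is Fourier
   transformed, zero-order phased on its dominant peak, and the real
   parts summed (`voxel_summed_spectrum()`; magnitude mode available).
   The phase is estimated from the complex sum of a symmetric ±4-bin
   window around the dominant peak rather than from the argmax bin: the
   dispersive part of an off-bin-centre line is odd about the peak and
   cancels in the windowed sum, while the argmax-bin phase carries a
   fractional-bin bias that would propagate a systematic error of order
   10% into the AUC ratio. No apodization is applied by default (line
   broadening worsened, not improved, the ratio accuracy here).
4. **Three-peak Lorentzian fitting** (`fit_three_peaks()`): simultaneous
   bounded least squares of three Lorentzians plus a constant baseline
   with analytic Jacobian. Centres start at the nominal apparent offsets
   and may move ±1 ppm; half-widths are bounded in [2, 200] Hz;
   amplitudes are non-negative. Each AUC is the analytic integral
   $\pi A \gamma$ with a delta-method standard error. Non-convergent or
   bound-saturated voxels are flagged and excluded from ratio maps.
5. **Readouts**: lactate/pyruvate AUC ratio per voxel (kept only where
   the pyruvate AUC exceeds 5 times its standard error), urea AUC
   normalized to the mean urea AUC of the vascular-reference voxels
   (`normalize_urea()`), ROI averaging over the brain region of interest
   (`roi_mean()`).

Cohort-level z-score maps use the per-voxel mean and *sample* standard
deviation (n−1 denominator — the formula's denominator is otherwise
unspecified, and the sample convention matches the statistics software
the field uses) across all animals (`compute_zscores()`); voxels with
zero spread are masked. Display maps are bilinearly interpolated to
anatomical resolution with an align-corners grid, so source voxel-centre
values are preserved exactly and no extrapolation occurs
(`render_heatmap()`).

The finite 60 s acquisition window, frame sampling and line-shape
truncation leave a small systematic difference between the pipeline
ratio and the kinetic identity: across $k_{PL} \in [0.005, 0.08]$ 1/s the
noiseless pipeline agrees with $k_{PL}/(R_{1,lac}+\lambda_{RF})$ to
within 10%, worst (about +9%) at the smallest rate where the lactate
line is faintest, and within ~1% above 0.02 1/s. The tests characterize
this bias explicitly; because it is nearly uniform across the rates a
study compares, group fold-changes are essentially unaffected.

## Synthetic cohorts

`group_spec()`/`generate_study()` draw animals from a one-factor latent
model: a Gaussian "inflammation burden" $b$ per animal drives every
readout. Conversion is log-linear, $k_{PL} = k_0 e^{\lambda b}$ (brain
voxels only; vascular-reference voxels keep template kinetics); the
clinical disability score is an ordered-categorical link on a latent
scale with euthanasia-at-4 censoring; nine ex vivo markers and the T1
enhancing volume are linear in $b$ with per-group intercepts, truncated
at zero. A single latent factor is the minimal structure that produces
the pairwise associations a treatment-response study tabulates, and its
implied correlations are analytically checkable (the tests verify the
closed-form correlation between $k_{PL}$ and a marker to ±0.05).

The packaged preset (`cpz_eae_preset()`, constants in
`inst/extdata/cpz_eae_preset.yaml`) encodes a four-group study — control,
untreated disease, and two treated arms (group sizes 14/12/11/14) — whose
designed contrasts are: lactate/pyruvate 2.1-fold higher in disease than
control, reduced 1.31- and 1.35-fold by the two therapies; mean clinical
scores 0/2.6/1.1/0 (the fully-protective therapy preset floors the score
latent); T1 enhancing volume 5.2- and 3.0-fold above control in the
untreated and partially-responding arms; an 8.1-fold PDH activity drop
with 3.7/3.2-fold treatment rescue; 7/25/455/95/3.5-fold increases of
Iba1/CD68/CD3/PDK1/GFAP; myelin loss; and a urea readout designed null.
Burden group means are obtained by inverting the log-linear $k_{PL}$ link
at the designed ratio folds, so the expected group contrasts of the
pipeline's readout equal the designed folds by construction. Marker
link slopes are proportional to the group mean (within-group burden CV
0.25, a config constant) with the sign of the marker's declared
direction; this keeps zero-truncation negligible even for near-zero
control means (a shared absolute slope would otherwise inflate them
catastrophically — a 455-fold contrast cannot ride on one linear link).
Per-animal distribution families (lognormal rates, truncated-Gaussian
markers) are generator choices; real per-animal distributions are not
observable from group summaries.

What the generator does *not* emulate: spatially heterogeneous lesions
within the ROI, longitudinal disease trajectories, treatment
pharmacokinetics, $B_0$/phase artifacts, or inter-marker correlations
beyond the single factor. Passing tests therefore demonstrate the
correctness and calibration of the analysis chain under the stated
physics, not robustness to every artifact of real data.

## Contrast-enhanced T1 endpoint

`simulate_t1_pair()` produces aligned pre/post images (256x256, 20x20
mm² field of view, 0.8 mm slice; voxel volume $(20/256)^2 \times 0.8
\approx 0.00488$ mm³) in which lesion voxels scale by $1 +$ enhancement
fraction. `enhancement_volume()` segments enhancement by thresholding the
relative signal change at `mean + k_sd * sd` of a normal-appearing
reference region — a rule made explicit here because volume endpoints
are commonly reported without one; both the rule and `k_sd` are exposed.
The single-pair default is $k = 3$. At the study level `run_study()`
counts enhancing voxels inside a central brain disc with $k = 4$: the
false-positive budget implies an expected spurious volume of about
0.2 mm³ at $k = 3$ over the ~31,000-voxel disc versus ~0.005 mm³ at
$k = 4$, and the smallest designed group volume is 0.3 mm³. A
false-positive-rate invariant (enhancing fraction at most the Gaussian
tail implied by `k_sd` on lesion-free pairs) is under test.

## Statistics

Group comparisons use one-way ANOVA with Tukey HSD pairwise contrasts,
or a Kruskal-Wallis omnibus with Dunn pairwise z-tests adjusted by the
two-stage step-up FDR procedure of Benjamini, Krieger and Yekutieli
(`bky_two_stage()`: stage one at $q/(1+q)$, stage two at
$q/(1+q) \cdot m/m_0$; the implementation is checked exactly against an
independently coded enumeration of the published definition). Which test
serves which endpoint is configurable; the default routes the ordinal
clinical score through the rank-based family and everything else through
ANOVA, since the original statistical reporting lists both families
without a per-endpoint assignment. Associations are Pearson correlations
(score and T1 volume) and simple linear regressions (markers on MR
readouts), mirroring the standard association-table layout. ANOVA size
is verified by simulation (type-I error within [0.04, 0.06] over 2000
null cohorts).

## Numerical conventions and degenerate inputs

* Forward spatial DFT normalized by $1/n^2$, centred layout; inverse
  unnormalized — chosen so zero-filling needs no rescaling. Energy obeys
  $\sum |x|^2 = n^2 \sum |K|^2$.
* Even matrix sizes only (centred zero-fill is exact); spectral axis
  ascending with DC at index $n/2+1$.
* Lorentzian width parameter is HWHM $\gamma$; linewidth inputs are FWHM.
* Ratio voxels need `AUC_pyr > 5 * se`; empty or non-positive urea
  reference sets raise errors (a bad mask should fail loudly).
* Zero-variance voxels in z-score maps, all-unreliable ROIs, and
  non-convergent fits are masked/flagged with warnings, never silently
  dropped; group-comparison outputs re-state per-group n so drops are
  visible.
* All randomness is seed-explicit; per-animal seeds derive
  deterministically from the master seed, and identical seeds reproduce
  studies byte-for-byte.

## Problem sizes used in the shipped checks

The test suite runs cohorts of up to 50 animals per group through the
full chain (about two minutes), 2000-replicate null calibrations for the
ANOVA size, 100-replicate noise studies for rate recovery, and
2000-animal draws for generator calibration — sizes at which Monte-Carlo
error is comfortably below every tolerance asserted.

## Known limitations

* The AUC-ratio pipeline has the characterized small-rate bias described
  above; it is a property of finite acquisition and line-shape
  truncation, not of the fit.
* Truncated-Gaussian marker links slightly inflate group means whose
  designed value is within ~3 SD of zero (the strongest case, the
  disease-arm PDH mean, shifts the 8.1-fold design to about 7.5
  measured).
* The urea reference region is simulated as genuinely vascular voxels;
  in real data the mask is user-supplied and its quality is the user's
  responsibility.
* T1 enhancement uses a single slice and a threshold rule; no
  registration or pharmacokinetic modeling.
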