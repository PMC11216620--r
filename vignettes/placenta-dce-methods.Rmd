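---
title: "Quantifying placental perfusion and uterine contraction from DCE-MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying placental perfusion and uterine contraction from DCE-MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement problem

Each mouse pregnancy carries 6–12 fetoplacental units in one maternal
environment, which makes the mouse an attractive model for separating
maternal from fetal contributions to placental disease — provided placental
function can be read out *in vivo*, repeatedly, across gestation.
`placentaDCE` implements such a readout from dynamic contrast-enhanced
(DCE) T1-weighted MRI: voxelwise perfusion by the steepest-slope model,
chamber decomposition by a physiologically motivated percentile threshold,
probabilistic perfusion biomarkers from a two-component Gaussian mixture,
apparent gadolinium uptake from variable-flip-angle (VFA) R1 mapping, and
quantification of phasic uterine motion by Horn–Schunck optical flow with
time–frequency analysis. A digital phantom generates data with the same
statistical structure so that every stage is testable without animal data.

# Models

## Signal model and R1 mapping

The spoiled gradient-echo steady-state signal at flip angle $\alpha$ and
repetition time $TR$ is

$$S = M_0 \sin\alpha \,\frac{1 - E_1}{1 - E_1\cos\alpha},
  \qquad E_1 = e^{-TR/T_1}.$$

`fit_t1_vfa()` estimates $(M_0, E_1)$ per voxel from the five-angle VFA
acquisition (75°, 55°, 30°, 20°, 10° at $TR = 114.88$ ms) by Gauss–Newton
least squares, initialised from the linearisation of the signal equation
($S/\sin\alpha$ regressed on $S/\tan\alpha$, whose slope is $E_1$). Then
$T_1 = -TR/\ln E_1$ and $R_1 = 1/T_1$ in Hz. Voxels whose $E_1$ is pinned
at the (0, 1) bounds are flagged invalid rather than zeroed. On noiseless
forward-model data the linear initialiser is already exact, so the fit
inverts the forward model to solver precision; the suite asserts 1e-6.

Gadolinium shortens $T_1$ in proportion to its local concentration, so
$\Delta R_1 = R_1^{post} - R_1^{pre}$ tracks accumulated contrast agent.
The apparent Gd uptake of a chamber is the extensive summary
$AGU = \overline{\Delta R_1}\,\cdot\,\#\text{voxels}$ (Hz·voxels); the
chamber-mean $\Delta R_1$ — the volume-normalised variant that some
figure-level summaries prefer — is emitted alongside, since the two differ
only by the voxel count. Negative $\Delta R_1$ values are retained: they
indicate the noise level and clamping them would bias chamber means.

## Steepest-slope perfusion

During bolus wash-in, before venous washout, tissue concentration follows
$dC_T/dt \simeq (F/V_T)\,C_A(t)$, with $C_A$ the arterial input function
(AIF). The maximum of the left side therefore estimates perfusion:

$$\frac{F}{V_T} \cong \frac{[dC_T/dt]_{\max}}{[C_A]_{\max}}.$$

`steepest_slope_map()` takes the per-voxel maximum forward difference of
the preprocessed signal over the 18-s frame interval, clamped at zero
(wash-out lies outside the model's validity); `perfusion_map()` divides by
the peak AIF enhancement and scales by 6000 to convert s⁻¹ to
mL/min/100 mL. Signal enhancement stands in for concentration — a linear
signal–concentration assumption under which the global signal scale
cancels, verified as a property test. A Savitzky–Golay derivative was
considered and deliberately not made the default: the model is defined on
the steepest slope of the measured signal, and any smoothing kernel would
become part of the estimator.

The AIF is the baseline-subtracted mean time course of a renal-hilum ROI.
It is extracted after temporal denoising but **before** the spatial median
filter: ROI averaging is itself a spatial filter, and a 3×3×3 median
around a small ROI bleeds surrounding tissue into the trace, biasing peak
enhancement (and hence every perfusion value) upward of 50% in phantom
experiments.

## Preprocessing

Per voxel along time: a median filter (default window 3 frames) removes
respiration-type spikes, then grayscale morphological closing (flat
structuring element, default 3 frames) suppresses transient downward
excursions from inter-frame displacement. The defaults are the smallest
nontrivial odd sizes — at 18 s per frame, wider windows would erase the
~10 mHz physiology of interest. Both operators use replicate padding, as
does the 3×3×3 spatial median applied frame by frame. The operators are
1-D temporal; a spatiotemporal closing variant was considered and
rejected because the artifacts being targeted are temporal.

The mean-removed maximum intensity projection (`mean_removed_mip()`)
subtracts the frame-average over the initial uptake phase (first
post-injection frame through the AIF peak frame, by default) and takes
the per-voxel maximum over time; it is the reference image a reader would
segment on.

## Chambers by physiological percentile

Stereology gives the labyrinth zone roughly 45% of placental volume at
E14.5 and 55% at E17.5. `physiological_threshold()` therefore thresholds
each placenta's perfusion values at its own 55th percentile (E14.5) or
45th percentile (E17.5): voxels strictly below form the low-perfusion
chamber (decidua + junctional zone proxy), the rest the high-perfusion
chamber (labyrinth proxy). Quantiles use linear interpolation of the
empirical CDF (R type 7); ties at the threshold go high, so a constant
placenta comes out all-high with a warning rather than failing. On
tie-free values the chamber fractions are exact by construction. The
threshold is per placenta by default; a `pool = "litter"` flag shares one
threshold across the litter, since litter-level pooling is a plausible
variant behind reported between-placenta variability in chamber fractions.

## Perfusion-distribution biomarkers

Pooled placental perfusion values are log10-transformed (zeros excluded
and counted) and summarised two ways. First, a histogram density
(Freedman–Diaconis bin count by default) whose returned grid is padded
with a zero-height point half a bin beyond each end, making the
trapezoidal integral exactly 1. Second, a two-component Gaussian mixture
fitted by expectation–maximisation written out explicitly: E-step
responsibilities

$$\gamma_i = \frac{\pi\,\phi(x_i;\mu_2,\sigma_2)}
  {(1-\pi)\,\phi(x_i;\mu_1,\sigma_1) + \pi\,\phi(x_i;\mu_2,\sigma_2)},$$

M-step responsibility-weighted moment updates, iterated until the
relative log-likelihood change falls below 1e-8. Initialisation splits
the sample at its median and moment-matches each half — deterministic, so
pipeline runs are reproducible; a seeded random-restart mode exists and a
multi-restart reference implementation backs the equivalence test. A
variance floor of 1e-6 guards against component collapse (fitted sigmas
in this domain can be as small as 0.01): a collapsing component is
re-spread once with a warning, and repeated collapse returns a
non-convergence flag instead of garbage. From the fit,
`pdf_biomarkers()` computes per weighted component $w\,N(\mu,\sigma^2)$:
peak height $w/(\sigma\sqrt{2\pi})$, FWHM $2\sqrt{2\ln 2}\,\sigma$
("half-width" and "half-height" in some summaries name this same
quantity), and trapezoidal AUC over $\mu \pm 6\sigma$, which the tests
check against the closed-form weights. The weighted component density is
used for the peak, as the unweighted alternative would not sum to the
mixture.

Apparent blood volume is reported as the extensive sum
$ABV = v_{voxel}\sum_i F_i / 100$ (mL/min): monotone in both placental
size and perfusion, which is the reading consistent with growth-driven
increases. The literal "normalised histogram integral" form
$(1/N)\int h\,dn$ is dimensionally degenerate — it evaluates to $1/N$
regardless of perfusion — and is emitted alongside only for comparison.

## Motion and its spectrum

`horn_schunck()` implements the classical global variational optical flow:
2×2×2 forward-difference gradient stencils and iterative updates from the
neighbourhood-averaged flow, $u = \bar u - I_x(I_x\bar u + I_y\bar v +
I_t)/(\alpha + I_x^2 + I_y^2)$, with `alpha` the squared smoothness weight
set to 10². Iteration stops at 100 sweeps or a mean update below 1e-4.
Flow is computed per slice in 2-D on the temporally denoised series — the
acquisition is strongly anisotropic and the programmed motion is in-plane.

Spectral summaries use three tools. `welch_psd()` averages mean-removed,
Hamming-windowed modified periodograms (default segment `floor(n/4)`
forced odd, 50% overlap); with a single full-length segment it degenerates
to the raw modified periodogram, and Parseval's identity holds to within
window bias. `spectrogram_stft()` wraps `signal::specgram` with the
15-sample Bartlett window, 50% overlap and a zero-padded FFT of ten times
the trace length. `subband_relative_power_map()` computes, per voxel, the
fraction of periodogram power inside 8–12 mHz. Voxel time courses are
mean-removed before transforming so that the DC term does not absorb the
"total power" denominator; the sub-band map is computed on the
*unfiltered* series because the temporal median/closing — tuned to remove
impulsive artifacts — also attenuates a genuine 10 mHz oscillation
(period ≈ 5.6 frames at 18 s sampling) roughly threefold. At the 55.6 mHz
sampling rate nothing above the 27.8 mHz Nyquist limit is reported.

`classify_phasic()` flags a placenta when the **maximum** voxel relative
sub-band power within either chamber exceeds 0.2. The maximum, not the
chamber mean, is the detector: sub-voxel displacement modulates intensity
in proportion to the local spatial gradient, so a moving chamber shows a
population of strongly modulated voxels near steep gradients while the
contrast-uptake ramp keeps every chamber-mean relative power low. On
phantom data this statistic separates movers (≈ 0.7) from static
placentas (≈ 0.01) by nearly two orders of magnitude.

# The digital phantom

`phantom_spec()` / `synthesize_dce()` emulate the acquisition end to end:
a litter of ellipsoidal placentas laid out in grid cells (one spare cell
holds a spherical renal-hilum surrogate), each split by a plane
perpendicular to its long axis into low/high chambers at the stereology
volume fractions; a gamma-variate bolus
$C_A(t) = p\,[(t-t_0)/ab]^a e^{a-(t-t_0)/b}$ injected between frames 4
and 5, peaking ~80 s later and washing out well before 350 s; no-washout
tissue uptake $C_T = (F/V_T)\int C_A$; linear relaxivity
$R_1(t) = R_{1,0} + r_1 C(t)$; Ernst-equation signal synthesis at the DCE
and VFA protocols; sinusoidal sub-voxel in-plane translation of the
high-perfusion chamber (linear interpolation, default 0.5 voxel at
10 mHz) applied to `round(prevalence × K)` placentas — prevalence 0.111
at E14.5 and 0.821 at E17.5; Gaussian noise added last (Rician optional).
Default chamber perfusion is (30, 55) mL/min/100 mL at E14.5 and
(45.6, 79.97) at E17.5, so the mid-to-late gestation increases are 15.6
and 24.97 mL/min/100 mL.

Choices worth stating explicitly:

* **Units are arbitrary-consistent.** No absolute AIF amplitude or tissue
  concentration scale is modelled; everything downstream is a ratio, and
  acceptance is on recovery of programmed values, not absolute signal.
* **Relaxivity 0.75 Hz per concentration unit** keeps the
  signal–concentration map in its near-linear regime (the steepest-slope
  surrogate assumption) while keeping enhancement well above the noise
  floor; pushing it higher makes the Ernst nonlinearity bias the AIF
  normaliser, pushing it lower amplifies the noise-driven upward bias of
  a max-of-differences statistic.
* **Proton density** carries a smooth slice-direction gradient (±25%)
  plus a sinusoidal texture (wavelength 6 voxels, amplitude 0.3)
  emulating labyrinth vascular texture. The gradient is deliberately
  orthogonal to the chamber divide: the signal-domain slope scales with
  local $M_0$, so a gradient along the chamber axis would bias
  chamber-mean perfusion by construction. The texture is what makes
  sub-voxel motion visible in voxel intensities, as real anatomy is.
* **Geometry at anatomical scale.** The default grid (128×128×10 at
  0.156×0.156×0.85 mm) makes placentas 25–40 voxels across. At coarser
  grids the 3×3×3 median erodes the chamber boundary shell — a
  substantial fraction of all voxels — and chamber means drop by well
  over 10%; that is a property of median filtering at organ sizes far
  below anatomy, not of the estimator.
* **What the phantom does not emulate:** retrospective self-gating
  reconstruction, k-space or coil effects, maternal organs beyond the
  hilum surrogate, placental growth between ages (chamber fractions and
  perfusion change with age; geometry does not), through-plane or
  non-rigid motion, and real labyrinth microstructure. Passing tests
  therefore demonstrate internal consistency of the estimators under the
  stated forward model, not performance on in vivo data.

# Numerical and degenerate-input policy

Invalid fits are flagged, never zeroed; an empty chamber mask, an
enhancement-free AIF ROI, a non-monotone time grid, an even filter
window, or a mismatched grid each raise an informative error. Negative
steepest slopes are clamped to zero in maps (outside the model's
regime) while negative $\Delta R_1$ is preserved in statistics. Zero
total spectral power defines relative power 0. EM ties, quantile ties and
label ordering are all resolved deterministically, and every stochastic
element flows from one root seed, so a pipeline run is bit-reproducible.

# Problem sizes

The packaged tests exercise unit behaviour on small synthetic arrays and
48×48×8 phantoms with four placentas, and the end-to-end recovery checks
on the default 128×128×10 grid with eight placentas and fifty frames —
sizes chosen so the whole suite completes in about a minute while still
operating at the geometry the estimators assume. A full two-age pipeline
at default size, all stages included, runs in well under a minute per
session on one CPU.

# Known limitations

Perfusion estimates inherit the steepest-slope model's assumptions: no
venous washout during wash-in, and signal linear in concentration.
Strong phasic motion inflates high-chamber steepest slopes (contrast
moving through voxel boundaries mimics uptake) — visible in the phantom
as a high-chamber overestimate at E17.5 with motion enabled, and a known
caveat of the method on real data. VFA fitting assumes a homogeneous
flip angle (no B1 correction). The chamber threshold is a volume prior,
not a segmentation: it will split even a perfusion-homogeneous placenta.
The EM fit fixes two components by design and can return a
non-convergence flag on pathological inputs rather than a forced answer.
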