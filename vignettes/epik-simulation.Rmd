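---
title: "Keyhole EPI at desk scale: sampling schedules, point spread functions and a BOLD phantom benchmark"
author: "epiksim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keyhole EPI at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiksim)
```

## The two acquisition schemes

Single-shot echo planar imaging (EPI) traverses all phase-encode lines of
k-space after one excitation. The long echo train gives T2* decay time to
modulate the k-space data line by line, which blurs the point spread
function (PSF) along the phase-encode axis, and gives off-resonance phase
errors time to accumulate, which distorts the image.

EPI with keyhole (EPIK) is a hybrid: a central band of k-space (the
*keyhole*, here one fourth of the lines) is fully sampled at the Nyquist
density on every excitation, while the periphery is sampled at one line in
`nInterleaves` (here 3), with the interleave offset cycling from shot to
shot. A sliding-window reconstruction completes each scan's k-space with
the most recent peripheral interleaves and discards the oldest, so a full
image is produced every TR, exactly as for single-shot EPI, while each shot
only acquires half the lines.

The package models one 2-D slice and only the phase-encode axis of the
acquisition: the readout axis is treated as instantaneously sampled, which
is the standard idealization for 1-D PSF analysis of EPI trains. Parallel
imaging, partial Fourier, multiband, motion and physiological noise are out
of scope.

### Shipped presets

Both presets share FOV 200 mm, TR/TE 2200/30 ms and grey-matter T2* = 66 ms
(the accepted 3 T value):

* `epi64` — 64 phase-encode lines, actual echo spacing 0.510 ms;
* `epik96` — 96 lines, keyhole of 24 lines (indices 36–59, DC inside),
  3 peripheral interleaves, actual echo spacing 0.890 ms.

Because an EPIK shot acquires 48 of 96 lines, the *effective* spacing per
reconstructed line is `0.890 * 48 / 96 = 0.445` ms. The sampling window
`TE ± (N/2) * effective spacing` is (13.68, 46.32) ms for `epi64` and
(8.64, 51.36) ms for `epik96`: EPIK covers a 10.08 ms wider window, which
matters for the susceptibility analysis below, while refreshing the
periphery at `1/(TR * 3) ≈ 0.15` Hz, comfortably above block-design
haemodynamic rates (~0.03 Hz).

## Timing models and echo-time shifting

Two per-line acquisition-time models are implemented
(`effectiveLineTimes()`):

* `uniform_effective` — every line at the effective spacing (0.445 ms).
  This is the model behind the sampling-window arithmetic.
* `physical_piecewise` — keyhole lines at the actual spacing (0.890 ms),
  peripheral lines at `0.890/3` ms, anchored so the central line sits at
  TE. Both models span the same total readout duration
  (`48 × 0.890 = 96 × 0.445 = 42.72` ms); they differ in how that duration
  is distributed across k-space.

The per-shot schedules (`epikSchedule()`) realize the piecewise map
physically: acquisition order is bottom periphery, keyhole, top periphery,
monotone in k_y. Echo-time shifting (ETS) is applied as an offset of
`offset * spacing / nInterleaves` on the peripheral entries of each shot,
which makes the peripheral acquisition times of the three interleaves knit
into a single smoothly increasing map. We deliberately leave the keyhole at
its nominal timing in every shot rather than shifting the whole echo train:
this keeps the reconstruction-relevant time (and hence the decay weight) of
every k-space line independent of which window scan sourced it, so the
sliding-window reconstruction of a stationary object is bit-for-bit
consistent from frame to frame — a property the test suite asserts at
1e-10. Alternative ETS conventions would only enter through this module;
the PSF machinery consumes the resulting time map.

The default timing model for PSF work is `physical_piecewise`. The choice
was calibrated once against the FWHM characterization of this protocol
(below) and then frozen: the uniform model yields a visibly narrower EPIK
PSF (0.0116 of FOV instead of 0.0120) because it under-weights the decay
across the keyhole.

## The PSF and how its width is measured

For a stationary object the k-space weight of line *j* is
`w_j = exp(-t_j / T2*)`. The PSF is the magnitude of the zero-padded DFT of
the weight profile (`computePsf()`), evaluated on `matrixPE × 64` points
across one FOV and peak-normalized.

Two conventions govern the FWHM (`fwhm()`):

* `convention` — magnitude (default) or squared-magnitude (intensity)
  profile;
* `grid` — `"pixel"` (default): the profile is read at reconstruction
  pixel centres only, with linear interpolation at the half-maximum
  crossings; or `"fine"`: the full oversampled profile is used.

The pixel grid is the shipped default because it answers the operative
question — how wide the point response is *on the image grid the scanner
reconstructs*. On that grid a uniform (decay-free) weight profile gives
exactly one pixel of width, since the Dirichlet kernel has zeros at all
other pixel centres; T2* decay leaks signal into the neighbouring pixels
and widens the response beyond one pixel. This convention, combined with
the piecewise timing model, reproduces the protocol's published-width pair
for this parameter set:

```{r psf}
fwhm(computePsf(decayTrajectory(effectiveLineTimes(seqPreset("epi64"),
                                                   "physical_piecewise"))))
fwhm(computePsf(decayTrajectory(effectiveLineTimes(seqPreset("epik96"),
                                                   "physical_piecewise"))))
```

i.e. 0.0170 of the FOV (3.39 mm) for EPI versus 0.0120 (2.40 mm) for EPIK,
a 41% sharpening. The `"fine"` grid remains available and is what the
Dirichlet-kernel closed-form oracle checks in the tests (magnitude FWHM
`1.2067/N`, intensity `0.886/N`).

## The dynamic (BOLD) case and the view-sharing ghost

During signal change, the shared peripheral interleaves of an EPIK frame
carry different object amplitudes. The worst case modelled here is a 5%
amplitude ramp across the three window scans — a typical BOLD increase at
3 T compressed into three TRs. `decayTrajectory()` assigns
`scanAmplitudes = c(1, 1.025, 1.05)` to the interleaves (oldest first); the
frame is referenced to the window's baseline scan, so the keyhole carries
amplitude 1 while the periphery fluctuates around it (`keyholeScan`
overrides this convention if needed).

The period-3 peripheral modulation produces a symmetric pair of ghost
peaks at ±FOV/3. On the pixel grid they are isolated cleanly (the
stationary background samples to near zero away from the main lobe):

```{r ghost}
psfMetrics(seqPreset("epik96"), "dynamic", ramp = 0.05)$metrics
```

The ghost magnitude is ~0.0068 of the main peak and the FWHM grows by
~0.15% — both negligible for imaging purposes, which is the quantitative
argument for why view sharing does not visibly degrade EPIK images under
BOLD-scale dynamics. Ghost identification ranks side peaks by their excess
over the stationary profile, so ordinary decay-ringing sidelobes (present
in both) are not mistaken for ghosts.

## Susceptibility: effective echo time

A local susceptibility gradient `G_SP` shifts the gradient echo within the
sampling window. The model (`susceptibilityModel()`, `effectiveTE()`) is

    Q  = 1 - gamma * dt / (2*pi) * FOV * G_SP
    TE' = TE / Q

with gamma the proton gyromagnetic ratio (2.675e8 rad/s/T; all quantities
converted to SI internally, `G_SP` given in mT/m). Positive `G_SP`
lengthens TE' and attenuates the signal by `exp(-(TE'-TE)/T2*)`
(`applySusceptibility()`); `Q <= 0` marks the void regime where the echo
is pushed out of the window entirely and the pixel is zeroed. Because TE'
increases with the echo spacing `dt`, EPIK (effective 0.445 ms) always
retains at least as much signal as EPI (0.510 ms) wherever `G_SP > 0` — a
pixelwise ordering the test suite verifies. Geometric distortion (the
other consequence of field gradients) is intentionally not modelled; only
the dropout mechanism is.

## The synthetic phantom and what it does (not) emulate

`phantomSpec()` describes a layered-ellipse object with disc ROIs, a block
paradigm (default: 20 s fixation, then 7 cycles of 32 s task / 32 s rest —
468 s, fitting 225 scans at TR 2.2 s with the first two dropped as
dummies), complex Gaussian k-space noise, and an optional `G_SP` map. ROI
time courses are the boxcar convolved with a canonical double-gamma HRF
(response peak 6 s, undershoot 16 s, ratio 6 — published canonical
constants), plateau-normalized so a sustained block reaches
`1 + amplitude`; the default amplitude is 0.05. Block boundaries are
evaluated in continuous time; frames sample the course at their scan
times, so no explicit TR snapping is applied.

Noise is drawn once per acquired k-space line (circularly symmetric,
`noiseSD/sqrt(2)` per quadrature component). This matters: peripheral
noise shared by the sliding window is *genuinely shared* across the frames
that reuse it, which is the mechanism behind EPIK's mildly elevated
low-lag residual autocorrelation and its keyhole-dominated tSNR behaviour.

The generator emulates the statistical structure of a block-design run —
amplitudes, timing, noise sharing, dropout — but not anatomy, motion,
physiological noise spectra, slice geometry or scanner non-idealities.
Passing tests therefore demonstrate the correctness of the sampling,
reconstruction and analysis machinery under those idealized conditions,
not in-vivo effect sizes; the in-vivo BOLD amplitudes this protocol
reports are outside what a synthetic phantom can reproduce and are not
claimed.

## Functional metrics

`tsnr()` is the temporal mean over temporal standard deviation per pixel
(infinite values flagged and excluded from summaries). `glmActivation()`
fits ordinary least squares per pixel with regressors: plateau-normalized
HRF response, its temporal derivative, a constant and a linear drift; the
task beta over the constant beta is the fractional signal change, and
ROI-level t statistics are computed on ROI-mean series.
`residualAutocorrelation()` reports lag-1..5 coefficients of ROI-mean
residuals against a `±1.96/sqrt(n)` white-noise band. No spatial
smoothing, realignment or normalization is applied — nothing in the
phantom calls for them — and analysis stays at the single (first) level.

## Numerical choices

* Oversampling factor 64 with linear interpolation at half-maximum
  crossings: the fine-grid step (`1/(96*64)` FOV) is far below the 1e-4
  print resolution of the width metrics, and every pixel centre is an
  exact subset of the oversampled axis.
* k-space layout: DC at 0-based index `matrix/2` on both axes; `fft`-based
  round trips are exact to ~1e-15 and asserted at 1e-9.
* Keyhole placement for even matrices: lines `N/2 - nk/2` through
  `N/2 + nk/2 - 1`, so the DC line is inside the keyhole.
* Line indexing is 0-based with line 0 the most negative k_y; interleave
  offsets are `shot mod nInterleaves`.
* Bootstrap: the first `nInterleaves - 1` scans have no full window and
  are never reconstructed; `dropFirst` (default 2, mirroring dummy scans)
  subsumes them, so 225 acquired EPIK scans yield 223 frames.
* Degenerate cases are first-class: EPI is exactly the
  `keyholeFraction = 1, nInterleaves = 1` case of the EPIK machinery, and
  both code paths produce identical schedules and PSFs there.

## Problem sizes used by the test and acceptance runs

The simulation-based checks run at deliberately small desk scale, chosen
to make the statistical assertions sharp while the suite stays fast:
24×24 EPIK-like grids (keyhole 6 lines, 3 interleaves) with 60–80 scans
for recovery and autocorrelation checks, 16×16 EPI grids with 48 scans and
200 seeded replicates for the type-I calibration, and 50 seeds for the ±10%
amplitude-recovery band at k-space noise sd 0.3 (image SNR ≈ 90,
i.e. realistic tSNR territory). PSF numbers use the full 64/96-line
presets, which cost milliseconds.

## Known limitations

* 1-D PSF treatment: readout-axis effects (ramp sampling, chemical shift)
  are not modelled.
* Susceptibility acts as static per-pixel attenuation; no geometric
  warping or field-map unwarping.
* The GLM assumes white noise; no prewhitening is implemented, because the
  EPIK-induced autocorrelation the package measures stays well inside the
  white-noise band at the one-fourth keyhole.
* Magnitude images make noise Rician; at the SNR levels simulated the
  Gaussian approximation is excellent, but very low SNR settings would
  bias tSNR and betas.
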