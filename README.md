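# epiksim

Desk-scale simulation of **EPI with keyhole (EPIK)** k-space sampling and
sliding-window reconstruction, side by side with standard single-shot EPI,
for functional MRI method analysis.

Single-shot EPI acquires all phase-encode lines after one excitation; T2*
decay along the echo train blurs the point spread function (PSF) and local
susceptibility gradients push the echo out of the sampling window, causing
signal dropout. EPIK fully samples a central k-space *keyhole* every shot
and cycles sparse peripheral interleaves across shots, completing each
frame by sliding-window view sharing — halving the lines per shot (and the
effective echo spacing) while still producing one volume per TR.

The package provides, for both schemes:

* **Sampling schedules** (`epiSchedule`, `epikSchedule`) with echo-time
  shifting, keyhole bookkeeping and sliding-window source maps
  (`slidingWindowSources`), plus the timing arithmetic: effective echo
  spacing, sampling windows, peripheral update rate.
* **PSF analysis** (`decayTrajectory`, `computePsf`, `fwhm`, `sidePeaks`,
  `dynamicFwhmChange`): T2*-decay-weighted PSFs, FWHM in FOV-normalized
  and mm units, and view-sharing ghost metrics for dynamic (BOLD-like)
  signal changes.
* **Susceptibility model** (`susceptibilityModel`, `effectiveTE`,
  `applySusceptibility`): the effective echo time
  `TE' = TE / Q`, `Q = 1 - γ·Δt/(2π)·FOV·G_SP`, and the resulting
  per-pixel dropout.
* **Synthetic BOLD phantom** (`phantomSpec`, `makePhantom`,
  `boldTimecourse`): block-design paradigm convolved with a canonical
  double-gamma HRF, complex k-space noise, optional susceptibility map.
* **Forward synthesis and reconstruction** (`synthesizeShot`,
  `assembleKspace`, `reconImage`, `reconSeries`, `simulateSeries`): per-line
  k-space synthesis from a time-varying object, direct (EPI) and
  sliding-window (EPIK) reconstruction.
* **Functional metrics** (`tsnr`, `glmActivation`,
  `residualAutocorrelation`, `compareSchemes`): temporal SNR, GLM percent
  signal change and t statistics, residual autocorrelation.
* **Command entry points** (`cmdPsf`, `cmdSimulate`, `cmdReport`; shell
  wrapper in `inst/exec/epiksim`) writing CSV, PNG and NIfTI outputs.

## Worked example

The shipped presets are the standard 200 mm FOV, TR/TE 2200/30 ms protocol:
`epi64` (64 lines, 0.510 ms echo spacing) and `epik96` (96 lines,
one-fourth keyhole, 3 interleaves, 0.890 ms actual / 0.445 ms effective
spacing), both at grey-matter T2* = 66 ms.

```r
library(epiksim)

samplingWindow(seqPreset("epi64"))
#>  tMinMS  tMaxMS widthMS
#>   13.68   46.32   32.64
samplingWindow(seqPreset("epik96"))
#>  tMinMS  tMaxMS widthMS
#>    8.64   51.36   42.72

# stationary PSF width on the reconstruction pixel grid
fwhm(computePsf(decayTrajectory(effectiveLineTimes(seqPreset("epi64"),
                                                   "physical_piecewise"))))
#>       norm         mm
#> 0.01695602 3.39120333
fwhm(computePsf(decayTrajectory(effectiveLineTimes(seqPreset("epik96"),
                                                   "physical_piecewise"))))
#>       norm         mm
#> 0.01200343 2.40068684

# dynamic 5% case: view-sharing ghost and FWHM change
psfMetrics(seqPreset("epik96"), "dynamic", ramp = 0.05)$metrics[
  , c("ghost_pos", "ghost_mag", "fwhm_change_pct")]
#>   ghost_pos   ghost_mag fwhm_change_pct
#> 1 0.3333333 0.006833732       0.1481806
```

Reading: the EPIK point response is 2.40 mm wide against 3.40 mm for EPI
(a 41% sharpening) despite EPIK's wider sampling window, because each shot
carries half the echo train. Under a worst-case 5% amplitude ramp across
one sliding window, view sharing adds only a pair of ghosts at ±FOV/3 of
relative magnitude 0.0068 and broadens the PSF by 0.15% — both negligible.

The same pipeline end to end from the shell:

```sh
inst/exec/epiksim psf --preset epik96 --mode dynamic --ramp 0.05 --out out/
inst/exec/epiksim simulate --schemes epi64,epik96 --nscans 225 --seed 1 --out out/
inst/exec/epiksim report --out out/
```

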