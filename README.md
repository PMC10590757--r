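# vacuoscope

Quantification of cell-cycle-linked vacuolar pH oscillations in single
budding-yeast cells, from timelapse fluorescence microscopy (or per-cell
trace tables) to population statistics.

## The problem

The yeast vacuole — the cell's lysosome-like, acidic amino-acid store —
does not hold a constant pH while cells grow. Once per cell cycle the
organelle transiently alkalinizes: from an acidic baseline near pH 5.82
it rises to about pH 6.20 (a ΔpH of ~0.38 units), peaking roughly an
hour after bud emergence and a few minutes before mother–daughter
separation, then re-acidifies. Measuring this rhythm quantitatively
requires a chain of steps, each of which `vacuoscope` implements and
tests:

* **Imaging** (`subtractBackground`, `registerStack`, `detectVacuoles`,
  `linkTracks`, `extractTraces`, or the `trackStacks` wrapper):
  rolling-ball background subtraction (disc radius 50 px), translational
  phase-correlation registration, Laplacian-of-Gaussian blob detection
  (diameter 27 px, quality threshold 0.3) with sub-pixel localization,
  motion-predictive linear-assignment tracking (gates 25/20 px), and
  disk-aperture photometry.
* **Oscillometry** (`selectTraces`, `detrendTrace`, `periodogram`,
  `dominantComponent`, `quantifyCohort`, `cohortSummary`,
  `dunnHolmCompare`): traces with ≥ 500 min of data are OLS-detrended;
  the periodogram `P(k) = |Σ x_t e^(−2πikt/n)|²/n` yields each cell's
  dominant oscillation amplitude and period; cohorts are summarized by
  medians with bootstrap CIs and compared with Dunn's rank test under
  Holm adjustment.
* **pH dynamics** (`fitCalibration`, `ratioToPh`, `detectPeaks`,
  `cycleMetrics`, `peakHalfwidthSummary`, `alignFirstPeak`,
  `eventIntervals`): a linear standard curve fitted to an in-situ
  buffer ladder (pH 5.0–7.5 in 0.5 steps) converts ratiometric traces
  to absolute pH; prominence-based peak calling yields per-cycle peak,
  minimum and ΔpH, half-maximal pulse widths, and peak timing relative
  to annotated bud-emergence/separation events.
* **Size control** (`ellipsoidVolume`, `relativeG1Growth`,
  `fitSizeControl`, `compareSlopes`): relative G1 growth
  `ln(V_bud / V_birth)` regressed on `ln(V_birth)`; a slope of −1 is the
  signature of a sizer (fixed volume at Start), 0 the absence of size
  control, and cohort slopes are compared with the extra-sum-of-squares
  F-test.
* **Synthetic data** (`simulatePhTrace`, `simulateCohort`,
  `renderImageStack`, `simulateCalibrationSeries`,
  `simulateSizeCohort`): a fully ground-truthed generator — Gaussian
  alkalinization pulses, Henderson–Hasselbalch fluorophore responses, a
  ratiometric dye model, rendered image stacks with camera noise, and
  sizer/linear size cohorts — so every pipeline stage is verifiable
  end to end without microscope data.

## Worked example

```r
library(vacuoscope)

## calibrate: in-situ buffer ladder -> linear standard curve
cal <- fitCalibration(simulateCalibrationSeries(seed = 2))
cal
#> CalibrationFit: pH = -3.543 + 8.768 * ratio  (valid pH 5.00-7.50, resid sd 0.0257, n = 6)

## a default SDC-condition cohort carrying the ratiometric dye channel
coh <- simulateCohort(nCells = 15, seed = 3, channels = ratioChannels())
cycles <- NULL; pks <- list()
for (tr in traces(coh)) {
  ph <- as.numeric(ratioToPh(cal, channelValues(tr, "ratio")))
  pk <- detectPeaks(ph, traceTimes(tr))
  pks[[cellId(tr)]] <- pk
  cycles <- rbind(cycles, cycleMetrics(ph, pk, traceTimes(tr)))
}
sprintf("cycles: %d | min pH %.3f | peak pH %.3f | delta pH %.3f | FWHM %.1f min",
        nrow(cycles), mean(cycles$min_ph), mean(cycles$peak_ph),
        mean(cycles$delta_ph), peakHalfwidthSummary(pks))
#> "cycles: 172 | min pH 5.805 | peak pH 6.191 | delta pH 0.386 | FWHM 11.3 min"

## peak timing against annotated cell-cycle events
eventIntervals(traces(coh),
               pks[vapply(traces(coh), cellId, character(1))])$summary
#>      interval  mean    sd    sem   n
#> 1 bud_to_peak 59.42 0.611 0.0476 165
#> 2 peak_to_sep  5.68 0.611 0.0476 165

## sizer regression: fixed Start volume -> slope -1
fitSizeControl(simulateSizeCohort(n = 200, noiseSd = 0.05, seed = 1))
#> SizeControlFit: slope -1.004 (se 0.013, p 1.57e-150), intercept 4.109, r^2 0.968, n = 200
```

The recovered per-cycle minimum (5.805), peak (6.191) and ΔpH (0.386)
match the generating program (5.82 / 6.20 / 0.38) to within the
estimator's expected bias; the median half-maximal width recovers the
11-min pulse; intervals recover the 59.4 / 5.7-min event offsets; and
the sizer cohort recovers slope −1.

A command-line front-end wraps the same functions:

```sh
exec/vacuoscope run --config config.yaml --seed 1 --out-dir out/
```

with subcommands `simulate`, `track`, `quantify`, `ph`, `size-control`
and `run`; all stage outputs are plain CSV plus a JSON run report, and
every run is byte-reproducible from config + seed.

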