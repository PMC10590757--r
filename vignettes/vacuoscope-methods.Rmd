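---
title: "Quantifying cell-cycle-linked vacuolar pH oscillations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-cycle-linked vacuolar pH oscillations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vacuoscope)
```

## The biological signal and what the package measures

The budding-yeast vacuole is an acidic, lysosome-like organelle and the
cell's main amino-acid store. In growing cells its lumenal pH is not
static: once per cell cycle the vacuole transiently alkalinizes, rising
from an acidic baseline near pH 5.8 to a peak near pH 6.2 shortly before
mother-daughter separation, then re-acidifying. `vacuoscope` implements
the complete measurement chain for this phenomenon:

1. **imaging** — timelapse stacks to per-cell intensity traces
   (background subtraction, registration, blob detection, tracking,
   aperture photometry);
2. **oscillometry** — per-cell periodograms of detrended traces, the
   dominant oscillation amplitude and period, and rank-based cohort
   comparisons;
3. **pH dynamics** — ratiometric calibration to absolute pH, per-cycle
   peak/minimum/amplitude metrics, pulse widths, and peak timing against
   cell-cycle events;
4. **size control** — the regression of relative G1 growth on log birth
   volume whose slope distinguishes a sizer (slope $-1$) from the absence
   of size control (slope $0$);
5. **synthetic data** — a ground-truthed generator of all of the above,
   so every stage is verifiable without microscope data.

## The synthetic generator defines the study conditions

`oscillationProfile()` describes one cell's pH program as Gaussian
alkalinization pulses riding on an acidic baseline:

$$\mathrm{pH}(t) = \mathrm{pH}_{base} + r\,t +
  A \sum_k \exp\!\left(-\frac{(t - t_k)^2}{2\sigma^2}\right)
  + \varepsilon_t,$$

with $A = (\mathrm{pH}_{peak} - \mathrm{pH}_{base}) \cdot m$ for a
cohort-level contrast multiplier $m$, $\sigma =
\mathrm{FWHM}/(2\sqrt{2\ln 2})$, and i.i.d. Gaussian noise
$\varepsilon_t$. A Gaussian pulse parameterized by its full width at
half maximum was chosen because the half-maximal width is the summary
statistic the downstream analysis reports; no claim is made about the
true biochemical pulse shape. Defaults are the wild-type
glucose-plus-amino-acids (SDC) condition:

| parameter | default | unit | meaning |
|---|---|---|---|
| `phBase` | 5.82 | pH | acidic inter-pulse baseline |
| `phPeak` | 6.20 | pH | pulse maximum (so $\Delta$pH = 0.38) |
| `period` | 85 | min | cell-cycle period (median ~85 min) |
| `pulseFwhm` | 11 | min | half-maximal pulse width in SDC |
| `budToPeak` | 59.4 | min | bud emergence to pulse maximum |
| `peakToSep` | 5.7 | min | pulse maximum to cell separation |
| `noiseSd` | 0.005 | pH | per-sample measurement noise |
| `driftRate` | 0 | pH/min | optional slow baseline drift |

Cohorts (`simulateCohort()`) sample 500 points per cell at `dt = 2` min
over 1000 min — the standard acquisition design — with an independent
uniform pulse phase per cell. Media presets: `YNBD` (no amino acids)
replaces the regular pulse train with a Poisson process of brief 2-min
pulses; `SCEG` (respiratory carbon) keeps the SDC program but carries an
amplitude multiplier of $\sqrt{1.8}$, so that spectral power — which
scales with the squared pulse height — shows the 1.8-fold
population-level contrast between the two media.

Two generator constants deserve comment because they are *choices*, not
measurements:

* **Trace noise (0.005 pH per sample).** This models the residual error
  of a disk-averaged, ratiometric measurement, which is far below raw
  pixel noise. The choice is constrained by an extreme-value argument:
  the per-cycle minimum is the minimum over roughly 28 baseline samples,
  and $E[\min]$ of $n$ Gaussians is about $-2.0\,\mathrm{sd}$ at
  $n = 28$. A noise sd of 0.005 keeps that extremum bias near 0.01 pH,
  consistent with the 0.02-pH accuracy the per-cycle metrics are
  expected to achieve; substantially larger per-sample noise would make
  the *estimator itself* (a windowed minimum) biased beyond that band
  regardless of how much data are collected.
* **Dye steepness (`ratioModel()` Hill 0.1, apparent pKa 6.98).** The
  ratiometric dye channel is a saturating sigmoid centered at the dye's
  apparent pKa, but with a shallow effective steepness so that the ratio
  is near-linear across the pH 5.0–7.5 calibration ladder. This mirrors
  practice — dual-excitation ratio standard curves are routinely fitted
  linearly in this window — and it is required for internal consistency:
  the default calibration fit *is* linear, and a steep (Hill ≈ 1)
  sigmoid would leave 0.2–0.3 pH lack-of-fit residuals that no amount of
  data could remove. With Hill 0.1 the linear standard curve reproduces
  truth to better than 0.01 pH across the vacuolar operating range.

The fluorophore reporter (`fluorophoreModel()`) uses the
Henderson–Hasselbalch form $I = I_{max}/(1 + 10^{h(pK_a - \mathrm{pH})})$
with defaults pKa 6.1, $h = 1$: the published titration curve of the
low-pKa reporter is shown only graphically, and these values place the
5.8–6.2 operating range on the steep flank of the curve, which is the
design goal of such a reporter. The pH-insensitive reference channel is
constant.

What the generator does **not** emulate: photobleaching, vacuole
fission/fusion morphology, mother/daughter lineage, focus drift, and
non-Gaussian camera artifacts. Passing the recovery tests therefore
demonstrates that the *analysis chain* is correct and unbiased under the
stated noise model — not that it is robust to every pathology of real
microscopy data.

## Imaging chain

* **Background**: per-frame grayscale opening with a disc of radius 50
  px (the disc-approximated rolling ball), subtracted and clipped at
  zero. EBImage performs the morphology; inputs are rescaled to its
  expected $[0,1]$ range and back.
* **Registration**: translation-only phase correlation against frame 0,
  integer-pixel shifts. Rotation/scaling are not modeled; stage drift is
  translational.
* **Detection**: scale-normalized Laplacian of Gaussian at $\sigma =
  d/(2\sqrt 2)$ for blob diameter $d = 27$ px, computed on the
  min–max-normalized frame so the quality threshold (0.3) is
  dimensionless. For an ideal matched disk of unit contrast the peak
  response is $2/e \approx 0.74$, which situates the threshold. Maxima
  are refined to sub-pixel precision with a 1-d parabola per axis.
* **Linking**: frame-to-frame linear assignment with constant-velocity
  prediction ($2p_t - p_{t-1}$), gates of 25 px (track initiation) and
  20 px (established tracks), solved exactly with an $O(n^3)$
  shortest-augmenting-path assignment solver. The no-match alternative
  costs the squared gate, so any in-gate pairing beats termination.
  Tracks end on their first miss: no gap closing, splitting or merging.
* **Photometry**: mean intensity in a disk at the track position, per
  channel. The measurement disk is shrunk one pixel below the detection
  radius so sub-pixel localization error cannot dilute the mean with
  background rim pixels; on rendered uniform disks this makes the
  round-trip exact to well under 1%.

## Spectral pipeline

Traces with at least 500 min of data are detrended by OLS on time
(intercept + trend only — seasonal terms would absorb the oscillation
itself) and transformed to the periodogram

$$P(k) = \frac{1}{n}\left|\sum_t x_t e^{-2\pi i k t/n}\right|^2,
  \qquad k = 1..\lfloor n/2\rfloor .$$

This scaling gives a sinusoid of amplitude $A$ power $A^2 n/4$ and makes
the Parseval identity exact, at the cost that amplitudes are comparable
only within a fixed $(n, dt)$ design — which is how they are used. The
dominant component is the spectral maximum; ties break toward the
smallest $k$ (the longest, biologically more plausible period). Periods
are reported on the Fourier grid $n\,dt/k$, so an off-grid cell-cycle
period of 85 min is reported as its nearest grid point (83.3 min for
$n = 500$, $dt = 2$).

Cohort medians carry 95% percentile bootstrap intervals (2000 seeded
resamples) — the upstream CI convention names no method, and the
bootstrap is assumption-free at these cohort sizes. Pairwise contrasts
use Dunn's rank test with tie correction and Holm step-down adjustment
(via `p.adjust`), the standard post-hoc chain after Kruskal–Wallis for
skewed amplitude distributions.

## Absolute pH and per-cycle metrics

The standard curve is fitted as pH linear in ratio over the buffer
ladder (5.0–7.5 in 0.5 steps), with validity range the span of the
buffers and a 0.25-pH extrapolation allowance; out-of-range samples are
flagged, and a wholly out-of-range trace is an error. Peaks are local
maxima with prominence at least 0.25 of the trace's 5th–95th percentile
range (robust to drift) and at least 20 min apart (well under the
shortest cell-cycle period, preventing double calls on noise); widths
are measured at half prominence with linear interpolation. Each cycle's
minimum is taken on the window from the previous peak (or trace start)
to the current peak — i.e. each minimum *precedes* its peak, matching
the acidic-then-alkaline reading of single-cell traces; the opposite
convention would differ only in cycle bookkeeping, not in means, for
periodic signals. Interval summaries report both sd and s.e.m.; the
"±" convention used for the headline timing numbers is s.e.m.

## Size control

Cell volumes follow the printed measurement convention $V = (4/3) L S^2$
from the long and short axes of a maximum-intensity projection. Note
that the geometric ellipsoid volume from full axis lengths would be
$(\pi/6) L S^2$; the package defaults to the formula as printed
(`usePi = FALSE`) because the constant cancels in $\ln$-space: every
slope, and the F-test, is identical in both modes. Relative G1 growth is
defined as $\ln(V_{bud}/V_{birth})$ — under exponential growth this is
proportional to G1 duration, and it is the unique scaling under which a
perfect sizer (fixed Start volume) gives exactly slope $-1$ against
$\ln V_{birth}$. Slopes between cohorts are compared with the
extra-sum-of-squares F-test (common slope + separate intercepts vs
separate slopes; $F(1, n_1+n_2-4)$), the test the standard curve-fitting
software performs for this comparison.

## Numerical and reproducibility choices

* Every generator is a pure function of (configuration, seed); the
  pipeline driver fans one global seed out deterministically per stage.
* Assignment problems use a large finite sentinel for gated-out pairs;
  a pair "matched" at the sentinel is reported unmatched.
* Degenerate inputs have defined behavior: constant frames detect
  nothing; all-zero spectra are flagged with amplitude 0 and undefined
  period; a response without variance has $r^2 = 0$; equal residual sums
  of squares give $F = 0$, $p = 1$.
* Frame indices are 0-based (time = frame · dt); pixel coordinates are
  1-based (x = column, y = row from top-left), R's native convention.

## Problem sizes

The shipped verification suite uses cohorts of 12–150 cells × 500
samples, rendered scenes up to 20 cells × 100 frames × 320² px, and 500
replicate null calibrations for the F-test — sizes chosen so the full
suite completes in well under a minute on a laptop while leaving every
estimate's Monte-Carlo error far below the tolerance it is tested
against.

## Known limitations

* The detector assumes bright, roughly circular vacuoles of a known
  scale; fragmented vacuoles (as in some trafficking mutants) violate
  the one-blob-per-cell assumption and are out of scope.
* Registration is integer-pixel and translational.
* The periodogram assumes uniform sampling; traces with interior gaps
  are truncated to their longest uniform run rather than interpolated.
* Absolute amplitudes are instrument- and design-specific; only
  within-design contrasts (ratios, ranks) are meaningful.
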