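---
title: "Quantifying CEST Z-spectra: model, pipeline and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying CEST Z-spectra: model, pipeline and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cestquant)
```

## The measurement and the model

Chemical exchange saturation transfer (CEST) MRI saturates exchangeable
solute protons at their characteristic chemical shift and reads out the
resulting attenuation of the water signal. The measured object is the
Z-spectrum: the normalized water signal $S/S_0$ as a function of the
saturation offset $\Delta\omega$ (in ppm relative to water). Around each
resonance, continuous-wave saturation produces a dip that is well described
by a Lorentzian line, so the spectrum is decomposed as

$$
Z(\Delta\omega) \;=\; 1 \;-\; \sum_{i=1}^{5}
A_i\,\frac{(\Gamma_i/2)^2}{(\Gamma_i/2)^2 + (\Delta\omega - \delta_i)^2},
$$

with amplitude $A_i$ (dimensionless, on the normalized-signal scale),
center $\delta_i$ (ppm) and full width at half maximum $\Gamma_i$ (ppm)
per pool. The five pools and their centers are the standard 7T brain set:

| pool      | center (ppm) | origin                                  |
|-----------|-------------:|-----------------------------------------|
| water     | 0            | direct water saturation                  |
| MT        | -1           | semi-solid macromolecular magnetization transfer |
| creatine  | 2            | creatine guanidinium protons             |
| glutamate | 3            | glutamate amine protons                  |
| NOE       | -3.5         | relayed nuclear Overhauser effect (mobile proteins, membrane lipids) |

The per-pool *contrast* is the area under that pool's fitted Lorentzian.
The full-line integral has the closed form $A\,\pi\,\Gamma/2$ and is the
default (`auc_mode = "analytic"`): it is independent of the sampling window
and scale-consistent across pools of different linewidth. A windowed
trapezoidal mode (`"numeric"`, default window $[-5, 5]$ ppm) is also
provided, because either convention is found in practice; the mode is
recorded in every output. The in-window fraction of a Lorentzian's mass is
$\frac{1}{\pi}\left[\arctan\frac{2(b-\delta)}{\Gamma} +
\arctan\frac{2(\delta-a)}{\Gamma}\right]$, which the tests verify against
the quadrature.

## The frequency axis

The default acquisition axis spans $-5$ to $+5$ ppm with 0.2 ppm steps on
$[-5,-4]\cup[4,5]$ and 0.1 ppm steps on $[-4,4]$ — 91 unique offsets,
denser where the creatine, glutamate and NOE resonances sit. Any
contiguous segment scheme can be supplied via `offset_scheme()`.

## B0 correction with WASSR

Static-field inhomogeneity shifts each voxel's spectrum along the
frequency axis. A paired low-power, water-only acquisition (WASSR) has its
minimum at the voxel's B0 offset. `estimate_b0()` upsamples the WASSR
spectrum with a cubic spline (factor 200 by default, giving sub-millippm
grid resolution on a 0.05 ppm-step axis) and takes the argmin. A
symmetry-based center-frequency search would be a drop-in alternative; the
interpolant argmin was chosen because it is simpler, adequate at WASSR
SNR, and directly testable, and the function is the single place to swap
it.

Three failure modes are flagged rather than silently handled: a flat
spectrum (no minimum), a minimum on the axis boundary (water line outside
the sampled window), and an offset beyond the configured bound (1.0 ppm by
default — phantom fields stay within $\pm 0.5$ ppm, so exceeding the bound
signals a bad voxel, not something to clamp).

`correct_zspectrum()` re-references the measured spectrum by evaluating it
at `axis + b0` with a cubic spline and reporting it on the nominal axis.
Points that would require extrapolation beyond the measured range are
marked missing and excluded from fitting through the weight mask — the
correction never fabricates data, so the number of valid points can only
decrease. A voxel needing extrapolation for more than 20% of its points is
flagged invalid. Whether one should re-interpolate spectra or shift the
fitted center per voxel is not dictated by the data; spectrum
re-interpolation was chosen so that all voxels share one axis and the
water-center bound can stay tight.

## Fitting

`fit_zspectrum()` minimizes the unweighted (mask-weighted) sum of squared
residuals with bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) and an
analytic Jacobian. Key choices:

* **Centers fixed** for MT, creatine, glutamate and NOE; the water center
  floats within $\pm 0.2$ ppm to absorb residual B0 error. Freeing all
  centers makes five overlapping Lorentzians poorly conditioned at
  realistic SNR; fixing them is the common stabilizer for five-pool fits
  at 7T.
* **Bounds** encode standard priors: amplitudes $[0, 1)$; linewidths
  (ppm) water $[0.3, 4]$, creatine $[0.3, 3]$, glutamate $[0.3, 4]$,
  NOE $[0.5, 6]$, MT $[1, 20]$ (the semi-solid pool is broad). All are
  configurable per pool.
* **Deterministic initialization**: water amplitude from $1 - \min Z$,
  solute amplitudes 0.02, linewidths at the midpoints of their bounds.
  There are no random restarts, so a fit is a pure function of its inputs.
* **Tolerances**: `ftol = ptol = 1e-15`, at most 500 iterations. On
  noiseless model-generated spectra the fit recovers amplitudes to
  machine precision (RSS below 1e-30 in practice; the test bound is
  1e-10), which is the regression oracle for the optimizer setup.
* **Degenerate inputs**: spectra with fewer unmasked points than free
  parameters + 2, or with values outside $[-0.1, 1.2]$, are skipped with
  a recorded reason; non-converged fits keep their flag and parameters.
  Nothing is silently dropped.
* `check_identifiability()` verifies once per configuration that the
  Jacobian at the default initialization has full column rank on the
  chosen axis.

Fitting is voxelwise by default because contrast heatmaps require it; for
low-SNR use the same machinery applies to region-averaged spectra (fit the
mean spectrum of a labeled region and quantify it once).

Precision at the defaults: with additive noise $\sigma = 0.005$ on the
91-point axis, the asymptotic (Cramér–Rao) standard deviation of the
glutamate amplitude at $A = 0.05$ corresponds to a median relative error
of about 4%; the creatine pool ($A = 0.04$, narrow and flanked by
creatine–glutamate overlap) sits near 5%. Least squares is the Gaussian
maximum-likelihood estimator here, so these are floors set by the design,
not by the implementation.

## Group statistics

Region means of the contrast maps (masked voxels excluded; empty regions
reported missing) feed a tidy per-subject table. For every (region, pool),
`comparison_suite()` runs the study's scheme: an ordinary one-way ANOVA
across all arms, then three post-hoc two-tailed t-tests — baseline vs the
6-week arm (pooled variance), baseline vs the untreated 12-week arm
(Welch, since that arm is much smaller), treated vs untreated at 12 weeks
(pooled by default; the Welch variant is a flag, as the convention for
this comparison is ambiguous). P-values map to the tier labels
`****/***/**/*/#/ns` at 1e-4, 1e-3, 0.01, 0.05 and 0.1.

Arms are treated as independent groups even though the timepoints are
repeated measures on the same animals — this mirrors the stated analysis
being reproduced; a paired mode (`paired = TRUE`, pairing by within-arm
order) is available but off by default. No multiplicity correction is
applied across regions and pools by default, again mirroring the
reproduced scheme; `adjust = "holm"` applies a Holm correction within each
comparison family. Zero-variance groups yield explicit degenerate reports
rather than NaNs.

## The synthetic phantom

No imaging data ship with the package; the generator provides study-shaped
inputs with known ground truth.

* **Design**: four arms (baseline, week 6, untreated week 12, treated
  week 12) with 14/14/5/4 subjects — the unbalanced longitudinal design
  the Welch comparison exists for.
* **Geometry**: a 64×64 grid (configurable) with five square "regions"
  named after the quantified structures. Anatomical fidelity is explicitly
  not a goal; the labels are what the statistics consume.
* **Spectra**: per (arm, region), the five pool amplitudes of the truth
  table; baseline water 0.75, MT 0.06, creatine 0.04, glutamate 0.05, NOE
  0.06 with linewidths 1.4/3.0/1.0/1.2/2.5 ppm — typical of 7T mouse
  brain fits. Arm effects: at week 6 creatine −10% (cortex, hippocampus)
  and NOE +10% (cortex); untreated week 12 glutamate −20% (cortex,
  hippocampus, piriform cortex), creatine −15% (those plus thalamus), NOE
  +15% (cortex, thalamus); treated week 12 restores glutamate and creatine
  while the NOE elevation persists.
* **Variability**: subjects are i.i.d.; between-subject variation is
  multiplicative Gaussian jitter on the region amplitudes with 5% CV. The
  reproduced analysis reports no variance components, so this value is a
  field-typical choice made once.
* **B0**: a low-order 2-D polynomial bounded to ±0.5 ppm — smooth,
  realistic, and keeps the water line inside the densely sampled window.
  The WASSR stack shares the field.
* **Noise**: additive Gaussian on the normalized signal
  ($\sigma = 0.005$ default). Z-spectra are high-SNR magnitude ratios, so
  Rician magnitude bias is negligible and not modeled.
* **Determinism**: everything derives from `config$seed`; an identical
  configuration is bit-identical, which the end-to-end checksum test
  relies on.

What passing tests on the phantom do **not** show: robustness to partial
volume, motion, B1 inhomogeneity, Rician bias at low SNR, or anatomy-
dependent susceptibility fields — none of these are simulated.

## The Bloch–McConnell oracle

`bloch_mcconnell()` integrates the coupled magnetization equations for
exchanging pools under continuous-wave saturation (default 2 µT for 2 s at
7 T) and returns the water $M_z/M_0$ per offset. The linear system is
solved exactly with a matrix exponential per offset, so there is no ODE
tolerance to tune. It shares no code with the Lorentzian model and acts as
an independent physics generator: tests verify that spectra produced from
increasing solute fractions yield strictly increasing fitted amplitudes,
and that a zero-exchange system collapses to the water-only
direct-saturation spectrum. Readout dynamics and pulsed saturation are not
modeled — the oracle validates the quantification, it does not emulate a
scanner.

## Problem sizes and runtimes used in the tests

Unit and acceptance tests run phantoms at 12×12 voxels with 2–3 subjects
per arm (a single voxel fit takes a few milliseconds; a demo pipeline run
fits ~160 voxels), 200 repetitions for the noisy-recovery study, 100
seeded repetitions per offset for the B0 study, 1000 table-level
repetitions for type-I calibration and 30 spectrum-level seeds for the
power property. These sizes were chosen so the whole suite exercises every
stage in well under half an hour on one core while keeping Monte-Carlo
intervals tight enough to be meaningful; all of them are parameters, not
constants, and scale up trivially.

## Known limitations

* Amplitudes are relative contrasts, not absolute concentrations; no
  B1 calibration or exchange-rate modeling is attempted (and no
  Bloch–McConnell *fitting* — the physics model is a generator only).
* No MTR-asymmetry analysis; quantification is via Lorentzian AUC only.
* The MT pool is modeled as a Lorentzian at −1 ppm; super-Lorentzian
  lineshapes for the semi-solid pool are out of scope.
* Heatmap PNGs are raw rasters with an in-margin colorbar; window and
  palette metadata live in a JSON sidecar rather than rendered text.
* The statistics deliberately reproduce a fixed comparison scheme;
  longitudinal mixed-effects modeling is out of scope.
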