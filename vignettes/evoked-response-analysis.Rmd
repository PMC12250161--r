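---
title: "Event-locked ΔF/F₀ analysis: model, generator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-locked ΔF/F₀ analysis: model, generator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the normalization
and quantification model, what the synthetic generator emulates and why its
defaults are what they are, the numerical conventions, and the limits of
what passing tests demonstrate.

## The measurement and its analysis model

An implanted µ-CMOS sensor images a 40 × 90-pixel field at 10 frames/s in
arbitrary digital units. The biological signal of interest is the phasic
change of GCaMP6s population fluorescence in the ventral tegmental area
evoked by a 5-s von Frey filament contact on the hind paw. Three slow
nuisance processes ride on top of it: photobleaching, spontaneous
population-activity fluctuation, and — under morphine — a tonic elevation
of baseline dopaminergic activity.

The analysis chain is deliberately simple and fully deterministic:

1. **ROI reduction.** A 10 × 10-pixel region of interest is reduced to its
   per-frame unweighted mean. Hand selection is replaced by an exhaustive
   max-mean-intensity search (`auto_select_roi()`); an explicit
   `roi_spec()` reproduces hand selection. Whether ROI pixels are averaged
   or summed is immaterial because the subsequent normalization is
   scale-free — a property the test suite asserts rather than assumes.
2. **Event-locked epoching.** Each stimulation contributes a 250-frame
   epoch: 50 baseline frames followed by a 200-frame evaluation. The
   filament contact opens the *stimulation* window, i.e. the evaluation
   starts 5 s before contact and its four 50-frame windows are
   pre-stimulation, stimulation, early and late post-stimulation. The
   event time in the schedule is defined as the contact time; this is the
   only alignment under which the evoked depression falls inside the
   stimulation window, and it is exposed as `align_offset_s` (default −5 s)
   rather than hard-coded.
3. **Dynamic-baseline normalization.** For each epoch, F₀ is the mean of
   its 50 baseline frames and every evaluation frame is expressed as
   ΔF/F₀% = (F − F₀)/F₀ × 100. The mean (not the median) is the default
   reducer because it is linear, which makes the scale-invariance of the
   normalization exact rather than approximate; the reducer is a
   configurable argument.
4. **Windowed AUC.** Each 50-frame window is summarized by the signed
   trapezoidal integral of ΔF/F₀ against time. With 50 samples at 0.1 s
   spacing a window spans 4.9 s, so a constant −2 % window integrates to
   −9.8 %·s — a convention worth stating because "area under the curve"
   names no rule. A rectangle rule and a per-window mean are provided for
   sensitivity analyses; all three differ only by positive scalings for
   near-constant signals, so group-level conclusions do not depend on the
   choice.
5. **Aggregation and inference.** Stimulations are first averaged within
   animal; hypothesis tests operate on the per-animal means (n = 4 pairs in
   the reference design), while condition traces are reported as mean ± SE
   across stimulations. Every paired contrast is routed by a Shapiro–Wilk
   test on the paired differences: *t*-test if the differences look normal
   (p ≥ 0.05), Wilcoxon signed-rank otherwise. Tests are two-sided at
   α = 0.05, reported unadjusted with a Holm column alongside, with the
   normality p-value, route and statistic carried in every result row.

Two consequences of this design are worth making explicit. First, the
dynamic baseline makes every epoch's ΔF/F₀ exactly invariant under
multiplicative rescaling of the raw data, which is what renders
photobleaching and tonic drug effects nearly harmless: a mono-exponential
bleach with time constant τ leaks at most ≈ 10⁴/τ %·s into any window AUC
(the worst window sits ~20 s after the baseline's centre, and
490 × 20.4/τ ≈ 10⁴/τ), a bound the tests verify by sweeping τ. Second,
with n = 4 animals the signed-rank route can never reach p < 0.05 (the
smallest two-sided exact p is 0.125), so whenever the Shapiro–Wilk gate
misfires — which happens ~5 % of the time under normality — a true effect
cannot be declared significant. Any "significant in x % of runs" statement
at this sample size is therefore capped near 95 %; this is a property of
the inferential procedure itself, not of the implementation.

## What the generator emulates

`simulate_recording()` produces movies with the statistical structure the
analysis assumes:

- a static brightness field: uniform background with a Gaussian bright
  region (the GCaMP-expressing tissue) that the ROI search should find;
- mono-exponential photobleaching (`bleach_tau`);
- a shared slow Ornstein–Uhlenbeck background fluctuation (`ou_sd`,
  `ou_tau`) standing in for spontaneous population activity — the dominant
  trial-to-trial noise source at the ROI level, and the reason repeated
  stimulations are informative rather than redundant;
- per-event evoked responses: a saturating-exponential depression during
  the 5-s contact, normalized so the configured peak is reached exactly at
  contact offset, then exponential recovery plus a unit-peak-normalized
  difference-of-exponentials rebound (`response_kernel()`);
- multiplicative trial-to-trial amplitude jitter (`amp_jitter_cv`);
- i.i.d. per-pixel Gaussian read noise (`noise_sd`);
- under morphine, a slow additive tonic ramp (`morphine_tonic_slope`) that
  the dynamic baseline is expected to filter.

Events are scheduled at the minimum inter-stimulation gap of 30 s, which
guarantees the 25-s epochs never overlap. Everything is a pure function of
the parameters and the seed; `null_recording()` keeps all noise processes
but forces both evoked amplitudes to exactly zero, providing sham
stimulation times for type-I-error calibration.

### Default parameters and why

| parameter | default | units | rationale |
|---|---|---|---|
| `fps` | 10 | frames/s | acquisition rate of the sensor |
| `n_rows × n_cols` | 40 × 90 | px | sensor geometry (7.5 µm pitch is metadata only) |
| `baseline_mean`, `roi_brightness_gain` | 1000, 2 | DU, – | mid-range 16-bit intensities; expressing region twice as bright |
| `bleach_tau` | 14 400 | s | slow session-scale bleaching under intermittent µLED illumination |
| `noise_sd` | 10 | DU | ~1 % per-pixel read noise |
| `ou_sd`, `ou_tau` | 0.013, 2 | fraction, s | spontaneous population fluctuation; sets the per-epoch AUC noise floor (≈5 %·s SD for a stimulation-vs-pre contrast) |
| `depression_amp` | −1/−2/−4 % at 0.04/0.16/1.4 g | fraction | round force-graded peaks; absolute magnitudes are a modelling choice, not measured values |
| `rebound_amp` | +0.8/+0.5/+0.2 % | fraction | rebound excitation inversely related to force |
| `onset_tau`, `recovery_tau`, `rebound_tau` | 0.5, 1.5, 2 | s | fast drop, slower recovery, seconds-scale rebound |
| `amp_jitter_cv` | 0.2 | – | trial-to-trial response variability |
| PNL post-surgery gain | 2.0 | – | allodynia: doubled evoked depression |
| morphine gain | 0.02 | – | near-elimination of the evoked response |
| `morphine_tonic_slope` | 2 × 10⁻⁴ | fraction/s | slow tonic baseline elevation under morphine |

The effect-size and noise defaults were fixed together, once, by a power
analysis of the reference design (4 animals × 15 stimulations, per-animal
inference, Shapiro-routed paired tests): with the OU noise floor above, the
chronic-pain contrast (gain 2.0 on a −2 % response) has *t*-route power
≈ 0.999 while the residual morphine response (gain 0.02) keeps the
pre-vs-stim contrast non-significant in ≈ 94 % of runs — i.e. the defaults
are chosen so the generator reproduces, at realistic variability, the
qualitative significance layout it is meant to emulate: graded force
ordering, exacerbated and significant post-PNL depression with a null sham
counterpart, a significant response under saline, and its near-abolition
under morphine. They are modelling choices, not measurements; no published
trace amplitudes exist to calibrate against, and analyses of real
recordings should treat them as free parameters.

### What the generator does *not* model

No optical point-spread function, no motion or registration artifacts, no
shot-noise (variance-scaling) statistics, no cellular-resolution structure,
no pharmacokinetics — morphine is a static gain plus a linear tonic ramp.
Passing tests therefore demonstrate correctness of the *analysis* under
the stated noise model, and calibration/power under that model; they do not
certify performance on recordings whose artifacts (movement, occlusion,
z-drift) violate it.

## Numerical conventions and degenerate inputs

- Pixel coordinates are 0-based, row-major; an ROI is the half-open box
  [row0, row0+h) × [col0, col0+w). ROI ties are broken to the
  lexicographically smallest (row0, col0); box sums within 10⁻⁹ relative
  of the maximum compare as tied, so numerically identical regions cannot
  be split by floating-point noise in the integral image.
- Epoch indices: with contact at t s and 10 fps, an epoch occupies 0-based
  trace frames 10t−100 … 10t+149. Epochs reaching outside the recording
  are a hard error naming the events; epochs closer than the 25-s span are
  kept but flagged (droppable via `drop_overlap`), since the 30-s minimum
  gap makes overlap impossible in well-formed schedules.
- A non-positive F₀ (dead sensor region) is a hard error, not a NaN.
- Paired contrasts need ≥ 3 pairs; all-zero differences return a flagged
  degenerate result with p = 1; constant non-zero differences (Shapiro
  inapplicable) fall back to the signed-rank route with a note.
- Stacks are written as 16-bit multi-page TIFF, rounding to integer DU;
  the round-trip is bit-exact for integer data.

## Problem sizes used by the test and acceptance suites

The statistical suites run the full pipeline on reduced sensors
(10 × 10 or 12 × 16 px) with the 4-animal × 15-stimulation design intact —
the ROI-level statistics are identical because the analysis collapses to
one ROI trace regardless of sensor size. Type-I calibration uses 2000
null replicates with one stimulation per animal (per-animal pairs are then
single-epoch AUCs, which leaves the calibration of the routed test
unchanged); effect-recovery rates use ≥ 100 replicate study designs; the
demo design runs the complete two-cohort layout at 12 × 16 px. These sizes
are the package's choice of simulation budget and are stated here so they
can be scaled up knowingly.

## Known limitations

Per-animal inference with n = 4 is exactly as fragile as in the motivating
experimental design — the signed-rank fallback is powerless at this n, and
a single aberrant animal dominates the paired SD. The generator's OU
background is Gaussian and shared across pixels; heavy-tailed artifacts
will route more contrasts to the signed-rank test than the defaults
suggest. The epoch geometry (50 + 200 frames, four 5-s windows) is fixed
by convention and only lightly parameterized; changing `fps` away from 10
changes window durations accordingly.
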