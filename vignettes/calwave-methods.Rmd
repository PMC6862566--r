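---
title: "Models and methods behind calwave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind calwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(calwave)
```

`calwave` simulates in vivo calcium imaging of zebrafish embryo trunk
muscle and implements the corresponding analysis pipeline. This vignette
documents the models, their assumptions, the default parameter values and
why they were chosen, the numerical conventions, and the limits of what
the synthetic data can show.

## The phantom and event schedules

The embryo is a 1-D chain of rectangular somites inside a horizontal
trunk band (`make_embryo_phantom()`), by default 12 somites of 100 µm at
12.8 µm/pixel on a 128×128 binned frame — the geometry of a 512×512
EM-CCD at 4×4 binning. The phantom is deliberately 2-D and flat: no
optics, point-spread function or third dimension are modelled, because
the analysis operates on binned, diffraction-uncritical images.

Spontaneous events are a homogeneous Poisson process thinned by an
absolute refractory period (`schedule_events()`): an arrival within the
refractory window of the last accepted event is discarded, not delayed.
Thinning makes the realized rate `λ/(1 + λρ)`; `schedule_observed()`
inverts this so a preset realizes its nominal observed frequency. The
scenario presets encode the study conditions:

* `sp2-short` — short recordings at 24–28 hpf, 0.2 Hz observed;
* `sp1-sp2-long` — an overnight 12–28 hpf run at the long-run rate of
  0.02 Hz, active 17.5–19.5 hpf and after 23 hpf with a ~3.5 h quiet gap;
* `tricaine` — anaesthetic block of neural input, rate 0;
* `fccp` / `ds` — mitochondrial uncoupling or MCU inhibition: observed
  rate raised by 50 % and mitochondrial calcium uptake disabled.

The preset refractory period is 3 s. Spontaneous coiling at these stages
is quasi-rhythmic rather than memoryless, and luminescent transients last
1–2 s, so a refractory of a few seconds is both physiological and what
makes events countable at all; 3 s also keeps the FCCP rate (0.3 Hz)
reachable (`rate × refractory < 1`). Event amplitudes (peak free calcium
at the rostral reference) are log-normal with mean 0.6 µM and CV 0.3 —
sub-micromolar sarcoplasmic peaks typical of a twitch, with embryo-to-
embryo variability. These values are fixed study conditions, not fitting
knobs.

Each event contributes a difference-of-exponentials calcium pulse
normalised to its scheduled amplitude, superposed on a 0.1 µM resting
baseline. Cytosolic defaults: rise 0.06 s, decay 0.40 s. Mitochondrial
matrix transients mirror the cytosolic rise but decay more slowly
(decay 1.2 s); because a slower decay by itself stretches the rise of a
difference of exponentials, the mitochondrial rise constant is
back-solved (0.044 s) so both compartments share the same intrinsic
10–90 % pulse rise of 0.072 s. That encodes the observation that rise
parameters are indistinguishable between compartments while decay and
duration are longer in mitochondria.

Waves: events start at the rostral-most somite and sweep caudally at
`speed` (default 1.6 mm/s), with amplitude multiplied by
`(1 − decrement)^distance_mm` (default decrement 0.1/mm) and an optional
caudal slowing of the rise constant.

## Indicator models

**Aequorin (GA/mitoGA).** The photon drive is a Hill law,
`R = pool · max_rate · Ca^h / (K^h + Ca^h)` with cooperativity `h = 2.5`.
`K` defaults to 10 µM so the whole physiological range sits in the
power-law regime where luminescence scales as the 2.5 power of calcium.
`max_rate` defaults to 1.5·10⁴ photons/s per unit photoprotein per pixel:
aequorin's photon flux is marginal by nature, and this value puts the
rendered movies in the photon-starved regime where 4.7 Hz acquisition
records essentially every event while 11.9 Hz loses some and 30 Hz more —
the regime the method operates in. Consumption, when enabled, depletes
the pool by the emitted photons so cumulative light can never exceed
`pool × yield`.

**Off-kinetics.** Both indicators are modelled with an attack–release
filter: the emitted signal follows *rises* of the drive instantly and
relaxes exponentially with the off half-time when the drive falls
(aequorin 0.6 s, mid-range of the reported 0.4–0.8 s; Twitch 0.5 s). A
symmetric first-order low-pass was considered and rejected: it smears
rises as much as falls, which contradicts three observed patterns — the
luminescent and fluorescent probes resolve the same rise parameters, the
mitochondrial rise mirrors the cytosolic one, and the quoted half-times
describe the decay of light after calcium drops, not a lag in its onset.

**Twitch-style FRET ratio.** The pixel ratio follows
`r_min + (r_max − r_min)·Ca^n/(Kd^n + Ca^n)` with `n = 1.04`, so the
ratio is near-linear in calcium below saturation. The apparent Kd is
construct-specific and not fixed by the source material; the default of
2.8 µM keeps 0.1–1 µM well below saturation — with a sub-micromolar Kd
the sensor saturates during events and its apparent kinetics distort.
`r_min = 1`, `r_max = 4` give a four-fold dynamic range.

**Bleaching.** Each channel's emissive capacity decays
mono-exponentially under continuous excitation; the default constants
are back-solved so 15 minutes bleaches 9 % of the donor
(τ ≈ 9543 s) and 19 % of the acceptor (τ ≈ 4271 s). The acceptor
bleaching faster makes the ratio of an event-free movie drift downward.

## Rendering

Per binned pixel and frame, expected photons are
`(signal + substrate glow over the embryo + dark rate) × Δt`; counts are
Poisson, scaled by the camera gain, plus Gaussian read noise, clipped to
the 16-bit range. Frame *i* spans `[iΔt, (i+1)Δt)` and traces are
evaluated at frame midpoints; the transmitted-light renderer integrates
contraction coverage over the frame span exactly, since a 0.2 s twitch
can otherwise fall between midpoints. Defaults — dark 5 photons/s/px,
substrate glow 2 photons/s/px, read noise SD 3, gain 1 — were chosen
once so that the mean + 2 SD background threshold combined with the
">9 adjacent pixels" rule yields essentially no false events on
event-free movies (about one per 10-minute recording). One top-level
seed drives each renderer; sub-streams for embryos and channels are
derived deterministically (`derive_seed()`), and identical seed and
configuration reproduce movies bit-identically.

The FRET renderer keeps `donor + FRET` constant at fixed bleaching, so
the channels move oppositely with calcium while their pixel-wise ratio is
exactly the Twitch response; a common multiplicative motion factor
(default 5 % at full activation) is applied to both channels during
events and cancels exactly in the ratio. The two half-fields are placed
side by side as an image splitter does, with an optional integer
misalignment for registration testing.

## The analysis pipeline

**Background and threshold.** The general background of each frame is
`GB = mean + 2 SD` of an off-embryo ROI with the same pixel count as the
trunk ROI; the embryo background is
`EB = mean(meanROI1 − meanROI2) + 2 SD` over 15 transient-free reference
frames, clamped at zero. Both SDs are sample standard deviations — the
SD in GB over the ROI's pixels within the frame, the SD in EB over the
15 per-frame differences; these are the only self-contained readings.
Reference frames default to the 15 frames with the lowest trunk
intensity (the interactive selection is replaced by this automatic
rule), and the per-frame detection threshold is `GB + EB`.

**Detection.** Suprathreshold pixels (strictly above threshold) over the
trunk are labelled by connected components (8-connectivity by default,
4 available); components of 9 pixels or fewer are rejected, i.e. a
transient must be *larger than* 9 adjacent pixels. The integrated
density trace is the per-frame sum of raw pixel values over accepted
components, with no background subtraction. Events are maximal positive
runs of that trace; runs separated by quiet spans of at most 0.8 s are
merged (specified in seconds so counting behaves consistently across
frame rates — photon-starved tails flicker around the threshold), and an
event must reach a peak integrated density of at least 10
threshold-equivalents. These two guards stand in for the interactive
event-curation step of the original workflow.

**Kinetics.** The baseline is the mean of the 5 frames before the event
(zero at a recording edge); levels at 10/50/90 % of the baseline-
subtracted peak are located by linear interpolation between samples.
Rise 10–90 %, decay 90–10 %, half-width, duration (10 % up to 10 % down)
and time-to-peak (from the 10 % rising crossing, an onset-referenced
measure) follow. Ties at the peak break to the earliest frame; events
with missing crossings at the recording edges are flagged truncated and
excluded from decay statistics; non-positive amplitudes are rejected
with an explicit status. `resample_trace()` sums counts into coarser
bins — photon semantics, conserving totals — to emulate longer
integration times.

**Contractions.** The ratio of mean intensities of two identical ROIs —
one on a somite, one in the medium — is constant except when the embryo
moves. Baseline statistics use the whole-trace median and scaled MAD
(contractions are sparse); a contraction is a run where the ratio
deviates by more than `k = 5` spreads, runs closer than 0.5 s merged.
The numeric rule is ours; the source describes the method qualitatively.

**FRET.** The split field is divided in half and the FRET half aligned
to the donor half by the integer translation maximising normalised
cross-correlation on the brightest frame (search radius ±10 px; at 4×4
binning sub-pixel alignment is below the noise floor); the same offset
applies to all frames, and a peak on the search edge raises a warning.
Ratios are computed pixel-wise where the donor exceeds the 1st
percentile of its nonzero values. Bleaching is quantified by a
log-linear mono-exponential fit to event-free channel means, reporting
`100·(1 − exp(−900/τ))`.

**Propagation.** Somites are grouped in threes (trailing remainder
kept); the onset in each grouped ROI is the 50 % rising crossing — the
same convention as the kinetics, and robust to the amplitude decrement,
unlike a fixed-threshold crossing. Wave speed is the reciprocal slope of
an ordinary least-squares fit of onset time against distance, using all
ROIs and reporting r² as a quality flag; zero slope is reported as
infinite speed, negative slope flagged caudo-rostral, and events with
valid onsets in fewer than two ROIs are labelled non-propagating.

**Workbench.** Contraction and calcium movies cannot be acquired
simultaneously, so `run_paired_experiment()` renders both from one
schedule per embryo and compares the two frequencies descriptively
(mean ± SEM of paired differences; no hypothesis tests).
`run_indicator_comparison()` reads one *propagating* schedule out
through both indicators: the whole-trunk rise is dominated by the wave
sweeping the ROI and is therefore shared between probes, while the
2.5-power law sharpens the luminescence peak relative to the near-linear
ratio — which is why rise parameters agree across probes while decay and
duration need not.

## Problem sizes and expected departures

The default analyses use a 12-somite, 128×128 phantom; frequency
recovery runs 600 s at 4.7 Hz, rate comparisons 240 s at 4.7/11.9/30 Hz,
and the uncoupler cohort eight embryos with paired 900 s transmitted-
light segments at 4.2 Hz on a 64×64, 25.6 µm/px phantom (contraction
detection needs no spatial resolution). With these sizes the whole
simulation-plus-analysis cycle runs in minutes on one CPU.

Two systematic departures from nominal values are worth knowing.
Detected transient frequency sits a few percent below the scheduled
0.2 Hz because events closer than the luminescent span still merge
occasionally and the dimmest events fall below the detection floor.
In the uncoupler experiment the measured frequency change is typically
+45–50 % rather than exactly +50 %: the refractory dead time compresses
a 1.5-fold intensity ratio into a slightly smaller realized event-count
ratio. Both effects are properties of the measurement process the
pipeline models, not bugs; the matching recovery tests use counting-error
bands.

## What passing tests do and do not show

The generator reproduces the statistical structure the analysis assumes:
Poisson photon counting, uniform substrate glow, rigid common-mode
motion, mono-exponential bleaching, a 1-D wave, and stationary event
rates within a scenario. Real recordings break several of these —
non-uniform glow and absorption within the embryo, z-drift and
non-rigid motion, developmental drift of event rates within a session,
aequorin consumption gradients, and camera artifacts beyond Gaussian
read noise. Passing tests therefore demonstrate correctness of the
implementation under the stated model, and calibration of each stage
against known ground truth — not that the pipeline's operating
characteristics (false-positive rates, recall at 30 Hz) transfer
unchanged to any particular microscope.
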