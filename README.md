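# calwave

Simulation and analysis of spontaneous calcium transients in zebrafish
embryo skeletal muscle imaging.

Developing zebrafish embryos twitch spontaneously from about 17 hours
post-fertilization, and each trunk contraction is driven by a calcium
transient that can be imaged in vivo with genetically encoded reporters:
bioluminescent GFP–apoaequorin in the cytosol (GA) or mitochondrial matrix
(mitoGA), and ratiometric FRET sensors of the Twitch family. `calwave` is
for researchers analysing such recordings — and for anyone who wants to
test such an analysis against known ground truth. It pairs:

* **a synthetic movie generator** — somite-resolved embryo phantoms, spike
  schedules with scenario presets (short recordings at 0.2 Hz, overnight
  signalling-period runs, anaesthetic block, mitochondrial uncoupling),
  aequorin photophysics with the supralinear luminescence law
  *L* ∝ [Ca²⁺]^2.5 below saturation and substrate consumption, Twitch-style
  ratio response with Hill slope 1.04, channel-specific photobleaching,
  common-mode motion artifacts, Poisson photon statistics and camera read
  noise, and rostro-caudal wave propagation at a configurable speed
  (default 1.6 mm/s); and
* **the analysis pipeline** — a two-component background model (general
  background GB = mean + 2 SD of an off-embryo ROI per frame, embryo
  background EB from 15 transient-free frames), per-frame detection
  thresholds GB + EB, connected components larger than 9 adjacent pixels
  over the trunk, integrated-density event traces, crossing-based kinetics
  (time to peak, rise time 10–90 %, decay time 90–10 %, half-width,
  duration), dual-ROI contraction detection in transmitted light,
  split-field FRET registration and pixel-wise FRET/donor ratioing with
  bleaching quantification, and wave-speed estimation by regressing event
  onset times on somite distance.

Because every movie is generated from an explicit spike schedule, every
stage of the analysis can be checked against exact ground truth.

## Worked example

Simulate a 10-minute bioluminescence recording of a 12-somite trunk at the
standard 4.7 Hz acquisition rate and run the full detection chain:

```r
library(calwave)

phantom  <- make_embryo_phantom(12)                 # 128x128 px, 12.8 um/px
schedule <- scenario_schedule("sp2-short", duration = 600, seed = 1)
rates    <- somite_rate_matrix(phantom, schedule,
                               transient_waveform("cytosol"),
                               aequorin_model(), 4.7, 600)
movie    <- render_luminescence_movie(phantom, rates$rates,
                                      camera_model(integration_time = 1/4.7),
                                      seed = 101)
res <- analyze_luminescence(movie, phantom)

length(schedule$onsets) / 600   # scheduled frequency
#> [1] 0.195
res$frequency                   # detected frequency
#> [1] 0.1916667
res$background$eb               # embryo background (substrate glow), counts
#> [1] 0.3185944
head(res$kinetics[, c("rise_10_90", "decay_90_10", "half_width", "duration")], 3)
#>   rise_10_90 decay_90_10 half_width  duration
#> 1  0.1702128   1.2489759  0.8227029 1.6053651
#> 2  0.1702128   0.6264021  0.3943440 0.8755584
#> 3  0.1702128   0.3403081  0.3115343 0.5728277
```

The detector recovers 115 of the 117 scheduled events (0.192 vs 0.195 Hz);
single events rise in ~0.2 s and decay over 1–2 s, the time course set by
the calcium waveform filtered through the indicator's off kinetics.

The numbered scripts under `analysis/` walk through the whole study:
simulation (`01`), background and detection (`02`), kinetics and indicator
comparison (`03`), contractions and the uncoupler experiment (`04`), FRET
ratioing and bleaching (`05`), and wave speed (`06`). Each writes its
tables under `results/`.

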