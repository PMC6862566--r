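#!/usr/bin/env Rscript
# Generate one ground-truthed synthetic embryo recording of each modality
# (bioluminescence, split-field FRET, transmitted light) and write the
# movies as 16-bit TIFF stacks with their ground truth beside them.

library(calwave)

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 1

phantom <- make_embryo_phantom(12)                       # 128x128, 12.8 um/px
small <- make_embryo_phantom(8, image_shape = c(64L, 64L), pixel_scale = 25.6)
schedule <- scenario_schedule("sp2-short", duration = 120, seed = seed)
cat(sprintf("schedule: %d events in 120 s (%.3f Hz realized)\n",
            length(schedule$onsets), length(schedule$onsets) / 120))

## GFP-aequorin bioluminescence at 4.7 Hz
srm <- somite_rate_matrix(phantom, schedule, transient_waveform("cytosol"),
                          aequorin_model(), 4.7, 120,
                          prop = propagation_params())
lum <- render_luminescence_movie(phantom, srm$rates,
                                 camera_model(integration_time = 1 / 4.7),
                                 seed = seed + 10)
write_movie_tiff(movie(round(lum$frames), lum$frame_interval,
                       lum$pixel_scale, lum$channel),
                 file.path(out, "luminescence_4p7Hz.tif"))

## Twitch-style split-field FRET at 33 Hz (50 s, as fluorescence runs are)
ca <- t(sapply(seq_len(phantom$n_somites), function(s) {
  d <- propagate_wave(phantom, propagation_params())
  ca_timecourse(schedule, transient_waveform("cytosol"), 33, 50,
                onset_shift = d$delay_s[s], amp_scale = d$amp_scale[s])$ca
}))
fret <- render_fret_movie(phantom, ca, twitch_model(),
                          camera = camera_model(
                            sensor_pixels = phantom$image_shape * 4L,
                            integration_time = 1 / 33,
                            substrate_glow_rate = 0),
                          channel_offset = c(2L, -1L), seed = seed + 20)
write_movie_tiff(movie(round(fret$frames), fret$frame_interval,
                       fret$pixel_scale, fret$channel),
                 file.path(out, "fret_split_33Hz.tif"))

## transmitted light at 4.2 Hz
tm <- render_transmitted_movie(small, schedule, seed = seed + 30)
write_movie_tiff(movie(round(tm$frames), tm$frame_interval, tm$pixel_scale,
                       tm$channel),
                 file.path(out, "transmitted_4p2Hz.tif"))

write_ground_truth(list(
  seed = seed,
  scenario = schedule$scenario,
  onsets_s = schedule$onsets,
  amplitudes_uM = schedule$amplitudes,
  propagation = list(speed_mm_s = 1.6, decrement_per_mm = 0.1),
  waveform = unclass(transient_waveform("cytosol")),
  aequorin = unclass(aequorin_model()),
  twitch = unclass(twitch_model()),
  bleaching = unclass(bleaching_model())
), file.path(out, "ground_truth.json"))

write_run_config(list(scenario = "sp2-short", seed = seed,
                      duration_s = 120, lum_rate_hz = 4.7,
                      fluor_rate_hz = 33, transmitted_rate_hz = 4.2),
                 file.path(out, "config.yaml"))
cat("wrote movies and ground truth to", out, "\n")
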