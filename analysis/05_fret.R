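#!/usr/bin/env Rscript
# Split-field FRET processing: channel registration, pixel-wise ratio,
# ROI ratio trace against the generating model, and photobleaching.

library(calwave)
dir.create("results", showWarnings = FALSE)

phantom <- make_embryo_phantom(12)
schedule <- schedule_events(0.1, 50, seed = 2, refractory = 3)
ca <- t(sapply(seq_len(phantom$n_somites), function(s)
  ca_timecourse(schedule, transient_waveform("cytosol"), 33, 50)$ca))
cam <- camera_model(sensor_pixels = phantom$image_shape * 4L,
                    integration_time = 1 / 33, substrate_glow_rate = 0)
mv <- render_fret_movie(phantom, ca, twitch_model(), camera = cam,
                        channel_offset = c(3L, -2L), seed = 7)

sr <- split_and_register(mv)
cat(sprintf("registration offset applied to FRET half: (%d, %d)\n",
            sr$offset[1], sr$offset[2]))
rs <- ratio_stack(sr$donor, sr$fret)
trace <- roi_ratio_trace(rs, phantom_mask(phantom))
truth <- attr(mv, "truth")
err <- abs(trace - colMeans(truth$ratio)) / colMeans(truth$ratio)
cat(sprintf("ROI ratio trace vs model: median |rel err| = %.3f\n",
            median(err)))
write.csv(data.frame(frame = seq_along(trace), ratio = trace),
          "results/fret_ratio_trace.csv", row.names = FALSE)

## photobleaching from an event-free movie (quiet baseline calcium)
ca0 <- matrix(0.1, phantom$n_somites, 33 * 50)
mv0 <- render_fret_movie(phantom, ca0, twitch_model(), camera = cam,
                         seed = 8)
sr0 <- split_and_register(mv0)
roi <- phantom_mask(phantom)
times <- (seq_len(dim(sr0$donor)[3]) - 0.5) / 33
for (ch in c("donor", "fret")) {
  means <- apply(sr0[[ch]], 3, function(fr) mean(fr[roi]))
  fit <- bleaching_summary(means, times)
  cat(sprintf("%s channel: tau = %.0f s -> %.1f%% decline at 15 min\n",
              ch, fit$tau, fit$percent_decline))
}
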