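#' Off-embryo background ROI paired with the trunk ROI
#'
#' Builds the ROI pair the background model needs: ROI1 is the embryo
#' trunk; ROI2 is the identical region translated into the medium above
#' (or below) the embryo.
#'
#' @param phantom an `embryo_phantom`.
#' @param gap_px clearance between the trunk and ROI2, pixels.
#' @export
make_background_roi_pair <- function(phantom, gap_px = 2L) {
  roi1 <- phantom_mask(phantom)
  rows <- which(apply(roi1, 1, any))
  height <- length(rows)
  up <- min(rows) - gap_px - height
  down <- max(rows) + gap_px
  dy <- if (up >= 1) -(gap_px + height)
        else if (down + height <= phantom$image_shape[1]) gap_px + height
        else stop("no room for an off-embryo ROI above or below the trunk")
  roi2 <- matrix(FALSE, nrow(roi1), ncol(roi1))
  roi2[rows + dy, ] <- roi1[rows, ]
  roi_pair(roi1, roi2, embryo_mask = roi1)
}

#' Paired contraction-detection ROIs
#'
#' One ROI on a mid-trunk somite and an identical one in the medium just
#' outside the embryo, for [dual_roi_ratio()].
#'
#' @param phantom an `embryo_phantom`.
#' @param somite somite carrying the on-embryo ROI (default: middle).
#' @param gap_px clearance above the trunk, pixels.
#' @export
make_contraction_rois <- function(phantom, somite = NULL, gap_px = 3L) {
  somite <- somite %||% max(1L, phantom$n_somites %/% 2L)
  on <- phantom_mask(phantom, somite)
  rows <- which(apply(on, 1, any))
  height <- length(rows)
  dy <- if (min(rows) - gap_px - height >= 1) -(gap_px + height)
        else gap_px + height
  off <- matrix(FALSE, nrow(on), ncol(on))
  off[rows + dy, ] <- on[rows, ]
  list(roi_on = on, roi_off = off)
}

#' Full luminescence analysis of one movie
#'
#' Runs the standard chain on a bioluminescence movie: background model
#' (GB per frame, EB from reference frames), per-frame thresholds,
#' size-gated component detection over the trunk, integrated-density
#' trace, event segmentation and kinetics.
#'
#' The merge window is specified in seconds (`merge_gap_s`) so event
#' counting behaves consistently across frame rates, and an event must
#' reach a peak integrated density of at least `min_peak_px`
#' threshold-equivalents (a guard against isolated noise clusters that
#' barely clear the size rule).
#'
#' @param mov a [movie()].
#' @param phantom the `embryo_phantom` the movie was rendered on (supplies
#'   trunk mask and the off-embryo ROI).
#' @param params a [detection_params()].
#' @param reference_frames indices for the embryo-background estimate, or
#'   `NULL` for automatic selection.
#' @param merge_gap_s event-free span bridged when segmenting, seconds.
#' @param min_peak_px minimum peak integrated density in units of the
#'   peak frame's threshold.
#' @param baseline_frames baseline window for kinetics.
#' @return list: `background`, `trace`, `events`, `kinetics`, `frequency`
#'   (Hz), `duration` (s).
#' @export
analyze_luminescence <- function(mov, phantom, params = detection_params(),
                                 reference_frames = NULL, merge_gap_s = 0.8,
                                 min_peak_px = 10, baseline_frames = 5) {
  pair <- make_background_roi_pair(phantom)
  bg <- frame_thresholds(mov, pair, reference_frames)
  trace <- integrated_density(mov, bg, phantom_mask(phantom), params)
  events <- segment_events(trace, floor(merge_gap_s / mov$frame_interval))
  if (nrow(events)) {
    keep <- trace$values[events$peak] >=
      min_peak_px * bg$threshold_per_frame[events$peak]
    events <- events[keep, , drop = FALSE]
    rownames(events) <- NULL
  }
  kin <- if (nrow(events)) events_kinetics(trace$values, mov$frame_interval,
                                           events, baseline_frames)
         else NULL
  dur <- n_frames(mov) * mov$frame_interval
  list(background = bg, trace = trace, events = events, kinetics = kin,
       frequency = series_frequency(events, dur), duration = dur)
}

#' Event windows of a continuous (non-zero-baseline) trace
#'
#' Segments traces whose baseline is not zero (FRET ratios, photon-rate
#' traces): frames above `baseline + frac * (max - baseline)` form the
#' suprathreshold runs passed to [segment_events()].
#'
#' @param values numeric trace.
#' @param frac threshold as a fraction of the full excursion.
#' @param merge_gap frames bridged between runs.
#' @export
trace_events <- function(values, frac = 0.05, merge_gap = 2L) {
  base <- stats::median(values)
  thr <- base + frac * (max(values) - base)
  segment_events(pmax(values - thr, 0), merge_gap)
}

#' Simulate one embryo and analyse contractions and calcium together
#'
#' Mirrors the paired experimental design: contraction and calcium movies
#' cannot be acquired simultaneously, so two movies are rendered from the
#' one spike schedule of the embryo and each is run through its own
#' pipeline. Returns both frequencies per embryo and the paired summary.
#'
#' @param n_embryos cohort size.
#' @param scenario preset passed to [scenario_schedule()].
#' @param duration seconds per movie.
#' @param seed top-level seed; embryo sub-seeds derive from it.
#' @param phantom an `embryo_phantom`, or `NULL` for the default trunk.
#' @param lum_rate_hz bioluminescence frame rate, Hz.
#' @return list: `per_embryo` data.frame (`contraction_hz`,
#'   `transient_hz`, `scheduled_hz`), `mean_diff`, `sem_diff`.
#' @export
run_paired_experiment <- function(n_embryos = 6, scenario = "sp2-short",
                                  duration = 600, seed = 1, phantom = NULL,
                                  lum_rate_hz = 4.7) {
  phantom <- phantom %||% make_embryo_phantom(12)
  small <- make_embryo_phantom(8, image_shape = c(64L, 64L),
                               pixel_scale = 25.6)
  wf <- transient_waveform("cytosol")
  aq <- aequorin_model()
  crois <- make_contraction_rois(small)
  rows <- lapply(seq_len(n_embryos), function(i) {
    s_i <- derive_seed(seed, i)
    sch <- scenario_schedule(scenario, duration = duration, seed = s_i)
    tm <- render_transmitted_movie(small, sch, seed = derive_seed(s_i, 1))
    ct <- dual_roi_ratio(tm, crois$roi_on, crois$roi_off)
    cdet <- detect_contractions(ct)
    srm <- somite_rate_matrix(phantom, sch, wf, aq, lum_rate_hz, duration)
    lm_ <- render_luminescence_movie(
      phantom, srm$rates,
      camera_model(integration_time = 1 / lum_rate_hz),
      seed = derive_seed(s_i, 2))
    lres <- analyze_luminescence(lm_, phantom)
    data.frame(contraction_hz = cdet$frequency,
               transient_hz = lres$frequency,
               scheduled_hz = length(sch$onsets) / duration)
  })
  tab <- do.call(rbind, rows)
  d <- tab$contraction_hz - tab$transient_hz
  list(per_embryo = tab, mean_diff = mean(d),
       sem_diff = if (n_embryos > 1) stats::sd(d) / sqrt(n_embryos) else NA_real_)
}

#' Before/after drug experiment on a seeded cohort
#'
#' For each embryo, a pre-drug segment at the spontaneous rate and a
#' post-drug segment under the preset (rate raised 50\%, mitochondrial
#' calcium uptake disabled for FCCP/DS) are simulated from separate
#' schedules. Contraction frequencies come from transmitted-light movies
#' through the dual-ROI detector; optionally, mitochondrial transient
#' frequencies come from mitoGA luminescence movies.
#'
#' @param preset `"fccp"` or `"ds"`.
#' @param n_embryos cohort size.
#' @param segment_duration seconds per segment (default 900 = 15 min).
#' @param seed top-level seed.
#' @param base_rate spontaneous contraction rate, Hz.
#' @param include_mito also simulate and analyse mitoGA movies (shorter
#'   `mito_duration` segments at `mito_rate_hz`).
#' @param mito_duration,mito_rate_hz mitoGA segment length and frame rate.
#' @return list: `contractions` ([paired_frequency_change()] output) and,
#'   when requested, `mito` (pre/post mitochondrial transient
#'   frequencies).
#' @export
run_drug_experiment <- function(preset = c("fccp", "ds"), n_embryos = 8,
                                segment_duration = 900, seed = 1,
                                base_rate = 0.2, include_mito = FALSE,
                                mito_duration = 300, mito_rate_hz = 4.7) {
  preset <- match.arg(preset)
  small <- make_embryo_phantom(8, image_shape = c(64L, 64L),
                               pixel_scale = 25.6)
  crois <- make_contraction_rois(small)
  contraction_freq <- function(sch, sd) {
    tm <- render_transmitted_movie(small, sch, seed = sd)
    ct <- dual_roi_ratio(tm, crois$roi_on, crois$roi_off)
    detect_contractions(ct)$frequency
  }
  pre <- post <- numeric(n_embryos)
  mito_pre <- mito_post <- numeric(n_embryos)
  if (include_mito) {
    phantom <- make_embryo_phantom(12)
    wf_m <- transient_waveform("mitochondria")
    aq <- aequorin_model()
    cam <- camera_model(integration_time = 1 / mito_rate_hz)
  }
  for (i in seq_len(n_embryos)) {
    s_i <- derive_seed(seed, i)
    sch_pre <- schedule_observed(base_rate, segment_duration, seed = s_i,
                                 scenario = "pre")
    sch_post <- scenario_schedule(preset, duration = segment_duration,
                                  seed = derive_seed(s_i, 5),
                                  base_rate = base_rate)
    pre[i] <- contraction_freq(sch_pre, derive_seed(s_i, 1))
    post[i] <- contraction_freq(sch_post, derive_seed(s_i, 2))
    if (include_mito) {
      mito_freq <- function(sch, uptake, sd) {
        srm <- somite_rate_matrix(phantom, sch, wf_m, aq, mito_rate_hz,
                                  mito_duration)
        if (!uptake) srm$rates <- somite_rate_matrix(
          phantom,
          schedule_events(0, mito_duration, seed = sd, scenario = "silent"),
          wf_m, aq, mito_rate_hz, mito_duration)$rates
        mv <- render_luminescence_movie(phantom, srm$rates, cam, seed = sd)
        analyze_luminescence(mv, phantom)$frequency
      }
      sch_pre_m <- schedule_observed(base_rate, mito_duration,
                                     seed = derive_seed(s_i, 6))
      sch_post_m <- schedule_observed(base_rate * 1.5, mito_duration,
                                      seed = derive_seed(s_i, 7))
      mito_pre[i] <- mito_freq(sch_pre_m, TRUE, derive_seed(s_i, 3))
      mito_post[i] <- mito_freq(sch_post_m, FALSE, derive_seed(s_i, 4))
    }
  }
  out <- list(contractions = paired_frequency_change(pre, post))
  if (include_mito)
    out$mito <- list(pre = mito_pre, post = mito_post,
                     mean_pre = mean(mito_pre), mean_post = mean(mito_post))
  out
}

# mean +/- SD summary of a kinetics table
kinetics_summary <- function(kin) {
  cols <- c("time_to_peak", "peak_amplitude", "rise_10_90", "decay_90_10",
            "half_width", "duration")
  ok <- kin[kin$status == "ok", , drop = FALSE]
  data.frame(parameter = cols,
             mean = vapply(cols, function(c) mean(ok[[c]]), numeric(1)),
             sd = vapply(cols, function(c) stats::sd(ok[[c]]), numeric(1)),
             n = nrow(ok), row.names = NULL)
}

#' Compare kinetic parameters across indicators on a matched schedule
#'
#' One calcium schedule, propagating as a rostro-caudal wave across the
#' somites, is read out through the aequorin forward model (summed over
#' somites, as an integrated-density trace, at the bioluminescence rate)
#' and through the Twitch ratio response (trunk-ROI mean ratio at the
#' fluorescence rate); the seven kinetic parameters are summarised per
#' indicator. The rise of the whole-trunk trace is dominated by the wave
#' sweeping across the ROI and is therefore shared by both indicators,
#' while the aequorin power law (cooperativity 2.5) sharpens peaks
#' relative to the near-linear ratio response, so decay and duration can
#' differ.
#'
#' @param schedule a `spike_schedule` (default: a 120 s run at 0.1 Hz).
#' @param seed seed for the default schedule.
#' @param lum_rate_hz,fluor_rate_hz sampling rates of the two readouts.
#' @param waveform the underlying calcium [transient_waveform()].
#' @param phantom somite geometry the wave crosses.
#' @param prop wave [propagation_params()].
#' @return list: `ga` and `twitch` summaries plus each full kinetics
#'   table and frequency.
#' @export
run_indicator_comparison <- function(schedule = NULL, seed = 1,
                                     lum_rate_hz = 11.9, fluor_rate_hz = 33,
                                     waveform = transient_waveform("cytosol"),
                                     phantom = make_embryo_phantom(12),
                                     prop = propagation_params()) {
  schedule <- schedule %||% schedule_events(0.1, 120, refractory = 3,
                                            seed = seed, amplitude_cv = 0.2)
  delays <- propagate_wave(phantom, prop)
  aq <- aequorin_model()
  tw <- twitch_model()
  one <- function(rate_hz, per_somite, combine) {
    per <- sapply(seq_len(phantom$n_somites), function(s) {
      tc <- ca_timecourse(schedule, waveform, rate_hz,
                          onset_shift = delays$delay_s[s],
                          amp_scale = delays$amp_scale[s],
                          rise_scale = delays$rise_scale[s])
      per_somite(tc$ca, 1 / rate_hz)
    })
    vals <- combine(per)
    ev <- trace_events(vals)
    kin <- events_kinetics(vals, 1 / rate_hz, ev)
    list(kinetics = kin, summary = kinetics_summary(kin),
         frequency = series_frequency(ev, schedule$duration))
  }
  list(ga = one(lum_rate_hz,
                function(ca, dt) aequorin_emission(ca, dt, aq)$rate,
                rowSums),
       twitch = one(fluor_rate_hz,
                    function(ca, dt) twitch_response(ca, dt, tw),
                    rowMeans))
}

#' Read or write a run configuration
#'
#' YAML round trip of a named list of run settings (scenario, indicator,
#' seed, camera and detection settings, output paths).
#'
#' @param config named list.
#' @param path YAML file.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
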