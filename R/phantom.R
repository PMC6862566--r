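#' Construct a somite phantom of a zebrafish embryo trunk
#'
#' Lays out `n_somites` rectangular somite masks side by side along a
#' rostro-caudal (left-to-right) axis inside a horizontal trunk band, the
#' geometry the in vivo movies show at 4x4 camera binning. All analysis
#' ROIs (somite masks, trunk mask, off-embryo background regions) derive
#' from this object.
#'
#' @param n_somites number of somites (>= 1).
#' @param somite_size somite length along the body axis, in micrometres.
#' @param image_shape integer vector `c(height, width)` in pixels.
#' @param pixel_scale micrometres per (binned) pixel.
#' @param trunk_width dorso-ventral extent of the trunk band, micrometres.
#' @param rostral_margin gap between the image edge and the first somite,
#'   micrometres.
#' @return An object of class `embryo_phantom`: somite centroids (um),
#'   per-somite pixel indices, trunk indices, an integer label image
#'   (0 = background), `image_shape` and `pixel_scale`.
#' @export
make_embryo_phantom <- function(n_somites, somite_size = 100,
                                image_shape = c(128L, 128L),
                                pixel_scale = 12.8,
                                trunk_width = 200,
                                rostral_margin = somite_size) {
  stopifnot(n_somites >= 1, somite_size > 0, pixel_scale > 0)
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  som_px <- max(1L, round(somite_size / pixel_scale))
  trunk_px <- max(1L, round(trunk_width / pixel_scale))
  margin_px <- max(1L, round(rostral_margin / pixel_scale))
  x0 <- margin_px + 1L
  x1 <- margin_px + n_somites * som_px
  if (x1 > w - 1L)
    stop(sprintf("somites span %d px but image width is only %d px", x1, w))
  if (trunk_px > h - 2L)
    stop(sprintf("trunk width %d px exceeds image height %d px", trunk_px, h))
  y0 <- (h - trunk_px) %/% 2L + 1L
  rows <- y0:(y0 + trunk_px - 1L)

  label <- matrix(0L, h, w)
  somite_px <- vector("list", n_somites)
  centroids <- matrix(NA_real_, n_somites, 2L,
                      dimnames = list(NULL, c("x_um", "y_um")))
  for (s in seq_len(n_somites)) {
    cols <- (x0 + (s - 1L) * som_px):(x0 + s * som_px - 1L)
    idx <- as.vector(outer(rows, (cols - 1L) * h, "+"))
    somite_px[[s]] <- idx
    label[idx] <- s
    centroids[s, ] <- c(mean(cols) - 0.5, mean(rows) - 0.5) * pixel_scale
  }
  structure(list(
    n_somites = n_somites,
    somite_centroids = centroids,
    somite_px = somite_px,
    trunk_px = which(label > 0L),
    label = label,
    image_shape = c(h, w),
    pixel_scale = pixel_scale
  ), class = "embryo_phantom")
}

#' @export
print.embryo_phantom <- function(x, ...) {
  cat(sprintf("embryo_phantom: %d somites, %dx%d px at %.1f um/px\n",
              x$n_somites, x$image_shape[1], x$image_shape[2], x$pixel_scale))
  invisible(x)
}

#' Logical mask for one somite or the whole trunk
#' @param phantom an `embryo_phantom`.
#' @param somite somite index, or `NULL` for the trunk union.
#' @return logical matrix of the phantom's image shape.
#' @export
phantom_mask <- function(phantom, somite = NULL) {
  m <- matrix(FALSE, phantom$image_shape[1], phantom$image_shape[2])
  m[if (is.null(somite)) phantom$trunk_px else phantom$somite_px[[somite]]] <- TRUE
  m
}

# deterministic sub-stream derivation from one top-level seed
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * as.numeric(k)) %% 2147483647)
}

#' Schedule spontaneous calcium-release events
#'
#' Homogeneous Poisson event times thinned by an absolute refractory period:
#' a candidate arriving within `refractory` seconds of the previously
#' accepted event is discarded, not delayed. Peak amplitudes (free calcium
#' at the rostral reference somite, micromolar) are drawn log-normal.
#'
#' @param rate mean event rate in Hz (>= 0).
#' @param duration recording length, seconds.
#' @param refractory refractory period, seconds.
#' @param seed integer seed; the schedule is reproducible given the seed.
#' @param amplitude_mean mean peak amplitude, micromolar.
#' @param amplitude_cv coefficient of variation of amplitudes.
#' @param scenario free-text label carried through to ground truth.
#' @return A `spike_schedule` with strictly increasing `onsets` (s),
#'   positive `amplitudes` (uM), `duration` and `scenario`.
#' @export
schedule_events <- function(rate, duration, refractory = 0.3, seed = 1,
                            amplitude_mean = 0.6, amplitude_cv = 0.3,
                            scenario = "custom") {
  if (rate < 0) stop("event rate must be >= 0")
  stopifnot(duration > 0, refractory >= 0)
  set.seed(seed)
  n <- stats::rpois(1, rate * duration)
  times <- sort(stats::runif(n, 0, duration))
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory) { keep[i] <- TRUE; last <- times[i] }
  }
  onsets <- times[keep]
  sdlog <- sqrt(log(1 + amplitude_cv^2))
  meanlog <- log(amplitude_mean) - sdlog^2 / 2
  amps <- stats::rlnorm(length(onsets), meanlog, sdlog)
  structure(list(onsets = onsets, amplitudes = amps, duration = duration,
                 refractory = refractory, rate = rate, scenario = scenario),
            class = "spike_schedule")
}

#' Scenario presets for event schedules
#'
#' Encodes the study conditions as named presets:
#' \describe{
#'   \item{sp2-short}{short recordings in the second signalling period
#'     (24-28 hpf), spontaneous rate 0.2 Hz.}
#'   \item{sp1-sp2-long}{overnight recording spanning both signalling
#'     periods at the long-run rate 0.02 Hz: SP1 active 17.5-19.5 hpf,
#'     a quiet gap of about 3.5 h, then SP2 from 23 hpf onward. Times are
#'     seconds from 12 hpf.}
#'   \item{tricaine}{anaesthetic block of neural input: rate 0.}
#'   \item{fccp, ds}{mitochondrial uncoupler / MCU inhibitor: spontaneous
#'     rate raised by 50\% and mitochondrial calcium uptake disabled
#'     (`mito_uptake = FALSE`).}
#' }
#'
#' @param scenario preset name.
#' @param duration seconds (default 600; the long preset defaults to the
#'   full 12-28 hpf span).
#' @param seed integer seed.
#' @param base_rate spontaneous observed rate the presets scale, Hz.
#' @param refractory preset refractory period, seconds. Spontaneous
#'   coiling is quasi-rhythmic, so the presets use a 3 s refractory.
#' @param ... passed to [schedule_events()].
#' @return a `spike_schedule`; presets that alter mitochondrial handling
#'   set its `mito_uptake` field to `FALSE`.
#' @export
scenario_schedule <- function(scenario = c("sp2-short", "sp1-sp2-long",
                                           "tricaine", "fccp", "ds"),
                              duration = NULL, seed = 1, base_rate = 0.2,
                              refractory = 3, ...) {
  scenario <- match.arg(scenario)
  sch <- switch(scenario,
    "sp2-short" = schedule_observed(base_rate, duration %||% 600,
                                    refractory = refractory, seed = seed,
                                    scenario = scenario, ...),
    "tricaine" = schedule_events(0, duration %||% 600, seed = seed,
                                 scenario = scenario, ...),
    "fccp" = ,
    "ds" = schedule_observed(base_rate * 1.5, duration %||% 600,
                             refractory = refractory, seed = seed,
                             scenario = scenario, ...),
    "sp1-sp2-long" = {
      dur <- duration %||% (16 * 3600)  # 12 -> 28 hpf
      # active windows in seconds from 12 hpf
      sp1 <- c(5.5, 7.5) * 3600        # 17.5 - 19.5 hpf
      sp2 <- c(11, 16) * 3600          # from 23 hpf
      sch <- schedule_observed(0.02, dur, refractory = refractory,
                               seed = seed, scenario = scenario, ...)
      keep <- (sch$onsets >= sp1[1] & sch$onsets <= sp1[2]) |
              (sch$onsets >= sp2[1] & sch$onsets <= min(sp2[2], dur))
      sch$onsets <- sch$onsets[keep]
      sch$amplitudes <- sch$amplitudes[keep]
      sch
    })
  sch$mito_uptake <- !(scenario %in% c("fccp", "ds"))
  sch
}

#' Schedule events so that the realized frequency matches a target
#'
#' Refractory thinning of a Poisson process lowers the realized event
#' rate to `lambda / (1 + lambda * refractory)` (non-paralyzable dead
#' time). This wrapper inverts that relation, drawing the process at
#' intensity `rate / (1 - rate * refractory)` so the expected observed
#' frequency equals `rate`. Requires `rate * refractory < 1`.
#'
#' @inheritParams schedule_events
#' @param ... passed to [schedule_events()].
#' @export
schedule_observed <- function(rate, duration, refractory = 3, seed = 1,
                              ...) {
  if (rate * refractory >= 1)
    stop("target rate unreachable: rate * refractory must be < 1")
  schedule_events(rate / (1 - rate * refractory), duration,
                  refractory = refractory, seed = seed, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Transient waveform parameters for one compartment
#'
#' Each event contributes a difference-of-exponentials calcium pulse,
#' `exp(-t/decay) - exp(-t/rise)`, normalised so its peak equals the
#' scheduled amplitude. Mitochondrial matrix transients mirror the
#' cytosolic rise but decay more slowly, so the mitochondrial default
#' decay constant is larger; its default rise constant is back-solved so
#' the pulse's intrinsic 10-90\% rise time equals the cytosolic one
#' (0.072 s), since a slower decay by itself would stretch the rise of a
#' difference of exponentials.
#'
#' An optional amplitude gain rescales the scheduled cytosolic-reference
#' amplitudes for compartments that concentrate calcium (the matrix can
#' accumulate well above cytosolic levels); the default leaves amplitudes
#' unscaled.
#'
#' @param compartment `"cytosol"` or `"mitochondria"`.
#' @param rise_tc rise time constant, seconds.
#' @param decay_tc decay time constant, seconds (must exceed `rise_tc`).
#' @param amp_gain multiplier on scheduled amplitudes for this
#'   compartment.
#' @export
transient_waveform <- function(compartment = c("cytosol", "mitochondria"),
                               rise_tc = NULL, decay_tc = NULL,
                               amp_gain = 1) {
  compartment <- match.arg(compartment)
  rise_tc <- rise_tc %||% if (compartment == "cytosol") 0.06 else 0.044
  decay_tc <- decay_tc %||% if (compartment == "cytosol") 0.40 else 1.20
  stopifnot(rise_tc > 0, decay_tc > 0, decay_tc > rise_tc, amp_gain > 0)
  structure(list(compartment = compartment, rise_tc = rise_tc,
                 decay_tc = decay_tc, amp_gain = amp_gain),
            class = "transient_waveform")
}

# unit-peak difference-of-exponentials pulse evaluated at times t (t<0 -> 0)
pulse_shape <- function(t, rise_tc, decay_tc) {
  tpk <- rise_tc * decay_tc / (decay_tc - rise_tc) * log(decay_tc / rise_tc)
  norm <- exp(-tpk / decay_tc) - exp(-tpk / rise_tc)
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- (exp(-t[pos] / decay_tc) - exp(-t[pos] / rise_tc)) / norm
  out
}

#' Free-calcium time course from a spike schedule
#'
#' Superposes one difference-of-exponentials pulse per scheduled event on a
#' constant resting baseline; overlapping events add linearly. Samples are
#' taken at frame midpoints `(i - 1/2)/sampling`.
#'
#' @param schedule a `spike_schedule`.
#' @param waveform a [transient_waveform()].
#' @param sampling sampling rate, Hz.
#' @param duration seconds (defaults to the schedule's duration).
#' @param baseline resting free calcium, micromolar.
#' @param onset_shift extra delay added to every onset (s), used for wave
#'   propagation.
#' @param amp_scale multiplier on all amplitudes (propagation decrement, or
#'   0 to silence a compartment).
#' @param rise_scale multiplier on the rise time constant (caudal rise
#'   slowing).
#' @return list with `time` (s), `ca` (uM) and `sampling`.
#' @export
ca_timecourse <- function(schedule, waveform, sampling, duration = NULL,
                          baseline = 0.1, onset_shift = 0, amp_scale = 1,
                          rise_scale = 1) {
  stopifnot(sampling > 0)
  duration <- duration %||% schedule$duration
  t <- (seq_len(ceiling(duration * sampling)) - 0.5) / sampling
  ca <- rep(baseline, length(t))
  gain <- waveform$amp_gain %||% 1
  if (amp_scale > 0) {
    for (i in seq_along(schedule$onsets)) {
      ca <- ca + amp_scale * gain * schedule$amplitudes[i] *
        pulse_shape(t - schedule$onsets[i] - onset_shift,
                    waveform$rise_tc * rise_scale, waveform$decay_tc)
    }
  }
  list(time = t, ca = ca, sampling = sampling)
}

#' Wave propagation parameters
#'
#' @param speed conduction speed along the body axis, mm/s.
#' @param decrement fractional amplitude loss per millimetre travelled
#'   (0 <= decrement < 1).
#' @param rise_slowing fractional increase of the rise time constant per
#'   millimetre (0 = none).
#' @export
propagation_params <- function(speed = 1.6, decrement = 0.1,
                               rise_slowing = 0) {
  stopifnot(speed > 0, decrement >= 0, decrement < 1, rise_slowing >= 0)
  structure(list(speed = speed, decrement = decrement,
                 rise_slowing = rise_slowing), class = "propagation_params")
}

#' Per-somite onset delays and amplitude scalings of a travelling wave
#'
#' Events start at the rostral-most somite and travel caudally: somite `s`
#' fires `distance(s)/speed` seconds later with amplitude scaled by
#' `(1 - decrement)^distance_mm`.
#'
#' @param phantom an `embryo_phantom`.
#' @param prop a [propagation_params()].
#' @return data.frame with `somite`, `distance_mm` (from the rostral
#'   reference), `delay_s`, `amp_scale` and `rise_scale`.
#' @export
propagate_wave <- function(phantom, prop) {
  d_mm <- (phantom$somite_centroids[, "x_um"] -
           phantom$somite_centroids[1, "x_um"]) / 1000
  data.frame(
    somite = seq_len(phantom$n_somites),
    distance_mm = d_mm,
    delay_s = d_mm / prop$speed,
    amp_scale = (1 - prop$decrement)^d_mm,
    rise_scale = 1 + prop$rise_slowing * d_mm
  )
}
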