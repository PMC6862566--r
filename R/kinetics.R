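# linearly interpolated level-crossing times on a sampled trace.
# rising: last upward crossing of `level` strictly before the peak;
# falling: first downward crossing at or after the peak. NA when the
# trace never crosses the level on that side (truncated event).
crossing_up <- function(t, y, level, ip) {
  if (ip < 2) return(NA_real_)
  for (i in (ip - 1):1) {
    if (y[i] < level && y[i + 1] >= level)
      return(t[i] + (level - y[i]) / (y[i + 1] - y[i]) * (t[i + 1] - t[i]))
  }
  NA_real_
}
crossing_down <- function(t, y, level, ip) {
  if (ip >= length(y)) return(NA_real_)
  for (i in ip:(length(y) - 1)) {
    if (y[i] >= level && y[i + 1] < level)
      return(t[i] + (y[i] - level) / (y[i] - y[i + 1]) * (t[i + 1] - t[i]))
  }
  NA_real_
}

#' Kinetic parameters of one event
#'
#' Crossing-based event kinetics in the Clampfit convention: the baseline
#' is the mean of the frames immediately preceding the event (zero when
#' none exist), the amplitude is peak minus baseline, and the 10/50/90\%
#' levels of the amplitude are located by linear interpolation between
#' samples. Reported parameters: `time_to_peak` (from the 10\% rising
#' crossing), `peak_amplitude`, `rise_10_90`, `decay_90_10`, `half_width`
#' (width at half height) and `duration` (10\% up to 10\% down). Events
#' cut by the recording edges are flagged `truncated` and their missing
#' crossings reported as `NA`; events with non-positive amplitude are
#' rejected with an explicit status.
#'
#' @param values numeric trace (or an `id_trace`).
#' @param dt frame interval, seconds (taken from an `id_trace` input).
#' @param window one-row data.frame with `start`, `end`, `peak` from
#'   [segment_events()].
#' @param baseline_frames frames averaged before the event for the
#'   baseline (default 5).
#' @return one-row data.frame of the kinetic parameters plus `status`
#'   ("ok", "rejected", "truncated") and `truncated`.
#' @export
event_kinetics <- function(values, dt = NULL, window, baseline_frames = 5) {
  if (inherits(values, "id_trace")) {
    dt <- values$frame_interval
    values <- values$values
  }
  stopifnot(!is.null(dt), dt > 0, window$start <= window$peak,
            window$peak <= window$end)
  n <- length(values)
  base <- if (window$start > 1)
    mean(values[max(1, window$start - baseline_frames):(window$start - 1)])
  else 0
  a <- max(1, window$start - 1); b <- min(n, window$end + 1)
  y <- values[a:b] - base
  t <- ((a:b) - 0.5) * dt
  ip <- window$peak - a + 1
  amp <- y[ip]
  out <- data.frame(time_to_peak = NA_real_, peak_amplitude = amp,
                    rise_10_90 = NA_real_, decay_90_10 = NA_real_,
                    half_width = NA_real_, duration = NA_real_,
                    status = "ok", truncated = FALSE,
                    stringsAsFactors = FALSE)
  if (!is.finite(amp) || amp <= 0) { out$status <- "rejected"; return(out) }
  up <- vapply(c(0.1, 0.5, 0.9) * amp, function(L) crossing_up(t, y, L, ip),
               numeric(1))
  dn <- vapply(c(0.9, 0.5, 0.1) * amp, function(L) crossing_down(t, y, L, ip),
               numeric(1))
  out$rise_10_90 <- up[3] - up[1]
  out$time_to_peak <- t[ip] - up[1]
  out$decay_90_10 <- dn[3] - dn[1]
  out$half_width <- dn[2] - up[2]
  out$duration <- dn[3] - up[1]
  if (anyNA(c(up, dn))) { out$truncated <- TRUE; out$status <- "truncated" }
  out
}

#' Kinetics table for all events of a trace
#' @inheritParams event_kinetics
#' @param events data.frame from [segment_events()].
#' @export
events_kinetics <- function(values, dt = NULL, events, baseline_frames = 5) {
  rows <- lapply(seq_len(nrow(events)), function(i)
    event_kinetics(values, dt, events[i, ], baseline_frames))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- event_kinetics(numeric(0), 1,
                                          data.frame(start = 1, end = 1,
                                                     peak = 1))[0, ]
  cbind(events, out)
}

#' Mean event frequency of a recording
#' @param events event count, or a data.frame of events.
#' @param duration recording length, seconds (> 0).
#' @return frequency in Hz.
#' @export
series_frequency <- function(events, duration) {
  if (duration <= 0) stop("recording duration must be positive")
  n <- if (is.data.frame(events)) nrow(events) else events
  n / duration
}

#' Resample a photon-count trace to a lower rate
#'
#' Emulates a longer camera integration time: consecutive samples falling
#' into each `1/target_rate` bin are summed (photon-count semantics), so
#' total counts are conserved. The target rate must not exceed the source
#' rate.
#'
#' @param values numeric trace of per-frame counts.
#' @param source_rate,target_rate Hz.
#' @return list with `values` and `rate = target_rate`.
#' @export
resample_trace <- function(values, source_rate, target_rate) {
  stopifnot(source_rate > 0, target_rate > 0)
  if (target_rate > source_rate * (1 + 1e-9))
    stop("target rate exceeds the source rate")
  tstart <- (seq_along(values) - 1) / source_rate
  bin <- floor(tstart * target_rate + 1e-9) + 1
  out <- vapply(split(values, bin), sum, numeric(1))
  names(out) <- NULL
  list(values = out, rate = target_rate)
}
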