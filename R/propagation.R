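#' Group consecutive somites into analysis ROIs
#'
#' Somite ROIs are merged in rostro-caudal order into groups of
#' `group_size` (default 3, matching how ROIs are drawn over somites in
#' threes); a trailing remainder group is kept if it holds at least one
#' somite. Group centroids are area-weighted means of member centroids.
#'
#' @param phantom an `embryo_phantom`.
#' @param group_size somites per group (>= 1).
#' @return list of groups, each with `somites`, `px` (pixel indices),
#'   `centroid_um` and `distance_mm` from the rostral-most group centroid.
#' @export
group_somite_rois <- function(phantom, group_size = 3L) {
  if (phantom$n_somites < 1) stop("phantom has no somites")
  stopifnot(group_size >= 1)
  idx <- split(seq_len(phantom$n_somites),
               ceiling(seq_len(phantom$n_somites) / group_size))
  groups <- lapply(idx, function(s) {
    areas <- lengths(phantom$somite_px[s])
    cx <- sum(phantom$somite_centroids[s, "x_um"] * areas) / sum(areas)
    cy <- sum(phantom$somite_centroids[s, "y_um"] * areas) / sum(areas)
    list(somites = s, px = unlist(phantom$somite_px[s]),
         centroid_um = c(x_um = cx, y_um = cy))
  })
  x0 <- groups[[1]]$centroid_um["x_um"]
  for (g in seq_along(groups))
    groups[[g]]$distance_mm <- unname(groups[[g]]$centroid_um["x_um"] - x0) / 1000
  names(groups) <- NULL
  groups
}

#' Onset time of an event in one ROI trace
#'
#' The time of the 50\% rising-amplitude crossing (linear interpolation),
#' the same convention the kinetics use; robust to the amplitude
#' decrement along the axis, unlike a fixed-threshold crossing. ROIs
#' whose amplitude is not positive are excluded (`NA`).
#'
#' @param values ROI trace.
#' @param dt frame interval, seconds.
#' @param window event window (`start`, `end`, `peak`).
#' @param baseline_frames frames averaged before the window.
#' @return onset time in seconds, or `NA`.
#' @export
onset_time <- function(values, dt, window, baseline_frames = 5) {
  n <- length(values)
  base <- if (window$start > 1)
    mean(values[max(1, window$start - baseline_frames):(window$start - 1)])
  else 0
  a <- max(1, window$start - 1); b <- min(n, window$end + 1)
  y <- values[a:b] - base
  t <- ((a:b) - 0.5) * dt
  ip <- which.max(y)
  if (y[ip] <= 0) return(NA_real_)
  crossing_up(t, y, 0.5 * y[ip], ip)
}

#' Wave speed from onset times along the body axis
#'
#' Ordinary least-squares fit of onset time against rostro-caudal
#' distance over all ROIs; the speed is the reciprocal slope and the fit
#' r-squared is reported as a quality flag. Zero slope is reported as
#' infinite speed (synchronous firing); a negative slope is flagged as
#' caudo-rostral.
#'
#' @param onsets per-ROI onset times, seconds (`NA` allowed).
#' @param distances_mm per-ROI distances from the rostral reference.
#' @param amplitudes optional per-ROI amplitudes, carried through.
#' @return A `propagation_result`: `speed_mm_s`, `r2`, `direction`
#'   ("rostro-caudal", "caudo-rostral" or "synchronous"), `n_roi`, and
#'   the per-ROI table.
#' @export
wave_speed <- function(onsets, distances_mm, amplitudes = NULL) {
  ok <- is.finite(onsets) & is.finite(distances_mm)
  if (sum(ok) < 2) stop("need at least two ROIs with valid onsets")
  fit <- stats::lm(onsets[ok] ~ distances_mm[ok])
  slope <- unname(stats::coef(fit)[2])
  sst <- sum((onsets[ok] - mean(onsets[ok]))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  if (abs(slope) < 1e-9) {
    speed <- Inf; dir <- "synchronous"
  } else if (slope < 0) {
    speed <- 1 / abs(slope); dir <- "caudo-rostral"
  } else {
    speed <- 1 / slope; dir <- "rostro-caudal"
  }
  tab <- data.frame(distance_mm = distances_mm, onset_s = onsets)
  if (!is.null(amplitudes)) tab$amplitude <- amplitudes
  structure(list(speed_mm_s = speed, r2 = r2, direction = dir,
                 n_roi = sum(ok), per_roi = tab),
            class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf("wave speed: %.3g mm/s (%s, r2 = %.3f, %d ROIs)\n",
              x$speed_mm_s, x$direction, x$r2, x$n_roi))
  invisible(x)
}

#' Propagation analysis of grouped-ROI traces
#'
#' Segments events on the summed trace, then for each event measures the
#' 50\% onset and amplitude in every grouped ROI and fits the wave speed.
#' Events with a positive amplitude in fewer than two ROIs are labelled
#' non-propagating and excluded from speed statistics.
#'
#' @param traces `n_frames x n_roi` matrix of ROI traces.
#' @param dt frame interval, seconds.
#' @param distances_mm per-ROI distances.
#' @param merge_gap frames bridged when segmenting the summed trace.
#' @param baseline_frames baseline window per ROI.
#' @return list of per-event results (`propagation_result` or the label
#'   `"non-propagating"`).
#' @export
analyze_propagation <- function(traces, dt, distances_mm, merge_gap = 2L,
                                baseline_frames = 5) {
  stopifnot(ncol(traces) == length(distances_mm))
  total <- rowSums(traces)
  total <- total - stats::median(total)
  total[total < 0] <- 0
  events <- segment_events(total, merge_gap)
  lapply(seq_len(nrow(events)), function(i) {
    win <- events[i, ]
    ons <- apply(traces, 2, onset_time, dt = dt, window = win,
                 baseline_frames = baseline_frames)
    amps <- apply(traces, 2, function(v) {
      base <- if (win$start > 1)
        mean(v[max(1, win$start - baseline_frames):(win$start - 1)]) else 0
      max(v[win$start:win$end]) - base
    })
    if (sum(is.finite(ons)) < 2) return("non-propagating")
    wave_speed(ons, distances_mm, amps)
  })
}
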