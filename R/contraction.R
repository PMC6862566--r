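#' Dual-ROI intensity ratio trace for contraction detection
#'
#' Two identical ROIs, one on a somite in the embryo trunk and one in the
#' medium just outside the embryo: the ratio of their mean intensities
#' changes whenever a contraction displaces the embryo. Baseline
#' statistics (median and scaled median absolute deviation) are taken
#' over the whole trace, since contractions are sparse.
#'
#' @param mov a [movie()] (transmitted light).
#' @param roi_on logical mask on a somite.
#' @param roi_off logical mask outside the embryo, same pixel count.
#' @param embryo_mask optional logical mask used to validate `roi_off`.
#' @return A `contraction_trace`: `ratio_values`, `frame_interval`,
#'   `baseline_median`, `baseline_spread`.
#' @export
dual_roi_ratio <- function(mov, roi_on, roi_off, embryo_mask = NULL) {
  pair <- roi_pair(roi_on, roi_off, embryo_mask)
  on <- vapply(seq_len(n_frames(mov)),
               function(f) mean(mov$frames[, , f][pair$roi1]), numeric(1))
  off <- vapply(seq_len(n_frames(mov)),
                function(f) mean(mov$frames[, , f][pair$roi2]), numeric(1))
  if (any(off <= 0))
    stop(sprintf("off-embryo ROI mean is zero at frame %d",
                 which(off <= 0)[1]))
  r <- on / off
  structure(list(ratio_values = r, frame_interval = mov$frame_interval,
                 baseline_median = stats::median(r),
                 baseline_spread = stats::mad(r)),
            class = "contraction_trace")
}

#' Detect contractions on a dual-ROI ratio trace
#'
#' A contraction is a maximal run of frames where the ratio deviates from
#' the baseline median by more than `k` times the baseline spread; runs
#' closer than the refractory period are merged into one contraction.
#'
#' @param trace a `contraction_trace`.
#' @param k spread multiplier (> 0, default 5).
#' @param refractory merge window, seconds.
#' @return list: `events` (data.frame `start`, `end`, `peak`),
#'   `frequency` (Hz), `duration` (s).
#' @export
detect_contractions <- function(trace, k = 5, refractory = 0.5) {
  if (k <= 0) stop("spread multiplier k must be positive")
  dev <- abs(trace$ratio_values - trace$baseline_median)
  spread <- trace$baseline_spread
  excited <- if (spread > 0) dev > k * spread else dev > 0
  gap <- max(0L, ceiling(refractory / trace$frame_interval) - 1L)
  ev <- segment_events(as.numeric(excited), merge_gap = gap)
  # peak = frame of largest deviation within the run
  ev$peak <- vapply(seq_len(nrow(ev)), function(i)
    ev$start[i] + which.max(dev[ev$start[i]:ev$end[i]]) - 1L, numeric(1))
  dur <- length(trace$ratio_values) * trace$frame_interval
  list(events = ev, frequency = nrow(ev) / dur, duration = dur)
}

#' Paired percent change in event frequency
#'
#' Descriptive before/after comparison within the same embryos: the
#' per-embryo percent change `100 * (post - pre) / pre` and its group
#' mean and standard error. Embryos with zero pre-drug frequency cannot
#' yield a percent change; they are flagged and excluded.
#'
#' @param pre_freq,post_freq per-embryo frequencies, Hz.
#' @return list: `per_embryo` data.frame (`pre`, `post`, `pct_change`,
#'   `excluded`), `mean_pct_change`, `sem_pct_change`, `n`.
#' @export
paired_frequency_change <- function(pre_freq, post_freq) {
  stopifnot(length(pre_freq) == length(post_freq))
  excluded <- pre_freq == 0
  pct <- ifelse(excluded, NA_real_, 100 * (post_freq - pre_freq) / pre_freq)
  ok <- pct[!excluded]
  list(per_embryo = data.frame(pre = pre_freq, post = post_freq,
                               pct_change = pct, excluded = excluded),
       mean_pct_change = if (length(ok)) mean(ok) else NA_real_,
       sem_pct_change = if (length(ok) > 1) stats::sd(ok) / sqrt(length(ok))
                        else NA_real_,
       n = length(ok))
}
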