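#' Paired analysis/background ROIs
#'
#' ROI1 covers the embryo region to be analysed; ROI2 is the same drawn
#' region moved to an artifact-free area of the medium outside the embryo,
#' so both contain the same number of pixels.
#'
#' @param roi1,roi2 logical masks of identical image shape and equal pixel
#'   count; `roi2` must not intersect `embryo_mask` when one is given.
#' @param embryo_mask optional logical mask of the embryo.
#' @export
roi_pair <- function(roi1, roi2, embryo_mask = NULL) {
  stopifnot(is.logical(roi1), is.logical(roi2),
            all(dim(roi1) == dim(roi2)))
  if (sum(roi1) == 0 || sum(roi2) == 0) stop("ROIs must be non-empty")
  if (sum(roi1) != sum(roi2))
    stop("ROI1 and ROI2 must contain the same number of pixels")
  if (!is.null(embryo_mask) && any(roi2 & embryo_mask))
    stop("ROI2 must lie outside the embryo")
  structure(list(roi1 = roi1, roi2 = roi2), class = "roi_pair")
}

#' General background (GB) of one frame
#'
#' Detector noise estimated from the off-embryo ROI:
#' `GB = mean(ROI2 pixels) + 2 * SD(ROI2 pixels)`, computed per frame with
#' the sample standard deviation. A single-pixel ROI has zero SD.
#'
#' @param frame numeric matrix.
#' @param roi2 logical mask, non-empty.
#' @export
compute_gb <- function(frame, roi2) {
  if (sum(roi2) == 0) stop("ROI2 is empty")
  v <- frame[roi2]
  s <- if (length(v) > 1) stats::sd(v) else 0
  mean(v) + 2 * s
}

#' Embryo background (EB) from reference frames
#'
#' The spontaneous substrate glow over the embryo, estimated once per
#' recording from frames free of visible transients:
#' `EB = mean_i(meanROI1_i - meanROI2_i) + 2 * SD_i(differences)` over the
#' chosen reference frames (default 15). Negative estimates are clamped to
#' zero, since a background term cannot be negative.
#'
#' @param mov a [movie()].
#' @param pair a [roi_pair()].
#' @param reference_frames integer frame indices (default length 15).
#' @param n_ref required number of reference frames.
#' @export
compute_eb <- function(mov, pair, reference_frames, n_ref = 15) {
  if (length(reference_frames) < n_ref)
    stop(sprintf("need %d reference frames, got %d", n_ref,
                 length(reference_frames)))
  if (any(reference_frames < 1 | reference_frames > n_frames(mov)))
    stop("reference frames outside the movie")
  d <- vapply(reference_frames, function(f) {
    fr <- mov$frames[, , f]
    mean(fr[pair$roi1]) - mean(fr[pair$roi2])
  }, numeric(1))
  max(0, mean(d) + 2 * stats::sd(d))
}

#' Pick reference frames automatically
#'
#' Fallback for the interactive selection step: the `n_ref` frames with
#' the lowest ROI1 mean intensity, i.e. the quietest frames.
#'
#' @inheritParams compute_eb
#' @export
select_reference_frames <- function(mov, pair, n_ref = 15) {
  m <- vapply(seq_len(n_frames(mov)),
              function(f) mean(mov$frames[, , f][pair$roi1]), numeric(1))
  sort(order(m)[seq_len(min(n_ref, length(m)))])
}

#' Per-frame detection thresholds (GB + EB)
#'
#' The final minimum intensity for transient detection in each frame is
#' the frame's general background plus the recording-wide embryo
#' background.
#'
#' @inheritParams compute_eb
#' @param reference_frames frame indices, or `NULL` to use
#'   [select_reference_frames()].
#' @return A `background_estimate`: `gb_per_frame`, scalar `eb`,
#'   `threshold_per_frame = gb + eb`, and the reference frame indices.
#' @export
frame_thresholds <- function(mov, pair, reference_frames = NULL, n_ref = 15) {
  if (is.null(reference_frames))
    reference_frames <- select_reference_frames(mov, pair, n_ref)
  gb <- vapply(seq_len(n_frames(mov)),
               function(f) compute_gb(mov$frames[, , f], pair$roi2),
               numeric(1))
  eb <- compute_eb(mov, pair, reference_frames, n_ref)
  structure(list(gb_per_frame = gb, eb = eb,
                 threshold_per_frame = gb + eb,
                 reference_frames = as.integer(reference_frames)),
            class = "background_estimate")
}
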