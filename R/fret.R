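#' Split a split-field movie into registered donor and FRET stacks
#'
#' The camera field holds the donor channel in the left half and the FRET
#' channel in the right half (image-splitter layout). The FRET half is
#' aligned to the donor half by the integer translation maximizing the
#' normalized cross-correlation on a reference frame; the same offset is
#' applied to every frame. A correlation peak on the search-window edge
#' triggers a warning (possible misregistration).
#'
#' @param mov a [movie()] with even width.
#' @param search integer search radius, pixels.
#' @param ref_frame reference frame index (default: brightest frame).
#' @return list: `donor`, `fret` (aligned `H x W/2 x T` arrays), `offset`
#'   (`c(dy, dx)` applied to the FRET half).
#' @export
split_and_register <- function(mov, search = 10L, ref_frame = NULL) {
  d <- dim(mov$frames)
  if (d[2] %% 2 != 0) stop("field width must be even to split")
  w <- d[2] %/% 2L
  donor <- mov$frames[, 1:w, , drop = FALSE]
  fret <- mov$frames[, (w + 1):(2 * w), , drop = FALSE]
  if (is.null(ref_frame)) {
    tot <- vapply(seq_len(d[3]), function(f) sum(donor[, , f]), numeric(1))
    ref_frame <- which.max(tot)
  }
  a <- donor[, , ref_frame]
  b <- fret[, , ref_frame]
  best <- c(0L, 0L); best_cc <- -Inf
  for (dy in -search:search) for (dx in -search:search) {
    bs <- shift_matrix(b, dy, dx)
    cc <- suppressWarnings(stats::cor(as.vector(a), as.vector(bs)))
    if (is.finite(cc) && cc > best_cc) { best_cc <- cc; best <- c(dy, dx) }
  }
  if (any(abs(best) == search))
    warning("registration peak on the search-window edge; offset may be wrong")
  if (any(best != 0L))
    for (f in seq_len(d[3])) fret[, , f] <- shift_matrix(fret[, , f],
                                                         best[1], best[2])
  list(donor = donor, fret = fret, offset = as.integer(best))
}

#' Pixel-wise FRET/donor ratio stack
#'
#' The ratio image is computed pixel by pixel wherever the donor is above
#' an intensity floor (default: the 1st percentile of nonzero donor
#' pixels); elsewhere the ratio is undefined (`NA`).
#'
#' @param donor,fret co-registered `H x W x T` arrays.
#' @param donor_floor_pct percentile (0-100) of nonzero donor pixels used
#'   as the validity floor.
#' @return A `ratio_movie`: `donor`, `fret`, `ratio` stacks, `floor`, and
#'   `valid` (logical stack).
#' @export
ratio_stack <- function(donor, fret, donor_floor_pct = 1) {
  stopifnot(all(dim(donor) == dim(fret)))
  nz <- donor[donor > 0]
  if (length(nz) == 0) stop("donor stack has no positive pixels")
  floor_v <- stats::quantile(nz, donor_floor_pct / 100, names = FALSE)
  valid <- donor > floor_v
  if (!any(valid)) stop("validity mask is empty: donor floor too high")
  ratio <- array(NA_real_, dim(donor))
  ratio[valid] <- fret[valid] / donor[valid]
  structure(list(donor = donor, fret = fret, ratio = ratio,
                 valid = valid, floor = floor_v), class = "ratio_movie")
}

#' Mean ratio trace over an ROI
#' @param rm a `ratio_movie`.
#' @param roi logical mask.
#' @return per-frame mean of valid ratio pixels inside the ROI.
#' @export
roi_ratio_trace <- function(rm, roi) {
  vapply(seq_len(dim(rm$ratio)[3]), function(f) {
    r <- rm$ratio[, , f][roi]
    mean(r, na.rm = TRUE)
  }, numeric(1))
}

#' Quantify photobleaching of one channel
#'
#' Fits a mono-exponential to the channel's ROI means on event-free
#' frames and reports the fitted time constant and the percent decline at
#' a time horizon, `100 * (1 - exp(-horizon/tau))`. A non-decaying trace
#' yields `tau = Inf` and 0% decline.
#'
#' @param means per-frame channel means (event-free frames only).
#' @param times frame times, seconds (same length, >= 2 points).
#' @param horizon seconds (default 900, i.e. 15 min).
#' @return list: `tau` (s), `percent_decline` at the horizon, `n`.
#' @export
bleaching_summary <- function(means, times, horizon = 900) {
  stopifnot(length(means) == length(times))
  if (length(means) < 2) stop("need at least two event-free time points")
  if (any(means <= 0)) stop("channel means must be positive to fit a decay")
  fit <- stats::lm(log(means) ~ times)
  slope <- stats::coef(fit)[2]
  if (slope >= -1e-12)
    return(list(tau = Inf, percent_decline = 0, n = length(means)))
  tau <- -1 / slope
  list(tau = unname(tau),
       percent_decline = unname(100 * (1 - exp(-horizon / tau))),
       n = length(means))
}
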