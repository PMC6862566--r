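#' Movie container
#'
#' A calibrated frame stack: `frames` is a numeric `H x W x T` array in
#' camera output units, with the frame interval (s) and pixel scale
#' (um/pixel) needed to interpret it. Frame `i` spans
#' `[(i-1)*dt, i*dt)`; traces are evaluated at frame midpoints.
#'
#' @param frames numeric array `H x W x T` (values >= 0).
#' @param frame_interval seconds per frame.
#' @param pixel_scale micrometres per pixel.
#' @param channel label, e.g. "luminescence", "donor", "fret-split".
#' @export
movie <- function(frames, frame_interval, pixel_scale,
                  channel = "luminescence") {
  stopifnot(length(dim(frames)) == 3, frame_interval > 0, pixel_scale > 0)
  if (any(frames < 0)) stop("pixel values must be non-negative")
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_scale = pixel_scale, channel = channel),
            class = "cw_movie")
}

#' @export
print.cw_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("cw_movie [%s]: %dx%d px, %d frames at %.4g s/frame (%.3g um/px)\n",
              x$channel, d[1], d[2], d[3], x$frame_interval, x$pixel_scale))
  invisible(x)
}

n_frames <- function(mov) dim(mov$frames)[3]

# camera noise applied to an expected photon-count image (photons/frame)
apply_camera <- function(lambda, camera, shot_noise = TRUE) {
  counts <- if (shot_noise) stats::rpois(length(lambda), lambda) else lambda
  v <- counts * camera$gain
  if (camera$read_noise_sd > 0)
    v <- v + stats::rnorm(length(v), 0, camera$read_noise_sd)
  pmin(pmax(v, 0), 65535)
}

#' Per-somite photon-rate matrix for a luminescence run
#'
#' Builds one calcium trace per somite (with optional wave propagation
#' delays, amplitude decrement and caudal rise slowing), passes each
#' through the aequorin forward model, and returns the expected photon
#' rate per pixel for every somite and frame.
#'
#' @param phantom an `embryo_phantom`.
#' @param schedule a `spike_schedule`.
#' @param waveform a [transient_waveform()].
#' @param aq an [aequorin_model()].
#' @param sampling frame rate, Hz.
#' @param duration seconds.
#' @param prop optional [propagation_params()]; `NULL` means synchronous
#'   firing of all somites.
#' @param baseline resting calcium, uM.
#' @return list: `rates` (`n_somites x n_frames` photons/s/pixel), `ca`
#'   (same shape, uM), `delays` (the [propagate_wave()] table or NULL).
#' @export
somite_rate_matrix <- function(phantom, schedule, waveform, aq, sampling,
                               duration = NULL, prop = NULL, baseline = 0.1) {
  duration <- duration %||% schedule$duration
  nf <- ceiling(duration * sampling)
  rates <- matrix(0, phantom$n_somites, nf)
  camat <- matrix(0, phantom$n_somites, nf)
  delays <- if (!is.null(prop)) propagate_wave(phantom, prop) else NULL
  for (s in seq_len(phantom$n_somites)) {
    tc <- ca_timecourse(schedule, waveform, sampling, duration,
                        baseline = baseline,
                        onset_shift = if (is.null(delays)) 0 else delays$delay_s[s],
                        amp_scale = if (is.null(delays)) 1 else delays$amp_scale[s],
                        rise_scale = if (is.null(delays)) 1 else delays$rise_scale[s])
    camat[s, ] <- tc$ca
    rates[s, ] <- aequorin_emission(tc$ca, 1 / sampling, aq)$rate
  }
  list(rates = rates, ca = camat, delays = delays)
}

#' Render a photon-limited bioluminescence movie
#'
#' Per binned pixel and frame, expected photons are
#' `(somite signal + substrate glow over the embryo + dark rate) * dt`;
#' counts are Poisson draws scaled by the camera gain with additive read
#' noise, clipped to 16 bits. Identical seed and configuration give a
#' bit-identical movie.
#'
#' @param phantom an `embryo_phantom`.
#' @param rates `n_somites x n_frames` matrix of signal photon rates per
#'   pixel (photons/s), e.g. from [somite_rate_matrix()].
#' @param camera a [camera_model()]; its binned image shape must match the
#'   phantom.
#' @param seed integer seed.
#' @param shot_noise set `FALSE` to return expected values (noiseless).
#' @return a [movie()].
#' @export
render_luminescence_movie <- function(phantom, rates, camera, seed = 1,
                                      shot_noise = TRUE) {
  stopifnot(nrow(rates) == phantom$n_somites)
  h <- phantom$image_shape[1]; w <- phantom$image_shape[2]
  dt <- camera$integration_time
  nf <- ncol(rates)
  set.seed(seed)
  base <- matrix(camera$dark_rate * dt, h, w)
  base[phantom$trunk_px] <- base[phantom$trunk_px] +
    camera$substrate_glow_rate * dt
  frames <- array(0, c(h, w, nf))
  for (f in seq_len(nf)) {
    lam <- base
    for (s in seq_len(phantom$n_somites))
      lam[phantom$somite_px[[s]]] <- lam[phantom$somite_px[[s]]] +
        rates[s, f] * dt
    frames[, , f] <- apply_camera(lam, camera, shot_noise)
  }
  movie(frames, dt, phantom$pixel_scale, "luminescence")
}

# shift a matrix by (dy, dx) pixels with edge replication
shift_matrix <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dy, 1), h)
  ci <- pmin(pmax(seq_len(w) - dx, 1), w)
  m[ri, ci, drop = FALSE]
}

#' Render a split-field two-channel FRET movie
#'
#' Mimics an image splitter: the left half-field carries the donor channel
#' and the right half the FRET (acceptor) channel of the same embryo,
#' acquired truly simultaneously. Donor and FRET intensities move
#' oppositely with calcium while their pixel-wise ratio follows the
#' Twitch response exactly; a common multiplicative motion artifact is
#' applied to both channels during events (it cancels in the ratio), and
#' each channel's emissive capacity bleaches mono-exponentially with its
#' own time constant.
#'
#' @param phantom an `embryo_phantom` (the half-field geometry).
#' @param ca `n_somites x n_frames` calcium matrix (uM), frame midpoints.
#' @param twitch a [twitch_model()].
#' @param bleach a [bleaching_model()], or `NULL` for no bleaching.
#' @param motion_amplitude fractional common-mode intensity modulation at
#'   full activation (0 disables it).
#' @param camera a [camera_model()].
#' @param seed integer seed.
#' @param channel_offset integer `(dy, dx)` misalignment of the FRET
#'   half-field relative to the donor half, pixels.
#' @param base_rate donor photon rate per pixel at rest (photons/s).
#' @param background_rate off-embryo photon rate (photons/s).
#' @param shot_noise set `FALSE` for expected values.
#' @return a [movie()] of width `2 * W` (donor left, FRET right), with the
#'   ground-truth ratio traces in `attr(, "truth")`.
#' @export
render_fret_movie <- function(phantom, ca, twitch, bleach = bleaching_model(),
                              motion_amplitude = 0.05, camera = camera_model(
                                integration_time = 0.03, substrate_glow_rate = 0),
                              seed = 1, channel_offset = c(0L, 0L),
                              base_rate = 2000, background_rate = 20,
                              shot_noise = TRUE) {
  stopifnot(nrow(ca) == phantom$n_somites)
  h <- phantom$image_shape[1]; w <- phantom$image_shape[2]
  dt <- camera$integration_time
  nf <- ncol(ca)
  tmid <- (seq_len(nf) - 0.5) * dt
  ratio <- t(apply(ca, 1, twitch_response, dt = dt, model = twitch))
  act <- (ratio - twitch$r_min) / (twitch$r_max - twitch$r_min)
  bl_d <- if (is.null(bleach)) rep(1, nf) else bleach_remaining(tmid, bleach$donor_tau)
  bl_a <- if (is.null(bleach)) rep(1, nf) else bleach_remaining(tmid, bleach$acceptor_tau)
  set.seed(seed)
  frames <- array(0, c(h, 2L * w, nf))
  for (f in seq_len(nf)) {
    donor <- matrix(background_rate, h, w)
    fret <- matrix(background_rate, h, w)
    for (s in seq_len(phantom$n_somites)) {
      idx <- phantom$somite_px[[s]]
      m <- 1 + motion_amplitude * act[s, f]
      # donor + fret conserve total at fixed bleach; ratio is exact
      d <- base_rate * (1 + twitch$r_min) / (1 + ratio[s, f]) * m
      donor[idx] <- d * bl_d[f]
      fret[idx] <- d * ratio[s, f] * bl_a[f]
    }
    if (any(channel_offset != 0L))
      fret <- shift_matrix(fret, channel_offset[1], channel_offset[2])
    frames[, , f] <- apply_camera(cbind(donor, fret) * dt, camera, shot_noise)
  }
  out <- movie(frames, dt, phantom$pixel_scale, "fret-split")
  attr(out, "truth") <- list(ratio = ratio, ca = ca,
                             channel_offset = as.integer(channel_offset),
                             bleach = bleach)
  out
}

#' Render a transmitted-light contraction movie
#'
#' The embryo is a static texture (somite stripes on a darker trunk inside
#' a bright medium). During each scheduled contraction the embryo texture
#' is displaced laterally by `displacement_um` for `contraction_duration`
#' seconds, changing the content of somite-anchored ROIs; the uniform
#' medium outside the embryo is unaffected. Photon shot noise and camera
#' read noise as in [render_luminescence_movie()].
#'
#' @param phantom an `embryo_phantom`.
#' @param schedule a `spike_schedule` of contraction onsets.
#' @param displacement_um lateral displacement during a contraction.
#' @param camera a [camera_model()] (transmitted light is bright; the
#'   default uses a 4.2 Hz frame rate).
#' @param seed integer seed.
#' @param contraction_duration seconds each contraction lasts.
#' @param medium_rate,embryo_rate,stripe_contrast texture photon rates
#'   (photons/s/pixel) and somite stripe modulation depth.
#' @param shot_noise set `FALSE` for expected values.
#' @return a [movie()]; ground-truth onsets in `attr(, "truth")`.
#' @export
render_transmitted_movie <- function(phantom, schedule, displacement_um = 30,
                                     camera = camera_model(
                                       sensor_pixels = phantom$image_shape * 4L,
                                       integration_time = 1 / 4.2,
                                       substrate_glow_rate = 0, dark_rate = 0),
                                     seed = 1, contraction_duration = 0.2,
                                     medium_rate = 3000, embryo_rate = 1500,
                                     stripe_contrast = 0.4, shot_noise = TRUE) {
  h <- phantom$image_shape[1]; w <- phantom$image_shape[2]
  dt <- camera$integration_time
  nf <- ceiling(schedule$duration / dt)
  tex <- matrix(medium_rate, h, w)
  for (s in seq_len(phantom$n_somites))
    tex[phantom$somite_px[[s]]] <- embryo_rate *
      (1 + stripe_contrast * if (s %% 2 == 0) 1 else -1)
  shift_px <- if (displacement_um > 0)
    max(1L, round(displacement_um / phantom$pixel_scale)) else 0L
  tex_shift <- if (shift_px > 0) shift_matrix(tex, 0L, shift_px) else tex
  set.seed(seed)
  # fraction of each frame's integration window covered by a contraction
  coverage <- numeric(nf)
  t0 <- (seq_len(nf) - 1) * dt
  for (on in schedule$onsets) {
    lo <- pmax(t0, on)
    hi <- pmin(t0 + dt, on + contraction_duration)
    coverage <- coverage + pmax(hi - lo, 0) / dt
  }
  coverage <- pmin(coverage, 1)
  frames <- array(0, c(h, w, nf))
  for (f in seq_len(nf)) {
    lam <- ((1 - coverage[f]) * tex + coverage[f] * tex_shift) * dt
    frames[, , f] <- apply_camera(lam, camera, shot_noise)
  }
  out <- movie(frames, dt, phantom$pixel_scale, "transmitted")
  attr(out, "truth") <- list(onsets = schedule$onsets,
                             contraction_duration = contraction_duration,
                             coverage = coverage)
  out
}

#' Write a movie as a multi-page 16-bit grayscale TIFF
#' @param mov a [movie()].
#' @param path output file.
#' @export
write_movie_tiff <- function(mov, path) {
  pages <- lapply(seq_len(n_frames(mov)),
                  function(f) mov$frames[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as a movie
#' @param path TIFF file.
#' @param frame_interval,pixel_scale,channel acquisition metadata (TIFF
#'   carries none).
#' @export
read_movie_tiff <- function(path, frame_interval, pixel_scale,
                            channel = "luminescence") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) frames[, , f] <- pages[[f]] * 65535
  movie(frames, frame_interval, pixel_scale, channel)
}

#' Serialize ground truth beside a rendered movie
#' @param truth list of ground-truth fields (onsets, delays, parameters).
#' @param path JSON output path.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read serialized ground truth
#' @param path JSON file written by [write_ground_truth()].
#' @export
read_ground_truth <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
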