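#' Aequorin luminescence model
#'
#' Luminescence follows a Hill law in free calcium with cooperativity
#' `h = 2.5`: below saturation the photon rate scales as the 2.5 power of
#' calcium, which is what makes aequorin blind to resting levels and sharp
#' around peaks. The half-saturation constant defaults to 10 uM so the
#' physiological 0.05-1 uM range sits in the power-law regime. The
#' photoprotein is consumed as it emits when `consumption = TRUE`, and the
#' finite off-rate of the indicator is modelled as an exponential release:
#' light tracks calcium rises instantly and decays with half-time
#' `off_half_time` when calcium falls.
#'
#' @param h Hill cooperativity (dimensionless).
#' @param K half-saturation constant, uM.
#' @param max_rate photons per second per unit photoprotein at saturation.
#' @param pool initial photoprotein amount per pixel (arbitrary units).
#' @param consumption logical; deplete the pool as photons are emitted.
#' @param yield photons obtainable per unit photoprotein.
#' @param off_half_time indicator off half-time, seconds (0.4-0.8 s range;
#'   default mid-range).
#' @export
aequorin_model <- function(h = 2.5, K = 10, max_rate = 1.5e4, pool = 1,
                           consumption = FALSE, yield = 1,
                           off_half_time = 0.6) {
  stopifnot(h > 0, K > 0, max_rate >= 0, pool >= 0, yield > 0,
            off_half_time > 0)
  structure(list(h = h, K = K, max_rate = max_rate, pool = pool,
                 consumption = consumption, yield = yield,
                 off_half_time = off_half_time), class = "aequorin_model")
}

# fractional saturation of the Hill law
hill_frac <- function(ca, h, K) ca^h / (K^h + ca^h)

# indicator off-kinetics: the emitted signal follows increases of the
# driving signal instantaneously (binding/attack is fast on the frame
# timescale) and relaxes toward it first-order with the off half-time
# when the drive falls. Steady state equals the input.
release_filter <- function(x, dt, half_time) {
  a <- 1 - exp(-dt * log(2) / half_time)
  y <- numeric(length(x))
  prev <- x[1]
  for (i in seq_along(x)) {
    prev <- max(x[i], prev + a * (x[i] - prev))
    y[i] <- prev
  }
  y
}

#' Expected photon rate from a calcium trace
#'
#' Instantaneous drive `pool(t) * max_rate * Ca^h / (K^h + Ca^h)`; the
#' emitted rate follows rises of the drive instantly and relaxes with the
#' indicator off half-time when calcium falls. With consumption enabled
#' the pool depletes as `d pool/dt = -R / yield` using the emitted rate,
#' so cumulative emitted photons can never exceed `pool * yield`.
#'
#' @param ca free-calcium trace, uM (>= 0).
#' @param dt sample interval, seconds.
#' @param model an [aequorin_model()].
#' @return list with `rate` (emitted photons/s), `raw_rate` (instantaneous
#'   drive) and `pool` (remaining photoprotein per sample).
#' @export
aequorin_emission <- function(ca, dt, model) {
  if (any(ca < 0)) stop("calcium trace must be non-negative")
  stopifnot(dt > 0)
  f <- hill_frac(ca, model$h, model$K)
  n <- length(ca)
  if (!model$consumption) {
    raw <- model$pool * model$max_rate * f
    return(list(rate = release_filter(raw, dt, model$off_half_time),
                raw_rate = raw, pool = rep(model$pool, n)))
  }
  a <- 1 - exp(-dt * log(2) / model$off_half_time)
  raw <- numeric(n); rate <- numeric(n); pool <- numeric(n)
  p <- model$pool
  prev <- p * model$max_rate * f[1]
  for (i in seq_len(n)) {
    x <- p * model$max_rate * f[i]
    raw[i] <- x
    r <- max(x, prev + a * (x - prev))
    # cannot emit more photons in one step than the pool supports
    r <- min(r, p * model$yield / dt)
    prev <- r
    rate[i] <- r
    p <- max(0, p - r * dt / model$yield)
    pool[i] <- p
  }
  list(rate = rate, raw_rate = raw, pool = pool)
}

#' Steady-state aequorin photon rate at constant calcium
#' @param ca calcium level(s), uM.
#' @param model an [aequorin_model()].
#' @export
aequorin_steady_rate <- function(ca, model) {
  if (any(ca < 0)) stop("calcium must be non-negative")
  model$pool * model$max_rate * hill_frac(ca, model$h, model$K)
}

#' Twitch-style ratiometric FRET indicator model
#'
#' The pixel-wise FRET/donor ratio responds to calcium through a Hill curve
#' with near-unity slope (`n = 1.04`), so the ratio is close to linear in
#' calcium below saturation. The apparent Kd is instrument/construct
#' specific; the default 2.8 uM keeps the sub-micromolar physiological
#' range well below saturation so the ratio stays near-linear in calcium.
#' Off-kinetics relax with half-time 0.5 s.
#'
#' @param n Hill slope.
#' @param Kd apparent dissociation constant, uM.
#' @param r_min,r_max ratio at zero and saturating calcium.
#' @param off_half_time seconds.
#' @export
twitch_model <- function(n = 1.04, Kd = 2.8, r_min = 1, r_max = 4,
                         off_half_time = 0.5) {
  stopifnot(n > 0, Kd > 0, r_min > 0, r_max > r_min, off_half_time > 0)
  structure(list(n = n, Kd = Kd, r_min = r_min, r_max = r_max,
                 off_half_time = off_half_time), class = "twitch_model")
}

#' Equilibrium FRET/donor ratio at a given calcium level
#' @param ca calcium, uM.
#' @param model a [twitch_model()].
#' @export
twitch_ratio <- function(ca, model) {
  if (any(ca < 0)) stop("calcium must be non-negative")
  model$r_min + (model$r_max - model$r_min) *
    hill_frac(ca, model$n, model$Kd)
}

#' Time-resolved FRET ratio response to a calcium trace
#'
#' Equilibrium ratio with rises followed instantly and falls relaxed by
#' the indicator off half-time.
#' @inheritParams twitch_ratio
#' @param dt sample interval, seconds.
#' @export
twitch_response <- function(ca, dt, model) {
  release_filter(twitch_ratio(ca, model), dt, model$off_half_time)
}

#' Photobleaching model for the two FRET channels
#'
#' Mono-exponential decay of each channel's emissive capacity under
#' continuous excitation. The default time constants are back-solved so
#' that 15 minutes of illumination bleaches 9\% of the donor and 19\% of
#' the acceptor, hence the acceptor bleaches faster and the FRET/donor
#' ratio of an event-free movie drifts downward.
#'
#' @param donor_tau,acceptor_tau time constants, seconds.
#' @export
bleaching_model <- function(donor_tau = -900 / log(1 - 0.09),
                            acceptor_tau = -900 / log(1 - 0.19)) {
  stopifnot(donor_tau > 0, acceptor_tau > 0)
  structure(list(donor_tau = donor_tau, acceptor_tau = acceptor_tau),
            class = "bleaching_model")
}

#' Remaining emissive fraction after continuous illumination
#' @param t illumination time, seconds.
#' @param tau bleaching time constant, seconds.
#' @export
bleach_remaining <- function(t, tau) exp(-t / tau)

#' Percent decline of emissive capacity at a time horizon
#' @inheritParams bleach_remaining
#' @export
bleach_percent_decline <- function(t, tau) 100 * (1 - exp(-t / tau))

#' Camera and acquisition model
#'
#' Photon-counting acquisition: per binned pixel and frame the expected
#' count is `(signal + glow + dark) * integration_time`; observed counts
#' are Poisson, scaled by `gain`, with additive Gaussian read noise,
#' clipped to the 16-bit range. The substrate glow (spontaneous
#' coelenterazine emission) applies only over the embryo; dark counts
#' apply everywhere.
#'
#' @param sensor_pixels unbinned sensor size `c(H, W)`.
#' @param binning integer binning factor (must divide both dimensions).
#' @param integration_time seconds per frame.
#' @param gain output units per photon.
#' @param read_noise_sd Gaussian read noise SD, output units.
#' @param substrate_glow_rate photons/s/pixel over the embryo.
#' @param dark_rate photons/s/pixel everywhere.
#' @export
camera_model <- function(sensor_pixels = c(512L, 512L), binning = 4L,
                         integration_time = 0.213, gain = 1,
                         read_noise_sd = 3, substrate_glow_rate = 2,
                         dark_rate = 5) {
  if (binning <= 0 || any(sensor_pixels %% binning != 0))
    stop("binning must be a positive divisor of both sensor dimensions")
  stopifnot(integration_time > 0, gain > 0, read_noise_sd >= 0,
            substrate_glow_rate >= 0, dark_rate >= 0)
  structure(list(sensor_pixels = as.integer(sensor_pixels),
                 binning = as.integer(binning),
                 image_shape = as.integer(sensor_pixels) %/% as.integer(binning),
                 integration_time = integration_time, gain = gain,
                 read_noise_sd = read_noise_sd,
                 substrate_glow_rate = substrate_glow_rate,
                 dark_rate = dark_rate), class = "camera_model")
}

#' Field of view from sensor geometry
#'
#' One side of the field of view: `sensor_px / binning / splits * scale`,
#' where `scale` is micrometres per binned pixel and `splits` is 2 for the
#' half-field of an image splitter.
#'
#' @param sensor_px unbinned pixels along the side.
#' @param binning binning factor.
#' @param scale_um micrometres per binned pixel.
#' @param splits number of optical splits along the side (1 or 2).
#' @return field of view in micrometres.
#' @export
fov_um <- function(sensor_px, binning, scale_um, splits = 1) {
  if (binning <= 0) stop("binning must be positive")
  stopifnot(sensor_px > 0, scale_um > 0, splits >= 1)
  sensor_px / binning / splits * scale_um
}

#' Acquisition frequency from integration time
#'
#' `1 / integration_time`, rounded to one decimal: 84 ms integration gives
#' 11.9 Hz, 213 ms gives 4.7 Hz.
#'
#' @param integration_s integration time per frame, seconds.
#' @return frequency in Hz, one decimal.
#' @export
acquisition_hz <- function(integration_s) {
  if (any(integration_s <= 0)) stop("integration time must be positive")
  round(1 / integration_s, 1)
}
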