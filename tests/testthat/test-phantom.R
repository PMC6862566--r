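test_that("phantom geometry satisfies its invariants", {
  ph <- make_embryo_phantom(12, somite_size = 100, pixel_scale = 12.8)
  # centroid spacing ~ somite size, strictly increasing rostro-caudally
  dx <- diff(ph$somite_centroids[, "x_um"])
  expect_true(all(dx > 0))
  expect_equal(dx, rep(8 * 12.8, 11))  # 100/12.8 rounds to 8 px
  # somite masks are disjoint and partition the trunk
  all_px <- unlist(ph$somite_px)
  expect_equal(anyDuplicated(all_px), 0L)
  expect_setequal(all_px, ph$trunk_px)
  expect_equal(sum(lengths(ph$somite_px)), length(ph$trunk_px))
  # masks lie inside the image
  expect_true(all(all_px >= 1 & all_px <= prod(ph$image_shape)))
})

test_that("a single-somite phantom has trunk equal to the somite", {
  ph <- make_embryo_phantom(1, image_shape = c(32L, 32L), pixel_scale = 25.6)
  expect_setequal(ph$somite_px[[1]], ph$trunk_px)
})

test_that("somites that do not fit raise an error naming the dimension", {
  expect_error(make_embryo_phantom(50, somite_size = 100,
                                   image_shape = c(64L, 64L),
                                   pixel_scale = 12.8),
               "width")
  expect_error(make_embryo_phantom(2, trunk_width = 4000,
                                   image_shape = c(64L, 64L),
                                   pixel_scale = 12.8),
               "height")
})

test_that("event schedules are Poisson with refractory thinning", {
  expect_error(schedule_events(-0.1, 100), "rate")
  empty <- schedule_events(0, 600, seed = 4)
  expect_length(empty$onsets, 0)
  # reproducibility
  a <- schedule_events(0.2, 300, seed = 9)
  b <- schedule_events(0.2, 300, seed = 9)
  expect_identical(a, b)
  # refractory respected, onsets increasing, amplitudes positive
  s <- schedule_events(0.5, 600, refractory = 1, seed = 2)
  expect_true(all(diff(s$onsets) >= 1))
  expect_true(all(s$amplitudes > 0))
  # Monte-Carlo mean count ~ rate * duration (refractory is short)
  counts <- vapply(1:40, function(k)
    length(schedule_events(0.2, 3000, seed = k)$onsets), numeric(1))
  # thinned mean = lambda/(1 + lambda*rho); allow 3 SE around it
  expected <- 0.2 * 3000 / (1 + 0.2 * 0.3)
  expect_lt(abs(mean(counts) - expected), 3 * sd(counts) / sqrt(40))
  expect_lt(abs(mean(counts) - 600), 0.1 * 600)
})

test_that("scenario presets encode the study conditions", {
  # tricaine: no events regardless of seed
  for (sd in 1:3)
    expect_length(scenario_schedule("tricaine", seed = sd)$onsets, 0)
  # fccp raises the observed rate 1.5x and disables mitochondrial uptake
  f <- scenario_schedule("fccp", duration = 3000, seed = 1)
  s <- scenario_schedule("sp2-short", duration = 3000, seed = 1)
  expect_false(f$mito_uptake)
  expect_true(s$mito_uptake)
  expect_gt(length(f$onsets), length(s$onsets))
  # compensated intensity realizes the nominal observed rate
  counts <- vapply(1:30, function(k)
    length(scenario_schedule("sp2-short", duration = 3000, seed = k)$onsets),
    numeric(1))
  expect_lt(abs(mean(counts) - 600), 3 * sd(counts) / sqrt(30))
  # long scenario: no events in the quiet gap between signalling periods
  l <- scenario_schedule("sp1-sp2-long", seed = 5)
  gap <- l$onsets > 7.5 * 3600 & l$onsets < 11 * 3600
  expect_false(any(gap))
  expect_true(any(l$onsets < 7.5 * 3600))
  expect_true(any(l$onsets > 11 * 3600))
})

test_that("calcium time courses superpose normalized pulses on a baseline", {
  wf <- transient_waveform("cytosol")
  flat <- ca_timecourse(schedule_events(0, 10, seed = 1), wf, 100, 10)
  expect_true(all(flat$ca == 0.1))
  # pulse peak equals the scheduled amplitude
  tc <- ca_timecourse(one_event_schedule(amplitude = 0.7), wf, 1000, 20)
  expect_equal(max(tc$ca) - 0.1, 0.7, tolerance = 1e-3)
  # doubling the decay constant doubles the noiseless 90-10 decay time
  decay_90_10 <- function(decay_tc) {
    w <- transient_waveform("cytosol", rise_tc = 0.06, decay_tc = decay_tc)
    y <- ca_timecourse(one_event_schedule(), w, 2000, 20)$ca - 0.1
    t <- (seq_along(y) - 0.5) / 2000
    ip <- which.max(y)
    t90 <- t[ip - 1 + min(which(y[ip:length(y)] <= 0.9 * y[ip]))]
    t10 <- t[ip - 1 + min(which(y[ip:length(y)] <= 0.1 * y[ip]))]
    t10 - t90
  }
  expect_equal(decay_90_10(0.8) / decay_90_10(0.4), 2, tolerance = 0.02)
  # time invariance: two identical well-separated events, identical shape
  sch2 <- structure(list(onsets = c(3, 12), amplitudes = c(0.5, 0.5),
                         duration = 20), class = "spike_schedule")
  y <- ca_timecourse(sch2, wf, 100, 20)$ca
  p1 <- y[301:800]; p2 <- y[1201:1700]
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("wave propagation gives d/v delays and geometric decrement", {
  ph <- make_embryo_phantom(12)
  d <- propagate_wave(ph, propagation_params(speed = 1.6, decrement = 0.1))
  expect_true(all(diff(d$delay_s) > 0))
  expect_true(all(diff(d$amp_scale) < 0))
  expect_equal(d$delay_s, d$distance_mm / 1.6)
  # a somite 1.6 mm caudal fires 1.0 s later
  expect_equal(approx(d$distance_mm, d$delay_s, xout = 1)$y * 1.6, 1)
  # decrement 0: all scalings 1; huge speed: all delays ~ 0
  d0 <- propagate_wave(ph, propagation_params(speed = 1e6, decrement = 0))
  expect_true(all(d0$amp_scale == 1))
  expect_true(all(d0$delay_s < 1e-5))
})

test_that("mitochondrial waveform mirrors the cytosolic rise but decays slower", {
  cy <- transient_waveform("cytosol")
  mt <- transient_waveform("mitochondria")
  expect_gt(mt$decay_tc, cy$decay_tc)
  t <- seq(0, 5, 1e-4)
  rise_10_90 <- function(w) {
    y <- calwave:::pulse_shape(t, w$rise_tc, w$decay_tc)
    t[min(which(y >= 0.9))] - t[min(which(y >= 0.1))]
  }
  expect_equal(rise_10_90(mt), rise_10_90(cy), tolerance = 0.01)
})
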