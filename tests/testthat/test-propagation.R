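test_that("somite grouping merges consecutive somites with a remainder", {
  ph9 <- make_embryo_phantom(9)
  expect_length(group_somite_rois(ph9, 3), 3)
  ph10 <- make_embryo_phantom(10)
  g10 <- group_somite_rois(ph10, 3)
  expect_length(g10, 4)
  expect_length(g10[[4]]$somites, 1)
  # group size 1 is the identity
  g1 <- group_somite_rois(ph9, 1)
  expect_length(g1, 9)
  expect_equal(g1[[4]]$px, ph9$somite_px[[4]])
  # distances start at zero and increase
  d <- vapply(g10, function(g) g$distance_mm, numeric(1))
  expect_equal(d[1], 0)
  expect_true(all(diff(d) > 0))
})

test_that("onset times are 50% crossings, equivariant under delays", {
  v <- c(0, 0, 1, 5, 10, 8, 3, 0)
  win <- data.frame(start = 3, end = 7, peak = 5)
  o <- onset_time(v, 0.5, win)
  expect_false(is.na(o))
  # delaying the trace by d frames shifts the onset by exactly d*dt
  v2 <- c(0, 0, v[-(1:2)], 0, 0)[1:10]
  v2 <- c(0, 0, v)  # two extra frames of baseline
  win2 <- data.frame(start = 5, end = 9, peak = 7)
  expect_equal(onset_time(v2, 0.5, win2), o + 2 * 0.5)
  # identical traces -> identical onsets; flat trace -> NA
  expect_equal(onset_time(v, 0.5, win), o)
  expect_true(is.na(onset_time(rep(0, 8), 0.5, win)))
})

test_that("wave speed comes from least squares on onset vs distance", {
  # hand least squares: onsets 0, 0.0625, 0.125 s at 0, 0.1, 0.2 mm
  res <- wave_speed(c(0, 0.0625, 0.125), c(0, 0.1, 0.2))
  expect_equal(res$speed_mm_s, 1.6)
  expect_equal(res$r2, 1)
  expect_equal(res$direction, "rostro-caudal")
  # synchronous onsets flag infinite speed
  syn <- wave_speed(c(0.5, 0.5, 0.5), c(0, 0.1, 0.2))
  expect_equal(syn$speed_mm_s, Inf)
  expect_equal(syn$direction, "synchronous")
  # reversed propagation is flagged
  rev <- wave_speed(c(0.125, 0.0625, 0), c(0, 0.1, 0.2))
  expect_equal(rev$direction, "caudo-rostral")
  expect_error(wave_speed(c(0.1, NA), c(0, 0.1)), "two ROIs")
})

test_that("noiseless rendered waves recover the generating speed within 5%", {
  ph <- make_embryo_phantom(12)
  groups <- group_somite_rois(ph, 3)
  dist <- vapply(groups, function(g) g$distance_mm, numeric(1))
  cam <- camera_model(integration_time = 1 / 11.9, read_noise_sd = 0,
                      substrate_glow_rate = 0, dark_rate = 0)
  for (v in c(0.5, 1.6, 5)) {
    srm <- somite_rate_matrix(ph, one_event_schedule(onset = 5),
                              transient_waveform("cytosol"),
                              aequorin_model(), 11.9, 20,
                              prop = propagation_params(speed = v))
    mv <- render_luminescence_movie(ph, srm$rates, cam, seed = 1,
                                    shot_noise = FALSE)
    traces <- sapply(groups, function(g)
      apply(mv$frames, 3, function(fr) mean(fr[g$px])))
    res <- analyze_propagation(traces, 1 / 11.9, dist)
    expect_s3_class(res[[1]], "propagation_result")
    expect_lt(abs(res[[1]]$speed_mm_s - v) / v, 0.05)
  }
})

test_that("amplitude decrement and caudal rise slowing leave their signatures", {
  ph <- make_embryo_phantom(12)
  groups <- group_somite_rois(ph, 3)
  dist <- vapply(groups, function(g) g$distance_mm, numeric(1))
  cam <- camera_model(integration_time = 1 / 11.9, read_noise_sd = 0,
                      substrate_glow_rate = 0, dark_rate = 0)
  srm <- somite_rate_matrix(ph, one_event_schedule(onset = 5),
                            transient_waveform("cytosol"), aequorin_model(),
                            11.9, 20,
                            prop = propagation_params(speed = 1.6,
                                                      decrement = 0.15,
                                                      rise_slowing = 0.5))
  mv <- render_luminescence_movie(ph, srm$rates, cam, seed = 1,
                                  shot_noise = FALSE)
  traces <- sapply(groups, function(g)
    apply(mv$frames, 3, function(fr) mean(fr[g$px])))
  res <- analyze_propagation(traces, 1 / 11.9, dist)[[1]]
  # amplitude strictly decreases rostro-caudally
  expect_true(all(diff(res$per_roi$amplitude) < 0))
  # rise 10-90 increases toward the tail (rank correlation > 0)
  ev <- data.frame(start = which(rowSums(traces) >
                                 min(rowSums(traces)) + 1)[1],
                   end = nrow(traces), peak = which.max(rowSums(traces)))
  rises <- apply(traces, 2, function(v) {
    w <- data.frame(start = max(2, which(v > v[1] + 1e-9)[1]),
                    end = length(v), peak = which.max(v))
    event_kinetics(v, 1 / 11.9, w, baseline_frames = 3)$rise_10_90
  })
  expect_gt(cor(rises, dist, method = "spearman"), 0)
})

test_that("events visible in fewer than two ROIs are non-propagating", {
  traces <- matrix(0, 50, 3)
  traces[20:25, 1] <- c(2, 6, 10, 7, 3, 1)  # only ROI 1 sees it
  res <- analyze_propagation(traces, 0.1, c(0, 0.3, 0.6))
  expect_equal(res[[1]], "non-propagating")
})
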