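test_that("rendered movies are reproducible and respect zero input", {
  ph <- tiny_phantom()
  rates <- matrix(30, ph$n_somites, 40)
  cam <- camera_model(integration_time = 0.1)
  m1 <- render_luminescence_movie(ph, rates, cam, seed = 7)
  m2 <- render_luminescence_movie(ph, rates, cam, seed = 7)
  expect_identical(m1$frames, m2$frames)
  m3 <- render_luminescence_movie(ph, rates, cam, seed = 8)
  expect_false(identical(m1$frames, m3$frames))
  # all rates zero, no noise -> all-zero movie
  cam0 <- camera_model(integration_time = 0.1, read_noise_sd = 0,
                       substrate_glow_rate = 0, dark_rate = 0)
  m0 <- render_luminescence_movie(ph, matrix(0, ph$n_somites, 10), cam0,
                                  seed = 1)
  expect_true(all(m0$frames == 0))
})

test_that("Poisson pixel statistics match the analytic mean", {
  ph <- tiny_phantom()
  rate <- 40
  cam <- camera_model(integration_time = 0.25, gain = 1, read_noise_sd = 0,
                      substrate_glow_rate = 3, dark_rate = 2)
  nf <- 400
  mv <- render_luminescence_movie(ph, matrix(rate, ph$n_somites, nf), cam,
                                  seed = 21)
  px <- ph$somite_px[[2]][1]
  vals <- mv$frames[cbind(arrayInd(px, ph$image_shape)[1],
                          arrayInd(px, ph$image_shape)[2], 1:nf)]
  lambda <- (rate + 3 + 2) * 0.25
  expect_lt(abs(mean(vals) - lambda), 3 * sqrt(lambda / nf))
  # off-embryo pixel sees only dark counts
  off <- which(!phantom_mask(ph))[1]
  ovals <- mv$frames[cbind(arrayInd(off, ph$image_shape)[1],
                           arrayInd(off, ph$image_shape)[2], 1:nf)]
  expect_lt(abs(mean(ovals) - 2 * 0.25), 3 * sqrt(2 * 0.25 / nf))
})

test_that("split-field FRET movies carry an exact pixel ratio", {
  ph <- tiny_phantom()
  sch <- one_event_schedule(duration = 10)
  ca <- t(sapply(seq_len(ph$n_somites), function(s)
    ca_timecourse(sch, transient_waveform("cytosol"), 20, 10)$ca))
  cam <- camera_model(sensor_pixels = ph$image_shape * 4L,
                      integration_time = 0.05, read_noise_sd = 0,
                      substrate_glow_rate = 0, dark_rate = 0)
  tw <- twitch_model()
  mv <- render_fret_movie(ph, ca, tw, bleach = NULL, motion_amplitude = 0.1,
                          camera = cam, seed = 1, shot_noise = FALSE)
  truth <- attr(mv, "truth")
  w <- ph$image_shape[2]
  px <- ph$somite_px[[3]][5]
  ij <- arrayInd(px, ph$image_shape)
  donor <- mv$frames[ij[1], ij[2], ]
  fret <- mv$frames[ij[1], ij[2] + w, ]
  # motion artifact is common-mode: the pixel ratio equals the model ratio
  expect_equal(fret / donor, truth$ratio[3, ], tolerance = 1e-10)
  # donor decreases while fret increases during the event
  expect_lt(which.min(donor), length(donor))
  expect_equal(which.max(fret), which.min(donor))
})

test_that("bleaching makes the FRET/donor ratio of quiet movies drift down", {
  ph <- tiny_phantom()
  ca <- matrix(0.1, ph$n_somites, 200)  # event-free
  cam <- camera_model(sensor_pixels = ph$image_shape * 4L,
                      integration_time = 1, read_noise_sd = 0,
                      substrate_glow_rate = 0, dark_rate = 0)
  mv <- render_fret_movie(ph, ca, twitch_model(), bleach = bleaching_model(),
                          camera = cam, seed = 1, shot_noise = FALSE)
  w <- ph$image_shape[2]
  px <- ph$somite_px[[2]][1]
  ij <- arrayInd(px, ph$image_shape)
  ratio <- mv$frames[ij[1], ij[2] + w, ] / mv$frames[ij[1], ij[2], ]
  expect_true(all(diff(ratio) < 0))
})

test_that("transmitted-light movies move only during contractions", {
  ph <- tiny_phantom()
  cam0 <- camera_model(sensor_pixels = ph$image_shape * 4L,
                       integration_time = 1 / 4.2, read_noise_sd = 0,
                       substrate_glow_rate = 0, dark_rate = 0)
  # displacement zero -> static movie
  sch <- one_event_schedule(duration = 10)
  mv0 <- render_transmitted_movie(ph, sch, displacement_um = 0, camera = cam0,
                                  seed = 1, shot_noise = FALSE)
  expect_true(all(mv0$frames == array(mv0$frames[, , 1], dim(mv0$frames))))
  # one event -> exactly one deviation interval in a somite ROI
  mv1 <- render_transmitted_movie(ph, sch, displacement_um = 30,
                                  camera = cam0, seed = 1, shot_noise = FALSE)
  roi <- phantom_mask(ph, 3)
  tr <- apply(mv1$frames, 3, function(fr) mean(fr[roi]))
  dev <- abs(tr - stats::median(tr)) > 1e-9
  expect_equal(sum(rle(dev)$values), 1)
  # an ROI fully outside the embryo stays flat
  out <- matrix(FALSE, ph$image_shape[1], ph$image_shape[2])
  out[1:4, 1:4] <- TRUE
  tro <- apply(mv1$frames, 3, function(fr) mean(fr[out]))
  expect_true(all(tro == tro[1]))
})

test_that("movies survive a 16-bit TIFF round trip", {
  ph <- tiny_phantom()
  mv <- render_luminescence_movie(ph, matrix(50, ph$n_somites, 5),
                                  camera_model(integration_time = 0.2),
                                  seed = 2)
  mv$frames <- round(mv$frames)
  path <- withr::local_tempfile(fileext = ".tif")
  write_movie_tiff(mv, path)
  back <- read_movie_tiff(path, mv$frame_interval, mv$pixel_scale)
  expect_equal(round(back$frames), mv$frames, tolerance = 1e-6)
  # ground truth JSON round trip
  gt <- list(onsets = c(1.5, 3.25), amplitudes = c(0.6, 0.7), seed = 2)
  jp <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gt, jp)
  expect_equal(read_ground_truth(jp)$onsets, gt$onsets)
})
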