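test_that("components are gated by size, intensity and trunk location", {
  frame <- matrix(0, 16, 16)
  mask <- matrix(TRUE, 16, 16)
  # a 3x4 block (12 px) passes the 'larger than 9 adjacent pixels' rule
  frame[5:7, 5:8] <- 10
  det <- detect_components(frame, 5, mask)
  expect_length(det$sizes, 1)
  expect_equal(det$sizes, 12L)
  # a 3x3 block (9 px) is rejected: 9 is not larger than 9
  frame9 <- matrix(0, 16, 16); frame9[5:7, 5:7] <- 10
  expect_length(detect_components(frame9, 5, mask)$sizes, 0)
  # bright block outside the mask is ignored
  off_mask <- matrix(FALSE, 16, 16); off_mask[12:15, 12:15] <- TRUE
  expect_length(detect_components(frame, 5, off_mask)$sizes, 0)
  # pixels exactly at the threshold are not suprathreshold
  expect_length(detect_components(frame, 10, mask)$sizes, 0)
  expect_error(detect_components(frame, 5, matrix(TRUE, 8, 8)), "shape")
  expect_error(detection_params(connectivity = 6), "connectivity")
})

test_that("labeling matches a brute-force flood fill for both connectivities", {
  set.seed(42)
  for (rep in 1:6) {
    bin <- matrix(runif(32 * 32) < 0.35, 32, 32)
    for (conn in c(4L, 8L)) {
      mine <- calwave:::label_components(bin, conn)
      oracle <- flood_fill_label(bin, conn)
      expect_true(same_partition(mine, oracle),
                  label = sprintf("rep %d conn %d", rep, conn))
    }
  }
})

test_that("4-connectivity labeling agrees with EBImage::bwlabel", {
  skip_if_not_installed("EBImage")
  set.seed(7)
  bin <- matrix(runif(32 * 32) < 0.3, 32, 32)
  mine <- calwave:::label_components(bin, 4L)
  ref <- EBImage::bwlabel(bin * 1)
  expect_true(same_partition(mine, matrix(as.integer(ref), 32, 32)))
})

test_that("raising the minimum size never adds components", {
  set.seed(3)
  frame <- matrix(rpois(32 * 32, 2), 32, 32)
  mask <- matrix(TRUE, 32, 32)
  ns <- vapply(c(1, 5, 10, 20, 50), function(ms)
    length(detect_components(frame, 3, mask,
                             detection_params(min_component_size = ms))$sizes),
    numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("integrated density sums raw pixel values over accepted components", {
  mask <- matrix(TRUE, 16, 16)
  frames <- array(0, c(16, 16, 3))
  frames[2:5, 2:5, 2] <- 7          # 16 px, sum 112
  frames[10:13, 10:13, 2] <- 3      # disjoint 16 px, sum 48
  mv <- movie(frames, 0.1, 12.8)
  tr <- integrated_density(mv, rep(1, 3), mask)
  expect_equal(tr$values, c(0, 112 + 48, 0))
  # additivity: a movie with only one of the blocks contributes its sum
  f1 <- array(0, c(16, 16, 3)); f1[2:5, 2:5, 2] <- 7
  tr1 <- integrated_density(movie(f1, 0.1, 12.8), rep(1, 3), mask)
  f2 <- array(0, c(16, 16, 3)); f2[10:13, 10:13, 2] <- 3
  tr2 <- integrated_density(movie(f2, 0.1, 12.8), rep(1, 3), mask)
  expect_equal(tr$values, tr1$values + tr2$values)
})

test_that("noiseless events are recovered exactly, nonzero only during them", {
  ph <- tiny_phantom()
  sch <- structure(list(onsets = c(4, 12), amplitudes = c(0.6, 0.8),
                        duration = 20), class = "spike_schedule")
  srm <- somite_rate_matrix(ph, sch, transient_waveform("cytosol"),
                           aequorin_model(), 4.7, 20)
  cam <- camera_model(integration_time = 1 / 4.7, read_noise_sd = 0,
                      substrate_glow_rate = 0, dark_rate = 0)
  mv <- render_luminescence_movie(ph, srm$rates, cam, seed = 1,
                                  shot_noise = FALSE)
  # a small margin above the noise-free background ends the exponential tails
  tr <- integrated_density(mv, rep(1, n_frames(mv)), phantom_mask(ph))
  ev <- segment_events(tr, merge_gap = 1L)
  expect_equal(nrow(ev), 2)
  peaks <- (ev$peak - 0.5) / 4.7
  expect_equal(peaks, sch$onsets + 0.2, tolerance = 0.3)
})

test_that("event segmentation follows the run/merge-gap rules", {
  expect_equal(nrow(segment_events(rep(0, 10))), 0)
  tr <- c(0, 5, 9, 3, 0, 0, 4, 0)
  ev0 <- segment_events(tr, 0)
  expect_equal(ev0$start, c(2, 7))
  expect_equal(ev0$end, c(4, 7))
  expect_equal(ev0$peak, c(3, 7))
  ev2 <- segment_events(tr, 2)
  expect_equal(nrow(ev2), 1)
  expect_equal(unlist(ev2[1, c("start", "end", "peak")], use.names = FALSE),
               c(2, 7, 3))
  # earliest maximum wins ties
  expect_equal(segment_events(c(0, 4, 4, 0), 0)$peak, 2)
})
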