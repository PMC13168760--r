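test_that("centroid detection hits ground truth sub-pixel and localizes under noise", {
  s <- generate_pillar_sequence(n_frames = 1, seed = 3)
  gt <- attr(s, "ground_truth")
  d <- detect_pillar_centroids(s$frames[[1]])
  expect_equal(nrow(d), 2)
  expect_lt(abs(d$x_px[1] - gt$left_x_px[1]), 0.5)
  expect_lt(abs(d$x_px[2] - gt$right_x_px[1]), 0.5)
  expect_lt(abs(d$y_px[1] - gt$y_px), 0.5)
  # RMS error at 10% dynamic-range noise stays below 1 px
  errs <- vapply(1:5, function(seed) {
    sn <- generate_pillar_sequence(n_frames = 1, noise_sd = 0.1, seed = seed)
    gtn <- attr(sn, "ground_truth")
    dn <- detect_pillar_centroids(sn$frames[[1]])
    sqrt(mean(c(dn$x_px - c(gtn$left_x_px[1], gtn$right_x_px[1]),
                dn$y_px - rep(gtn$y_px, 2))^2))
  }, numeric(1))
  expect_lt(max(errs), 1)
})

test_that("detection errors name the failure and count mismatch", {
  s <- generate_pillar_sequence(n_frames = 1, seed = 3)
  expect_error(detect_pillar_centroids(s$frames[[1]], expected_count = 3,
                                       frame_index = 7),
               regexp = "frame 7", class = "pillarforce_detection_failure")
  expect_error(detect_pillar_centroids(matrix(0.5, 50, 50)),
               class = "pillarforce_detection_failure")
})

test_that("detection is translation-equivariant", {
  s <- generate_pillar_sequence(n_frames = 1, seed = 3)
  f <- s$frames[[1]]
  d0 <- detect_pillar_centroids(f)
  dx <- 6L; dy <- 3L
  shifted <- f[c((dy + 1):nrow(f), 1:dy), c((dx + 1):ncol(f), 1:dx)]
  # circular shift moves content by (-dx, -dy)
  d1 <- detect_pillar_centroids(shifted)
  expect_equal(d1$x_px, d0$x_px - dx, tolerance = 0.1)
  expect_equal(d1$y_px, d0$y_px - dy, tolerance = 0.1)
})

test_that("interpillar distance is Euclidean, calibrated and warns when degenerate", {
  pts <- tibble::tibble(x_px = c(0, 3), y_px = c(0, 4))
  expect_equal(interpillar_distance(pts, 10), 50)
  same <- tibble::tibble(x_px = c(1, 1), y_px = c(2, 2))
  expect_warning(d0 <- interpillar_distance(same, 10),
                 class = "pillarforce_coincident_centroids")
  expect_equal(d0, 0)
})

test_that("static sequences track to identically zero deflection", {
  s <- generate_pillar_sequence(n_frames = 5, seed = 6)
  tr <- track_sequence(s)
  expect_lt(max(abs(tr$left_defl_um)), 0.5)
  expect_lt(max(abs(tr$right_defl_um)), 0.5)
  expect_equal(sd(tr$distance_um), 0, tolerance = 0.5)
})

test_that("programmed compaction ramp is recovered within 1%", {
  s <- generate_pillar_sequence(n_frames = 8, compaction_um = 400,
                                noise_sd = 0.02, seed = 3)
  tr <- track_sequence(s)
  drop <- tr$distance_um[1] - tr$distance_um[8]
  expect_equal(drop, 400, tolerance = 0.01)
  cm <- compaction_metrics(tr, tibble::tibble(t0 = 0, t1 = 7))
  expect_equal(cm$reduction_um, 400, tolerance = 4 / 400)
})

test_that("sinusoidal tip motion amplitude is recovered within 2% at SNR 10", {
  fs <- 20
  t <- (0:199) / fs
  A <- 30
  wave <- A / 2 - A / 2 * cos(2 * pi * 1 * t) # starts at 0, peak A
  s <- generate_pillar_sequence(n_frames = length(t), contraction_um = wave,
                                frame_rate_hz = fs, noise_sd = 0.1, seed = 8)
  tr <- track_sequence(s)
  # spectral amplitude at the programmed frequency (robust to frame jitter)
  n <- length(t)
  rec_A <- 4 * Mod(fft(tr$left_defl_um)[1 + n / fs]) / n # peak-to-peak
  expect_equal(rec_A, A, tolerance = 0.02)
  # symmetric programmed contraction gives antisymmetric pillar motion:
  # both deflections (contraction-positive) agree within tolerance
  expect_equal(tr$left_defl_um, tr$right_defl_um, tolerance = 0.15)
})

test_that("distance measurement is rotation-invariant", {
  s <- generate_pillar_sequence(n_frames = 1, frame_dim = c(380, 380),
                                spacing_um = 2600, seed = 3)
  f <- s$frames[[1]]
  d0 <- interpillar_distance(detect_pillar_centroids(f), s$pixel_size_um)
  r90 <- t(f)[ncol(f):1, ] # 90-degree rotation
  d90 <- interpillar_distance(detect_pillar_centroids(r90), s$pixel_size_um)
  expect_equal(d90, d0, tolerance = 0.005)
})

test_that("compaction metrics respect windows and the fixed-length boundary case", {
  s <- generate_pillar_sequence(n_frames = 8, compaction_um = 300, seed = 5)
  tr <- track_sequence(s)
  cm <- compaction_metrics(tr, tibble::tibble(t0 = c(0, 3), t1 = c(3, 7)))
  expect_true(all(cm$reduction_um > 0))
  expect_error(compaction_metrics(tr, tibble::tibble(t0 = 0, t1 = 99)),
               class = "pillarforce_window_out_of_range")
  # spacer emulation: zero programmed compaction -> ~0 reduction
  s0 <- generate_pillar_sequence(n_frames = 8, compaction_um = 0, seed = 5)
  cm0 <- compaction_metrics(track_sequence(s0), tibble::tibble(t0 = 0, t1 = 7))
  expect_equal(cm0$reduction_um, 0, tolerance = 0.5)
})

test_that("cohort mean compaction is recovered within 2 SEM of the program", {
  conds <- tibble::tibble(label = "Hc15", mean_reduction_um = 434.9,
                          sd_reduction_um = 147.6)
  coh <- generate_cohort(conds, n_per_group = 6, type = "compaction", seed = 2)
  rec <- vapply(coh$tissues, function(s) {
    tr <- track_sequence(s)
    tr$distance_um[1] - tr$distance_um[nrow(tr)]
  }, numeric(1))
  expect_equal(rec, coh$manifest$programmed_reduction_um, tolerance = 0.01)
  sem <- sd(coh$manifest$programmed_reduction_um) / sqrt(length(rec))
  expect_lt(abs(mean(rec) - mean(coh$manifest$programmed_reduction_um)),
            2 * sem)
})
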