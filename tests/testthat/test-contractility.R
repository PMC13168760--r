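test_that("force trace applies Hooke's law per pillar and sums to the total", {
  defl <- tibble::tibble(time_s = 0:3, left_defl_um = c(0, 100, 50, 0),
                         right_defl_um = c(0, 100, 25, 0))
  ft <- force_trace(defl, 0.249)
  expect_equal(ft$left_force_un, c(0, 24.9, 12.45, 0))
  expect_equal(ft$total_force_un, ft$left_force_un + ft$right_force_un)
  # two equal 38-uN pillars make a 76-uN total
  d38 <- tibble::tibble(time_s = 0, left_defl_um = 38 / 0.249,
                        right_defl_um = 38 / 0.249)
  expect_equal(force_trace(d38, 0.249)$total_force_un, 76)
  # doubling k doubles every force
  expect_equal(force_trace(defl, 0.498)$left_force_un,
               2 * ft$left_force_un)
  expect_error(force_trace(defl, 0), class = "pillarforce_invalid_stiffness")
  expect_error(force_trace(defl[, 1:2], 0.249),
               class = "pillarforce_invalid_trace")
})

test_that("kernel simulation is deterministic, peak-exact and fuses at high rates", {
  proto1 <- stimulus_protocol(1, epochs = tibble::tibble(
    t_start = 2, t_end = 3, frequency_hz = 1))
  tr <- simulate_contraction(proto1, amplitude_un = 12, fs_hz = 2000)
  expect_equal(max(tr$force_un), 12, tolerance = 0.01)
  # determinism: identical seeds are bitwise identical
  a <- simulate_contraction(two_epoch_protocol(), noise_sd_un = 0.5, seed = 3)
  b <- simulate_contraction(two_epoch_protocol(), noise_sd_un = 0.5, seed = 3)
  expect_identical(a, b)
  # closed-form fusion limit: at period T << tau the plateau approaches the
  # geometric-series sum of sampled kernels
  proto90 <- stimulus_protocol(90, epochs = tibble::tibble(
    t_start = 2, t_end = 6, frequency_hz = 90))
  tr90 <- simulate_contraction(proto90, amplitude_un = 10, tau_rise_s = 0.03,
                               tau_decay_s = 0.2, fs_hz = 2000)
  plateau <- mean(tr90$force_un[tr90$time_s > 4 & tr90$time_s < 6])
  tstar <- 0.03 * 0.2 / (0.2 - 0.03) * log(0.2 / 0.03)
  peak <- exp(-tstar / 0.2) - exp(-tstar / 0.03)
  T <- 1 / 90
  # closed-form steady-state mean of the kernel sum: rate x kernel integral
  avg_limit <- (10 / peak) * (0.2 - 0.03) / T
  expect_equal(plateau, avg_limit, tolerance = 0.05)
  expect_gt(plateau, 10) # far above a single twitch
  expect_error(simulate_contraction(proto1, tau_rise_s = 0.5, tau_decay_s = 0.2),
               class = "pillarforce_invalid_kernel")
})

test_that("twitch metrics recover programmed amplitudes and scale linearly", {
  proto <- two_epoch_protocol()
  tr <- simulate_contraction(proto, amplitude_un = 8, noise_sd_un = 0.1,
                             seed = 5)
  tw <- twitch_metrics(tr, proto)
  expect_equal(tw$twitch_amplitude_un, 8, tolerance = 0.03)
  expect_equal(tw$n_periods, 10)
  expect_lte(abs(tw$n_peaks - 10), 1)
  tr2 <- simulate_contraction(proto, amplitude_un = 16, noise_sd_un = 0.1,
                              seed = 5)
  tw2 <- twitch_metrics(tr2, proto)
  expect_equal(tw2$twitch_amplitude_un / tw$twitch_amplitude_un, 2,
               tolerance = 0.03)
  # flat trace: zero amplitude with a warning, not an error
  flat <- tibble::tibble(time_s = seq(0, 18, 0.01), force_un = 5)
  expect_warning(tw0 <- twitch_metrics(flat, proto),
                 class = "pillarforce_no_peaks")
  expect_equal(tw0$twitch_amplitude_un, 0)
})

test_that("tetanic metrics measure the plateau and the force-frequency relation is non-decreasing", {
  proto <- two_epoch_protocol()
  tr <- simulate_contraction(proto, amplitude_un = 10, seed = 5)
  te <- tetanic_metrics(tr, proto)
  tw <- twitch_metrics(tr, proto)
  expect_gt(te$tetanic_force_un, tw$twitch_amplitude_un)
  expect_lt(te$ripple_un, 0.2 * te$tetanic_force_un)
  # flat trace gives zero
  flat <- tibble::tibble(time_s = seq(0, 18, 0.01), force_un = 2)
  expect_equal(tetanic_metrics(flat, proto)$tetanic_force_un, 0)
  # force-frequency sweep on the kernel model
  mean_force <- vapply(c(0.5, 1, 2, 3, 90), function(f) {
    p <- stimulus_protocol(f, epochs = tibble::tibble(
      t_start = 2, t_end = 10, frequency_hz = f))
    s <- simulate_contraction(p, amplitude_un = 10, fs_hz = 500)
    mean(s$force_un[s$time_s >= 6 & s$time_s < 10])
  }, numeric(1))
  expect_true(all(diff(mean_force) > -1e-9))
  # epoch shorter than 2x relaxation time warns
  pshort <- stimulus_protocol(90, epochs = tibble::tibble(
    t_start = 2, t_end = 2.3, frequency_hz = 90))
  trs <- simulate_contraction(pshort, fs_hz = 500)
  expect_warning(tetanic_metrics(trs, pshort),
                 class = "pillarforce_unreliable_plateau")
})

test_that("fusion ratio orders tetanus above twitch and metrics resist pre-tension offsets", {
  proto <- two_epoch_protocol()
  tr <- simulate_contraction(proto, amplitude_un = 10, tau_decay_s = 0.2,
                             seed = 5)
  tw <- twitch_metrics(tr, proto)
  te <- tetanic_metrics(tr, proto)
  fr <- fusion_ratio(tw, te)
  expect_gt(fr$fusion_ratio, 1)
  # baseline subtraction: a constant pre-tension offset changes nothing
  off <- tr
  off$force_un <- off$force_un + 7.3
  expect_equal(twitch_metrics(off, proto)$twitch_amplitude_un,
               tw$twitch_amplitude_un, tolerance = 1e-9)
  expect_equal(tetanic_metrics(off, proto)$tetanic_force_un,
               te$tetanic_force_un, tolerance = 1e-9)
  # tidiers
  expect_named(tidy(fr), c("metric", "value"))
  expect_equal(nrow(glance(fr)), 1)
})

test_that("dose-response summaries flag programmed trends and normalize to vehicle", {
  mk <- function(compound, dose, mult, n = 5, seed = 1) {
    set.seed(seed + round(100 * mult))
    tibble::tibble(compound = compound, dose = dose,
                   force_un = 10 * mult * exp(rnorm(n, 0, 0.03)))
  }
  dex <- dplyr::bind_rows(
    mk("vehicle", 0, 1),
    mk("DEX", 0.01, 0.8), mk("DEX", 0.1, 0.6), mk("DEX", 1, 0.4))
  s_dex <- dose_response_summary(dex)
  expect_equal(unique(s_dex$trend[s_dex$compound == "DEX"]), "decreasing")
  tes <- dplyr::bind_rows(
    mk("vehicle", 0, 1),
    mk("TES", 0.01, 1.1), mk("TES", 0.1, 1.25), mk("TES", 1, 1.4))
  s_tes <- dose_response_summary(tes)
  expect_equal(unique(s_tes$trend[s_tes$compound == "TES"]), "increasing")
  veh_ratio <- s_tes$ratio_to_vehicle[s_tes$compound == "vehicle"]
  expect_equal(veh_ratio, 1)
  # identical groups: ratios 1, trend none
  same <- dplyr::bind_rows(
    tibble::tibble(compound = "vehicle", dose = 0, force_un = rep(5, 4)),
    tibble::tibble(compound = "X", dose = 0.1, force_un = rep(5, 4)),
    tibble::tibble(compound = "X", dose = 1, force_un = rep(5, 4)))
  s_same <- dose_response_summary(same)
  expect_true(all(s_same$ratio_to_vehicle == 1))
  expect_equal(unique(s_same$trend[s_same$compound == "X"]), "none")
  expect_error(dose_response_summary(dex[dex$compound != "vehicle", ]),
               class = "pillarforce_missing_vehicle")
})

test_that("effect sizes match hand-computed fixtures and symmetry", {
  expect_error(effect_sizes(rep(1, 4), rep(1, 4)),
               class = "pillarforce_zero_variance")
  # constructed fixture with pooled SD exactly 1 and shift 2
  a <- c(-1, 1, -1, 1) + 2 # mean 2, var 4/3
  b <- c(-1, 1, -1, 1)
  sp <- sqrt(4 / 3)
  es <- effect_sizes(a, b)
  expect_equal(es$cohens_d, 2 / sp)
  es_swap <- effect_sizes(b, a)
  expect_equal(es_swap$cohens_d, -es$cohens_d)
  expect_equal(es_swap$eta_squared, es$eta_squared)
  # identical distributions centered equal -> d = 0, eta2 = 0
  es0 <- effect_sizes(c(1, 2, 3), c(2, 1, 3))
  expect_equal(es0$cohens_d, 0)
  expect_equal(es0$eta_squared, 0)
  expect_error(effect_sizes(1, c(1, 2)), class = "pillarforce_invalid_groups")
})
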