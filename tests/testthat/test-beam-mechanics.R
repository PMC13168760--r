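test_that("elliptical second moment matches the closed form and its limits", {
  g <- default_geometry()
  # circle limit: a = b = r reduces to pi r^4 / 4
  r <- 150
  gc <- pillar_geometry(r, r)
  expect_equal(second_moment_elliptical(gc), pi * (r * 1e-6)^4 / 4)
  # default section vs brute-force area integration of y^2
  I <- second_moment_elliptical(g)
  expect_equal(I, pi * 300e-6 * (200e-6)^3 / 4)
  expect_equal(I, second_moment_numeric(300, 200), tolerance = 1e-3)
  # degenerate section: I -> 0 monotonically as b -> 0
  bs <- c(150, 100, 50, 10)
  Is <- vapply(bs, function(b) second_moment_elliptical(
    pillar_geometry(300, b)), numeric(1))
  expect_true(all(diff(Is) < 0))
  expect_error(pillar_geometry(300, 0), class = "pillarforce_invalid_geometry")
})

test_that("lateral stiffness follows 3EI/h^3 with cubic height scaling", {
  g <- default_geometry()
  k <- lateral_stiffness(g)
  expect_equal(k, 0.2133, tolerance = 1e-3)
  # doubling the load height divides k by exactly 8
  g8 <- pillar_geometry(height_h_mm = 8)
  expect_equal(lateral_stiffness(g8, 8) * 8, k)
  expect_equal(lateral_stiffness(g8, 4), k)
  # load height out of range
  expect_error(lateral_stiffness(g, 0), class = "pillarforce_invalid_load_height")
  expect_error(lateral_stiffness(g, 5), class = "pillarforce_invalid_load_height")
  # user-supplied calibration value is accepted downstream as-is
  expect_equal(force_from_deflection(0.249, 100), 24.9)
})

test_that("closed-form stiffness agrees with the numerical beam oracle", {
  set.seed(42)
  for (i in 1:10) {
    b <- runif(1, 100, 300)
    g <- pillar_geometry(semi_major_a_um = b * runif(1, 1, 2),
                         semi_minor_b_um = b,
                         height_h_mm = runif(1, 2, 6),
                         youngs_modulus_mpa = runif(1, 1, 5))
    f <- 20
    delta_num <- cantilever_deflection_numeric(g, f)
    delta_cf <- f / lateral_stiffness(g)
    expect_equal(delta_num, delta_cf, tolerance = 1e-3)
  }
})

test_that("stiffness scales as b^3 and h^-3 on logarithmic grids", {
  bs <- 50 * 2^(0:3)
  ks <- vapply(bs, function(b) lateral_stiffness(
    pillar_geometry(400, b)), numeric(1))
  expect_equal(ks / ks[1], (bs / bs[1])^3, tolerance = 1e-12)
  hs <- 2^(1:4)
  kh <- vapply(hs, function(h) lateral_stiffness(
    pillar_geometry(height_h_mm = h)), numeric(1))
  expect_equal(kh / kh[1], (hs / hs[1])^-3, tolerance = 1e-12)
})

test_that("Hooke's law conversion is linear with zero at zero", {
  expect_equal(force_from_deflection(0.249, 0), 0)
  d <- c(-5, 1, 10, 100)
  expect_equal(force_from_deflection(0.3, 2 * d),
               2 * force_from_deflection(0.3, d))
  expect_equal(sign(force_from_deflection(0.3, d)), sign(d))
  expect_error(force_from_deflection(0, 1), class = "pillarforce_invalid_stiffness")
})

test_that("modulus back-calculation inverts the stiffness relation", {
  g <- default_geometry()
  expect_equal(back_calculate_modulus(lateral_stiffness(g), g),
               g$youngs_modulus_mpa, tolerance = 1e-10)
  expect_equal(back_calculate_modulus(0.2133, g), 2.414, tolerance = 1e-3)
  expect_equal(back_calculate_modulus(2 * 0.2133, g),
               2 * back_calculate_modulus(0.2133, g))
  # round trip over random geometries
  set.seed(7)
  for (i in 1:5) {
    gg <- pillar_geometry(280, 180, runif(1, 2, 6), runif(1, 1, 4))
    expect_equal(back_calculate_modulus(lateral_stiffness(gg), gg),
                 gg$youngs_modulus_mpa, tolerance = 1e-10)
  }
})

test_that("shear modulus covers the printed value and analytic limits", {
  expect_equal(shear_modulus(2.414, 0.49), 0.81, tolerance = 0.005)
  expect_equal(shear_modulus(3, 1e-9), 1.5, tolerance = 1e-6)
  expect_equal(shear_modulus(3, 0.5 - 1e-9), 1, tolerance = 1e-6)
  expect_error(shear_modulus(3, 0.6), class = "pillarforce_invalid_poisson")
  expect_error(shear_modulus(-1, 0.3), class = "pillarforce_invalid_modulus")
})

test_that("static deflection inverts force conversion and flags large deflections", {
  g <- default_geometry()
  k <- lateral_stiffness(g)
  expect_equal(deflection_under_load(g, 38), 38 / k)
  expect_equal(force_from_deflection(k, deflection_under_load(g, 38)), 38)
  expect_equal(deflection_under_load(g, 0), 0)
  # delta strictly increases with h at fixed force and section
  hs <- seq(3, 5, 0.5)
  ds <- vapply(hs, function(h) deflection_under_load(
    pillar_geometry(height_h_mm = h), 10), numeric(1))
  expect_true(all(diff(ds) > 0))
  # small-deflection warning contract at delta/h > 0.1
  expect_warning(deflection_under_load(g, 100),
                 class = "pillarforce_large_deflection")
  expect_no_warning(deflection_under_load(g, 10))
})

test_that("design-space sweep is exhaustive, ordered and monotone", {
  sw <- design_space_sweep()
  expect_equal(nrow(sw), 20) # 5 heights x 4 sections
  expect_equal(sw, dplyr::arrange(sw, h_mm, b_um), ignore_attr = TRUE)
  # delta increasing in h at fixed b, decreasing in b at fixed h
  by_b <- split(sw, sw$b_um)
  for (grp in by_b) expect_true(all(diff(grp$delta_um) > 0))
  by_h <- split(sw, sw$h_mm)
  for (grp in by_h) expect_true(all(diff(grp$delta_um) < 0))
  expect_error(design_space_sweep(heights_mm = numeric(0)),
               class = "pillarforce_empty_grid")
})
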