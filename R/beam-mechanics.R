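# Elliptical-cantilever beam mechanics: pillar deflection <-> force.
#
# All user-facing quantities are in lab units (um, mm, MPa, uN); conversions
# to SI happen only inside si_* helpers so no scattered factors exist.

# unit conversions, centralised
si_m_from_um <- function(x) x * 1e-6
si_m_from_mm <- function(x) x * 1e-3
si_pa_from_mpa <- function(x) x * 1e6
# uN/um is numerically identical to N/m (1e-6 N / 1e-6 m)
un_per_um_from_n_per_m <- function(x) x

#' Elliptical force-sensing pillar geometry
#'
#' Bundles the dimensions and material constants of a 3D-printed elastic
#' pillar with an elliptical cross-section, clamped at its base and loaded
#' laterally by the muscle tissue. `semi_minor_b_um` is the semi-axis along
#' the bending direction (the tissue's line of action); the pillar is
#' elongated orthogonally to it so bending is biased along the tissue axis.
#'
#' Defaults are the platform's standard pillar: a = 300 um, b = 200 um,
#' h = 4 mm, E = 2.414 MPa (elastic print resin, back-calculated from
#' force-displacement testing), nu = 0.49 (nearly incompressible).
#'
#' @param semi_major_a_um Semi-major axis of the cross-section (um).
#' @param semi_minor_b_um Semi-minor axis, along the bending direction (um).
#' @param height_h_mm Load application height above the clamped base (mm).
#' @param youngs_modulus_mpa Young's modulus E (MPa).
#' @param poisson_nu Poisson's ratio, in (0, 0.5).
#' @return An object of class `pillar_geometry`.
#' @examples
#' g <- pillar_geometry()
#' lateral_stiffness(g)
#' @export
pillar_geometry <- function(semi_major_a_um = 300,
                            semi_minor_b_um = 200,
                            height_h_mm = 4,
                            youngs_modulus_mpa = 2.414,
                            poisson_nu = 0.49) {
  if (!is.numeric(semi_major_a_um) || !is.numeric(semi_minor_b_um) ||
      semi_minor_b_um <= 0 || semi_major_a_um < semi_minor_b_um) {
    abort("invalid geometry: require semi_major_a_um >= semi_minor_b_um > 0",
          class = "pillarforce_invalid_geometry")
  }
  if (height_h_mm <= 0) {
    abort("invalid geometry: height_h_mm must be > 0",
          class = "pillarforce_invalid_geometry")
  }
  if (youngs_modulus_mpa <= 0) {
    abort("invalid geometry: youngs_modulus_mpa must be > 0",
          class = "pillarforce_invalid_geometry")
  }
  if (poisson_nu <= 0 || poisson_nu >= 0.5) {
    abort("invalid geometry: poisson_nu must lie in (0, 0.5)",
          class = "pillarforce_invalid_geometry")
  }
  structure(
    list(semi_major_a_um = semi_major_a_um,
         semi_minor_b_um = semi_minor_b_um,
         height_h_mm = height_h_mm,
         youngs_modulus_mpa = youngs_modulus_mpa,
         poisson_nu = poisson_nu),
    class = "pillar_geometry"
  )
}

#' @export
print.pillar_geometry <- function(x, ...) {
  cat("<pillar_geometry>\n")
  cat(sprintf("  cross-section: a = %g um, b = %g um (bending axis)\n",
              x$semi_major_a_um, x$semi_minor_b_um))
  cat(sprintf("  height h = %g mm, E = %g MPa, nu = %g\n",
              x$height_h_mm, x$youngs_modulus_mpa, x$poisson_nu))
  cat(sprintf("  k(h) = %.4f uN/um\n", lateral_stiffness(x)))
  invisible(x)
}

#' Second moment of area of an elliptical cross-section
#'
#' I = pi * a * b^3 / 4 about the neutral axis, with b the semi-axis along
#' the bending direction. Returned in m^4 (SI), since I only ever feeds the
#' stiffness formula.
#'
#' @param geometry A [pillar_geometry()].
#' @return Second moment of area (m^4).
#' @export
second_moment_elliptical <- function(geometry) {
  stopifnot(inherits(geometry, "pillar_geometry"))
  a <- si_m_from_um(geometry$semi_major_a_um)
  b <- si_m_from_um(geometry$semi_minor_b_um)
  pi * a * b^3 / 4
}

#' Lateral stiffness of a clamped elliptical cantilever
#'
#' Euler-Bernoulli small-deflection stiffness k(h) = 3 E I / h^3 for a point
#' load applied at height `load_height_mm` above the base. With the default
#' geometry this evaluates to about 0.213 uN/um; an empirically calibrated
#' value (for the platform, 0.249 uN/um from mechanical testing) can be used
#' instead wherever a stiffness is an argument.
#'
#' @param geometry A [pillar_geometry()].
#' @param load_height_mm Height of load application (mm); defaults to the
#'   full pillar height.
#' @return Stiffness (uN/um).
#' @export
lateral_stiffness <- function(geometry, load_height_mm = geometry$height_h_mm) {
  stopifnot(inherits(geometry, "pillar_geometry"))
  if (load_height_mm <= 0 || load_height_mm > geometry$height_h_mm) {
    abort("load_height_mm must satisfy 0 < load_height_mm <= height_h_mm",
          class = "pillarforce_invalid_load_height")
  }
  E <- si_pa_from_mpa(geometry$youngs_modulus_mpa)
  I <- second_moment_elliptical(geometry)
  h <- si_m_from_mm(load_height_mm)
  un_per_um_from_n_per_m(3 * E * I / h^3)
}

#' Force from pillar deflection (Hooke's law)
#'
#' F = k * delta per pillar. Sign follows the deflection sign, so
#' contraction-positive deflections give contraction-positive forces.
#'
#' @param stiffness_un_per_um Pillar lateral stiffness k (uN/um), > 0.
#' @param deflection_um Lateral tip deflection delta (um); vectorised.
#' @return Force (uN).
#' @export
force_from_deflection <- function(stiffness_un_per_um, deflection_um) {
  if (!is.numeric(stiffness_un_per_um) || stiffness_un_per_um <= 0) {
    abort("stiffness_un_per_um must be > 0",
          class = "pillarforce_invalid_stiffness")
  }
  stiffness_un_per_um * deflection_um
}

#' Back-calculate Young's modulus from a measured stiffness
#'
#' Inverts the cantilever relation: E = k h^3 / (3 I). Round-trips exactly
#' with [lateral_stiffness()]. This is how the print resin's modulus is
#' obtained from a force-displacement test on the physical pillar.
#'
#' @param stiffness_un_per_um Measured lateral stiffness (uN/um).
#' @param geometry A [pillar_geometry()]; its modulus field is ignored.
#' @param load_height_mm Height at which the stiffness was measured (mm).
#' @return Young's modulus (MPa).
#' @export
back_calculate_modulus <- function(stiffness_un_per_um, geometry,
                                   load_height_mm = geometry$height_h_mm) {
  stopifnot(inherits(geometry, "pillar_geometry"))
  if (stiffness_un_per_um <= 0) {
    abort("stiffness_un_per_um must be > 0",
          class = "pillarforce_invalid_stiffness")
  }
  if (load_height_mm <= 0 || load_height_mm > geometry$height_h_mm) {
    abort("load_height_mm must satisfy 0 < load_height_mm <= height_h_mm",
          class = "pillarforce_invalid_load_height")
  }
  I <- second_moment_elliptical(geometry)
  h <- si_m_from_mm(load_height_mm)
  k_si <- stiffness_un_per_um # N/m
  (k_si * h^3 / (3 * I)) / 1e6
}

#' Shear modulus from E and Poisson's ratio
#'
#' mu = E / (2 (1 + nu)) for an isotropic linear-elastic solid. For the
#' standard resin (E = 2.414 MPa, nu = 0.49) this gives about 0.81 MPa.
#'
#' @param youngs_modulus_mpa Young's modulus (MPa), > 0.
#' @param poisson_nu Poisson's ratio in (0, 0.5).
#' @return Shear modulus (MPa).
#' @export
shear_modulus <- function(youngs_modulus_mpa, poisson_nu) {
  if (youngs_modulus_mpa <= 0) {
    abort("youngs_modulus_mpa must be > 0",
          class = "pillarforce_invalid_modulus")
  }
  if (poisson_nu <= 0 || poisson_nu >= 0.5) {
    abort("poisson_nu must lie in (0, 0.5)",
          class = "pillarforce_invalid_poisson")
  }
  youngs_modulus_mpa / (2 * (1 + poisson_nu))
}

#' Tip deflection under a static lateral load
#'
#' delta = F / k(h). When the predicted deflection exceeds 10% of the pillar
#' height the result is outside the small-deflection regime of the beam
#' model and a warning is raised (the value is still returned).
#'
#' @param geometry A [pillar_geometry()].
#' @param force_un Applied lateral force per pillar (uN); vectorised.
#' @param load_height_mm Load application height (mm).
#' @return Deflection (um).
#' @export
deflection_under_load <- function(geometry, force_un,
                                  load_height_mm = geometry$height_h_mm) {
  k <- lateral_stiffness(geometry, load_height_mm)
  delta_um <- force_un / k
  h_um <- load_height_mm * 1e3
  if (any(is.finite(delta_um) & abs(delta_um) / h_um > 0.1)) {
    warn("predicted deflection exceeds 10% of pillar height; outside the small-deflection regime",
         class = "pillarforce_large_deflection")
  }
  delta_um
}

#' Design-space sweep over pillar height and section thickness
#'
#' Evaluates stiffness and static deflection under a reference load on an
#' exhaustive (height, semi-minor axis) grid, holding the cross-section
#' aspect ratio fixed (default 1.5:1, the platform's print design). Taller,
#' thinner pillars give softer springs and larger deflections, which is the
#' design lever for force sensitivity.
#'
#' @param heights_mm Pillar heights to sweep (mm); default 3-5 mm in 0.5-mm
#'   steps.
#' @param semi_minor_b_um Semi-minor (bending-direction) axes to sweep (um);
#'   default 150-300 um in 50-um steps.
#' @param reference_force_un Static reference load per pillar (uN);
#'   default 38 (half of a 76-uN two-pillar contraction).
#' @param aspect_ratio Major:minor axis ratio (default 1.5).
#' @param youngs_modulus_mpa,poisson_nu Material constants.
#' @return A tibble with columns `h_mm`, `b_um`, `k_uN_per_um`, `delta_um`,
#'   `outside_linear_regime`, ordered by (h_mm, b_um). Class
#'   `design_space_sweep` for [autoplot()].
#' @export
design_space_sweep <- function(heights_mm = seq(3, 5, by = 0.5),
                               semi_minor_b_um = seq(150, 300, by = 50),
                               reference_force_un = 38,
                               aspect_ratio = 1.5,
                               youngs_modulus_mpa = 2.414,
                               poisson_nu = 0.49) {
  if (length(heights_mm) == 0 || length(semi_minor_b_um) == 0) {
    abort("empty sweep grid", class = "pillarforce_empty_grid")
  }
  grid <- tidyr::expand_grid(h_mm = sort(heights_mm),
                             b_um = sort(semi_minor_b_um))
  out <- dplyr::mutate(
    grid,
    k_uN_per_um = purrr::map2_dbl(.data$h_mm, .data$b_um, function(h, b) {
      g <- pillar_geometry(semi_major_a_um = aspect_ratio * b,
                           semi_minor_b_um = b, height_h_mm = h,
                           youngs_modulus_mpa = youngs_modulus_mpa,
                           poisson_nu = poisson_nu)
      lateral_stiffness(g)
    }),
    delta_um = reference_force_un / .data$k_uN_per_um,
    outside_linear_regime = .data$delta_um / (.data$h_mm * 1e3) > 0.1
  )
  class(out) <- c("design_space_sweep", class(out))
  out
}

#' Numerical Euler-Bernoulli cantilever oracle
#'
#' Computes the tip deflection of a clamped cantilever under a point load at
#' height h by integrating the bending relation w''(x) = M(x) / (E I) twice
#' with cumulative trapezoids, independent of the closed form 3EI/h^3. Used
#' as a cross-check of [lateral_stiffness()].
#'
#' @param geometry A [pillar_geometry()].
#' @param force_un Point load at the tip (uN).
#' @param n_nodes Number of quadrature nodes along the beam.
#' @return Deflection at the load point (um).
#' @export
cantilever_deflection_numeric <- function(geometry, force_un, n_nodes = 2001) {
  stopifnot(inherits(geometry, "pillar_geometry"))
  E <- si_pa_from_mpa(geometry$youngs_modulus_mpa)
  I <- second_moment_elliptical(geometry)
  h <- si_m_from_mm(geometry$height_h_mm)
  F_n <- force_un * 1e-6
  x <- seq(0, h, length.out = n_nodes)
  curvature <- F_n * (h - x) / (E * I)      # M(x)/EI for tip point load
  slope <- pracma::cumtrapz(x, curvature)   # w'(0) = 0
  w <- pracma::cumtrapz(x, as.numeric(slope)) # w(0) = 0
  as.numeric(w[n_nodes]) * 1e6
}
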