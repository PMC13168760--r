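# Synthetic microscopy data with ground-truth sidecars: two-pillar
# bright-field sequences, fiber textures with prescribed angular
# distributions, and condition cohorts. Everything is deterministic given
# (parameters, seed), and every artifact carries its ground truth.

# local, restorable RNG scope
with_seed <- function(seed, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  force(code)
}

# soft-edged elliptical blob added onto a canvas (vectorised over a patch)
add_blob <- function(canvas, cx_px, cy_px, rx_px, ry_px, amplitude) {
  ny <- nrow(canvas); nx <- ncol(canvas)
  # 0-based pixel-center coordinates
  x0 <- max(0, floor(cx_px - 2.5 * rx_px)); x1 <- min(nx - 1, ceiling(cx_px + 2.5 * rx_px))
  y0 <- max(0, floor(cy_px - 2.5 * ry_px)); y1 <- min(ny - 1, ceiling(cy_px + 2.5 * ry_px))
  xs <- x0:x1; ys <- y0:y1
  dx2 <- ((xs - cx_px) / rx_px)^2
  dy2 <- ((ys - cy_px) / ry_px)^2
  r4 <- outer(dy2, dx2, `+`)^2
  canvas[ys + 1, xs + 1] <- canvas[ys + 1, xs + 1] + amplitude * exp(-r4)
  canvas
}

#' Generate a synthetic two-pillar bright-field image sequence
#'
#' Renders two soft-edged elliptical pillar heads on a textured background.
#' The pillar centroids follow a programmed compaction drift (both pillars
#' move toward the midline, closing the interpillar distance) plus a
#' superimposed contraction waveform, with optional Gaussian and Poisson
#' noise. The returned object carries a `ground_truth` attribute with the
#' exact programmed trajectories.
#'
#' Defaults mirror the physical platform: 2.6-mm pillar spacing imaged at
#' 10 um/px (260-px initial separation).
#'
#' @param n_frames Number of frames.
#' @param compaction_um Total interpillar-distance reduction over the
#'   sequence (um), applied as a linear ramp split equally between the two
#'   pillars. May also be a vector of per-frame cumulative reductions.
#' @param contraction_um Per-pillar contraction displacement per frame
#'   (um): a numeric vector of length `n_frames` (each pillar moves toward
#'   the midline by this amount), or a single 0 for none.
#' @param spacing_um Initial centroid separation (um, default 2600).
#' @param pixel_size_um Pixel size (um/px, default 10).
#' @param frame_rate_hz Frame rate (Hz, default 1).
#' @param frame_dim Frame size as c(rows, cols) px (default c(80, 360)).
#' @param pillar_radius_px Blob radii c(rx, ry) in px (default c(12, 9)).
#' @param noise_sd Gaussian noise SD as a fraction of pillar contrast
#'   (default 0).
#' @param poisson_noise Add Poisson shot noise (default FALSE).
#' @param seed RNG seed.
#' @return An [image_sequence()] with attribute `ground_truth` (list:
#'   centroid trajectories in px, programmed distance trace in um, seed).
#' @export
generate_pillar_sequence <- function(n_frames = 8,
                                     compaction_um = 0,
                                     contraction_um = 0,
                                     spacing_um = 2600,
                                     pixel_size_um = 10,
                                     frame_rate_hz = 1,
                                     frame_dim = c(80, 360),
                                     pillar_radius_px = c(12, 9),
                                     noise_sd = 0,
                                     poisson_noise = FALSE,
                                     seed = 1) {
  if (length(compaction_um) == 1) {
    compaction_um <- seq(0, compaction_um, length.out = n_frames)
  }
  stopifnot(length(compaction_um) == n_frames)
  if (length(contraction_um) == 1) {
    contraction_um <- rep(contraction_um, n_frames)
  }
  stopifnot(length(contraction_um) == n_frames)

  ny <- frame_dim[1]; nx <- frame_dim[2]
  cy <- (ny - 1) / 2
  mid_x <- (nx - 1) / 2
  half_sep_px <- spacing_um / pixel_size_um / 2
  # per-pillar inward displacement in px
  inward_px <- (compaction_um / 2 + contraction_um) / pixel_size_um
  left_x <- mid_x - half_sep_px + inward_px
  right_x <- mid_x + half_sep_px - inward_px
  if (any(left_x < 3 * pillar_radius_px[1]) ||
      any(right_x > nx - 1 - 3 * pillar_radius_px[1]) ||
      any(left_x >= right_x)) {
    abort("programmed trajectory exits the frame or pillars cross",
          class = "pillarforce_trajectory_out_of_frame")
  }

  frames <- with_seed(seed, {
    background <- 0.2 + 0.02 * matrix(rnorm(ny * nx), ny, nx)
    background <- (background + background[, c(2:nx, nx)]) / 2 # mild smoothing
    lapply(seq_len(n_frames), function(i) {
      f <- background
      f <- add_blob(f, left_x[i], cy, pillar_radius_px[1],
                    pillar_radius_px[2], amplitude = 1)
      f <- add_blob(f, right_x[i], cy, pillar_radius_px[1],
                    pillar_radius_px[2], amplitude = 1)
      if (noise_sd > 0) f <- f + matrix(rnorm(ny * nx, sd = noise_sd), ny, nx)
      if (poisson_noise) {
        scale <- 1000
        f <- matrix(stats::rpois(ny * nx, pmax(f, 0) * scale) / scale, ny, nx)
      }
      f
    })
  })
  seq <- image_sequence(frames, pixel_size_um = pixel_size_um,
                        frame_rate_hz = frame_rate_hz)
  attr(seq, "ground_truth") <- list(
    left_x_px = left_x, right_x_px = right_x, y_px = cy,
    distance_um = (right_x - left_x) * pixel_size_um,
    compaction_um = compaction_um, contraction_um = contraction_um,
    seed = seed
  )
  seq
}

#' Generate a synthetic fiber-texture image
#'
#' Renders anti-aliased line segments whose angles are drawn from a wrapped
#' normal distribution around `modal_angle_deg` (SD = 1/sqrt(concentration)
#' radians, mapped to degrees), or uniformly on \[-90, 90) for
#' `"isotropic"`. Angle convention matches the analyzer: 0 deg =
#' horizontal, counterclockwise positive (y up).
#'
#' @param modal_angle_deg Modal fiber angle (deg) or the string
#'   `"isotropic"`.
#' @param concentration Angular concentration kappa (>= 0); larger is
#'   tighter. `Inf` renders perfectly parallel lines. Ignored for
#'   isotropic.
#' @param size Image side in pixels (default 256).
#' @param n_lines Number of fiber segments (default 300; 0 gives a
#'   degenerate constant image).
#' @param snr Signal-to-noise ratio: line contrast over Gaussian noise SD
#'   (default Inf = noiseless).
#' @param pixel_size_um Pixel size (um/px).
#' @param seed RNG seed.
#' @return A [fiber_image()] with attribute `ground_truth` (angles of all
#'   rendered segments, parameters, seed).
#' @export
generate_fiber_image <- function(modal_angle_deg = 0, concentration = 10,
                                 size = 256, n_lines = 300, snr = Inf,
                                 pixel_size_um = 1, seed = 1) {
  isotropic <- identical(modal_angle_deg, "isotropic")
  if (!isotropic && (!is.numeric(concentration) || concentration < 0)) {
    abort("concentration must be >= 0",
          class = "pillarforce_invalid_parameters")
  }
  img <- matrix(0, size, size)
  angles <- numeric(0)
  img <- with_seed(seed, {
    if (n_lines > 0) {
      angles <- if (isotropic) {
        runif(n_lines, -90, 90)
      } else if (is.infinite(concentration)) {
        rep(modal_angle_deg, n_lines)
      } else {
        sd_deg <- (1 / sqrt(concentration)) * 180 / pi
        a <- rnorm(n_lines, modal_angle_deg, sd_deg)
        ((a + 90) %% 180) - 90
      }
      cx <- runif(n_lines, 0, size - 1)
      cy <- runif(n_lines, 0, size - 1)
      len <- runif(n_lines, 0.15 * size, 0.4 * size)
      for (i in seq_len(n_lines)) {
        th <- angles[i] * pi / 180
        # y up means row decreases with +sin
        n_steps <- max(2L, ceiling(len[i]))
        s <- seq(-len[i] / 2, len[i] / 2, length.out = n_steps)
        xs <- cx[i] + s * cos(th)
        ys <- cy[i] - s * sin(th)
        ok <- xs >= 1 & xs <= size - 2 & ys >= 1 & ys <= size - 2
        xs <- xs[ok]; ys <- ys[ok]
        if (length(xs) == 0) next
        # bilinear splat of unit mass per step (anti-aliased 1-px line)
        x0 <- floor(xs); y0 <- floor(ys)
        fx <- xs - x0; fy <- ys - y0
        for (dd in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
          wgt <- (if (dd[1] == 0) 1 - fy else fy) *
                 (if (dd[2] == 0) 1 - fx else fx)
          idx <- cbind(y0 + dd[1] + 1, x0 + dd[2] + 1)
          img[idx] <- img[idx] + wgt
        }
      }
    }
    if (is.finite(snr) && n_lines > 0) {
      contrast <- max(img)
      img <- img + matrix(rnorm(size * size, sd = contrast / snr), size, size)
    }
    img
  })
  out <- fiber_image(img, pixel_size_um = pixel_size_um)
  attr(out, "ground_truth") <- list(
    modal_angle_deg = modal_angle_deg, concentration = concentration,
    segment_angles_deg = angles, n_lines = n_lines, snr = snr, seed = seed
  )
  if (n_lines == 0) {
    warn("zero fiber segments: degenerate constant image",
         class = "pillarforce_degenerate_image")
  }
  out
}

#' Generate a cohort of synthetic tissues for a study condition design
#'
#' Produces per-tissue artifacts whose programmed effects follow the
#' condition design: compaction cohorts draw per-tissue total interpillar
#' reductions from N(mean, sd) per condition (a spacer condition programs
#' zero compaction: fixed-length boundary), and drug cohorts scale twitch
#' and tetanic amplitudes by per-dose multipliers (decreasing for a
#' dexamethasone-like scenario, increasing for a testosterone-like one).
#'
#' @param conditions A tibble describing one row per condition. For
#'   `type = "compaction"`: columns `label`, `mean_reduction_um`,
#'   `sd_reduction_um`. For `type = "drug"`: columns `compound`, `dose`,
#'   `amplitude_multiplier`.
#' @param n_per_group Tissues per condition (>= 1).
#' @param type `"compaction"` (image sequences) or `"drug"` (force
#'   traces).
#' @param n_frames Frames per compaction sequence (default 8,
#'   every-other-day cadence over 14 days).
#' @param base_amplitude_un Vehicle twitch amplitude for drug cohorts
#'   (uN, default 10).
#' @param noise_sd Noise level passed to the per-tissue generator.
#' @param seed Master seed; per-tissue seeds are derived from it.
#' @return A `cohort` list: `manifest` tibble (one row per tissue with its
#'   programmed ground truth) and `tissues` (list of generated artifacts).
#' @export
generate_cohort <- function(conditions, n_per_group = 10,
                            type = c("compaction", "drug"),
                            n_frames = 8, base_amplitude_un = 10,
                            noise_sd = 0.02, seed = 1) {
  type <- match.arg(type)
  if (n_per_group < 1) {
    abort("n_per_group must be >= 1", class = "pillarforce_invalid_design")
  }
  conditions <- tibble::as_tibble(conditions)
  need <- if (type == "compaction") {
    c("label", "mean_reduction_um", "sd_reduction_um")
  } else {
    c("compound", "dose", "amplitude_multiplier")
  }
  if (!all(need %in% names(conditions))) {
    abort(sprintf("conditions must have columns: %s",
                  paste(need, collapse = ", ")),
          class = "pillarforce_unknown_condition")
  }
  tissues <- list()
  rows <- list()
  tid <- 0L
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    for (ri in seq_len(n_per_group)) {
      tid <- tid + 1L
      tseed <- (seed * 10007L + tid * 97L) %% .Machine$integer.max
      if (type == "compaction") {
        red <- with_seed(tseed, max(0, rnorm(1, cond$mean_reduction_um,
                                             cond$sd_reduction_um)))
        art <- generate_pillar_sequence(n_frames = n_frames,
                                        compaction_um = red,
                                        noise_sd = noise_sd,
                                        seed = tseed + 1L)
        rows[[tid]] <- tibble(tissue_id = tid, label = cond$label,
                              programmed_reduction_um = red, seed = tseed)
      } else {
        amp <- base_amplitude_un * cond$amplitude_multiplier
        amp <- with_seed(tseed, amp * exp(rnorm(1, 0, 0.05)))
        proto <- stimulus_protocol(
          frequency_hz = 1,
          epochs = tibble(t_start = c(2, 14), t_end = c(12, 18),
                          frequency_hz = c(1, 90)))
        art <- simulate_contraction(proto, amplitude_un = amp,
                                    noise_sd_un = noise_sd * amp,
                                    seed = tseed + 1L)
        attr(art, "protocol") <- proto
        rows[[tid]] <- tibble(tissue_id = tid, compound = cond$compound,
                              dose = cond$dose,
                              programmed_amplitude_un = amp, seed = tseed)
      }
      tissues[[tid]] <- art
    }
  }
  structure(list(manifest = dplyr::bind_rows(rows), tissues = tissues,
                 type = type, seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %s, %d tissues, seed %d\n", x$type,
              length(x$tissues), x$seed))
  print(x$manifest, n = 5)
  invisible(x)
}
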