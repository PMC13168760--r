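# Fiber orientation analysis: Fourier directionality histogram and the
# cosine-weighted orientation index.
#
# Angle convention: 0 deg = horizontal interpillar axis (image x, columns),
# counterclockwise positive with y pointing up; range [-90, +90) deg.

#' Angular fiber-orientation distribution
#'
#' A discrete distribution P(theta) of fiber angles on [-90, +90] degrees,
#' either a binned histogram (default 36 half-open 5-degree bins with
#' centers -87.5, ..., +87.5) or arbitrary angle/weight samples (so the
#' idealised all-mass-at-0 and all-mass-at-90 limits are representable
#' exactly).
#'
#' @param angles_deg Angles in degrees, strictly increasing, within
#'   \[-90, 90\].
#' @param weights Nonnegative weights summing to 1 (within 1e-9).
#' @param bin_width_deg Bin width in degrees, or `NA` for unbinned samples.
#' @return An object of class `orientation_distribution` (a tibble with
#'   columns `angle_deg`, `weight`).
#' @examples
#' d <- orientation_distribution(0, 1)
#' orientation_index(d)
#' @export
orientation_distribution <- function(angles_deg, weights,
                                     bin_width_deg = NA_real_) {
  if (length(angles_deg) != length(weights) || length(angles_deg) == 0) {
    abort("angles_deg and weights must be nonempty and of equal length",
          class = "pillarforce_invalid_distribution")
  }
  if (any(weights < 0)) {
    abort("weights must be nonnegative",
          class = "pillarforce_invalid_distribution")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    abort("weights must sum to 1 (no silent renormalization)",
          class = "pillarforce_unnormalized_weights")
  }
  if (any(diff(angles_deg) <= 0)) {
    abort("angles_deg must be strictly increasing",
          class = "pillarforce_invalid_distribution")
  }
  if (any(angles_deg < -90 | angles_deg > 90)) {
    abort("angles_deg must lie within [-90, 90]",
          class = "pillarforce_invalid_distribution")
  }
  out <- tibble(angle_deg = as.numeric(angles_deg),
                weight = as.numeric(weights))
  structure(out,
            bin_width_deg = bin_width_deg,
            n_bins = length(angles_deg),
            class = c("orientation_distribution", class(out)))
}

#' Standard 36-bin centers on \[-90, 90) degrees
#' @param bin_width_deg Bin width (degrees), default 5.
#' @return Bin center angles in degrees.
#' @export
standard_bin_centers <- function(bin_width_deg = 5) {
  seq(-90 + bin_width_deg / 2, 90 - bin_width_deg / 2, by = bin_width_deg)
}

#' Orientation index (cosine-weighted mean of the angular distribution)
#'
#' OI = sum_i P(theta_i) cos(theta_i). Because cos is nonnegative on
#' \[-90, +90\] degrees, OI lies in \[0, 1\]: 1 for fibers parallel to the
#' interpillar axis (theta = 0), 0 for perpendicular fibers
#' (theta = +/-90), and 2/pi (~0.637) for an isotropic distribution.
#'
#' @param dist An [orientation_distribution()].
#' @return OI, dimensionless in \[0, 1\].
#' @export
orientation_index <- function(dist) {
  if (!inherits(dist, "orientation_distribution")) {
    abort("dist must be an orientation_distribution",
          class = "pillarforce_invalid_distribution")
  }
  if (abs(sum(dist$weight) - 1) > 1e-9) {
    abort("weights must sum to 1 (no silent renormalization)",
          class = "pillarforce_unnormalized_weights")
  }
  # cospi keeps the +/-90 deg limit exactly zero
  sum(dist$weight * cospi(dist$angle_deg / 180))
}

#' Fiber image container
#'
#' @param intensity Numeric matrix (rows = y, columns = x) of arbitrary
#'   intensity units; at least 64 x 64 for spectral estimation.
#' @param pixel_size_um Pixel size (um/px).
#' @return Object of class `fiber_image`.
#' @export
fiber_image <- function(intensity, pixel_size_um = 1) {
  if (!is.matrix(intensity) || !is.numeric(intensity)) {
    abort("intensity must be a numeric matrix",
          class = "pillarforce_invalid_image")
  }
  if (nrow(intensity) < 64 || ncol(intensity) < 64) {
    abort("fiber image must be at least 64 x 64 pixels",
          class = "pillarforce_image_too_small")
  }
  if (pixel_size_um <= 0) {
    abort("pixel_size_um must be > 0", class = "pillarforce_invalid_image")
  }
  structure(list(intensity = intensity, pixel_size_um = pixel_size_um),
            class = "fiber_image")
}

# Hann window of length n
hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Fourier directionality histogram of a fiber texture
#'
#' Estimates the distribution of local fiber orientations from the 2D power
#' spectrum: the image is cut into overlapping square tiles, each tile is
#' Hann-windowed and Fourier-transformed, and spectral energy is accumulated
#' by angular sector. A fiber oriented at real-space angle theta puts its
#' spectral energy along theta + 90 degrees, so sectors are rotated back
#' before binning. Energy per sector is density-corrected (divided by the
#' number of Cartesian frequency samples falling in the sector) so an
#' isotropic texture maps to a flat histogram.
#'
#' @param image A [fiber_image()] or plain numeric matrix.
#' @param n_bins Number of angular bins over \[-90, 90) (default 36, i.e.
#'   5-degree bins).
#' @param tile Tile side in pixels (default 64).
#' @return An [orientation_distribution()]; a constant image yields uniform
#'   weights with a warning and attribute `degenerate = TRUE`.
#' @export
orientation_histogram <- function(image, n_bins = 36, tile = 64) {
  if (inherits(image, "fiber_image")) image <- image$intensity
  if (!is.matrix(image) || nrow(image) < 64 || ncol(image) < 64) {
    abort("image must be a matrix of at least 64 x 64 pixels",
          class = "pillarforce_image_too_small")
  }
  bw <- 180 / n_bins
  centers <- standard_bin_centers(bw)
  if (sd(image) == 0) {
    warn("constant image: orientation is undefined; returning uniform weights",
         class = "pillarforce_degenerate_image")
    d <- orientation_distribution(centers, rep(1 / n_bins, n_bins),
                                  bin_width_deg = bw)
    attr(d, "degenerate") <- TRUE
    return(d)
  }

  # spectral angles and radii for one tile (computed once)
  freq <- function(n) {
    f <- c(seq(0, floor(n / 2)), seq(-(ceiling(n / 2) - 1), -1)) / n
    f
  }
  fx <- freq(tile)                    # column (x) frequencies
  fy <- freq(tile)                    # row (y) frequencies, y down in matrix
  kx <- matrix(fx, nrow = tile, ncol = tile, byrow = TRUE)
  ky_up <- -matrix(fy, nrow = tile, ncol = tile) # flip to y-up convention
  r <- sqrt(kx^2 + ky_up^2)
  # real-space fiber angle = spectral angle - 90 deg, wrapped to [-90, 90)
  ang <- atan2(ky_up, kx) * 180 / pi - 90
  ang <- ((ang + 90) %% 180) - 90
  keep <- r > 2 / tile & r <= 0.45    # drop DC/low-freq leakage and corners
  bin_idx <- pmin(floor((ang + 90) / bw) + 1, n_bins)
  grp <- factor(bin_idx[keep], levels = seq_len(n_bins))
  sector_n <- tabulate(bin_idx[keep], nbins = n_bins)

  w2d <- outer(hann(tile), hann(tile))
  step <- tile %/% 2
  rows <- seq(1, nrow(image) - tile + 1, by = step)
  cols <- seq(1, ncol(image) - tile + 1, by = step)
  acc <- numeric(n_bins)
  for (i in rows) {
    for (j in cols) {
      patch <- image[i:(i + tile - 1), j:(j + tile - 1)]
      patch <- (patch - mean(patch)) * w2d
      p <- Mod(fft(patch))^2
      acc <- acc + as.numeric(tapply(p[keep], grp, sum, default = 0))
    }
  }
  dens <- acc / pmax(sector_n, 1)
  if (sum(dens) == 0) {
    warn("no spectral energy in passband; returning uniform weights",
         class = "pillarforce_degenerate_image")
    d <- orientation_distribution(centers, rep(1 / n_bins, n_bins),
                                  bin_width_deg = bw)
    attr(d, "degenerate") <- TRUE
    return(d)
  }
  w <- dens / sum(dens)
  w <- w / sum(w) # guard rounding
  orientation_distribution(centers, w, bin_width_deg = bw)
}

#' Image-to-OI pipeline
#'
#' Composition of [orientation_histogram()] and [orientation_index()];
#' deterministic for a fixed input image.
#'
#' @inheritParams orientation_histogram
#' @return OI in \[0, 1\].
#' @export
oi_pipeline <- function(image, n_bins = 36, tile = 64) {
  orientation_index(orientation_histogram(image, n_bins = n_bins, tile = tile))
}

#' @method autoplot orientation_distribution
#' @export
autoplot.orientation_distribution <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$angle_deg, y = .data$weight)) +
    ggplot2::geom_col(width = attr(object, "bin_width_deg") %||% 2,
                      fill = "steelblue") +
    ggplot2::labs(x = "fiber angle (deg, 0 = interpillar axis)",
                  y = "P(theta)",
                  subtitle = sprintf("OI = %.3f", orientation_index(object))) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
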