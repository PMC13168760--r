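# Stimulation-chamber electric field: analytic parallel-plate estimate and
# a 2D finite-difference Laplace solver with insulating inclusions.

#' Analytic parallel-plate field estimate
#'
#' E = V / d. The standard chamber (40 V across 22 mm) gives about
#' 1.82 V/mm.
#'
#' @param voltage_v Applied potential difference (V), >= 0.
#' @param gap_mm Electrode separation (mm), > 0.
#' @return Field strength (V/mm).
#' @export
uniform_field_estimate <- function(voltage_v, gap_mm) {
  if (gap_mm <= 0) {
    abort("gap_mm must be > 0", class = "pillarforce_invalid_chamber")
  }
  if (voltage_v < 0) {
    abort("voltage_v must be >= 0", class = "pillarforce_invalid_chamber")
  }
  voltage_v / gap_mm
}

#' Stimulation chamber specification for the finite-difference solver
#'
#' Rectangular 2D cross-section with Dirichlet electrodes on the left
#' (0 V) and right (`voltage_v`) edges, zero-flux top/bottom walls, and
#' optional perfectly insulating inclusions (e.g. parylene-coated pillars)
#' given as a logical mask.
#'
#' @param voltage_v Applied voltage (V, default 40).
#' @param gap_mm Electrode gap = domain width (mm, default 22).
#' @param height_mm Domain height (mm, default 10).
#' @param spacing_mm Grid spacing (mm); must be < gap_mm / 10.
#' @param insulator_mask Optional logical matrix (rows = y, cols = x) of
#'   the solver grid marking insulating cells, or `NULL`.
#' @return Object of class `chamber_spec` with the grid coordinates.
#' @export
chamber_spec <- function(voltage_v = 40, gap_mm = 22, height_mm = 10,
                         spacing_mm = 0.25, insulator_mask = NULL) {
  if (voltage_v < 0 || gap_mm <= 0 || height_mm <= 0) {
    abort("invalid chamber dimensions",
          class = "pillarforce_invalid_chamber")
  }
  if (spacing_mm >= gap_mm / 10) {
    abort("spacing_mm must be < gap_mm / 10",
          class = "pillarforce_invalid_chamber")
  }
  x <- seq(0, gap_mm, by = spacing_mm)
  y <- seq(0, height_mm, by = spacing_mm)
  if (!is.null(insulator_mask)) {
    stopifnot(is.logical(insulator_mask),
              nrow(insulator_mask) == length(y),
              ncol(insulator_mask) == length(x))
  }
  structure(list(voltage_v = voltage_v, gap_mm = gap_mm,
                 height_mm = height_mm, spacing_mm = spacing_mm,
                 x_mm = x, y_mm = y, insulator_mask = insulator_mask),
            class = "chamber_spec")
}

#' Add a circular insulating inclusion to a chamber mask
#'
#' @param spec A [chamber_spec()].
#' @param center_mm Length-2 vector (x, y) of the circle center (mm).
#' @param radius_mm Circle radius (mm).
#' @return The spec with the inclusion added to its insulator mask.
#' @export
add_insulating_circle <- function(spec, center_mm, radius_mm) {
  stopifnot(inherits(spec, "chamber_spec"))
  m <- spec$insulator_mask
  if (is.null(m)) {
    m <- matrix(FALSE, length(spec$y_mm), length(spec$x_mm))
  }
  xs <- matrix(spec$x_mm, nrow = length(spec$y_mm),
               ncol = length(spec$x_mm), byrow = TRUE)
  ys <- matrix(spec$y_mm, nrow = length(spec$y_mm),
               ncol = length(spec$x_mm))
  m <- m | ((xs - center_mm[1])^2 + (ys - center_mm[2])^2 <= radius_mm^2)
  spec$insulator_mask <- m
  spec
}

#' Finite-difference Laplace solution of the chamber field
#'
#' Solves the 5-point-stencil discrete Laplace equation for the potential
#' with Dirichlet electrode columns, zero-flux outer walls and zero-flux
#' insulator boundaries (links into insulating or exterior cells are
#' dropped from the stencil). The sparse system is solved directly; the
#' maximum stencil residual relative to the applied voltage must be below
#' `tol` or an error is raised. |E| is obtained by central differences
#' (one-sided at boundaries).
#'
#' @param spec A [chamber_spec()].
#' @param tol Residual tolerance relative to the applied voltage
#'   (default 1e-6).
#' @return A `field_map` list with matrices `potential_v` and
#'   `e_mag_v_per_mm` (insulator cells `NA`), the grid vectors, and the
#'   attained `residual`.
#' @export
solve_field_fd <- function(spec, tol = 1e-6) {
  stopifnot(inherits(spec, "chamber_spec"))
  nx <- length(spec$x_mm)
  ny <- length(spec$y_mm)
  ins <- spec$insulator_mask
  if (is.null(ins)) ins <- matrix(FALSE, ny, nx)
  if (any(ins[, 1]) || any(ins[, nx])) {
    abort("insulator cells may not overlap the electrode columns",
          class = "pillarforce_invalid_chamber")
  }
  pot <- matrix(NA_real_, ny, nx)
  pot[, 1] <- 0
  pot[, nx] <- spec$voltage_v

  unknown <- !ins
  unknown[, c(1, nx)] <- FALSE
  uid <- matrix(0L, ny, nx)
  uid[unknown] <- seq_len(sum(unknown))
  n_unk <- sum(unknown)

  trips_i <- integer(5L * n_unk)
  trips_j <- integer(5L * n_unk)
  trips_x <- numeric(5L * n_unk)
  pos <- 0L
  rhs <- numeric(n_unk)
  nbr <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  cells <- which(unknown, arr.ind = TRUE)
  for (k in seq_len(nrow(cells))) {
    r <- cells[k, 1]; c <- cells[k, 2]
    me <- uid[r, c]
    diag_coef <- 0
    for (d in nbr) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > ny || cc < 1 || cc > nx) next      # outer wall: zero flux
      if (ins[rr, cc]) next                                  # insulator: zero flux
      diag_coef <- diag_coef + 1
      if (cc == 1 || cc == nx) {
        rhs[me] <- rhs[me] + pot[rr, cc]                     # Dirichlet neighbor
      } else {
        pos <- pos + 1L
        trips_i[pos] <- me; trips_j[pos] <- uid[rr, cc]; trips_x[pos] <- -1
      }
    }
    pos <- pos + 1L
    trips_i[pos] <- me; trips_j[pos] <- me; trips_x[pos] <- diag_coef
  }
  trips_i <- trips_i[seq_len(pos)]
  trips_j <- trips_j[seq_len(pos)]
  trips_x <- trips_x[seq_len(pos)]
  A <- Matrix::sparseMatrix(i = trips_i, j = trips_j, x = trips_x,
                            dims = c(n_unk, n_unk))
  sol <- as.numeric(Matrix::solve(A, rhs))
  res <- max(abs(A %*% sol - rhs)) / max(spec$voltage_v, 1)
  if (res > tol) {
    abort(sprintf("Laplace solve did not meet tolerance: residual %.3e", res),
          class = "pillarforce_solver_failure")
  }
  pot[unknown] <- sol
  pot[ins] <- NA_real_

  h <- spec$spacing_mm
  grad_1d <- function(v, h) {
    n <- length(v)
    g <- rep(NA_real_, n)
    if (n >= 3) g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
    if (n >= 2) {
      g[1] <- (v[2] - v[1]) / h
      g[n] <- (v[n] - v[n - 1]) / h
    }
    g
  }
  ex <- t(apply(pot, 1, grad_1d, h = h))
  ey <- apply(pot, 2, grad_1d, h = h)
  emag <- sqrt(ex^2 + ey^2)
  emag[ins] <- NA_real_
  structure(list(potential_v = pot, e_mag_v_per_mm = emag,
                 x_mm = spec$x_mm, y_mm = spec$y_mm,
                 residual = res, spec = spec),
            class = "field_map")
}

#' @export
print.field_map <- function(x, ...) {
  cat(sprintf("<field_map> %d x %d grid, residual %.2e\n",
              nrow(x$potential_v), ncol(x$potential_v), x$residual))
  cat(sprintf("  |E| interior range: %.3f - %.3f V/mm\n",
              min(x$e_mag_v_per_mm, na.rm = TRUE),
              max(x$e_mag_v_per_mm, na.rm = TRUE)))
  invisible(x)
}

#' Tidy a field map into a long tibble
#' @param x A `field_map`.
#' @param ... Unused.
#' @return Tibble with `x_mm`, `y_mm`, `potential_v`, `e_mag_v_per_mm`.
#' @method tidy field_map
#' @export
tidy.field_map <- function(x, ...) {
  out <- tidyr::expand_grid(y_mm = x$y_mm, x_mm = x$x_mm)
  out$potential_v <- as.numeric(t(x$potential_v))
  out$e_mag_v_per_mm <- as.numeric(t(x$e_mag_v_per_mm))
  out
}

#' @method autoplot field_map
#' @export
autoplot.field_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                               fill = .data$e_mag_v_per_mm)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|E| (V/mm)", na.value = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
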