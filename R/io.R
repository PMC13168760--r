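# File IO: image sequences (PNG/TIFF + YAML sidecar), trace/histogram CSV,
# metric JSON, and the run-config schema.

#' Write an image sequence to a directory of image frames
#'
#' Frames are written as zero-padded `frame_0000.png` (8- or 16-bit) or
#' `.tif` files with a `metadata.yaml` sidecar holding `pixel_size_um` and
#' `frame_rate_hz`. Intensities are clipped to \[0, 1\].
#'
#' @param seq An [image_sequence()].
#' @param dir Output directory (created if needed).
#' @param format `"tiff"` (16-bit, default) or `"png"` (8-bit, for small
#'   fixtures).
#' @return `dir`, invisibly.
#' @export
write_image_sequence <- function(seq, dir, format = c("tiff", "png")) {
  format <- match.arg(format)
  stopifnot(inherits(seq, "image_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(seq$frames)) {
    f <- pmin(pmax(seq$frames[[i]], 0), 1)
    path <- file.path(dir, sprintf("frame_%04d.%s", i - 1,
                                   if (format == "png") "png" else "tif"))
    if (format == "png") {
      png::writePNG(f, path)
    } else {
      tiff::writeTIFF(f, path, bits.per.sample = 16)
    }
  }
  yaml::write_yaml(list(pixel_size_um = seq$pixel_size_um,
                        frame_rate_hz = seq$frame_rate_hz,
                        n_frames = length(seq$frames)),
                   file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Read an image sequence from a directory of PNG/TIFF frames
#'
#' Expects the layout written by [write_image_sequence()]: sorted
#' `frame_*.png`/`.tif` files plus a `metadata.yaml` sidecar with
#' `pixel_size_um` and `frame_rate_hz` (both mandatory).
#'
#' @param dir Directory containing frames and `metadata.yaml`.
#' @return An [image_sequence()].
#' @export
read_image_sequence <- function(dir) {
  meta_path <- file.path(dir, "metadata.yaml")
  if (!file.exists(meta_path)) {
    abort("missing metadata.yaml sidecar (pixel_size_um, frame_rate_hz)",
          class = "pillarforce_missing_metadata")
  }
  meta <- yaml::read_yaml(meta_path)
  if (is.null(meta$pixel_size_um) || is.null(meta$frame_rate_hz)) {
    abort("metadata.yaml must provide pixel_size_um and frame_rate_hz",
          class = "pillarforce_missing_metadata")
  }
  files <- sort(list.files(dir, pattern = "^frame_.*\\.(png|tif|tiff)$",
                           full.names = TRUE))
  if (length(files) == 0) {
    abort("no frame_*.png / frame_*.tif files found",
          class = "pillarforce_missing_frames")
  }
  frames <- lapply(files, function(p) {
    m <- if (grepl("\\.png$", p)) png::readPNG(p) else tiff::readTIFF(p)
    if (length(dim(m)) == 3) m <- m[, , 1]
    m
  })
  image_sequence(frames, pixel_size_um = meta$pixel_size_um,
                 frame_rate_hz = meta$frame_rate_hz)
}

#' Write a deflection or force trace to CSV
#' @param trace A trace tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(tibble::as_tibble(trace), path)
  invisible(path)
}

#' Read a trace CSV written by [write_trace_csv()]
#' @param path CSV path.
#' @return A tibble; classed as a deflection trace if it has the standard
#'   columns.
#' @export
read_trace_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (all(c("left_defl_um", "right_defl_um", "distance_um") %in% names(out))) {
    class(out) <- c("deflection_trace", class(out))
  } else if (any(grepl("force_un$", names(out)))) {
    class(out) <- c("force_trace", class(out))
  }
  out
}

#' Write an orientation histogram to CSV (angle_deg, weight)
#' @param dist An [orientation_distribution()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_histogram_csv <- function(dist, path) {
  readr::write_csv(tibble::as_tibble(dist), path)
  invisible(path)
}

#' Write an orientation-index JSON record
#'
#' Record: `{OI, n_bins, bin_width_deg}`.
#'
#' @param dist An [orientation_distribution()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_oi_json <- function(dist, path) {
  jsonlite::write_json(
    list(OI = orientation_index(dist),
         n_bins = attr(dist, "n_bins"),
         bin_width_deg = attr(dist, "bin_width_deg")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Export a design-space sweep as CSV
#'
#' Header columns: `h_mm`, `b_um`, `k_uN_per_um`, `delta_um`.
#'
#' @param sweep Output of [design_space_sweep()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  readr::write_csv(
    tibble::as_tibble(sweep)[, c("h_mm", "b_um", "k_uN_per_um", "delta_um")],
    path)
  invisible(path)
}

#' Export a field map as a CSV grid
#' @param fmap A `field_map` from [solve_field_fd()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_field_csv <- function(fmap, path) {
  readr::write_csv(tidy(fmap), path)
  invisible(path)
}

# allowed run-config keys; every physical quantity carries its unit in the
# key name
run_config_keys <- c(
  "input_dir", "output_dir", "seed",
  "pixel_size_um", "frame_rate_hz",
  "semi_major_a_um", "semi_minor_b_um", "height_h_mm",
  "youngs_modulus_mpa", "poisson_nu",
  "stiffness_un_per_um",
  "frequency_hz", "pulse_width_ms", "amplitude_v", "electrode_gap_mm",
  "epochs", "windows_s"
)

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected (typo safety); every physical quantity carries
#' explicit units in its key name (`*_um`, `*_mm`, `*_hz`, ...). The pillar
#' stiffness has no silent default: pipelines that need `k` require either
#' `stiffness_un_per_um` (empirical calibration) or the full geometry block
#' to derive it from beam theory.
#'
#' @param path YAML config path.
#' @return Named list of validated config values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), run_config_keys)
  if (length(bad) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
          class = "pillarforce_invalid_config")
  }
  cfg
}

#' Resolve the pillar stiffness from a run configuration
#'
#' Prefers the empirical `stiffness_un_per_um` override; otherwise derives
#' k from the geometry block with [lateral_stiffness()]; errors if neither
#' is available (no silent defaults for a calibration constant).
#'
#' @param cfg Config list from [read_run_config()].
#' @return Stiffness (uN/um).
#' @export
resolve_stiffness <- function(cfg) {
  if (!is.null(cfg$stiffness_un_per_um)) {
    if (cfg$stiffness_un_per_um <= 0) {
      abort("stiffness_un_per_um must be > 0",
            class = "pillarforce_invalid_config")
    }
    return(cfg$stiffness_un_per_um)
  }
  geo_keys <- c("semi_major_a_um", "semi_minor_b_um", "height_h_mm",
                "youngs_modulus_mpa")
  if (all(geo_keys %in% names(cfg))) {
    g <- pillar_geometry(cfg$semi_major_a_um, cfg$semi_minor_b_um,
                         cfg$height_h_mm, cfg$youngs_modulus_mpa,
                         cfg$poisson_nu %||% 0.49)
    return(lateral_stiffness(g))
  }
  abort("no stiffness calibration: provide stiffness_un_per_um or a full geometry block",
        class = "pillarforce_missing_calibration")
}
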