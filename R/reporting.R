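# Pipeline entry points: one function per CLI subcommand. Each reads its
# inputs, runs the corresponding analysis stage, writes CSV/JSON artifacts
# plus a run log, and returns the artifact paths invisibly. The shipped
# `inst/cli/pillarforce` Rscript is a thin argv wrapper over these.

write_run_log <- function(out_dir, stage, params) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- c(sprintf("stage: %s", stage),
           sprintf("pillarforce: %s",
                   as.character(utils::packageVersion("pillarforce"))),
           sprintf("R: %s", R.version.string),
           vapply(names(params), function(n) {
             sprintf("%s: %s", n, paste(format(params[[n]], digits = 6),
                                        collapse = ", "))
           }, character(1)))
  writeLines(log, file.path(out_dir, sprintf("run_log_%s.txt", stage)))
}

#' Generate a synthetic dataset directory
#'
#' Writes `images/` (frame files + sidecar), `ground_truth.json` and a run
#' log under `out_dir`.
#'
#' @param out_dir Output directory.
#' @param n_frames,compaction_um,noise_sd,seed Passed to
#'   [generate_pillar_sequence()].
#' @param format Frame file format ("tiff" or "png").
#' @return Paths of written artifacts, invisibly.
#' @export
run_generate <- function(out_dir, n_frames = 8, compaction_um = 400,
                         noise_sd = 0.02, seed = 1, format = "png") {
  seq <- generate_pillar_sequence(n_frames = n_frames,
                                  compaction_um = compaction_um,
                                  noise_sd = noise_sd, seed = seed)
  img_dir <- file.path(out_dir, "images")
  write_image_sequence(seq, img_dir, format = format)
  gt_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(attr(seq, "ground_truth"), gt_path, digits = NA)
  write_run_log(out_dir, "generate",
                list(n_frames = n_frames, compaction_um = compaction_um,
                     noise_sd = noise_sd, seed = seed))
  invisible(list(images = img_dir, ground_truth = gt_path))
}

#' Track a pillar image sequence and write the deflection trace
#'
#' @param input_dir Directory of frames with `metadata.yaml`.
#' @param out_dir Output directory.
#' @return Path of the trace CSV, invisibly.
#' @export
run_track <- function(input_dir, out_dir) {
  seq <- read_image_sequence(input_dir)
  trace <- track_sequence(seq)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "trace.csv")
  write_trace_csv(trace, path)
  write_run_log(out_dir, "track", list(input_dir = input_dir,
                                       n_frames = length(seq$frames)))
  invisible(path)
}

#' Compute and persist the orientation index of a fiber image
#'
#' @param image_path PNG or TIFF fiber image.
#' @param out_dir Output directory for `histogram.csv` and `oi.json`.
#' @return The OI value, invisibly.
#' @export
run_oi <- function(image_path, out_dir) {
  m <- if (grepl("\\.png$", image_path)) {
    png::readPNG(image_path)
  } else {
    tiff::readTIFF(image_path)
  }
  if (length(dim(m)) == 3) m <- m[, , 1]
  dist <- orientation_histogram(m)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_histogram_csv(dist, file.path(out_dir, "histogram.csv"))
  write_oi_json(dist, file.path(out_dir, "oi.json"))
  write_run_log(out_dir, "oi", list(image = image_path))
  oi <- orientation_index(dist)
  message(sprintf("OI = %.4f", oi))
  invisible(oi)
}

#' Convert a deflection trace to forces and extract contraction metrics
#'
#' @param trace_path Deflection-trace CSV.
#' @param out_dir Output directory.
#' @param stiffness_un_per_um Pillar stiffness calibration (mandatory; no
#'   silent default).
#' @param twitch_freq_hz,tetanic_freq_hz Epoch frequencies.
#' @param epochs Optional epochs tibble; defaults assume the trace starts
#'   with 2 s of baseline followed by the twitch epoch then the tetanic
#'   epoch.
#' @return Metrics list, invisibly; writes `force_trace.csv` and
#'   `metrics.json`.
#' @export
run_contract <- function(trace_path, out_dir, stiffness_un_per_um,
                         twitch_freq_hz = 1, tetanic_freq_hz = 90,
                         epochs = NULL) {
  if (missing(stiffness_un_per_um) || is.null(stiffness_un_per_um)) {
    abort("no stiffness calibration supplied",
          class = "pillarforce_missing_calibration")
  }
  defl <- read_trace_csv(trace_path)
  ft <- force_trace(defl, stiffness_un_per_um)
  t_end <- max(ft$time_s)
  if (is.null(epochs)) {
    epochs <- tibble(t_start = c(2, 2 + (t_end - 2) * 0.6),
                     t_end = c(2 + (t_end - 2) * 0.6, t_end),
                     frequency_hz = c(twitch_freq_hz, tetanic_freq_hz))
  }
  proto <- stimulus_protocol(twitch_freq_hz, epochs = epochs)
  tw <- twitch_metrics(ft, proto, twitch_freq_hz)
  te <- tetanic_metrics(ft, proto, tetanic_freq_hz)
  fused <- fusion_ratio(tw, te)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_trace_csv(ft, file.path(out_dir, "force_trace.csv"))
  jsonlite::write_json(lapply(unclass(fused), as.numeric),
                       file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  write_run_log(out_dir, "contract",
                list(trace = trace_path, k = stiffness_un_per_um))
  invisible(fused)
}

#' Solve the chamber field and export the grid
#'
#' @param out_dir Output directory for `field.csv`.
#' @param voltage_v,gap_mm,height_mm,spacing_mm Chamber parameters.
#' @return The `field_map`, invisibly.
#' @export
run_field <- function(out_dir, voltage_v = 40, gap_mm = 22,
                      height_mm = 10, spacing_mm = 0.25) {
  fmap <- solve_field_fd(chamber_spec(voltage_v, gap_mm, height_mm,
                                      spacing_mm))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_field_csv(fmap, file.path(out_dir, "field.csv"))
  write_run_log(out_dir, "field",
                list(voltage_v = voltage_v, gap_mm = gap_mm,
                     uniform_estimate = uniform_field_estimate(voltage_v,
                                                               gap_mm)))
  invisible(fmap)
}

#' Merge per-tissue metrics into a cohort report with effect sizes
#'
#' Groups a per-tissue metric table by condition, summarises the chosen
#' force column, and appends pairwise effect sizes (Cohen's d and eta^2)
#' of every condition against the reference group. With fewer than two
#' groups the effect-size columns are empty and a warning is raised.
#'
#' @param metrics Data frame with a `group` column and the metric column.
#' @param out_dir Output directory for `report.csv`.
#' @param metric Metric column name (default "force_un").
#' @param reference Reference group label (default the first group).
#' @return The report tibble, invisibly.
#' @export
run_report <- function(metrics, out_dir, metric = "force_un",
                       reference = NULL) {
  stopifnot("group" %in% names(metrics), metric %in% names(metrics))
  groups <- unique(metrics$group)
  if (is.null(reference)) reference <- groups[1]
  summ <- metrics |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data[[metric]]),
                     sd = sd(.data[[metric]]), .groups = "drop")
  if (length(groups) < 2) {
    warn("only one group: effect-size columns left empty",
         class = "pillarforce_single_group")
    summ$cohens_d <- NA_real_
    summ$eta_squared <- NA_real_
  } else {
    ref_vals <- metrics[[metric]][metrics$group == reference]
    es <- purrr::map_dfr(summ$group, function(g) {
      if (g == reference) {
        return(tibble(cohens_d = NA_real_, eta_squared = NA_real_))
      }
      effect_sizes(metrics[[metric]][metrics$group == g], ref_vals)
    })
    summ <- dplyr::bind_cols(summ, es)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(summ, file.path(out_dir, "report.csv"))
  write_run_log(out_dir, "report",
                list(metric = metric, reference = reference))
  invisible(summ)
}
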