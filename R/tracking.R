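# Pillar centroid detection and frame-by-frame tracking.
#
# Detection pipeline: global Otsu threshold -> connected components -> area
# filter -> intensity-weighted (sub-pixel) centroid, ordered left-to-right.
# Coordinates are 0-based pixel centers; distances are center-to-center.

#' Calibrated grayscale image sequence
#'
#' @param frames List of numeric matrices, all the same shape.
#' @param pixel_size_um Pixel size (um/px), > 0.
#' @param frame_rate_hz Frame rate (Hz), > 0.
#' @param timestamps_s Optional explicit frame times (s); default
#'   `(0:(n-1)) / frame_rate_hz`.
#' @return Object of class `image_sequence`.
#' @export
image_sequence <- function(frames, pixel_size_um, frame_rate_hz,
                           timestamps_s = NULL) {
  if (!is.list(frames) || length(frames) == 0 ||
      !all(vapply(frames, is.matrix, logical(1)))) {
    abort("frames must be a nonempty list of matrices",
          class = "pillarforce_invalid_sequence")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all frames must have the same shape",
          class = "pillarforce_invalid_sequence")
  }
  if (pixel_size_um <= 0 || frame_rate_hz <= 0) {
    abort("pixel_size_um and frame_rate_hz must be > 0",
          class = "pillarforce_invalid_sequence")
  }
  if (is.null(timestamps_s)) {
    timestamps_s <- (seq_along(frames) - 1) / frame_rate_hz
  }
  stopifnot(length(timestamps_s) == length(frames))
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 frame_rate_hz = frame_rate_hz,
                 timestamps_s = as.numeric(timestamps_s)),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  cat(sprintf("<image_sequence> %d frames of %d x %d px, %g um/px, %g Hz\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              x$pixel_size_um, x$frame_rate_hz))
  invisible(x)
}

#' Detect bright pillar centroids in a single frame
#'
#' Thresholds the frame with Otsu's method, labels connected components,
#' discards components below `min_area_px`, and requires exactly
#' `expected_count` survivors. Centroids are intensity-weighted over each
#' component's above-threshold pixels (sub-pixel), returned in 0-based pixel
#' coordinates ordered left-to-right.
#'
#' @param frame Numeric matrix (rows = y, cols = x).
#' @param expected_count Number of pillars expected (default 2).
#' @param min_area_px Minimum component area in pixels (default 20).
#' @param frame_index Index used in error messages when called from a
#'   sequence loop.
#' @return Tibble with columns `x_px`, `y_px` (0-based pixel centers) and
#'   `area_px`.
#' @export
detect_pillar_centroids <- function(frame, expected_count = 2,
                                    min_area_px = 20, frame_index = NA) {
  if (!is.matrix(frame) || sd(frame) == 0) {
    abort("frame must be a non-constant numeric matrix",
          class = "pillarforce_detection_failure")
  }
  rng <- range(frame)
  norm <- (frame - rng[1]) / (rng[2] - rng[1])
  img <- EBImage::Image(norm)
  th <- EBImage::otsu(img, range = c(0, 1))
  mask <- img > th
  labels <- EBImage::bwlabel(mask)
  lab <- EBImage::imageData(labels)
  n_obj <- max(lab)
  if (n_obj == 0) {
    abort(sprintf("no blobs detected%s",
                  if (is.na(frame_index)) "" else
                    sprintf(" in frame %d", frame_index)),
          class = "pillarforce_detection_failure")
  }
  idx <- which(lab > 0)
  comp <- lab[idx]
  areas <- tabulate(comp, nbins = n_obj)
  keep_ids <- which(areas >= min_area_px)
  if (length(keep_ids) != expected_count) {
    abort(sprintf(
      "detected %d blob(s) after area filtering, expected %d%s",
      length(keep_ids), expected_count,
      if (is.na(frame_index)) "" else sprintf(" (frame %d)", frame_index)),
      class = "pillarforce_detection_failure")
  }
  # intensity-weighted centroids; EBImage Image is indexed [x, y]
  nr <- nrow(norm)
  cents <- purrr::map_dfr(keep_ids, function(id) {
    sel <- idx[comp == id]
    w <- norm[sel]
    row0 <- (sel - 1) %% nr        # 0-based row (y, downward)
    col0 <- (sel - 1) %/% nr       # 0-based column (x)
    tibble(x_px = sum(w * col0) / sum(w),
           y_px = sum(w * row0) / sum(w),
           area_px = length(sel))
  })
  dplyr::arrange(cents, .data$x_px)
}

#' Interpillar distance from two centroids
#'
#' Euclidean center-to-center distance scaled by the pixel size.
#'
#' @param centroids A two-row data frame with columns `x_px`, `y_px`.
#' @param pixel_size_um Pixel size (um/px).
#' @return Distance in um; 0 with a warning for coincident points.
#' @export
interpillar_distance <- function(centroids, pixel_size_um) {
  stopifnot(nrow(centroids) == 2)
  d_px <- sqrt(diff(centroids$x_px)^2 + diff(centroids$y_px)^2)
  if (d_px == 0) {
    warn("coincident centroids: interpillar distance is 0",
         class = "pillarforce_coincident_centroids")
  }
  as.numeric(d_px * pixel_size_um)
}

#' Track the two pillars through an image sequence
#'
#' Detects both pillar centroids in every frame, assigns identities by
#' nearest neighbor to the previous frame, and reports per-pillar deflection
#' as the signed displacement along the frame-0 interpillar axis relative to
#' frame 0 (motion toward the opposite pillar is positive, i.e. contraction
#' positive). Pre-tension present before the first frame is by construction
#' not recoverable. An assignment step larger than half the current
#' interpillar distance is treated as an identity swap and raises an error.
#'
#' @param seq An [image_sequence()].
#' @param expected_count Number of pillars (2).
#' @param min_area_px Detection area filter, see
#'   [detect_pillar_centroids()].
#' @return A `deflection_trace`: tibble with columns `time_s`,
#'   `left_defl_um`, `right_defl_um`, `distance_um`, plus attribute
#'   `centroids_px` (per-frame raw centroids).
#' @export
track_sequence <- function(seq, expected_count = 2, min_area_px = 20) {
  stopifnot(inherits(seq, "image_sequence"))
  n <- length(seq$frames)
  cents <- vector("list", n)
  cents[[1]] <- detect_pillar_centroids(seq$frames[[1]], expected_count,
                                        min_area_px, frame_index = 1)
  for (i in seq_len(n)[-1]) {
    det <- detect_pillar_centroids(seq$frames[[i]], expected_count,
                                   min_area_px, frame_index = i)
    prev <- cents[[i - 1]]
    # nearest-neighbor identity assignment to previous frame
    cost <- outer(seq_len(expected_count), seq_len(expected_count),
                  Vectorize(function(p, q) {
                    sqrt((prev$x_px[p] - det$x_px[q])^2 +
                         (prev$y_px[p] - det$y_px[q])^2)
                  }))
    assign_q <- apply(cost, 1, which.min)
    if (anyDuplicated(assign_q)) {
      abort(sprintf("ambiguous identity assignment at frame %d", i),
            class = "pillarforce_tracking_error")
    }
    step <- cost[cbind(seq_len(expected_count), assign_q)]
    d_now <- sqrt(diff(det$x_px)^2 + diff(det$y_px)^2)
    if (any(step > d_now / 2)) {
      abort(sprintf("identity swap suspected at frame %d (step > half interpillar distance)", i),
            class = "pillarforce_tracking_error")
    }
    cents[[i]] <- det[assign_q, ]
  }
  ref <- cents[[1]]
  # unit vector along the frame-0 interpillar axis, left -> right
  u <- c(ref$x_px[2] - ref$x_px[1], ref$y_px[2] - ref$y_px[1])
  u <- u / sqrt(sum(u^2))
  px <- seq$pixel_size_um
  left <- vapply(cents, function(cc) {
    sum((c(cc$x_px[1], cc$y_px[1]) - c(ref$x_px[1], ref$y_px[1])) * u)
  }, numeric(1)) * px            # toward right pillar positive
  right <- vapply(cents, function(cc) {
    -sum((c(cc$x_px[2], cc$y_px[2]) - c(ref$x_px[2], ref$y_px[2])) * u)
  }, numeric(1)) * px            # toward left pillar positive
  dist <- vapply(cents, function(cc) {
    sqrt(diff(cc$x_px)^2 + diff(cc$y_px)^2)
  }, numeric(1)) * px
  out <- tibble(time_s = seq$timestamps_s,
                left_defl_um = left, right_defl_um = right,
                distance_um = dist)
  structure(out, centroids_px = cents, pixel_size_um = px,
            frame_rate_hz = seq$frame_rate_hz,
            class = c("deflection_trace", class(out)))
}

#' Per-window interpillar-distance reductions (compaction)
#'
#' reduction = distance(t0) - distance(t1); positive values mean the tissue
#' shortened over the window. Distances at window edges are linearly
#' interpolated between sampled frames.
#'
#' @param trace A `deflection_trace` (or any tibble with `time_s` and
#'   `distance_um`).
#' @param windows Data frame (or list of 2-vectors) of window start/end
#'   times `t0`, `t1` in seconds.
#' @return Tibble with `t0`, `t1`, `reduction_um`.
#' @export
compaction_metrics <- function(trace, windows) {
  if (!is.data.frame(windows)) {
    windows <- tibble(t0 = vapply(windows, `[`, numeric(1), 1),
                      t1 = vapply(windows, `[`, numeric(1), 2))
  }
  tr <- range(trace$time_s)
  if (any(windows$t0 < tr[1] - 1e-9) || any(windows$t1 > tr[2] + 1e-9)) {
    abort("requested window outside the trace time range",
          class = "pillarforce_window_out_of_range")
  }
  d_at <- function(t) approx(trace$time_s, trace$distance_um, xout = t,
                             rule = 2)$y
  dplyr::mutate(tibble::as_tibble(windows),
                reduction_um = d_at(.data$t0) - d_at(.data$t1))
}

#' @method autoplot deflection_trace
#' @export
autoplot.deflection_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("left_defl_um", "right_defl_um"),
                              names_to = "pillar", values_to = "defl_um")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$defl_um,
                                     color = .data$pillar)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "deflection (um, contraction +)") +
    ggplot2::theme_minimal()
}
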