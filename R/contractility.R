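# Deflection -> force conversion and twitch/tetanus metric extraction under
# electrical stimulation protocols.

#' Electrical stimulation protocol
#'
#' Field stimulation descriptor. Twitch measurements use 1 Hz with a 10-ms
#' pulse width; tetanus uses 90 Hz with the same pulse width; the standard
#' frequency sweep is 0.5, 1, 2, 3 and 90 Hz. Amplitude and electrode gap
#' give the nominal field via [uniform_field_estimate()].
#'
#' @param frequency_hz Stimulation frequency (Hz), > 0.
#' @param pulse_width_ms Pulse width (ms), > 0 (default 10).
#' @param amplitude_v Applied voltage (V, default 40).
#' @param electrode_gap_mm Electrode separation (mm, default 22).
#' @param epochs Tibble with `t_start`, `t_end`, `frequency_hz` giving the
#'   stimulation schedule (s); default one epoch \[2, 12\] s at
#'   `frequency_hz`, leaving a 2-s pre-stimulus baseline.
#' @return Object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(frequency_hz, pulse_width_ms = 10,
                              amplitude_v = 40, electrode_gap_mm = 22,
                              epochs = NULL) {
  if (frequency_hz <= 0 || pulse_width_ms <= 0) {
    abort("frequency_hz and pulse_width_ms must be > 0",
          class = "pillarforce_invalid_protocol")
  }
  if (is.null(epochs)) {
    epochs <- tibble(t_start = 2, t_end = 12, frequency_hz = frequency_hz)
  }
  epochs <- dplyr::arrange(tibble::as_tibble(epochs), .data$t_start)
  if (nrow(epochs) > 1 &&
      any(epochs$t_start[-1] < epochs$t_end[-nrow(epochs)])) {
    abort("epochs must not overlap", class = "pillarforce_invalid_protocol")
  }
  structure(list(frequency_hz = frequency_hz,
                 pulse_width_ms = pulse_width_ms,
                 amplitude_v = amplitude_v,
                 electrode_gap_mm = electrode_gap_mm,
                 epochs = epochs),
            class = "stimulus_protocol")
}

#' Convert a deflection trace to a force trace
#'
#' Applies Hooke's law per frame and per pillar: F = k * delta. Reports
#' per-pillar forces and their sum (the two-pillar total), following the
#' convention that a 76-uN total contraction corresponds to 38 uN per
#' pillar.
#'
#' @param deflection A `deflection_trace` from [track_sequence()], or any
#'   tibble with `time_s`, `left_defl_um`, `right_defl_um`.
#' @param stiffness_un_per_um Calibrated pillar stiffness k (uN/um); no
#'   default — supply either [lateral_stiffness()] output or an empirical
#'   calibration (e.g. 0.249).
#' @return A `force_trace` tibble: `time_s`, `left_force_un`,
#'   `right_force_un`, `total_force_un`.
#' @export
force_trace <- function(deflection, stiffness_un_per_um) {
  if (stiffness_un_per_um <= 0) {
    abort("stiffness_un_per_um must be > 0",
          class = "pillarforce_invalid_stiffness")
  }
  need <- c("time_s", "left_defl_um", "right_defl_um")
  if (!all(need %in% names(deflection))) {
    abort("deflection must have columns time_s, left_defl_um, right_defl_um",
          class = "pillarforce_invalid_trace")
  }
  out <- tibble(
    time_s = deflection$time_s,
    left_force_un = force_from_deflection(stiffness_un_per_um,
                                          deflection$left_defl_um),
    right_force_un = force_from_deflection(stiffness_un_per_um,
                                           deflection$right_defl_um)
  )
  out$total_force_un <- out$left_force_un + out$right_force_un
  structure(out, stiffness_un_per_um = stiffness_un_per_um,
            class = c("force_trace", class(out)))
}

# single force column used by the metric extractors
metric_signal <- function(force, per_pillar = TRUE) {
  if (is.data.frame(force)) {
    col <- if (per_pillar && "left_force_un" %in% names(force))
      "left_force_un" else if ("total_force_un" %in% names(force))
      "total_force_un" else "force_un"
    list(t = force$time_s, f = force[[col]])
  } else {
    abort("force must be a data frame trace",
          class = "pillarforce_invalid_trace")
  }
}

# baseline = median of the 2 s preceding the epoch; falls back to the
# epoch's rolling minimum when no pre-stimulus samples exist
epoch_baseline <- function(t, f, t_start, pre_s = 2) {
  pre <- t >= t_start - pre_s & t < t_start
  if (any(pre)) median(f[pre]) else min(f[t >= t_start])
}

#' Twitch metrics from a force trace
#'
#' Locates the epoch at the twitch frequency, slices it into stimulation
#' periods, and reports the mean per-period peak force above baseline
#' (baseline = median of the 2 s preceding the epoch). Peaks must exceed
#' the noise floor (3 x the median absolute deviation of the within-period
#' detrended signal); if none do, the amplitude is 0 with a warning.
#'
#' @param force A `force_trace` (or tibble with `time_s` and a force
#'   column).
#' @param protocol A [stimulus_protocol()].
#' @param twitch_freq_hz Frequency identifying the twitch epoch (default 1).
#' @param per_pillar Use the per-pillar (left) force column (default) or
#'   the two-pillar total.
#' @return A `contraction_metrics` object (see [tidy()]): baseline,
#'   twitch amplitude, peak count, n periods.
#' @export
twitch_metrics <- function(force, protocol, twitch_freq_hz = 1,
                           per_pillar = TRUE) {
  sig <- metric_signal(force, per_pillar)
  ep <- protocol$epochs[protocol$epochs$frequency_hz == twitch_freq_hz, ]
  if (nrow(ep) == 0) {
    abort("no epoch at the twitch frequency in the protocol",
          class = "pillarforce_invalid_protocol")
  }
  ep <- ep[1, ]
  period <- 1 / twitch_freq_hz
  if ((ep$t_end - ep$t_start) < 3 * period) {
    abort("twitch epoch must span at least 3 stimulation periods",
          class = "pillarforce_invalid_protocol")
  }
  base <- epoch_baseline(sig$t, sig$f, ep$t_start)
  in_ep <- sig$t >= ep$t_start & sig$t < ep$t_end
  t_ep <- sig$t[in_ep]
  f_ep <- sig$f[in_ep]
  per_idx <- floor((t_ep - ep$t_start) / period)
  maxima <- tapply(f_ep, per_idx, max)
  noise <- mad(diff(f_ep)) / sqrt(2)
  above <- maxima - base > 3 * noise
  if (!any(above)) {
    warn("no twitch peaks above the noise floor; amplitude set to 0",
         class = "pillarforce_no_peaks")
    amp <- 0
    n_peaks <- 0L
  } else {
    amp <- mean(maxima[above]) - base
    n_peaks <- sum(above)
  }
  new_contraction_metrics(
    baseline_force_un = base, twitch_amplitude_un = amp,
    tetanic_force_un = NA_real_, fusion_ratio = NA_real_,
    n_peaks = n_peaks,
    n_periods = length(maxima),
    frequency_hz = twitch_freq_hz
  )
}

#' Tetanic metrics from a force trace
#'
#' Locates the epoch at the tetanic frequency and reports the mean force of
#' its plateau window (the last 50% of the epoch, excluding the fusion
#' transient) above baseline, plus the within-plateau ripple
#' (peak-to-trough). Warns if the epoch is shorter than twice the supplied
#' twitch relaxation time, where the plateau estimate is unreliable.
#'
#' @inheritParams twitch_metrics
#' @param tetanic_freq_hz Frequency identifying the tetanic epoch
#'   (default 90).
#' @param relaxation_tau_s Twitch relaxation time scale used for the
#'   epoch-length sanity check (default 0.2 s).
#' @return A `contraction_metrics` object with `tetanic_force_un` and
#'   `ripple_un` filled in.
#' @export
tetanic_metrics <- function(force, protocol, tetanic_freq_hz = 90,
                            per_pillar = TRUE, relaxation_tau_s = 0.2) {
  sig <- metric_signal(force, per_pillar)
  ep <- protocol$epochs[protocol$epochs$frequency_hz == tetanic_freq_hz, ]
  if (nrow(ep) == 0) {
    abort("no epoch at the tetanic frequency in the protocol",
          class = "pillarforce_invalid_protocol")
  }
  ep <- ep[1, ]
  if ((ep$t_end - ep$t_start) < 2 * relaxation_tau_s) {
    warn("tetanic epoch shorter than 2x the twitch relaxation time; plateau unreliable",
         class = "pillarforce_unreliable_plateau")
  }
  base <- epoch_baseline(sig$t, sig$f, ep$t_start)
  t_mid <- (ep$t_start + ep$t_end) / 2
  plat <- sig$t >= t_mid & sig$t < ep$t_end
  f_pl <- sig$f[plat]
  new_contraction_metrics(
    baseline_force_un = base, twitch_amplitude_un = NA_real_,
    tetanic_force_un = mean(f_pl) - base, fusion_ratio = NA_real_,
    ripple_un = diff(range(f_pl)),
    frequency_hz = tetanic_freq_hz
  )
}

new_contraction_metrics <- function(...) {
  structure(purrr::compact(list(...)), class = "contraction_metrics")
}

#' @export
print.contraction_metrics <- function(x, ...) {
  cat("<contraction_metrics>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' @method tidy contraction_metrics
#' @export
tidy.contraction_metrics <- function(x, ...) {
  tibble(metric = names(x),
         value = vapply(x, as.numeric, numeric(1)))
}

#' @method glance contraction_metrics
#' @export
glance.contraction_metrics <- function(x, ...) {
  tibble::as_tibble(lapply(x, as.numeric))
}

#' Combine twitch and tetanic metrics into a fusion ratio
#'
#' fusion_ratio = tetanic plateau force / twitch amplitude; > 1 indicates
#' temporal summation of twitches.
#'
#' @param twitch,tetanic `contraction_metrics` from [twitch_metrics()] and
#'   [tetanic_metrics()].
#' @return A merged `contraction_metrics` with `fusion_ratio`.
#' @export
fusion_ratio <- function(twitch, tetanic) {
  new_contraction_metrics(
    baseline_force_un = twitch$baseline_force_un,
    twitch_amplitude_un = twitch$twitch_amplitude_un,
    tetanic_force_un = tetanic$tetanic_force_un,
    fusion_ratio = tetanic$tetanic_force_un / twitch$twitch_amplitude_un
  )
}

#' Simulate a stimulated force trace (kernel-summation model)
#'
#' Linear summation of per-pulse alpha-like twitch kernels
#' `g(t) = A' (exp(-t/tau_decay) - exp(-t/tau_rise))`, normalised so the
#' kernel peak equals `amplitude_un`, evaluated at the protocol's pulse
#' times, with optional additive Gaussian noise. This is a deliberate
#' linear simplification of excitation-contraction dynamics: at high
#' stimulation frequency the kernels fuse into a plateau exceeding the
#' single-twitch amplitude, reproducing the twitch/tetanus ordering.
#'
#' @param protocol A [stimulus_protocol()].
#' @param amplitude_un Single-twitch peak amplitude (uN).
#' @param tau_rise_s,tau_decay_s Kernel rise and decay time constants (s);
#'   defaults 0.03 and 0.2.
#' @param noise_sd_un Gaussian noise SD (uN), default 0.
#' @param fs_hz Sampling rate (Hz), default 200.
#' @param duration_s Trace length (s); default covers all epochs + 2 s.
#' @param seed RNG seed for the noise (deterministic given seed).
#' @return A `force_trace` tibble with columns `time_s`, `force_un`.
#' @export
simulate_contraction <- function(protocol, amplitude_un = 10,
                                 tau_rise_s = 0.03, tau_decay_s = 0.2,
                                 noise_sd_un = 0, fs_hz = 200,
                                 duration_s = NULL, seed = 1) {
  if (tau_rise_s <= 0 || tau_decay_s <= 0 || tau_rise_s >= tau_decay_s) {
    abort("require 0 < tau_rise_s < tau_decay_s",
          class = "pillarforce_invalid_kernel")
  }
  if (is.null(duration_s)) duration_s <- max(protocol$epochs$t_end) + 2
  t <- seq(0, duration_s, by = 1 / fs_hz)
  f <- numeric(length(t))
  # peak of (exp(-t/td) - exp(-t/tr)) is at t* = tr*td/(td-tr)*log(td/tr)
  tstar <- tau_rise_s * tau_decay_s / (tau_decay_s - tau_rise_s) *
    log(tau_decay_s / tau_rise_s)
  peak <- exp(-tstar / tau_decay_s) - exp(-tstar / tau_rise_s)
  for (i in seq_len(nrow(protocol$epochs))) {
    ep <- protocol$epochs[i, ]
    pulses <- seq(ep$t_start, ep$t_end - 1e-9, by = 1 / ep$frequency_hz)
    for (tp in pulses) {
      s <- t >= tp
      dt <- t[s] - tp
      f[s] <- f[s] + amplitude_un / peak *
        (exp(-dt / tau_decay_s) - exp(-dt / tau_rise_s))
    }
  }
  if (noise_sd_un > 0) {
    old <- .Random.seed_save()
    set.seed(seed)
    f <- f + rnorm(length(f), sd = noise_sd_un)
    .Random.seed_restore(old)
  }
  out <- tibble(time_s = t, force_un = f)
  structure(out, class = c("force_trace", class(out)))
}

# save/restore global RNG state so seeded generators do not clobber it
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Dose-response summary table
#'
#' Per-compound, per-dose force summaries with the ratio to the vehicle
#' group and a monotonic-trend flag from the Spearman rank correlation of
#' dose versus group mean force ("increasing", "decreasing" or "none").
#'
#' @param data Data frame of per-tissue metrics with at least the columns
#'   named by `force`, `compound` and `dose`.
#' @param force,compound,dose Column names (strings).
#' @param vehicle_label Dose/compound label identifying the vehicle group
#'   (matched against the `compound` column; default "vehicle").
#' @return A `dose_response` tibble: compound, dose, n, mean/sd force,
#'   ratio_to_vehicle, trend.
#' @export
dose_response_summary <- function(data, force = "force_un",
                                  compound = "compound", dose = "dose",
                                  vehicle_label = "vehicle") {
  stopifnot(all(c(force, compound, dose) %in% names(data)))
  veh <- data[data[[compound]] == vehicle_label, ]
  if (nrow(veh) == 0) {
    abort("missing vehicle group", class = "pillarforce_missing_vehicle")
  }
  if (length(setdiff(unique(data[[compound]]), vehicle_label)) < 1 ||
      length(unique(data[[dose]][data[[compound]] != vehicle_label])) < 2) {
    abort("need at least 2 dose groups plus vehicle",
          class = "pillarforce_invalid_design")
  }
  veh_mean <- mean(veh[[force]])
  summ <- data |>
    dplyr::group_by(.data[[compound]], .data[[dose]]) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_force_un = mean(.data[[force]]),
                     sd_force_un = sd(.data[[force]]),
                     .groups = "drop") |>
    dplyr::mutate(ratio_to_vehicle = .data$mean_force_un / veh_mean)
  trend_of <- function(d, m) {
    if (length(unique(m)) == 1) return("none")
    rho <- suppressWarnings(cor(d, m, method = "spearman"))
    if (is.na(rho) || rho == 0) "none"
    else if (rho > 0) "increasing" else "decreasing"
  }
  trends <- summ |>
    dplyr::filter(.data[[compound]] != vehicle_label) |>
    dplyr::group_by(.data[[compound]]) |>
    dplyr::summarise(trend = trend_of(.data[[dose]], .data$mean_force_un),
                     .groups = "drop")
  out <- dplyr::left_join(summ, trends, by = compound)
  out$trend[out[[compound]] == vehicle_label] <- NA_character_
  structure(out, class = c("dose_response", class(out)))
}

#' @method autoplot dose_response
#' @export
autoplot.dose_response <- function(object, ...) {
  cmp <- names(object)[1]
  dose <- names(object)[2]
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data[[dose]]),
                               y = .data$mean_force_un,
                               fill = .data[[cmp]])) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_force_un - .data$sd_force_un,
                   ymax = .data$mean_force_un + .data$sd_force_un),
      position = ggplot2::position_dodge(0.9), width = 0.2) +
    ggplot2::labs(x = "dose", y = "force (uN)") +
    ggplot2::theme_minimal()
}

#' Two-group effect sizes: Cohen's d and eta squared
#'
#' d = (mean(a) - mean(b)) / s_pooled with the pooled (Bessel-corrected)
#' SD; eta^2 = SS_between / SS_total for the two-group one-way layout.
#' Swapping the groups flips the sign of d and leaves eta^2 unchanged.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return Tibble with columns `cohens_d`, `eta_squared`.
#' @export
effect_sizes <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) {
    abort("each group needs n >= 2", class = "pillarforce_invalid_groups")
  }
  sp2 <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / (na + nb - 2)
  if (sp2 == 0) {
    abort("zero pooled variance: effect size undefined",
          class = "pillarforce_zero_variance")
  }
  d <- (mean(group_a) - mean(group_b)) / sqrt(sp2)
  all <- c(group_a, group_b)
  gm <- mean(all)
  ss_b <- na * (mean(group_a) - gm)^2 + nb * (mean(group_b) - gm)^2
  ss_t <- sum((all - gm)^2)
  tibble(cohens_d = d, eta_squared = ss_b / ss_t)
}

#' @method autoplot force_trace
#' @export
autoplot.force_trace <- function(object, ...) {
  col <- if ("force_un" %in% names(object)) "force_un" else "left_force_un"
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time_s, y = .data[[col]])) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "force (uN)") +
    ggplot2::theme_minimal()
}
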