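# Shared fixtures for the suite. Everything is generated in code; no binary
# fixtures ship with the package.

default_geometry <- function() pillar_geometry()

# twitch + tetanus protocol with a 2-s pre-stimulus baseline
two_epoch_protocol <- function() {
  stimulus_protocol(
    frequency_hz = 1,
    epochs = tibble::tibble(t_start = c(2, 14), t_end = c(12, 18),
                            frequency_hz = c(1, 90)))
}

# uniform 36-bin distribution at the standard bin centers
uniform_36 <- function() {
  orientation_distribution(standard_bin_centers(), rep(1 / 36, 36),
                           bin_width_deg = 5)
}

# brute-force second moment of an ellipse by midpoint-grid integration of
# y^2 over the section (independent of the closed form)
second_moment_numeric <- function(a_um, b_um, n = 2000) {
  a <- a_um * 1e-6
  b <- b_um * 1e-6
  ys <- seq(-b + b / n, b - b / n, length.out = n)
  dy <- 2 * b / n
  # chord width at height y: 2 a sqrt(1 - (y/b)^2); bending axis is y (= b)
  sum(ys^2 * 2 * a * sqrt(pmax(0, 1 - (ys / b)^2))) * dy
}

# wrap angle difference to [-90, 90)
ang_diff <- function(a, b) ((a - b + 90) %% 180) - 90
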