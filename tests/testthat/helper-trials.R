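# Builders for deterministic fixture trials, generated in code.

# Noise-free outward Archimedean tracing at constant angular rate, starting
# at the template centre (radius 0 at t = 0).
ideal_spiral_trial <- function(pitch = 10, omega = 1.9, n = 100, rate = 10,
                               center = c(0, 0), phase = 0, ...) {
  t <- (seq_len(n) - 1L) / rate
  theta <- omega * t + phase
  r <- pitch * omega * t
  spiral_trial(x = center[1L] + r * cos(theta),
               y = center[2L] + r * sin(theta),
               t = t, ...)
}

# Noise-free Archimedean tracing at constant tangential (pen) speed: samples
# equally spaced in arc length, the way a steady hand traces the template.
constant_speed_spiral_trial <- function(pitch = 10, turns = 3, n = 100,
                                        rate = 10, center = c(0, 0)) {
  theta_max <- 2 * pi * turns
  grid <- seq(0, theta_max, length.out = 20000)
  arc <- (pitch / 2) * (grid * sqrt(1 + grid^2) + asinh(grid))
  s_targets <- seq(0, max(arc), length.out = n)
  theta <- approx(arc, grid, xout = s_targets)$y
  r <- pitch * theta
  t <- (seq_len(n) - 1L) / rate
  spiral_trial(x = center[1L] + r * cos(theta),
               y = center[2L] + r * sin(theta), t = t)
}

# Straight-line tracing at constant speed along +x.
uniform_line_trial <- function(speed = 100, n = 20, rate = 10) {
  t <- (seq_len(n) - 1L) / rate
  spiral_trial(x = speed * t, y = rep(0, n), t = t)
}

# Reverse the sample order of a trial, remapping time to stay increasing.
reverse_trial <- function(trial) {
  s <- trial$samples
  n <- nrow(s)
  spiral_trial(x = rev(s$x), y = rev(s$y),
               t = s$t[n] - rev(s$t))
}

brady_label <- function(lbl) {
  factor(ifelse(lbl == "bradykinetic", "bradykinesia", "dyskinesia"),
         levels = c("bradykinesia", "dyskinesia"))
}
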