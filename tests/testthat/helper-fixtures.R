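# Small fixtures shared across test files; everything is generated in code.

# Clean raised-cosine pulse train at `rate_hz` (no noise), for estimator
# oracles independent of the cardiac simulator.
pulse_train <- function(rate_hz, duration_s, fs = 100, width_frac = 0.4) {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  period <- 1 / rate_hz
  w <- width_frac * period
  phase <- (t + period / 2) %% period - period / 2
  ifelse(abs(phase) < w / 2, 0.5 * (1 + cos(2 * pi * phase / w)), 0)
}

# Straight-line track at constant speed, starting at the arena centre.
line_track <- function(speed_mm_s, duration_s, fs = 10, id = "l1") {
  t <- seq(0, duration_s, by = 1 / fs)
  data.frame(larva_id = id, time_s = t, x_mm = 1 + speed_mm_s * t / sqrt(2),
             y_mm = 1 + speed_mm_s * t / sqrt(2), stringsAsFactors = FALSE)
}

# Uniform-scaling displacement field u(x) = (s - 1) x on a grid.
scaling_field <- function(shape, voxel_size_um, s) {
  u <- array(0, c(shape, 3))
  for (i in 1:3) {
    co <- (seq_len(shape[i])) * voxel_size_um[i]
    u[, , , i] <- array(rep((s - 1) * co,
                            each = prod(shape[seq_len(i - 1)])), shape)
  }
  u
}
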