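# Shared fixtures and independent oracles, all built in code at test time.

# Brute-force trigger oracle: scan every 1 kHz sample, fire on the first
# per-axis threshold crossing outside the refractory interval. Returns
# 1-based trigger sample indices. Deliberately written as a plain loop,
# independent of detect_events' vectorized scan.
brute_force_triggers <- function(lin_acc, threshold, refractory_ms) {
  trig <- integer(0)
  last <- -Inf
  for (i in seq_len(ncol(lin_acc))) {
    if (max(abs(lin_acc[, i])) > threshold && (i - last) > refractory_ms) {
      trig <- c(trig, i)
      last <- i
    }
  }
  trig
}

# A haversine pulse on a 1 kHz trace: amplitude A (g) along +x, base width
# w_ms, pulse starting at start_ms.
pulse_trace <- function(duration_s, pulses, device_id = "fix") {
  n <- duration_s * 1000
  lin <- matrix(0, 3, n)
  for (p in pulses) {
    idx <- seq(p$start_ms, p$start_ms + p$width_ms) + 1L
    idx <- idx[idx >= 1 & idx <= n]
    t <- (idx - 1) - p$start_ms
    lin[1, idx] <- lin[1, idx] + p$A * sin(pi * t / p$width_ms)^2
  }
  session_trace(lin, matrix(0, 3, 8 * n), device_id = device_id)
}

# Small labeled event set with several groups, cheap to build.
tiny_dataset <- function(n_true = 10, n_false = 12, seed = 42) {
  generate_dataset(n_true, n_false, seed = seed, group_size = 5L)
}

# One noise-free impact event along a given axis.
clean_impact <- function(peak = 30, width = 10, axis = c(1, 0, 0), seed = 1) {
  simulate_true_impact(
    impact_params(peak_lin_acc = peak, pulse_width = width, direction = axis),
    seed = seed, noise_lin_sd = 0, noise_ang_sd = 0)
}

expect_valid_probability <- function(p) {
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0 & p <= 1))
}
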