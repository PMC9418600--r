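# Shared fixtures: short recordings and coarse solver settings keep the unit
# suite fast while exercising the same code paths as the full-scale runs.

quick_config <- function(duration = 20, seed = 1L) {
  recording_config(sampling_rate = 1000, duration = duration, seed = seed)
}

quiet_noise <- function() noise_model(white_sd = 0, drift_amplitude = 0)

coarse_domain <- function() sim_domain(grid_spacing = 5)

# one spectral bin of the default 4096-point transform at 1 kHz
default_bin <- 1000 / 4096

expect_within_bin <- function(peak, freq, bin = default_bin) {
  expect_lte(abs(peak - freq), bin + 1e-12)
}

# closed-form moving-average (Dirichlet kernel) gain at frequency f
dirichlet_gain <- function(f, n, fs) {
  abs(sin(pi * f * n / fs) / (n * sin(pi * f / fs)))
}

# amplitude of a sinusoidal component by least squares (phase-free)
fitted_amplitude <- function(x, f, fs) {
  t <- (seq_along(x) - 1) / fs
  co <- stats::coef(stats::lm(x ~ sin(2 * pi * f * t) + cos(2 * pi * f * t)))
  unname(sqrt(co[2]^2 + co[3]^2))
}
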