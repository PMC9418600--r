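#' Recording configuration
#'
#' Sampling parameters shared by all synthetic recordings. The 1 kHz default
#' matches the data-logger rate used for the bench voltage measurements.
#'
#' @param sampling_rate sampling rate in Hz (default 1000).
#' @param duration recording length in s (default 60).
#' @param seed integer RNG seed; identical seed + parameters give bit-identical
#'   output.
#' @return a `recording_config` list.
#' @export
recording_config <- function(sampling_rate = 1000, duration = 60, seed = 1L) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be positive", call. = FALSE)
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  structure(list(sampling_rate = sampling_rate, duration = duration,
                 seed = as.integer(seed)),
            class = "recording_config")
}

#' Larval motion specification
#'
#' Parameters of the group bend–stretch motion model. Each active larva emits
#' intermittent bursts of a sinusoidal oscillation at `motion_frequency`
#' (nominally the 1–2 Hz bend–stretch rate), gated by raised-cosine ramps,
#' with a fresh random phase per burst so that larvae are unsynchronized.
#'
#' The default `per_larva_amplitude` is set so that with 8 of 10 larvae
#' active the group envelope amplitude is about 0.11 mV, the scale of the
#' measured device voltage.
#'
#' @param n_larvae number of larvae on the device (default 10).
#' @param active_fraction fraction of larvae that revived and move, in [0, 1].
#' @param motion_frequency bend–stretch rate in Hz (default 2).
#' @param burst_duty fraction of time an active larva spends moving.
#' @param per_larva_amplitude voltage amplitude contributed by one larva (V).
#' @param phase_jitter scale in [0, 1] for per-burst random phase; 1 gives
#'   fully unsynchronized bursts.
#' @return a `larva_motion_spec` list.
#' @export
larva_motion_spec <- function(n_larvae = 10L, active_fraction = 0.8,
                              motion_frequency = 2, burst_duty = 0.5,
                              per_larva_amplitude = 3e-5, phase_jitter = 1) {
  if (active_fraction < 0 || active_fraction > 1) {
    stop("`active_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (motion_frequency <= 0) stop("`motion_frequency` must be positive", call. = FALSE)
  if (per_larva_amplitude < 0) stop("`per_larva_amplitude` must be >= 0", call. = FALSE)
  if (burst_duty <= 0 || burst_duty > 1) stop("`burst_duty` must lie in (0, 1]", call. = FALSE)
  structure(list(n_larvae = as.integer(n_larvae),
                 active_fraction = active_fraction,
                 motion_frequency = motion_frequency,
                 burst_duty = burst_duty,
                 per_larva_amplitude = per_larva_amplitude,
                 phase_jitter = phase_jitter),
            class = "larva_motion_spec")
}

#' Instrument noise model
#'
#' White measurement noise plus a slow sinusoidal baseline drift. The drift
#' frequency must stay below 0.2 Hz so that it falls outside the analysis
#' band, emulating the low-frequency artifact background of real recordings.
#' The default drift amplitude is kept at a tenth of the white-noise level:
#' a near-DC tone leaks through the Hamming window skirt into the lowest
#' in-band bins, and the no-larvae control should stay spectrally flat in
#' 0.2-4 Hz as the bench control is.
#'
#' @param white_sd standard deviation of white noise (V).
#' @param drift_amplitude amplitude of the baseline drift (V).
#' @param drift_frequency drift frequency in Hz (< 0.2).
#' @return a `noise_model` list.
#' @export
noise_model <- function(white_sd = 5e-6, drift_amplitude = 5e-7,
                        drift_frequency = 0.05) {
  if (white_sd < 0) stop("`white_sd` must be >= 0", call. = FALSE)
  if (drift_frequency >= 0.2) {
    stop("`drift_frequency` must be below 0.2 Hz (outside the analysis band)",
         call. = FALSE)
  }
  structure(list(white_sd = white_sd, drift_amplitude = drift_amplitude,
                 drift_frequency = drift_frequency),
            class = "noise_model")
}

# Deterministic substream seed derivation (Lehmer-style fold, keeps the result
# in [0, 2^31 - 2] so it is a valid 32-bit R seed).
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in idx) s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

# Raised-cosine gate: cosine on/off ramps of `ramp` samples around a flat top.
# Falls back to a full Hann bell when the burst is shorter than two ramps.
raised_cosine_gate <- function(len, ramp) {
  if (len < 2L) return(rep(1, len))
  if (2L * ramp >= len) {
    k <- seq_len(len) - 1L
    return(0.5 * (1 - cos(2 * pi * k / (len - 1))))
  }
  up <- 0.5 * (1 - cos(pi * (seq_len(ramp) - 1) / (ramp - 1)))
  c(up, rep(1, len - 2L * ramp), rev(up))
}

# Unit-amplitude burst train for one larva: bouts of oscillation lasting a
# geometric number of cycles (min 10, mean 14 — seconds-long bouts at 2 Hz)
# with 4-cycle raised-cosine on/off ramps. The soft gating keeps >= 99% of
# the signal power within +/- 0.5 Hz of the carrier while the inter-bout
# gaps reproduce the intermittent motion; gaps are sized so the long-run on
# fraction approximates `duty`. Uses the current RNG state.
larva_burst_train <- function(n, fs, freq, duty, jitter) {
  x <- numeric(n)
  cycle_samples <- fs / freq
  ramp <- max(2L, round(4 * cycle_samples))
  # random initial offset so larvae do not all start a burst at t = 0
  i0 <- 1L + floor(stats::runif(1) * 2 * cycle_samples / duty)
  while (i0 <= n) {
    cycles <- 10 + stats::rgeom(1, 1 / 5)           # mean 14, min 10
    len <- max(2L, round(cycles * cycle_samples))
    phase <- stats::runif(1, 0, 2 * pi) * jitter
    env <- raised_cosine_gate(len, ramp)
    m <- min(len, n - i0 + 1L)
    k <- seq_len(m)
    x[i0 + k - 1L] <- sin(2 * pi * freq * (k - 1) / fs + phase) * env[k]
    gap <- max(1L, round(len * (1 - duty) / duty * stats::runif(1, 0.5, 1.5)))
    i0 <- i0 + len + gap
  }
  x
}

# Noise realisation (white + slow drift), using the dedicated noise substream.
noise_samples <- function(n, fs, noise, seed) {
  set.seed(derive_seed(seed, 9001L))
  drift_phase <- stats::runif(1, 0, 2 * pi)
  white <- if (noise$white_sd > 0) stats::rnorm(n, 0, noise$white_sd) else numeric(n)
  t <- (seq_len(n) - 1) / fs
  white + noise$drift_amplitude * sin(2 * pi * noise$drift_frequency * t + drift_phase)
}

#' Generate a synthetic larval recording
#'
#' Sum over active larvae of burst-gated, phase-jittered oscillations at the
#' bend–stretch frequency, plus instrument noise. Each larva draws from its
#' own deterministic RNG substream, so the k-larvae signal is exactly the
#' sample-wise sum of the k single-larva signals, and doubling
#' `per_larva_amplitude` doubles the signal component sample-by-sample while
#' leaving the noise unchanged.
#'
#' @param config a [recording_config()].
#' @param motion a [larva_motion_spec()].
#' @param noise a [noise_model()].
#' @param return_components also store the per-larva signal matrix in the
#'   metadata (columns = active larvae), for superposition checks.
#' @return a [waveform()] whose metadata records the generating parameters
#'   (including the number of active larvae) for recovery tests.
#' @export
generate_recording <- function(config, motion = larva_motion_spec(),
                               noise = noise_model(),
                               return_components = FALSE) {
  stopifnot(inherits(config, "recording_config"),
            inherits(motion, "larva_motion_spec"),
            inherits(noise, "noise_model"))
  fs <- config$sampling_rate
  n <- round(fs * config$duration)
  n_active <- round(motion$active_fraction * motion$n_larvae)
  sig <- numeric(n)
  comps <- if (return_components && n_active > 0)
    matrix(0, n, n_active) else NULL
  for (i in seq_len(n_active)) {
    # larva i draws from substream (seed, i) only, so its contribution is
    # unchanged when larvae are added or removed (superposition)
    set.seed(derive_seed(config$seed, 101L, i))
    ci <- larva_burst_train(n, fs, motion$motion_frequency,
                            motion$burst_duty, motion$phase_jitter) *
      motion$per_larva_amplitude
    if (!is.null(comps)) comps[, i] <- ci
    sig <- sig + ci
  }
  nz <- noise_samples(n, fs, noise, config$seed)
  waveform(sig + nz, fs,
           metadata = list(kind = "larval", n_active = n_active,
                           motion = unclass(motion), noise = unclass(noise),
                           seed = config$seed, components = comps))
}

#' Generate a machine-driven constant-frequency recording
#'
#' Emulates the constant-vibration-machine validation: a single fixed-frequency
#' oscillation (the larva moved mechanically at the servo rate) plus noise.
#'
#' @param config a [recording_config()].
#' @param drive_frequency drive frequency in Hz; must be positive and below
#'   the Nyquist frequency.
#' @param amplitude oscillation amplitude in V.
#' @param noise a [noise_model()].
#' @return a [waveform()]; metadata records `drive_frequency`.
#' @export
generate_driven_recording <- function(config, drive_frequency,
                                      amplitude = 1e-4,
                                      noise = noise_model()) {
  stopifnot(inherits(config, "recording_config"), inherits(noise, "noise_model"))
  if (drive_frequency <= 0 || drive_frequency >= config$sampling_rate / 2) {
    stop("`drive_frequency` must lie strictly between 0 and the Nyquist frequency",
         call. = FALSE)
  }
  fs <- config$sampling_rate
  n <- round(fs * config$duration)
  t <- (seq_len(n) - 1) / fs
  sig <- amplitude * sin(2 * pi * drive_frequency * t)
  nz <- noise_samples(n, fs, noise, config$seed)
  waveform(sig + nz, fs,
           metadata = list(kind = "driven", drive_frequency = drive_frequency,
                           amplitude = amplitude, seed = config$seed))
}

#' Condition-response curves for the synthetic experiments
#'
#' Phenomenological response of the larvae to temperature or pH: the fraction
#' of larvae that revive and their bend–stretch frequency, per condition grid
#' point. Defaults are piecewise anchors reflecting the observed behaviour:
#' the temperature response is zero at 10 and 50 °C, maximal at 30 °C and
#' intermediate at 40 °C; the pH response is zero at pH 2 and 13 and peaks in
#' pH 5–7, with more tolerance on the acid side. Both are overridable.
#'
#' @param condition_name `"temperature"` or `"pH"`.
#' @param grid condition values (°C or pH units); defaults per condition.
#' @param active_fraction_curve revived fraction per grid point, in [0, 1].
#' @param frequency_curve bend–stretch frequency (Hz) per grid point.
#' @return a `condition_response` list.
#' @export
condition_response <- function(condition_name = c("temperature", "pH"),
                               grid = NULL, active_fraction_curve = NULL,
                               frequency_curve = NULL) {
  condition_name <- match.arg(condition_name)
  if (is.null(grid)) {
    if (condition_name == "temperature") {
      grid <- c(10, 20, 30, 40, 50)
      active_fraction_curve <- active_fraction_curve %||% c(0, 0.4, 0.8, 0.4, 0)
      frequency_curve <- frequency_curve %||% c(1, 1.5, 2, 1.5, 1)
    } else {
      grid <- c(2, 3, 5, 7, 9, 12, 13)
      active_fraction_curve <- active_fraction_curve %||%
        c(0, 0.4, 0.8, 0.75, 0.3, 0.05, 0)
      frequency_curve <- frequency_curve %||% c(1, 1.5, 2, 2, 1.5, 1, 1)
    }
  }
  if (length(grid) < 1L) stop("`grid` must be non-empty", call. = FALSE)
  if (length(active_fraction_curve) != length(grid) ||
      length(frequency_curve) != length(grid)) {
    stop("response curves must have the same length as `grid`", call. = FALSE)
  }
  if (any(active_fraction_curve < 0 | active_fraction_curve > 1)) {
    stop("`active_fraction_curve` values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(condition_name = condition_name, grid = grid,
                 active_fraction_curve = active_fraction_curve,
                 frequency_curve = frequency_curve),
            class = "condition_response")
}

#' Generate a labeled condition series of recordings
#'
#' For each grid point of a [condition_response()], generates `replicates`
#' independent recordings whose motion specs follow the response curves.
#' Replicate seeds are spawned deterministically from
#' `(config$seed, grid index, replicate index)`, so an n = 3 experiment is
#' exactly reproducible.
#'
#' @param config a [recording_config()]; its `seed` is the top-level seed.
#' @param response a [condition_response()].
#' @param replicates recordings per condition (default 3).
#' @param motion base [larva_motion_spec()]; its `active_fraction` and
#'   `motion_frequency` are overridden per condition.
#' @param noise a [noise_model()].
#' @return a `condition_series`: list of [waveform()]s, each with
#'   `condition_name`, `condition_value` and `replicate` in its metadata.
#' @export
generate_condition_series <- function(config, response, replicates = 3L,
                                      motion = larva_motion_spec(),
                                      noise = noise_model()) {
  stopifnot(inherits(config, "recording_config"),
            inherits(response, "condition_response"))
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  if (length(response$grid) < 1L) stop("empty condition grid", call. = FALSE)
  out <- list()
  for (gi in seq_along(response$grid)) {
    spec_i <- motion
    spec_i$active_fraction <- response$active_fraction_curve[gi]
    spec_i$motion_frequency <- max(response$frequency_curve[gi], 1e-6)
    for (r in seq_len(replicates)) {
      cfg_r <- config
      cfg_r$seed <- derive_seed(config$seed, 31L, gi, r)
      w <- generate_recording(cfg_r, spec_i, noise)
      w$metadata$condition_name <- response$condition_name
      w$metadata$condition_value <- response$grid[gi]
      w$metadata$replicate <- r
      out[[length(out) + 1L]] <- w
    }
  }
  structure(out, class = "condition_series",
            grid = response$grid, replicates = as.integer(replicates),
            condition_name = response$condition_name)
}
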