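# Pipeline configuration: every constant of every stage in one flat,
# overridable structure that round-trips losslessly through YAML.

#' Default pipeline configuration
#'
#' All stage constants in one place: the recording parameters (1 kHz),
#' analysis constants (10 s segments, 200-point moving average, Hamming
#' 4096-point FFT, 0.2-4 Hz band), the electrostatic model geometry
#' (80/20 um comb, -21 mV surface potential, 150 ohm load) and the
#' significance thresholds (0.05 / 0.01). Unknown keys are rejected when
#' merging or reading, so typos cannot silently fall back to defaults.
#'
#' @param ... named overrides of the form `section = list(key = value)`.
#' @return a `pipeline_config` nested list.
#' @examples
#' cfg <- pipeline_config(recording = list(duration = 30))
#' cfg$recording$duration
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    output_dir = "larvasense-out",
    recording = list(sampling_rate = 1000, duration = 60),
    motion = list(n_larvae = 10L, active_fraction = 0.8,
                  motion_frequency = 2, burst_duty = 0.5,
                  per_larva_amplitude = 3e-5, phase_jitter = 1),
    noise = list(white_sd = 5e-6, drift_amplitude = 5e-7,
                 drift_frequency = 0.05),
    analysis = list(segment_length = 10, ma_window = 200L, n_fft = 4096L,
                    window_name = "hamming", band_low = 0.2, band_high = 4.0,
                    use_residual = FALSE),
    electrostatics = list(tooth_width = 80, gap_width = 20, n_teeth = 6.5,
                          out_of_plane_depth = 0.2, domain_width = 680,
                          domain_height = 130, grid_spacing = 2.5,
                          permittivity_water = 80, length_min = 80,
                          length_max = 600, larva_height = 100,
                          surface_potential = -21e-3, clearance = 10,
                          cycle_frequency = 2, load_resistance = 150,
                          n_steps = 40L, n_cycles = 1L),
    stats = list(alpha = 0.05, alpha_strong = 0.01, welch = FALSE),
    replicates = 3L
  )
  structure(merge_config(defaults, list(...)), class = "pipeline_config")
}

# Recursive merge that rejects keys absent from the defaults.
merge_config <- function(defaults, overrides, path = "") {
  if (!length(overrides)) return(defaults)
  nms <- names(overrides)
  if (is.null(nms) || any(nms == "")) {
    stop("config overrides must be named", call. = FALSE)
  }
  for (nm in nms) {
    full <- paste0(path, nm)
    if (!nm %in% names(defaults)) {
      stop("unknown config key: ", full, call. = FALSE)
    }
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]],
                                     paste0(full, "$"))
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

#' Write a pipeline configuration to YAML
#' @param config a [pipeline_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Values are validated against the default schema; unknown keys raise an
#' error, so the file round-trips losslessly.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Stable hash of a configuration
#' @param config a [pipeline_config()].
#' @return character hash recorded in every pipeline log.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}
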