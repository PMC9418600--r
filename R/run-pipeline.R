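# Pipeline driver tying the stages into reproducible, logged runs. The same
# entry point backs the thin command-line wrapper shipped under inst/cli.

cfg_motion <- function(config) {
  do.call(larva_motion_spec, config$motion)
}
cfg_noise <- function(config) {
  do.call(noise_model, config$noise)
}
cfg_recording <- function(config, seed_offset = 0L) {
  recording_config(config$recording$sampling_rate, config$recording$duration,
                   derive_seed(config$seed, seed_offset))
}
cfg_analyze <- function(w, config) {
  a <- config$analysis
  analyze_recording(w, segment_length = a$segment_length,
                    ma_window = a$ma_window, n_fft = a$n_fft,
                    window_name = a$window_name,
                    band = c(a$band_low, a$band_high),
                    use_residual = a$use_residual)
}

pipeline_log <- function(dir, config, lines) {
  msg <- c(sprintf("larvasense run %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           sprintf("config_hash: %s", config_hash(config)),
           sprintf("seed: %d", config$seed), lines)
  writeLines(msg, file.path(dir, "run.log"))
  message(paste(msg, collapse = "\n"))
  invisible(msg)
}

#' Run a pipeline stage end-to-end
#'
#' Subcommands:
#' \describe{
#'   \item{`generate`}{write a synthetic larval recording plus a no-larvae
#'     control as CSV.}
#'   \item{`simulate`}{run the electrostatic forward model and write the
#'     simulated voltage waveform.}
#'   \item{`analyze`}{analyze waveform CSVs (`input` paths): spectra and an
#'     activity table.}
#'   \item{`stats`}{summarize an activity table CSV (`input`) against its
#'     first condition as control.}
#'   \item{`track`}{binarize and trace a frame-stack directory (`input`).}
#'   \item{`demo`}{the full synthetic temperature + pH experiment: generate
#'     condition series, analyze, and write summary tables.}
#' }
#' Every run writes `run.log` with the config hash and seed, so identical
#' config + seed give byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @param command one of the subcommands above.
#' @param input input path(s) for `analyze`, `stats`, `track`.
#' @return invisibly, list with `status` (0 on success) and `artifacts`
#'   (paths written).
#' @export
run_pipeline <- function(config = pipeline_config(),
                         command = c("demo", "generate", "simulate",
                                     "analyze", "stats", "track"),
                         input = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  command <- match.arg(command)
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  art <- character(0)

  if (command == "generate") {
    w <- generate_recording(cfg_recording(config, 1L), cfg_motion(config),
                            cfg_noise(config))
    ctrl_motion <- cfg_motion(config); ctrl_motion$active_fraction <- 0
    ctrl <- generate_recording(cfg_recording(config, 2L), ctrl_motion,
                               cfg_noise(config))
    art <- c(write_waveform_csv(w, file.path(dir, "recording_larvae.csv")),
             write_waveform_csv(ctrl, file.path(dir, "recording_control.csv")))
  } else if (command == "simulate") {
    e <- config$electrostatics
    w <- simulate_cycle(
      sim_domain(e$domain_width, e$domain_height, e$grid_spacing,
                 e$permittivity_water),
      comb_geometry(e$tooth_width, e$gap_width, e$n_teeth,
                    out_of_plane_depth = e$out_of_plane_depth),
      larva_body(e$length_min, e$length_max, e$larva_height,
                 e$surface_potential, e$clearance),
      motion_kinematics(e$cycle_frequency),
      circuit(e$load_resistance), e$n_steps, e$n_cycles)
    art <- write_waveform_csv(w, file.path(dir, "simulated_cycle.csv"))
  } else if (command == "analyze") {
    if (is.null(input)) stop("`analyze` needs waveform CSV paths", call. = FALSE)
    rows <- list()
    for (p in input) {
      an <- cfg_analyze(read_waveform_csv(p), config)
      sp_path <- file.path(dir, paste0(tools::file_path_sans_ext(basename(p)),
                                       "_spectrum.csv"))
      write_spectrum_csv(an$spectrum, sp_path)
      rows[[p]] <- data.frame(condition = basename(p), replicate = 1L,
                              activity = as.numeric(an$activity),
                              peak_hz = an$peak_frequency)
      art <- c(art, sp_path)
    }
    act_path <- file.path(dir, "activity.csv")
    data.table::fwrite(do.call(rbind, rows), act_path)
    art <- c(art, act_path)
  } else if (command == "stats") {
    if (is.null(input)) stop("`stats` needs an activity table CSV", call. = FALSE)
    d <- data.table::fread(input[1])
    prof <- condition_profile(d$condition, d$activity, d$condition[1],
                              welch = config$stats$welch)
    out <- file.path(dir, "summary.csv")
    data.table::fwrite(prof, out)
    art <- c(art, out)
  } else if (command == "track") {
    if (is.null(input)) stop("`track` needs a frame-stack directory", call. = FALSE)
    stack <- read_frame_stack(input[1])
    tr <- trace_displacement(binarize(stack))
    out <- file.path(dir, "track.csv")
    write_track_csv(tr, out)
    f <- track_frequency(tr)
    freq_path <- file.path(dir, "track_frequency.csv")
    data.table::fwrite(data.frame(frequency_hz = as.numeric(f)), freq_path)
    art <- c(art, out, freq_path)
  } else if (command == "demo") {
    for (cond in c("temperature", "pH")) {
      cfg_r <- cfg_recording(config, if (cond == "temperature") 10L else 20L)
      series <- generate_condition_series(cfg_r, condition_response(cond),
                                          config$replicates,
                                          cfg_motion(config),
                                          cfg_noise(config))
      res <- profile_condition_series(
        series,
        segment_length = config$analysis$segment_length,
        ma_window = config$analysis$ma_window,
        n_fft = config$analysis$n_fft,
        window_name = config$analysis$window_name,
        band = c(config$analysis$band_low, config$analysis$band_high),
        use_residual = config$analysis$use_residual)
      sc_path <- file.path(dir, paste0("activity_", cond, ".csv"))
      su_path <- file.path(dir, paste0("summary_", cond, ".csv"))
      data.table::fwrite(res$scores, sc_path)
      data.table::fwrite(res$profile, su_path)
      art <- c(art, sc_path, su_path)
    }
  }

  pipeline_log(dir, config, c(sprintf("command: %s", command),
                              paste("artifact:", art)))
  invisible(list(status = 0L, artifacts = art))
}
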