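#' Uniformly sampled voltage time series
#'
#' The `waveform` object is the common currency of the package: the synthetic
#' generator, the electrostatic simulator and the spectral pipeline all produce
#' or consume it. Samples are in volts; the sampling rate is in Hz. The
#' `metadata` list carries condition labels and, for synthetic recordings, the
#' true generating parameters so that recovery can be tested.
#'
#' @param samples numeric vector of voltage samples (V); must be finite.
#' @param sampling_rate sampling frequency in Hz (> 0).
#' @param metadata named list of free-form annotations.
#' @return an object of class `waveform`.
#' @examples
#' w <- waveform(sin(2 * pi * 2 * (0:999) / 1000), 1000)
#' duration(w)
#' @export
waveform <- function(samples, sampling_rate, metadata = list()) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive finite number", call. = FALSE)
  }
  samples <- as.double(samples)
  if (length(samples) < 1L) {
    stop("`samples` must contain at least one value", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("all waveform samples must be finite", call. = FALSE)
  }
  structure(
    list(samples = samples, sampling_rate = as.double(sampling_rate),
         metadata = metadata),
    class = "waveform"
  )
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sampling_rate, duration(x)))
  if (!is.null(x$metadata$kind)) cat("  kind:", x$metadata$kind, "\n")
  if (!is.null(x$metadata$condition_value)) {
    cat(sprintf("  condition: %s = %s\n",
                x$metadata$condition_name %||% "?", x$metadata$condition_value))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Duration of a waveform in seconds
#' @param w a `waveform`.
#' @return duration in s.
#' @export
duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$sampling_rate
}

#' Time axis of a waveform
#' @param w a `waveform`.
#' @return numeric vector of sample times in s, starting at 0.
#' @export
time_axis <- function(w) {
  stopifnot(inherits(w, "waveform"))
  (seq_along(w$samples) - 1) / w$sampling_rate
}

#' @export
as.data.frame.waveform <- function(x, ...) {
  data.frame(time_s = time_axis(x), voltage_V = x$samples)
}

#' Write a waveform to CSV
#'
#' Two-column dialect `time_s,voltage_V` with a header row, one row per sample.
#'
#' @param w a `waveform`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  data.table::fwrite(as.data.frame(w), path)
  invisible(path)
}

#' Read a waveform from CSV
#'
#' Expects the two-column dialect written by [write_waveform_csv()]. The
#' sampling rate is inferred from the time column, which must be uniform to
#' within 1 ppm.
#'
#' @param path CSV file path.
#' @return a `waveform`.
#' @export
read_waveform_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- data.table::fread(path, colClasses = list(character = NULL),
                         showProgress = FALSE)
  if (!all(c("time_s", "voltage_V") %in% names(d))) {
    stop("expected columns `time_s` and `voltage_V` in ", path, call. = FALSE)
  }
  for (col in c("time_s", "voltage_V")) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column `%s` at data line %d of %s",
                     col, bad[1], path), call. = FALSE)
      }
      d[[col]] <- num
    }
  }
  if (nrow(d) < 2L) {
    stop("insufficient data: need at least 2 samples in ", path, call. = FALSE)
  }
  dt <- diff(d$time_s)
  dt_med <- stats::median(dt)
  if (dt_med <= 0 || any(abs(dt - dt_med) > 1e-6 * dt_med)) {
    stop("non-uniform sampling in ", path,
         " (time steps deviate by more than 1 ppm)", call. = FALSE)
  }
  waveform(d$voltage_V, 1 / dt_med, metadata = list(source = path))
}

#' Scale a waveform's samples
#' @param w a `waveform`.
#' @param factor multiplicative factor.
#' @return scaled `waveform`.
#' @export
scale_waveform <- function(w, factor) {
  stopifnot(inherits(w, "waveform"), is.numeric(factor), length(factor) == 1L)
  waveform(w$samples * factor, w$sampling_rate, w$metadata)
}
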