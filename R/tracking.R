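# Video quantification of larval motion: Otsu binarization, outer-boundary
# displacement trace, and motion-frequency estimation reusing the spectral
# machinery.

#' Binarize a frame stack
#'
#' Per-frame foreground mask via Otsu's threshold (through `EBImage::otsu`).
#' With `polarity = "dark"` (default) pixels darker than the threshold are
#' foreground, matching a dark larva on a bright background. A blank frame
#' (single intensity level) yields an empty mask with a warning.
#'
#' @param stack a `frame_stack` (see [render_larva_frames()]).
#' @param method thresholding method; only `"otsu"` is implemented.
#' @param polarity `"dark"` or `"bright"` foreground.
#' @return a `binary_stack`: list of logical matrices plus `fps`,
#'   `pixel_pitch` and metadata.
#' @export
binarize <- function(stack, method = "otsu", polarity = c("dark", "bright")) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!identical(method, "otsu")) {
    stop("only Otsu thresholding is implemented", call. = FALSE)
  }
  polarity <- match.arg(polarity)
  if (!length(stack$frames)) stop("empty frame stack", call. = FALSE)
  masks <- lapply(stack$frames, function(m) {
    if (diff(range(m)) == 0) {
      warning("degenerate threshold: frame has a single intensity; empty mask",
              call. = FALSE)
      return(matrix(FALSE, nrow(m), ncol(m)))
    }
    thr <- EBImage::otsu(EBImage::Image(m / 255)) * 255
    if (polarity == "dark") m < thr else m > thr
  })
  structure(list(frames = masks, fps = stack$fps,
                 pixel_pitch = stack$pixel_pitch, metadata = stack$metadata),
            class = "binary_stack")
}

#' Trace the outer-boundary displacement at one column
#'
#' For each frame, takes the topmost foreground pixel in the chosen column
#' (the "outer body line"), converts rows to micrometres and references the
#' trace to frame 1, so upward motion is positive and d(0) = 0. Frames with
#' no foreground in the column are linearly interpolated and flagged.
#'
#' @param bstack a `binary_stack` from [binarize()].
#' @param column pixel column to trace; defaults to the renderer's tracked
#'   mid-body column when available.
#' @return a `track` data frame (`time_s`, `displacement_um`) with
#'   attributes `fps`, `pixel_pitch` and `gap_frames` (indices that were
#'   interpolated).
#' @export
trace_displacement <- function(bstack, column = NULL) {
  stopifnot(inherits(bstack, "binary_stack"))
  column <- column %||% bstack$metadata$tracked_column
  if (is.null(column)) stop("`column` must be given", call. = FALSE)
  tops <- vapply(bstack$frames, function(m) {
    rows <- which(m[, column])
    if (length(rows)) min(rows) else NA_real_
  }, 0)
  if (is.na(tops[1])) {
    stop("no foreground in frame 1 at column ", column, call. = FALSE)
  }
  gaps <- which(is.na(tops))
  if (length(gaps)) {
    tops <- stats::approx(which(!is.na(tops)), tops[!is.na(tops)],
                          xout = seq_along(tops), rule = 2)$y
  }
  d <- (tops[1] - tops) * bstack$pixel_pitch
  tr <- data.frame(time_s = (seq_along(tops) - 1) / bstack$fps,
                   displacement_um = d)
  structure(tr, class = c("track", "data.frame"),
            fps = bstack$fps, pixel_pitch = bstack$pixel_pitch,
            gap_frames = gaps)
}

#' Write a track to CSV (`time_s,displacement_um`)
#' @param track a `track`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_track_csv <- function(track, path) {
  data.table::fwrite(as.data.frame(track)[, c("time_s", "displacement_um")],
                     path)
  invisible(path)
}

#' Dominant motion frequency of a displacement track
#'
#' Runs the displacement trace through the same amplitude-spectrum /
#' dominant-peak machinery as the voltage channel, at the track's frame
#' rate. A track with no in-band structure (e.g. a static larva) returns
#' `NA` with a `reason` attribute instead of a spurious peak.
#'
#' @param track a `track` from [trace_displacement()].
#' @param band analysis band in Hz; the upper edge is clipped below the
#'   track's Nyquist frequency.
#' @return peak frequency in Hz, or flagged `NA` when no peak stands out
#'   (maximum in-band amplitude below 3x the in-band median).
#' @export
track_frequency <- function(track, band = c(0.2, 4.0)) {
  stopifnot(inherits(track, "track"))
  fps <- attr(track, "fps")
  n <- nrow(track)
  if (n / fps < 2 / band[1]) {
    stop("insufficient data: track shorter than two cycles of the lowest ",
         "detectable frequency", call. = FALSE)
  }
  n_fft <- 2^floor(log2(n))
  d <- track$displacement_um - mean(track$displacement_um)
  w <- waveform(d + 0, fps)
  sp <- amplitude_spectrum(w, n_fft = n_fft)
  hi <- min(band[2], 0.99 * fps / 2)
  bf <- band_filter(sp, band[1], hi)
  if (max(bf$amplitude) <= 0 ||
      max(bf$amplitude) < 3 * stats::median(bf$amplitude)) {
    return(structure(NA_real_, reason = "no in-band peak"))
  }
  dominant_peak(bf)
}
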