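# Synthetic larva video: renders a worm-like body whose boundary oscillates
# vertically with known frequency and amplitude, so the tracking stage can be
# validated against ground truth.

#' Frame-stack specification for the synthetic larva video
#'
#' A dark worm-like body on a bright background, bending vertically at
#' `bend_frequency` with peak boundary displacement `bend_amplitude`. The
#' body is drawn as a thick horizontal rod whose centreline bows like half a
#' sine wave along the body, maximal at mid-body.
#'
#' @param frame_width,frame_height frame size in pixels (default 160 x 120).
#' @param pixel_pitch physical pixel size in um/pixel (default 10).
#' @param fps frame rate in frames/s (default 30); must exceed twice
#'   `bend_frequency`.
#' @param bend_frequency bend rate in Hz (default 2).
#' @param bend_amplitude peak mid-body displacement in um (default 200,
#'   a few hundred micrometres as observed).
#' @param larva_length body length in um (default 1500; real larvae are
#'   1-2 mm).
#' @param larva_width body diameter in um (default 200).
#' @param background_gray,larva_gray 8-bit intensity levels.
#' @param duration video length in s (default 10).
#' @param seed RNG seed (reserved for optional noise; rendering itself is
#'   deterministic).
#' @return a `frame_stack_spec` list.
#' @export
frame_stack_spec <- function(frame_width = 160L, frame_height = 120L,
                             pixel_pitch = 10, fps = 30,
                             bend_frequency = 2, bend_amplitude = 200,
                             larva_length = 1500, larva_width = 200,
                             background_gray = 255L, larva_gray = 40L,
                             duration = 10, seed = 1L) {
  if (fps <= 2 * bend_frequency) {
    stop("`fps` must exceed twice `bend_frequency` (Nyquist for tracking)",
         call. = FALSE)
  }
  spec <- structure(
    list(frame_width = as.integer(frame_width),
         frame_height = as.integer(frame_height),
         pixel_pitch = pixel_pitch, fps = fps,
         bend_frequency = bend_frequency, bend_amplitude = bend_amplitude,
         larva_length = larva_length, larva_width = larva_width,
         background_gray = as.integer(background_gray),
         larva_gray = as.integer(larva_gray),
         duration = duration, seed = as.integer(seed)),
    class = "frame_stack_spec")
  len_px <- larva_length / pixel_pitch
  amp_px <- bend_amplitude / pixel_pitch
  halfw_px <- larva_width / 2 / pixel_pitch
  if (len_px > frame_width ||
      frame_height / 2 - halfw_px - amp_px < 1 ||
      frame_height / 2 + halfw_px + amp_px > frame_height - 1) {
    stop("larva does not fit inside the frame at all bend phases", call. = FALSE)
  }
  spec
}

#' Render the synthetic larva frame stack
#'
#' @param spec a [frame_stack_spec()].
#' @return a `frame_stack`: list of integer grayscale matrices (row 1 = top
#'   of the image), `fps`, `pixel_pitch` and metadata holding the spec and a
#'   ground-truth table (`time_s`, continuous top-boundary displacement in
#'   um at the tracked mid-body column, and its pixel row).
#' @export
render_larva_frames <- function(spec) {
  stopifnot(inherits(spec, "frame_stack_spec"))
  n_frames <- round(spec$fps * spec$duration)
  pp <- spec$pixel_pitch
  len_px <- spec$larva_length / pp
  amp_px <- spec$bend_amplitude / pp
  halfw_px <- spec$larva_width / 2 / pp
  x0 <- (spec$frame_width - len_px) / 2
  y0 <- spec$frame_height / 2        # centreline row at rest
  xc <- round(x0 + len_px / 2)       # tracked column: mid-body
  cols_body <- which(seq_len(spec$frame_width) >= x0 &
                     seq_len(spec$frame_width) <= x0 + len_px)
  shape <- sin(pi * (cols_body - x0) / len_px)  # 0 at ends, 1 mid-body

  frames <- vector("list", n_frames)
  truth <- data.frame(time_s = (seq_len(n_frames) - 1) / spec$fps,
                      displacement_um = NA_real_, top_row_px = NA_real_)
  for (f in seq_len(n_frames)) {
    t <- (f - 1) / spec$fps
    bend <- amp_px * sin(2 * pi * spec$bend_frequency * t)
    m <- matrix(spec$background_gray, spec$frame_height, spec$frame_width)
    yc <- y0 - bend * shape          # upward bend lowers the row index
    for (j in seq_along(cols_body)) {
      r0 <- max(1L, ceiling(yc[j] - halfw_px))
      r1 <- min(spec$frame_height, floor(yc[j] + halfw_px))
      if (r1 >= r0) m[r0:r1, cols_body[j]] <- spec$larva_gray
    }
    frames[[f]] <- m
    truth$displacement_um[f] <- bend * pp   # upward-positive, 0 at t = 0
    truth$top_row_px[f] <- ceiling(y0 - bend - halfw_px)
  }
  structure(list(frames = frames, fps = spec$fps, pixel_pitch = pp,
                 metadata = list(spec = unclass(spec), truth = truth,
                                 tracked_column = xc)),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<frame_stack> %d frames of %dx%d px @ %g fps (%g um/px)\n",
              length(x$frames), d[2], d[1], x$fps, x$pixel_pitch))
  invisible(x)
}

#' Write a frame stack as numbered PNGs with a JSON sidecar
#'
#' @param stack a `frame_stack`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_frame_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_along(stack$frames)) {
    png::writePNG(stack$frames[[f]] / 255,
                  file.path(dir, sprintf("frame_%04d.png", f)))
  }
  side <- list(fps = stack$fps, pixel_pitch = stack$pixel_pitch,
               metadata = stack$metadata)
  jsonlite::write_json(side, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a frame stack written by [write_frame_stack()]
#' @param dir directory of numbered PNGs plus `stack.json`.
#' @return a `frame_stack`.
#' @export
read_frame_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no frame PNGs found in ", dir, call. = FALSE)
  frames <- lapply(files, function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    round(m * 255)
  })
  side_path <- file.path(dir, "stack.json")
  fps <- 30; pp <- 1; md <- list()
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    fps <- side$fps; pp <- side$pixel_pitch
    md <- side$metadata
    if (!is.null(md$truth)) md$truth <- as.data.frame(md$truth)
  }
  structure(list(frames = frames, fps = fps, pixel_pitch = pp, metadata = md),
            class = "frame_stack")
}
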