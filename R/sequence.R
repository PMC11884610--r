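#' Image sequence container
#'
#' A `T x H x W` stack of nonnegative intensities with acquisition metadata.
#' Frame `t` is the matrix `seq$frames[t, , ]`.
#'
#' @param frames Numeric array of dim `c(T, H, W)` (a single `H x W` matrix
#'   is promoted to a one-frame stack). All values must be finite and >= 0
#'   unless `signed = TRUE` (differential stacks carry signed values).
#' @param frame_interval Frame interval in ms (default 2, i.e. 500 fps).
#' @param pixel_size Pixel pitch in um/px.
#' @param meta Free-form provenance list.
#' @param signed Allow negative values (differential sequences).
#' @return An object of class `sprm_sequence`.
#' @export
image_sequence <- function(frames, frame_interval = 2, pixel_size = 0.108,
                           meta = list(), signed = FALSE) {
  if (is.matrix(frames))
    frames <- array(frames, c(1, nrow(frames), ncol(frames)))
  d <- dim(frames)
  if (length(d) != 3) stop("frames must be a T x H x W array")
  if (d[1] < 1 || d[2] < 1 || d[3] < 1) stop("empty sequence")
  if (any(!is.finite(frames))) stop("frames contain non-finite values")
  if (!signed && any(frames < 0)) stop("negative intensities in sequence")
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_size = pixel_size, meta = meta),
            class = "sprm_sequence")
}

#' @export
print.sprm_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("SPRM sequence: %d frames of %d x %d px, %g ms/frame\n",
              d[1], d[2], d[3], x$frame_interval))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$frames), max(x$frames)))
  invisible(x)
}

#' @export
dim.sprm_sequence <- function(x) dim(x$frames)

#' Number of frames in a sequence
#' @param seq An [image_sequence()].
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$frames)[1]

#' Extract one frame as a matrix
#' @param seq An [image_sequence()].
#' @param t Frame index (1-based).
#' @return An `H x W` matrix.
#' @export
get_frame <- function(seq, t) {
  array(seq$frames[t, , ], dim(seq$frames)[2:3])
}

as_sequence_like <- function(frames, template, signed = TRUE, meta = NULL) {
  image_sequence(frames, frame_interval = template$frame_interval,
                 pixel_size = template$pixel_size,
                 meta = if (is.null(meta)) template$meta else meta,
                 signed = signed)
}
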