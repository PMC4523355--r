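#' Frame stack: an ordered grayscale image sequence
#'
#' The unit of video input/output. Frames are stored as an integer array of
#' dimension `height x width x n_frames` with 8-bit gray values in `[0, 255]`,
#' together with the acquisition frame rate (`fps`, Hz) and the spatial
#' calibration (`scale`, micrometres per pixel). Frame indices are 0-based in
#' all output tables; pixel coordinates use `x` = column, `y` = row with the
#' origin at the top-left pixel centre.
#'
#' `fps` and `scale` are always supplied by the user (video container
#' metadata is unreliable and calibration depends on the optics).
#'
#' @param frames a `height x width x n` numeric array, or a list of equally
#'   sized matrices, with values in `[0, 255]`.
#' @param fps frames per second (Hz), > 0.
#' @param scale micrometres per pixel, > 0.
#' @param source_name character tag identifying the source video; used as the
#'   merge key (`video` column) in all output tables.
#' @return an object of class `frame_stack`.
#' @examples
#' f <- matrix(0, 32, 32)
#' stack <- frame_stack(list(f, f, f), fps = 25, scale = 1, source_name = "demo")
#' n_frames(stack)
#' @export
frame_stack <- function(frames, fps, scale, source_name = "video") {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop("all frames must share identical dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be a height x width x n_frames array or list of matrices")
  }
  stop_if_not_scalar_number(fps, "fps")
  stop_if_not_scalar_number(scale, "scale")
  rng <- range(frames)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    stop("pixel values must lie in [0, 255] with no missing values")
  }
  storage.mode(frames) <- "integer"
  structure(
    list(frames = frames, fps = fps, scale = scale,
         source_name = as.character(source_name)),
    class = "frame_stack"
  )
}

#' Number of frames in a stack
#' @param stack a [frame_stack()].
#' @return integer frame count.
#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  dim(stack$frames)[3L]
}

#' Extract one frame as a matrix
#' @param stack a [frame_stack()].
#' @param frame 0-based frame index.
#' @return an integer matrix (rows x cols).
#' @export
get_frame <- function(stack, frame) {
  stopifnot(inherits(stack, "frame_stack"))
  if (frame < 0 || frame >= n_frames(stack)) {
    stop(sprintf("frame index %d out of range [0, %d]", frame, n_frames(stack) - 1L))
  }
  stack$frames[, , frame + 1L]
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack '%s': %d frames of %d x %d px, %g fps, %g um/px>\n",
              x$source_name, d[3], d[1], d[2], x$fps, x$scale))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames)
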