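#' Segmentation parameters
#'
#' Parameters for dynamic difference-image segmentation. The reference frame
#' lies `offset` frames after the analyzed frame (e.g. 25 frames = 1 s at
#' 25 fps); stationary pixels cancel in the difference so immobile objects
#' (debris, inactive individuals) never enter the foreground. The gray-value
#' `threshold` that binarizes the difference image must be validated per
#' experimental system (see [check_threshold_values()]). `min_area`/`max_area`
#' (in px^2) bound the connected components kept by the particle analysis.
#'
#' @param offset frame offset between analyzed and reference frame (>= 1).
#' @param threshold binarization cut on the difference gray value, in (0, 255].
#' @param min_area,max_area component area bounds in pixels^2.
#' @return a list of class `segmentation_params`.
#' @export
segmentation_params <- function(offset = 25, threshold = 40,
                                min_area = 5, max_area = 1e5) {
  stop_if_not_scalar_number(offset, "offset")
  stop_if_not_scalar_number(threshold, "threshold")
  if (offset < 1 || offset != round(offset)) stop("`offset` must be an integer >= 1")
  if (threshold <= 0 || threshold > 255) stop("`threshold` must be in (0, 255]")
  if (min_area < 0 || min_area >= max_area) stop("need 0 <= min_area < max_area")
  structure(list(offset = as.integer(offset), threshold = threshold,
                 min_area = min_area, max_area = max_area),
            class = "segmentation_params")
}

#' Dynamic difference image
#'
#' For every frame `t` with a partner `t + offset` inside the stack, computes
#' the pixel-wise intensity difference between the analyzed frame and its
#' reference frame. The result contains only objects that moved between the
#' two frames; the stationary background and immobile particles cancel.
#'
#' Two difference conventions are available. `"subtract"` (the default)
#' keeps only the positive part `max(I_t - I_(t+offset), 0)`: for bright
#' objects on a dark background this images each mover at its *current*
#' position only. `"abs"` takes the unsigned difference, which additionally
#' images the vacated position ("ghost blob") from the reference frame; ghosts
#' form coherent time-shifted tracks that survive trajectory filtering and
#' inflate by-frame counts, so `"abs"` is provided for diagnostic use rather
#' than as the counting default.
#'
#' An optional Gaussian pre-blur (`blur_sigma` > 0, in px) can tame noisy
#' recordings; it is off by default to keep the reference behaviour minimal.
#'
#' @param stack a [frame_stack()] with `T` frames.
#' @param offset frame offset (1 <= offset < T).
#' @param method `"subtract"` (positive part) or `"abs"` (unsigned).
#' @param blur_sigma Gaussian blur sigma in px applied to the raw frames
#'   before differencing; 0 disables.
#' @return a [frame_stack()] of `T - offset` difference frames; output frame
#'   `t` (0-based) corresponds to original frame `t`, the earlier of the pair.
#' @examples
#' f <- matrix(10, 16, 16)
#' s <- frame_stack(list(f, f, f, f), fps = 25, scale = 1)
#' d <- difference_image(s, offset = 1)
#' all(d$frames == 0)  # static scene cancels
#' @export
difference_image <- function(stack, offset, method = c("subtract", "abs"),
                             blur_sigma = 0) {
  stopifnot(inherits(stack, "frame_stack"))
  method <- match.arg(method)
  nf <- n_frames(stack)
  if (offset < 1 || offset != round(offset)) stop("`offset` must be an integer >= 1")
  if (offset >= nf) {
    stop(sprintf("offset (%d) must be smaller than the number of frames (%d)",
                 offset, nf), call. = FALSE)
  }
  fr <- stack$frames
  if (blur_sigma > 0) {
    for (t in seq_len(nf)) {
      fr[, , t] <- EBImage::gblur(fr[, , t], sigma = blur_sigma)
    }
  }
  a <- fr[, , seq_len(nf - offset), drop = FALSE]
  b <- fr[, , seq_len(nf - offset) + offset, drop = FALSE]
  d <- if (method == "abs") abs(a - b) else pmax(a - b, 0)
  out <- frame_stack(d, fps = stack$fps, scale = stack$scale,
                     source_name = stack$source_name)
  attr(out, "offset") <- as.integer(offset)
  attr(out, "method") <- method
  out
}

#' Binarize a difference stack
#'
#' A pixel is foreground iff its difference value is greater than or equal to
#' the threshold (the chosen value itself counts as foreground). Raising the
#' threshold can only remove foreground pixels.
#'
#' @param diff a difference [frame_stack()] from [difference_image()].
#' @param threshold gray-value cut in (0, 255].
#' @return a logical `height x width x n` array of masks with attributes
#'   `fps`, `scale`, `source_name`, `offset` carried over.
#' @export
binarize <- function(diff, threshold) {
  stopifnot(inherits(diff, "frame_stack"))
  if (threshold <= 0 || threshold > 255) stop("`threshold` must be in (0, 255]")
  m <- diff$frames >= threshold
  attr(m, "fps") <- diff$fps
  attr(m, "scale") <- diff$scale
  attr(m, "source_name") <- diff$source_name
  attr(m, "offset") <- attr(diff, "offset")
  m
}

#' Write threshold-selection montages
#'
#' For each candidate threshold writes a side-by-side panel (raw frame |
#' difference frame | binarized mask) so the user can pick the threshold
#' visually; thresholding is system-specific and must be validated by eye.
#'
#' @param stack a [frame_stack()].
#' @param offset difference-image frame offset.
#' @param candidate_thresholds numeric vector of thresholds to preview.
#' @param out_dir directory for the montage PNGs (created if absent).
#' @param frame 0-based index of the difference frame to display.
#' @return invisibly, the paths written (`<stem>_thr<value>.png`).
#' @export
check_threshold_values <- function(stack, offset, candidate_thresholds,
                                   out_dir = ".", frame = 0) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!length(candidate_thresholds)) {
    stop("`candidate_thresholds` must contain at least one value", call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  diff <- difference_image(stack, offset)
  raw <- get_frame(stack, frame)
  dif <- get_frame(diff, frame)
  sep <- matrix(255L, nrow(raw), 2L)
  paths <- character(length(candidate_thresholds))
  for (k in seq_along(candidate_thresholds)) {
    thr <- candidate_thresholds[k]
    mask <- (dif >= thr) * 255L
    panel <- cbind(raw, sep, dif, sep, mask)
    paths[k] <- file.path(out_dir, sprintf("%s_thr%g.png", stack$source_name, thr))
    png::writePNG(panel / 255, paths[k])
  }
  invisible(paths)
}
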