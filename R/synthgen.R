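#' Species specification for synthetic videos
#'
#' Describes one synthetic species: body size (major axis, um), elongation
#' (aspect ratio major/minor), swimming speed (um/s) and heading persistence
#' of a correlated random walk (standard deviation of the per-frame turning
#' angle, radians; small values give near-ballistic paths). `intensity` is
#' the rendered gray value (bright on the dark heterogeneous background, as
#' under dark-field illumination).
#'
#' @param name species label.
#' @param major_mean,major_sd major-axis length distribution (um).
#' @param aspect_mean,aspect_sd aspect-ratio distribution (truncated >= 1).
#' @param speed_mean,speed_sd swimming speed distribution (um/s).
#' @param turning_sd per-frame turning-angle SD (radians).
#' @param intensity rendered gray value in (background, 255].
#' @return a list of class `species_spec`.
#' @export
species_spec <- function(name, major_mean, major_sd = 0.1 * major_mean,
                         aspect_mean = 2, aspect_sd = 0.2,
                         speed_mean = 100, speed_sd = 0.2 * speed_mean,
                         turning_sd = 0.5, intensity = 200) {
  for (nm in c("major_mean", "aspect_mean", "speed_mean")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  if (intensity <= 0 || intensity > 255) stop("`intensity` must be in (0, 255]")
  structure(list(name = as.character(name), major_mean = major_mean,
                 major_sd = major_sd, aspect_mean = aspect_mean,
                 aspect_sd = aspect_sd, speed_mean = speed_mean,
                 speed_sd = speed_sd, turning_sd = turning_sd,
                 intensity = intensity),
            class = "species_spec")
}

# fill pixels of an ellipse centred at (x, y) px (0-based), semi-axes a, b px,
# heading theta (radians, y-up); returns (row, col) 1-based pixel subscripts
ellipse_pixels <- function(x, y, a, b, theta, nr, nc) {
  r0 <- max(1L, floor(y - a) + 1L); r1 <- min(nr, ceiling(y + a) + 1L)
  c0 <- max(1L, floor(x - a) + 1L); c1 <- min(nc, ceiling(x + a) + 1L)
  if (r0 > r1 || c0 > c1) return(matrix(integer(0), 0, 2))
  cols <- c0:c1; rows <- r0:r1
  px <- rep(cols - 1L, each = length(rows)) - x
  py <- rep(rows - 1L, times = length(cols)) - y
  ct <- cos(theta); st <- sin(theta)
  # y grows downward; heading theta is y-up
  u <- px * ct - py * st
  w <- -px * st - py * ct
  inside <- (u / a)^2 + (w / b)^2 <= 1
  cbind(row = rep(rows, times = length(cols))[inside],
        col = rep(cols, each = length(rows))[inside])
}

#' Score pipeline output against synthetic ground truth
#'
#' Matches detections to true positions frame by frame (greedy
#' nearest-first within `match_radius`) and reports four metric groups:
#' \itemize{
#'   \item counts: mean detected and true per-frame counts over
#'     `frame_range` and their relative error (percent);
#'   \item position RMSE over matched detections (px);
#'   \item trajectory identity recovery: pairwise co-assignment F1 (two
#'     matched detections of the same true individual should share one
#'     recovered `id`), with precision and recall;
#'   \item morphology recovery: median measured / median true major axis.
#' }
#'
#' @param detections filtered detection-level table (columns id, frame, x, y
#'   and optionally major).
#' @param truth ground-truth table from [simulate_video()].
#' @param match_radius maximum matching distance (px).
#' @param frame_range 0-based inclusive `c(first, last)` frame window the
#'   counts are averaged over (default: frames present in `detections`'
#'   segmentable range, i.e. `range(truth$frame)` clipped to detections).
#' @return a list with components `counts`, `position_rmse`, `identity`,
#'   `morphology`, and the per-detection match table `matches`.
#' @export
score_against_truth <- function(detections, truth, match_radius = 10,
                                frame_range = NULL) {
  require_columns(detections, c("id", "frame", "x", "y"), "detection table")
  tru <- truth[truth$rendered, , drop = FALSE]
  if (is.null(frame_range)) {
    frame_range <- c(0, max(detections$frame))
  }
  frames <- frame_range[1]:frame_range[2]
  tru <- tru[tru$frame >= frame_range[1] & tru$frame <= frame_range[2], ,
             drop = FALSE]
  det <- detections[detections$frame >= frame_range[1] &
                      detections$frame <= frame_range[2], , drop = FALSE]
  match_rows <- vector("list", length(frames))
  for (k in seq_along(frames)) {
    t <- frames[k]
    dt <- which(det$frame == t)
    tt <- which(tru$frame == t)
    if (!length(dt) || !length(tt)) next
    dmat <- sqrt(outer(det$x[dt], tru$x[tt], "-")^2 +
                   outer(det$y[dt], tru$y[tt], "-")^2)
    pairs <- NULL
    while (TRUE) {
      m <- which.min(dmat)
      if (!length(m) || dmat[m] > match_radius || !is.finite(dmat[m])) break
      i <- (m - 1) %% nrow(dmat) + 1
      j <- (m - 1) %/% nrow(dmat) + 1
      pairs <- rbind(pairs, c(dt[i], tt[j], dmat[m]))
      dmat[i, ] <- Inf
      dmat[, j] <- Inf
    }
    if (!is.null(pairs)) {
      match_rows[[k]] <- data.frame(det_row = pairs[, 1], tru_row = pairs[, 2],
                                    dist = pairs[, 3])
    }
  }
  matches <- do.call(rbind, match_rows[!vapply(match_rows, is.null, logical(1))])
  det_counts <- tabulate(factor(det$frame, levels = frames),
                         nbins = length(frames))
  tru_counts <- tabulate(factor(tru$frame, levels = frames),
                         nbins = length(frames))
  mean_det <- mean(det_counts); mean_tru <- mean(tru_counts)
  pair_sum <- function(n) sum(n * (n - 1) / 2)
  if (!is.null(matches) && nrow(matches)) {
    cont <- table(tru$id[matches$tru_row], det$id[matches$det_row])
    tp <- pair_sum(as.vector(cont))
    pred_pairs <- pair_sum(colSums(cont))
    true_pairs <- pair_sum(rowSums(cont))
    precision <- if (pred_pairs > 0) tp / pred_pairs else NA_real_
    recall <- if (true_pairs > 0) tp / true_pairs else NA_real_
    f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
      NA_real_ else 2 * precision * recall / (precision + recall)
    rmse <- sqrt(mean(matches$dist^2))
  } else {
    precision <- recall <- f1 <- rmse <- NA_real_
  }
  morph <- if (!is.null(matches) && nrow(matches) && "major" %in% names(det)) {
    list(median_major_detected = stats::median(det$major[matches$det_row]),
         median_major_true = stats::median(tru$major[matches$tru_row]),
         major_recovery = stats::median(det$major[matches$det_row]) /
           stats::median(tru$major[matches$tru_row]))
  } else list(median_major_detected = NA_real_, median_major_true = NA_real_,
              major_recovery = NA_real_)
  list(
    counts = list(mean_detected = mean_det, mean_true = mean_tru,
                  count_error_pct = if (mean_tru > 0)
                    100 * abs(mean_det - mean_tru) / mean_tru else NA_real_),
    position_rmse = rmse,
    identity = list(f1 = f1, precision = precision, recall = recall),
    morphology = morph,
    matches = matches
  )
}
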