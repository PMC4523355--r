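morph_descriptor_cols <- c("area", "perimeter", "major", "minor",
                           "circularity", "aspect_ratio", "roundness",
                           "solidity", "mean_grey", "min_grey", "max_grey")

#' Summarize trajectories
#'
#' Aggregates each trajectory to a single row: counts and temporal coverage,
#' displacement and step statistics, and central tendency plus variability of
#' every morphology descriptor present in the input. Averaging morphology
#' over a trajectory's detections damps frame-level segmentation errors
#' (e.g. shapes truncated by partial overlap between the frames of a
#' difference image).
#'
#' Definitions: `duration = (last_frame - first_frame) / fps` seconds (gaps
#' count as elapsed time); `detection_rate = n_detections / frames spanned`
#' with an inclusive span (`last - first + 1`), so a trajectory spanning 10
#' frames needs 8 detections to reach a rate of 0.8;
#' `net_displacement` is the start-to-end distance (um), `gross_displacement`
#' the cumulative path length (um); `mean_speed = gross / duration` (um/s).
#' Variability is the sample standard deviation (NA when too few values);
#' the interquartile range of step length is emitted alongside.
#'
#' @param traj_table output of [compute_step_metrics()].
#' @param fps frames per second.
#' @param scale micrometres per pixel (used for the net displacement when
#'   step metrics are absent).
#' @return one row per trajectory `id`; empty input gives an empty table.
#' @export
summarize_trajectories <- function(traj_table, fps, scale) {
  stop_if_not_scalar_number(fps, "fps")
  require_columns(traj_table, c("video", "traj_id", "frame", "x", "y"),
                  "trajectory table")
  tab <- traj_table[order(traj_table$video, traj_table$traj_id,
                          traj_table$frame), , drop = FALSE]
  morph <- intersect(morph_descriptor_cols, names(tab))
  base_cols <- c("id", "video", "traj_id", "n_detections", "first_frame",
                 "last_frame", "duration", "detection_rate",
                 "net_displacement", "gross_displacement", "median_step",
                 "mean_step", "sd_step", "iqr_step", "mean_speed",
                 "mean_turning", "sd_turning")
  morph_out <- as.vector(t(outer(c("mean", "median", "sd"), morph,
                                 paste, sep = "_")))
  if (!nrow(tab)) {
    out <- as.data.frame(matrix(numeric(0), 0,
                                length(base_cols) + length(morph_out) - 2,
                                dimnames = list(NULL, setdiff(c(base_cols, morph_out),
                                                              c("id", "video")))))
    return(cbind(data.frame(id = character(0), video = character(0)), out))
  }
  grp <- paste(tab$video, tab$traj_id, sep = "\r")
  idx_list <- split(seq_len(nrow(tab)), factor(grp, levels = unique(grp)))
  has_steps <- all(c("step_length", "nsd", "gross", "turning_angle") %in% names(tab))
  one <- function(idx) {
    m <- length(idx)
    fr <- tab$frame[idx]
    first <- fr[1]; last <- fr[m]
    if (has_steps) {
      sl <- tab$step_length[idx][-1]
      net <- sqrt(tab$nsd[idx][m])
      gross <- tab$gross[idx][m]
      trn <- tab$turning_angle[idx]
    } else {
      dx <- diff(tab$x[idx]); dy <- diff(tab$y[idx])
      sl <- scale * sqrt(dx^2 + dy^2)
      net <- scale * sqrt((tab$x[idx][m] - tab$x[idx][1])^2 +
                            (tab$y[idx][m] - tab$y[idx][1])^2)
      gross <- sum(sl)
      trn <- NA_real_
    }
    duration <- (last - first) / fps
    vals <- c(
      n_detections = m, first_frame = first, last_frame = last,
      duration = duration,
      detection_rate = m / (last - first + 1),
      net_displacement = if (m > 1) net else 0,
      gross_displacement = if (m > 1) gross else 0,
      median_step = if (m > 1) stats::median(sl, na.rm = TRUE) else NA_real_,
      mean_step = if (m > 1) mean(sl, na.rm = TRUE) else NA_real_,
      sd_step = if (m > 2) stats::sd(sl, na.rm = TRUE) else NA_real_,
      iqr_step = if (m > 1) stats::IQR(sl, na.rm = TRUE) else NA_real_,
      mean_speed = if (duration > 0) gross / duration else NA_real_,
      mean_turning = if (sum(is.finite(trn)) >= 1) mean(trn, na.rm = TRUE) else NA_real_,
      sd_turning = if (sum(is.finite(trn)) >= 2) stats::sd(trn, na.rm = TRUE) else NA_real_
    )
    for (mc in morph) {
      v <- tab[[mc]][idx]
      vals[paste0("mean_", mc)] <- mean(v)
      vals[paste0("median_", mc)] <- stats::median(v)
      vals[paste0("sd_", mc)] <- if (m > 1) stats::sd(v) else NA_real_
    }
    vals
  }
  mat <- t(vapply(idx_list, one, one(idx_list[[1]])))
  firsts <- vapply(idx_list, `[`, integer(1), 1L)
  out <- data.frame(
    id = if ("id" %in% names(tab)) tab$id[firsts] else
      paste0(tab$video[firsts], "-", tab$traj_id[firsts]),
    video = tab$video[firsts],
    as.data.frame(mat)
  )
  rownames(out) <- NULL
  out$traj_id <- tab$traj_id[firsts]
  out[, intersect(c(base_cols, morph_out), names(out)), drop = FALSE]
}

#' Filter trajectory summaries
#'
#' Removes artefact trajectories (moving debris, segmentation noise, broken
#' fragments): a trajectory is retained when its net displacement and
#' duration reach their minima (inclusive), its detection rate reaches the
#' minimum fraction (inclusive), and its median step length strictly exceeds
#' `min_median_step`. Defaults: net displacement >= 50 um, duration >= 0.2 s,
#' detection rate >= 80%, median step > 2 um. Trajectories with undefined
#' median step (single detections) are removed.
#'
#' Relaxing any threshold never removes a previously retained trajectory;
#' `filter_data(x, 0, 0, 0, -1)` is the identity.
#'
#' @param summaries output of [summarize_trajectories()].
#' @param min_net minimum net displacement (um).
#' @param min_duration minimum duration (s).
#' @param min_detection_rate minimum detection rate (fraction in \[0, 1\]).
#' @param min_median_step median step length must strictly exceed this (um).
#' @return the retained rows; the thresholds used are recorded in the
#'   `"thresholds"` attribute.
#' @export
filter_data <- function(summaries, min_net = 50, min_duration = 0.2,
                        min_detection_rate = 0.8, min_median_step = 2) {
  require_columns(summaries, c("net_displacement", "duration",
                               "detection_rate", "median_step"),
                  "summary table")
  keep <- summaries$net_displacement >= min_net &
    summaries$duration >= min_duration &
    summaries$detection_rate >= min_detection_rate &
    !is.na(summaries$median_step) &
    summaries$median_step > min_median_step
  out <- summaries[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(min_net = min_net, min_duration = min_duration,
                               min_detection_rate = min_detection_rate,
                               min_median_step = min_median_step)
  out
}
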