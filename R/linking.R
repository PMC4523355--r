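#' Trajectory linking parameters
#'
#' `link_range` (L) is the maximum number of frames across which a detection
#' gap may be bridged (a particle missing on intervening frames can be
#' re-linked up to L frames later). `max_disp` is the largest allowed
#' displacement (px) between two successive frames; for a link spanning `g`
#' frames the allowance is `g * max_disp` under `gap_mode = "linear"` (the
#' default) or a constant `max_disp` under `"fixed"`.
#'
#' Defaults follow validated settings for ciliate videos at 25 fps:
#' L = 5 frames, max_disp = 20 px (fast swimmers may need 25).
#'
#' @param link_range maximum frame gap L (>= 1).
#' @param max_disp maximum per-frame-pair displacement in px (> 0).
#' @param gap_mode `"linear"` or `"fixed"` displacement allowance for gaps.
#' @return a list of class `link_params`.
#' @export
link_params <- function(link_range = 5, max_disp = 20,
                        gap_mode = c("linear", "fixed")) {
  gap_mode <- match.arg(gap_mode)
  if (link_range < 1 || link_range != round(link_range)) {
    stop("`link_range` must be an integer >= 1")
  }
  stop_if_not_scalar_number(max_disp, "max_disp")
  structure(list(link_range = as.integer(link_range), max_disp = max_disp,
                 gap_mode = gap_mode), class = "link_params")
}

# Jonker-style O(n^3) solver for the linear assignment problem on a square
# finite cost matrix (shortest augmenting paths with dual potentials).
# Returns match[i] = column assigned to row i and the total cost.
lap_solve <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  if (n == 1L) return(list(match = 1L, cost = cost[1, 1]))
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)    # p[j+1]: row assigned to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free_j <- which(!used[-1L])
      cur <- cost[i0, free_j] - u[i0] - v[free_j + 1L]
      upd <- cur < minv[free_j]
      if (any(upd)) {
        minv[free_j[upd]] <- cur[upd]
        way[free_j[upd] + 1L] <- j0
      }
      kk <- which.min(minv[free_j])
      j1 <- free_j[kk]
      delta <- minv[j1]
      usedj <- which(used) - 1L
      for (j in usedj) {
        if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
        v[j + 1L] <- v[j + 1L] - delta
      }
      minv[free_j] <- minv[free_j] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) match[p[j + 1L]] <- j
  list(match = match, cost = sum(cost[cbind(seq_len(n), match)]))
}

# One association stage: nT candidate trajectories vs nD detections.
# sqd: squared displacement costs; allowed: which links are admissible;
# d0sq: cost of leaving a trajectory or a detection unmatched (null option).
# Solved as optimal one-to-one assignment on the standard padded matrix
#   [ C        diag(d0) ]
#   [ diag(d0) 0        ]
# Returns the matched (trajectory, detection) index pairs and the stage cost
# (matched costs + d0sq per unmatched trajectory/detection).
assign_stage <- function(sqd, allowed, d0sq) {
  nT <- nrow(sqd); nD <- ncol(sqd)
  big <- (nT + nD) * d0sq + sum(sqd[allowed]) + 1
  n <- nT + nD
  C <- matrix(big, n, n)
  C[seq_len(nT), seq_len(nD)] <- ifelse(allowed, sqd, big)
  C[cbind(seq_len(nT), nD + seq_len(nT))] <- d0sq
  C[cbind(nT + seq_len(nD), seq_len(nD))] <- d0sq
  C[nT + seq_len(nD), nD + seq_len(nT)] <- 0
  sol <- lap_solve(C)
  ti <- seq_len(nT)
  dj <- sol$match[ti]
  keep <- dj <= nD
  keep[keep] <- allowed[cbind(ti[keep], dj[keep])]
  pairs <- cbind(traj = ti[keep], det = dj[keep])
  cost <- sum(sqd[pairs]) + d0sq * ((nT - nrow(pairs)) + (nD - nrow(pairs)))
  list(pairs = pairs, cost = cost)
}

# Exhaustive-enumeration oracle for a single association stage (tiny
# instances only); same contract as assign_stage.
assign_stage_exhaustive <- function(sqd, allowed, d0sq) {
  nT <- nrow(sqd); nD <- ncol(sqd)
  best <- Inf
  best_pairs <- cbind(traj = integer(0), det = integer(0))
  rec <- function(i, used, pairs, acc) {
    if (acc >= best) return(invisible())
    if (i > nT) {
      total <- acc + d0sq * (nD - sum(used))
      if (total < best) {
        best <<- total
        best_pairs <<- pairs
      }
      return(invisible())
    }
    rec(i + 1L, used, pairs, acc + d0sq)  # trajectory stays unmatched
    for (j in seq_len(nD)) {
      if (!used[j] && allowed[i, j]) {
        used[j] <- TRUE
        rec(i + 1L, used, rbind(pairs, c(i, j)), acc + sqd[i, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nD), cbind(traj = integer(0), det = integer(0)), 0)
  colnames(best_pairs) <- c("traj", "det")
  list(pairs = best_pairs, cost = best)
}

#' Link detections into trajectories
#'
#' Reconstructs movement trajectories from per-frame detections. Frames are
#' processed in temporal order; at each frame, trajectories whose last
#' detection lies `g` frames back (g = 1, ..., L) compete in turn for the
#' still-unmatched detections. Each stage is solved as an optimal one-to-one
#' assignment minimizing total squared displacement, with a null option
#' priced at `max_disp^2` so that implausible links are left unmade; links
#' farther than the gap allowance are excluded outright. Detections that no
#' trajectory claims start new trajectories (singletons allowed).
#'
#' Occlusions (two trajectories converging on one detection) are handled
#' conservatively: the assignment lets the lower-cost predecessor continue
#' (ties resolved toward the lower `traj_id`), the loser is left unmatched
#' and simply ends once it stays unmatched for more than L frames. No
#' attempt is made to recombine partial trajectories after an occlusion.
#'
#' Linking uses positions only; all other columns of `particles` are carried
#' through to the output. `traj_id` is assigned in order of trajectory birth
#' (frame, then x, then y), so the output is deterministic and invariant to
#' permutations of the input rows.
#'
#' @param particles data.frame with at least video, frame, x, y columns (as
#'   produced by [locate_and_measure_particles()]).
#' @param params a [link_params()] object.
#' @param solver `"hungarian"` (default) or `"exhaustive"` (tiny instances;
#'   used for cross-checking).
#' @param diagnostics if TRUE, attach a per-stage log (frame, gap, sizes,
#'   stage cost) as attribute `"stages"`.
#' @return the input rows (re-ordered) with columns `traj_id` (integer,
#'   unique within video) and `id` (`"<video>-<traj_id>"`) added.
#' @export
link_particles <- function(particles, params = link_params(),
                           solver = c("hungarian", "exhaustive"),
                           diagnostics = FALSE) {
  solver <- match.arg(solver)
  stopifnot(inherits(params, "link_params"))
  require_columns(particles, c("video", "frame", "x", "y"), "particle table")
  if (!nrow(particles)) {
    out <- particles
    out$traj_id <- integer(0)
    out$id <- character(0)
    return(out)
  }
  stage_fun <- if (solver == "hungarian") assign_stage else assign_stage_exhaustive
  d0sq <- params$max_disp^2
  L <- params$link_range
  stages <- list()
  out_chunks <- list()
  for (vid in sort(unique(particles$video))) {
    df <- particles[particles$video == vid, , drop = FALSE]
    df <- df[order(df$frame, df$x, df$y), , drop = FALSE]
    x <- df$x; y <- df$y; fr <- df$frame
    by_frame <- split(seq_len(nrow(df)), fr)
    traj_det <- list()
    traj_last <- numeric(0)
    for (t in sort(unique(fr))) {
      unmatched <- by_frame[[as.character(t)]]
      for (g in seq_len(L)) {
        if (!length(unmatched)) break
        cand <- which(traj_last == t - g)
        if (!length(cand)) next
        last_det <- vapply(traj_det[cand], function(d) d[length(d)], numeric(1))
        sqd <- outer(x[last_det], x[unmatched], "-")^2 +
          outer(y[last_det], y[unmatched], "-")^2
        allow <- if (params$gap_mode == "linear") g * params$max_disp else
          params$max_disp
        allowed <- sqd <= allow^2
        if (!any(allowed)) next
        res <- stage_fun(sqd, allowed, d0sq)
        if (diagnostics) {
          stages[[length(stages) + 1L]] <-
            data.frame(video = vid, frame = t, gap = g,
                       n_traj = length(cand), n_det = length(unmatched),
                       n_linked = nrow(res$pairs), cost = res$cost)
        }
        if (nrow(res$pairs)) {
          for (k in seq_len(nrow(res$pairs))) {
            ti <- cand[res$pairs[k, 1L]]
            di <- unmatched[res$pairs[k, 2L]]
            traj_det[[ti]] <- c(traj_det[[ti]], di)
            traj_last[ti] <- t
          }
          unmatched <- unmatched[-res$pairs[, 2L]]
        }
      }
      for (di in unmatched) {  # births, already ordered by x then y
        traj_det[[length(traj_det) + 1L]] <- di
        traj_last[length(traj_last) + 1L] <- t
      }
    }
    det_order <- unlist(traj_det, use.names = FALSE)
    chunk <- df[det_order, , drop = FALSE]
    chunk$traj_id <- rep(seq_along(traj_det),
                         vapply(traj_det, length, integer(1)))
    chunk$id <- paste0(vid, "-", chunk$traj_id)
    out_chunks[[vid]] <- chunk
  }
  out <- do.call(rbind, out_chunks)
  rownames(out) <- NULL
  if (diagnostics) {
    attr(out, "stages") <- if (length(stages)) do.call(rbind, stages) else NULL
  }
  out
}

#' Per-step movement metrics
#'
#' For each pair of consecutive detections within a trajectory computes:
#' step length (um), absolute angle of the displacement vector (radians,
#' measured counterclockwise from the +x axis with y pointing up, in
#' (-pi, pi]), turning angle (wrapped difference of consecutive absolute
#' angles; defined from the second step onward), net squared displacement
#' from the trajectory start (um^2), and gross displacement (cumulative path
#' length, um). The first detection of a trajectory has no step; zero-length
#' steps have an undefined absolute angle (NA), and any turning angle
#' involving them is NA as well. A `time` column (frame / fps, seconds) is
#' added for convenience.
#'
#' @param traj_table linked detection table from [link_particles()].
#' @param fps frames per second.
#' @param scale micrometres per pixel.
#' @return `traj_table` ordered by (video, traj_id, frame) with columns
#'   time, step_length, abs_angle, turning_angle, nsd, gross appended.
#' @export
compute_step_metrics <- function(traj_table, fps, scale) {
  require_columns(traj_table, c("video", "traj_id", "frame", "x", "y"),
                  "trajectory table")
  stop_if_not_scalar_number(fps, "fps")
  stop_if_not_scalar_number(scale, "scale")
  n <- nrow(traj_table)
  tab <- traj_table[order(traj_table$video, traj_table$traj_id,
                          traj_table$frame), , drop = FALSE]
  tab$time <- tab$frame / fps
  step_length <- abs_angle <- turning_angle <- nsd <- gross <- rep(NA_real_, n)
  if (n) {
    grp <- paste(tab$video, tab$traj_id, sep = "\r")
    idx_list <- split(seq_len(n), factor(grp, levels = unique(grp)))
    for (idx in idx_list) {
      xs <- tab$x[idx]; ys <- tab$y[idx]
      m <- length(idx)
      nsd[idx] <- scale^2 * ((xs - xs[1])^2 + (ys - ys[1])^2)
      if (m == 1L) { gross[idx] <- 0; next }
      dx <- diff(xs); dy <- diff(ys)
      sl <- scale * sqrt(dx^2 + dy^2)
      ang <- atan2(-dy, dx)  # y-up convention
      ang[sl == 0] <- NA_real_
      trn <- c(NA_real_, wrap_angle(diff(ang)))
      step_length[idx] <- c(NA_real_, sl)
      abs_angle[idx] <- c(NA_real_, ang)
      turning_angle[idx] <- c(NA_real_, trn)
      gross[idx] <- c(0, cumsum(sl))
    }
  }
  tab$step_length <- step_length
  tab$abs_angle <- abs_angle
  tab$turning_angle <- turning_angle
  tab$nsd <- nsd
  tab$gross <- gross
  rownames(tab) <- NULL
  tab
}
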