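#' Locate particles in a binary mask
#'
#' Connected-component labeling under 8-connectivity (diagonally touching
#' pixels belong to the same particle, as in the ImageJ particle analyzer).
#' Components touching the image border are kept: the viewing field is
#' unrestricted, so discarding border particles would bias counts downward.
#' Components with pixel area outside `[min_area, max_area]` are discarded.
#'
#' @param mask a 2-D logical (or 0/1) matrix.
#' @param min_area,max_area inclusive area bounds in pixels^2.
#' @return a list of components, each a 2-column integer matrix of (row, col)
#'   pixel coordinates (1-based), ordered by the component's first pixel in
#'   row-major scan order (topmost, then leftmost).
#' @examples
#' m <- matrix(FALSE, 8, 8); m[2:4, 2:4] <- TRUE; m[6, 6] <- TRUE
#' length(label_particles(m))
#' @export
label_particles <- function(mask, min_area = 0, max_area = Inf) {
  stopifnot(length(dim(mask)) == 2L)
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(list())
  lab <- EBImage::imageData(EBImage::bwlabel(m))
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  lab <- merge_diagonal_labels(lab)
  idx <- which(lab > 0L, arr.ind = TRUE)
  comps <- split.data.frame(idx, lab[idx])
  comps <- lapply(comps, function(p) {
    p <- as.matrix(p); dimnames(p) <- list(NULL, c("row", "col")); p
  })
  n <- vapply(comps, nrow, integer(1))
  comps <- comps[n >= min_area & n <= max_area]
  if (!length(comps)) return(list())
  # deterministic order: first pixel in row-major scan
  key <- vapply(comps, function(p) min((p[, 1] - 1) * ncol(m) + (p[, 2] - 1)),
                numeric(1))
  unname(comps[order(key)])
}

# bwlabel is 4-connective; union labels that touch diagonally.
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < 2L || nc < 2L) return(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # (i,j) vs (i+1,j+1)
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]   # (i,j+1) vs (i+1,j)
  pairs <- rbind(
    cbind(a1[a1 > 0 & b1 > 0 & a1 != b1], b1[a1 > 0 & b1 > 0 & a1 != b1]),
    cbind(a2[a2 > 0 & b2 > 0 & a2 != b2], b2[a2 > 0 & b2 > 0 & a2 != b2])
  )
  if (!nrow(pairs)) return(lab)
  maxl <- max(lab)
  parent <- seq_len(maxl)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(maxl), find, integer(1))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  lab
}

# Moore boundary tracing; returns the closed boundary path length in px
# (diagonal steps weighted sqrt(2)) and the area of the boundary polygon
# (shoelace over the visited pixel centres). Isolated pixels get the
# unit-square outline length 4 and polygon area equal to the pixel.
trace_boundary <- function(pixels) {
  n <- nrow(pixels)
  if (n == 1L) return(list(length = 4, poly_area = 1))
  r0 <- min(pixels[, 1]); c0 <- min(pixels[, 2])
  patch <- matrix(FALSE, max(pixels[, 1]) - r0 + 3L, max(pixels[, 2]) - c0 + 3L)
  patch[cbind(pixels[, 1] - r0 + 2L, pixels[, 2] - c0 + 2L)] <- TRUE
  # clockwise neighbor ring starting at W
  off <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
               c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  # start pixel: topmost then leftmost => W neighbor is background
  in_patch <- which(patch, arr.ind = TRUE)
  start <- in_patch[order(in_patch[, 1], in_patch[, 2]), , drop = FALSE][1, ]
  cur <- start
  b_idx <- 1L  # scan begins at W
  len <- 0
  second <- NULL
  steps <- 0L
  max_steps <- 8L * n + 8L
  path_r <- start[1]; path_c <- start[2]
  repeat {
    found_idx <- 0L
    for (k in seq_len(8L)) {
      idx <- ((b_idx + k - 2L) %% 8L) + 1L
      np <- cur + off[idx, ]
      if (patch[np[1], np[2]]) { found_idx <- idx; break }
    }
    if (found_idx == 0L) return(list(length = 4, poly_area = 1))  # isolated
    nxt <- cur + off[found_idx, ]
    if (!is.null(second) && all(cur == start) && all(nxt == second)) break
    if (is.null(second)) second <- nxt
    len <- len + sqrt(sum(off[found_idx, ]^2))
    path_r <- c(path_r, nxt[1]); path_c <- c(path_c, nxt[2])
    # new scan start: direction from `nxt` back to the last background
    # neighbor checked before `nxt` (or to `cur` if it was first)
    back <- if (found_idx == b_idx) cur - nxt else
      (cur + off[((found_idx - 2L) %% 8L) + 1L, ]) - nxt
    b_idx <- which(off[, 1] == back[1] & off[, 2] == back[2])
    cur <- nxt
    steps <- steps + 1L
    if (steps > max_steps) break  # safety net; cannot occur on valid masks
  }
  m <- length(path_r)
  poly_area <- if (m >= 3L) {
    j <- c(m, seq_len(m - 1L))
    abs(sum(path_c[j] * path_r - path_c * path_r[j])) / 2
  } else n
  list(length = len, poly_area = max(poly_area, 1))
}

# Solidity as a ratio of pixel counts: component pixels over pixel centres
# lying inside (or on) the convex hull of the component. Using the same
# discretisation for numerator and denominator makes convex shapes score ~ 1
# regardless of stair-step rasterization.
hull_pixel_count <- function(pixels) {
  n <- nrow(pixels)
  px <- pixels[, 2]; py <- pixels[, 1]
  h <- grDevices::chull(px, py)
  if (length(h) < 3L) return(n)
  hx <- px[h]; hy <- py[h]   # chull returns vertices clockwise in (x, y-up)
  r0 <- min(py); r1 <- max(py); c0 <- min(px); c1 <- max(px)
  gx <- rep(c0:c1, each = r1 - r0 + 1L)
  gy <- rep(r0:r1, times = c1 - c0 + 1L)
  inside <- rep(TRUE, length(gx))
  m <- length(h)
  eps <- 1e-9
  for (k in seq_len(m)) {
    k2 <- if (k == m) 1L else k + 1L
    ex <- hx[k2] - hx[k]; ey <- hy[k2] - hy[k]
    # half-plane test; orientation sign fixed by testing the centroid
    s <- ex * (mean(hy) - hy[k]) - ey * (mean(hx) - hx[k])
    cr <- ex * (gy - hy[k]) - ey * (gx - hx[k])
    inside <- inside & (if (s >= 0) cr >= -eps else cr <= eps)
  }
  max(sum(inside), n)
}

#' Measure one particle
#'
#' Computes the ImageJ-compatible descriptor set for a single connected
#' component, measured on a gray frame (by convention the difference frame it
#' was segmented from):
#' \itemize{
#'   \item area `= n_pixels * scale^2` (um^2); centroid `(x, y)` in px,
#'     0-based, x = column, y = row, origin top-left;
#'   \item gray statistics (mean/min/max) over the component's pixels;
#'   \item fitted ellipse from second-order central moments, rescaled so that
#'     `pi * (major/2) * (minor/2)` equals the component area; `angle` is the
#'     major-axis direction in degrees `[0, 180)`, measured counterclockwise
#'     from the x-axis with y pointing up (ImageJ convention);
#'   \item perimeter from the Moore boundary path (diagonal steps weighted
#'     sqrt(2)), in um;
#'   \item circularity `= 4*pi*area / perimeter^2` (clamped to <= 1),
#'     aspect_ratio `= major/minor`, roundness `= 4*area/(pi*major^2)`,
#'     solidity = particle area / convex-hull area, both measured as pixel
#'     counts on the same grid so convex shapes score ~ 1.
#' }
#' Moments include the pixel-extent term (1/12 per axis), so single-pixel
#' components stay finite (their area-matched disc has diameter
#' `2/sqrt(pi)` px); a half-pixel semi-minor floor guards thin components.
#' Degenerate rows are flagged in the `degenerate` attribute of the result.
#'
#' @param component 2-column matrix of (row, col) pixel coordinates, 1-based,
#'   as returned by [label_particles()].
#' @param grey_frame the gray image (matrix) the statistics are read from.
#' @param scale micrometres per pixel.
#' @return a one-row data.frame with columns x, y, area, mean_grey, min_grey,
#'   max_grey, perimeter, major, minor, angle, circularity, aspect_ratio,
#'   roundness, solidity.
#' @export
measure_particle <- function(component, grey_frame, scale) {
  v <- measure_particle_core(component, grey_frame, scale)
  out <- as.data.frame(as.list(v[particle_measure_cols]))
  attr(out, "degenerate") <- v[["degenerate"]] > 0
  out
}

particle_measure_cols <- c("x", "y", "area", "mean_grey", "min_grey",
                           "max_grey", "perimeter", "major", "minor", "angle",
                           "circularity", "aspect_ratio", "roundness",
                           "solidity")

measure_particle_core <- function(component, grey_frame, scale) {
  n <- nrow(component)
  if (!n) stop("empty component")
  x <- component[, 2] - 1
  y <- component[, 1] - 1
  cx <- mean(x); cy <- mean(y)
  g <- grey_frame[component]
  # central second moments with the pixel-extent term (each pixel is a unit
  # square, variance 1/12), then ellipse matched to the pixel area
  mu20 <- mean((x - cx)^2) + 1 / 12
  mu02 <- mean((y - cy)^2) + 1 / 12
  mu11 <- mean((x - cx) * (y - cy))
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 1e-12)
  a0 <- 2 * sqrt(l1)
  b0 <- 2 * sqrt(l2)
  f <- sqrt(n / (pi * a0 * b0))
  a <- a0 * f; b <- b0 * f
  degenerate <- n == 1L
  if (b < 0.5) {  # semi-minor floor: half a pixel (thin-component guard)
    degenerate <- TRUE
    b <- 0.5
    a <- max(n / (pi * b), b)
  }
  # major-axis direction; flip y for the y-up reporting convention
  ang <- if (abs(mu11) < 1e-12 && mu20 >= mu02) 0
  else if (abs(mu11) < 1e-12) 90
  else (atan2(l1 - mu20, mu11) * 180 / pi)
  ang <- (-ang) %% 180
  bnd <- trace_boundary(component)
  area <- n * scale^2
  perimeter <- bnd$length * scale
  major <- 2 * a * scale
  minor <- 2 * b * scale
  hull_n <- hull_pixel_count(component)
  c(x = cx, y = cy, area = area, mean_grey = mean(g), min_grey = min(g),
    max_grey = max(g), perimeter = perimeter, major = major, minor = minor,
    angle = ang,
    circularity = min(1, 4 * pi * area / perimeter^2),
    aspect_ratio = major / minor,
    roundness = min(1, 4 * area / (pi * major^2)),
    solidity = n / hull_n,
    degenerate = as.numeric(degenerate))
}

#' Locate and measure particles on all frames
#'
#' Runs difference-image segmentation and particle analysis over a whole
#' stack: difference image at `params$offset`, binarization at
#' `params$threshold`, 8-connected labeling with the area bounds, and the
#' full descriptor set per particle. Gray statistics are measured on the
#' difference frame by default (the image that was segmented); set
#' `grey_source = "raw"` to read them from the original frame instead.
#'
#' @param stack a [frame_stack()].
#' @param params a [segmentation_params()] object.
#' @param grey_source `"difference"` or `"raw"`.
#' @param method,blur_sigma passed to [difference_image()].
#' @return a data.frame with one row per particle and columns: video, frame
#'   (0-based), x, y, area, mean_grey, min_grey, max_grey, perimeter, major,
#'   minor, angle, circularity, aspect_ratio, roundness, solidity. Rows are
#'   ordered by frame, then by the component's top-left-most pixel.
#' @export
locate_and_measure_particles <- function(stack, params,
                                         grey_source = c("difference", "raw"),
                                         method = "subtract", blur_sigma = 0) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(params, "segmentation_params"))
  grey_source <- match.arg(grey_source)
  diff <- difference_image(stack, params$offset, method = method,
                           blur_sigma = blur_sigma)
  masks <- binarize(diff, params$threshold)
  nfd <- dim(masks)[3L]
  rows <- vector("list", nfd)
  for (t in seq_len(nfd)) {
    mk <- masks[, , t]
    if (!any(mk)) next
    comps <- label_particles(mk, params$min_area, params$max_area)
    if (!length(comps)) next
    gf <- if (grey_source == "difference") diff$frames[, , t] else
      stack$frames[, , t]
    meas <- t(vapply(comps, measure_particle_core, numeric(15),
                     grey_frame = gf, scale = stack$scale))
    rows[[t]] <- cbind(frame = t - 1L, meas)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- as.data.frame(matrix(numeric(0), 0, length(particle_measure_cols) + 1,
                                dimnames = list(NULL, c("frame", particle_measure_cols))))
    return(cbind(video = character(0), out))
  }
  m <- do.call(rbind, rows)
  out <- data.frame(video = stack$source_name,
                    as.data.frame(m[, c("frame", particle_measure_cols),
                                    drop = FALSE]))
  rownames(out) <- NULL
  out
}
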