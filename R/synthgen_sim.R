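#' Simulate a dark-field-style video with ground truth
#'
#' Renders bright ellipsoidal individuals moving by correlated random walks
#' over a dark, heterogeneous, noisy background, together with the full
#' per-frame ground truth. Each individual draws a fixed body (major axis,
#' aspect ratio) from its species distribution; each frame it advances by a
#' truncated-normal step along its heading
#' (`Normal(speed_mean, speed_sd) / fps`, >= 0) and turns by a
#' `Normal(0, turning_sd)` angle. The field is open: individuals that leave
#' it are gone for good, and new ones may enter at the edges at a constant
#' Poisson rate. Immobile debris particles are rendered identically on every
#' frame (so they cancel in a difference image). Detection dropout removes
#' an individual from the rendering of a frame with probability
#' `dropout_rate` without interrupting its true path.
#'
#' With `min_separation` set, the generator produces a *well-separated*
#' (dilute) sample: all paths are simulated first, then any path that comes
#' within `min_separation` px of another at any frame is redrawn until no
#' two individuals ever approach each other. In this regime occlusions are
#' absent by construction, which is the precondition under which trajectory
#' identities are recoverable by position-based linking. Separation is only
#' achievable for dilute scenarios (roughly up to ~15 individuals on a
#' 512 x 512 field over a few hundred frames); an error is raised if a
#' conflict-free configuration cannot be found.
#'
#' The background is a static low-frequency gray gradient plus per-frame
#' per-pixel Gaussian noise. Everything is driven by one RNG stream, so a
#' given `seed` reproduces the stack bit-exactly.
#'
#' @param species list of [species_spec()] objects.
#' @param n_per_species individuals per species (recycled).
#' @param n_frames number of frames.
#' @param fps frames per second.
#' @param scale micrometres per pixel.
#' @param field c(height, width) in px.
#' @param background_mean mean background gray value.
#' @param background_ampl amplitude of the low-frequency background gradient.
#' @param noise_sd per-pixel Gaussian noise SD (gray values).
#' @param dropout_rate per-frame probability that an individual is not
#'   rendered.
#' @param n_debris number of immobile debris particles.
#' @param entry_rate expected number of new individuals entering per frame
#'   (Poisson; species drawn uniformly); must be 0 with `min_separation`.
#' @param min_separation NULL (default) or minimum pairwise centre distance
#'   in px enforced over the whole video (see Details).
#' @param seed integer seed.
#' @param source_name name given to the rendered stack (the `video` key).
#' @return a list with components `stack` (a [frame_stack()]) and `truth`
#'   (data.frame: frame, id, species, x, y, major, minor, heading, rendered),
#'   plus `debris` (data.frame of debris positions) and the call parameters
#'   in `params`.
#' @examples
#' sp <- species_spec("tet", major_mean = 30, speed_mean = 100)
#' sim <- simulate_video(list(sp), n_per_species = 3, n_frames = 20,
#'                       field = c(128, 128), seed = 1)
#' dim(sim$stack)
#' @export
simulate_video <- function(species, n_per_species = 10, n_frames = 100,
                           fps = 25, scale = 1, field = c(512, 512),
                           background_mean = 30, background_ampl = 20,
                           noise_sd = 2, dropout_rate = 0, n_debris = 0,
                           entry_rate = 0, min_separation = NULL, seed = 1,
                           source_name = "synthetic") {
  if (inherits(species, "species_spec")) species <- list(species)
  stopifnot(all(vapply(species, inherits, logical(1), "species_spec")))
  nr <- field[1]; nc <- field[2]
  n_sp <- length(species)
  n_per_species <- rep_len(n_per_species, max(n_sp, 1L))
  max_body_px <- if (n_sp) max(vapply(species, function(s)
    s$major_mean + 3 * s$major_sd, numeric(1))) / scale else 0
  if (max_body_px > min(nr, nc) / 2) {
    stop("field too small for the requested body sizes", call. = FALSE)
  }
  if (!is.null(min_separation) && entry_rate > 0) {
    stop("entry_rate must be 0 when min_separation is set", call. = FALSE)
  }
  set.seed(seed)

  # -- phase 1: motion ------------------------------------------------------
  sim_path <- function(sp_idx, start_frame, at_edge) {
    sp <- species[[sp_idx]]
    major <- max(stats::rnorm(1, sp$major_mean, sp$major_sd), sp$major_mean / 4)
    aspect <- max(stats::rnorm(1, sp$aspect_mean, sp$aspect_sd), 1)
    margin <- major / scale / 2 + 1
    if (at_edge) {
      side <- sample.int(4L, 1L)
      x <- switch(side, stats::runif(1, 0, nc - 1), stats::runif(1, 0, nc - 1),
                  0, nc - 1)
      y <- switch(side, 0, nr - 1, stats::runif(1, 0, nr - 1),
                  stats::runif(1, 0, nr - 1))
    } else {
      x <- stats::runif(1, margin, nc - 1 - margin)
      y <- stats::runif(1, margin, nr - 1 - margin)
    }
    heading <- stats::runif(1, -pi, pi)
    n_max <- n_frames - start_frame
    xs <- ys <- hs <- numeric(n_max)
    k <- 0L
    while (k < n_max) {
      k <- k + 1L
      xs[k] <- x; ys[k] <- y; hs[k] <- heading
      step <- max(stats::rnorm(1, sp$speed_mean / fps, sp$speed_sd / fps),
                  0) / scale
      heading <- wrap_angle(heading + stats::rnorm(1, 0, sp$turning_sd))
      x <- x + step * cos(heading)
      y <- y - step * sin(heading)   # y-up heading; rows grow downward
      if (x < 0 || x > nc - 1 || y < 0 || y > nr - 1) break
    }
    list(sp_idx = sp_idx, species = sp$name, major = major,
         minor = major / aspect, intensity = sp$intensity,
         frames = start_frame + seq_len(k) - 1L,
         x = xs[seq_len(k)], y = ys[seq_len(k)], heading = hs[seq_len(k)])
  }

  paths <- list()
  for (s in seq_len(n_sp)) {
    for (k in seq_len(n_per_species[s])) {
      paths[[length(paths) + 1L]] <- sim_path(s, 0L, at_edge = FALSE)
    }
  }
  if (entry_rate > 0) {
    for (t in seq_len(n_frames) - 1L) {
      for (k in seq_len(stats::rpois(1, entry_rate))) {
        paths[[length(paths) + 1L]] <-
          sim_path(sample.int(n_sp, 1L), t, at_edge = TRUE)
      }
    }
  }

  # -- phase 2: separation repair ------------------------------------------
  if (!is.null(min_separation) && length(paths) > 1L) {
    pos_mat <- function(p) {
      x <- rep(NA_real_, n_frames); y <- rep(NA_real_, n_frames)
      x[p$frames + 1L] <- p$x; y[p$frames + 1L] <- p$y
      cbind(x, y)
    }
    pm <- lapply(paths, pos_mat)
    n_ind <- length(paths)
    conflicts <- function() {
      bad <- logical(n_ind)
      for (i in seq_len(n_ind - 1L)) {
        for (j in (i + 1L):n_ind) {
          d2 <- (pm[[i]][, 1] - pm[[j]][, 1])^2 +
            (pm[[i]][, 2] - pm[[j]][, 2])^2
          if (any(d2 < min_separation^2, na.rm = TRUE)) bad[j] <- TRUE
        }
      }
      bad
    }
    for (iter in seq_len(500L)) {
      bad <- conflicts()
      if (!any(bad)) break
      for (i in which(bad)) {
        paths[[i]] <- sim_path(paths[[i]]$sp_idx, 0L, at_edge = FALSE)
        pm[[i]] <- pos_mat(paths[[i]])
      }
      if (iter == 500L) {
        stop("could not find a well-separated configuration; reduce the ",
             "number of individuals or min_separation", call. = FALSE)
      }
    }
  }

  # -- phase 3: rendering ---------------------------------------------------
  debris <- if (n_debris > 0) data.frame(
    x = stats::runif(n_debris, 1, nc - 2),
    y = stats::runif(n_debris, 1, nr - 2),
    r = stats::runif(n_debris, 1.5, 4),
    intensity = stats::runif(n_debris, 120, 220)
  ) else data.frame(x = numeric(0), y = numeric(0), r = numeric(0),
                    intensity = numeric(0))

  gx <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  gy <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  base <- background_mean +
    background_ampl * sin(2 * pi * gx / nc) * cos(2 * pi * gy / nr)
  if (nrow(debris)) {
    for (d in seq_len(nrow(debris))) {
      pp <- ellipse_pixels(debris$x[d], debris$y[d], debris$r[d], debris$r[d],
                           0, nr, nc)
      if (nrow(pp)) base[pp] <- debris$intensity[d]
    }
  }

  by_frame <- vector("list", n_frames)
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    for (k in seq_along(p$frames)) {
      t <- p$frames[k] + 1L
      by_frame[[t]] <- rbind(by_frame[[t]],
                             c(i, k))
    }
  }

  frames <- array(0L, dim = c(nr, nc, n_frames))
  truth <- vector("list", n_frames)
  for (t in seq_len(n_frames)) {
    fr <- base + stats::rnorm(nr * nc, 0, noise_sd)
    pres <- by_frame[[t]]
    rows <- NULL
    if (!is.null(pres)) {
      rows <- vector("list", nrow(pres))
      for (q in seq_len(nrow(pres))) {
        i <- pres[q, 1L]; k <- pres[q, 2L]
        p <- paths[[i]]
        rendered <- dropout_rate <= 0 || stats::runif(1) >= dropout_rate
        if (rendered) {
          pp <- ellipse_pixels(p$x[k], p$y[k], p$major / scale / 2,
                               p$minor / scale / 2, p$heading[k], nr, nc)
          if (nrow(pp)) fr[pp] <- pmax(fr[pp], p$intensity)
        }
        rows[[q]] <- data.frame(
          frame = t - 1L, id = i, species = p$species,
          x = p$x[k], y = p$y[k], major = p$major, minor = p$minor,
          heading = p$heading[k], rendered = rendered)
      }
    }
    fr <- round(fr)
    fr[fr < 0] <- 0; fr[fr > 255] <- 255
    frames[, , t] <- as.integer(fr)
    truth[[t]] <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  truth <- do.call(rbind, truth[!vapply(truth, is.null, logical(1))])
  if (is.null(truth)) {
    truth <- data.frame(frame = integer(0), id = integer(0),
                        species = character(0), x = numeric(0), y = numeric(0),
                        major = numeric(0), minor = numeric(0),
                        heading = numeric(0), rendered = logical(0))
  }
  rownames(truth) <- NULL
  list(stack = frame_stack(frames, fps = fps, scale = scale,
                           source_name = source_name),
       truth = truth, debris = debris,
       params = list(n_per_species = n_per_species, n_frames = n_frames,
                     fps = fps, scale = scale, field = field,
                     dropout_rate = dropout_rate, n_debris = n_debris,
                     entry_rate = entry_rate, min_separation = min_separation,
                     seed = seed))
}
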