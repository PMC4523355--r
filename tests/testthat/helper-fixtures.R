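# Programmatic fixtures shared across the test files.

# constant-value frame stack
flat_stack <- function(n = 4, value = 10, dim = c(16, 16), fps = 25,
                       scale = 1, name = "flat") {
  frame_stack(array(value, dim = c(dim, n)), fps = fps, scale = scale,
              source_name = name)
}

# rasterize a filled ellipse into a logical mask; semi-axes a, b in px,
# centre (cx, cy) in 0-based pixel coords, phi in degrees, y-up convention
ellipse_mask <- function(nrow, ncol, cx, cy, a, b, phi_deg = 0) {
  phi <- phi_deg * pi / 180
  m <- matrix(FALSE, nrow, ncol)
  for (r in seq_len(nrow)) {
    dy <- (r - 1) - cy
    dx <- (seq_len(ncol) - 1) - cx
    u <- dx * cos(phi) - dy * sin(phi)
    w <- -dx * sin(phi) - dy * cos(phi)
    m[r, ] <- (u / a)^2 + (w / b)^2 <= 1
  }
  m
}

disk_mask <- function(nrow, ncol, cx, cy, radius) {
  ellipse_mask(nrow, ncol, cx, cy, radius, radius, 0)
}

# a stack with one bright square dot moving right by `step` px per frame
dot_stack <- function(n_frames = 6, dim = c(24, 48), dot = 200, bg = 10,
                      size = 2, step = 8, fps = 25, scale = 1) {
  frames <- lapply(seq_len(n_frames) - 1L, function(t) {
    f <- matrix(bg, dim[1], dim[2])
    c0 <- 3 + t * step
    f[10:(10 + size - 1), c0:(c0 + size - 1)] <- dot
    f
  })
  frame_stack(frames, fps = fps, scale = scale, source_name = "dot")
}

# minimal linked-detection table for direct metric/summary tests
make_traj_table <- function(frames, x, y, video = "v", traj_id = 1L) {
  data.frame(video = video, traj_id = traj_id,
             id = paste0(video, "-", traj_id), frame = frames, x = x, y = y)
}

# trajectory summaries drawn from parametric distributions, for the
# classifier tests (bypasses video rendering)
make_summaries <- function(n, species, area_mean = 500, speed_mean = 100,
                           seed_offset = 0) {
  morph <- c("area", "perimeter", "major", "minor", "circularity",
             "aspect_ratio", "roundness", "solidity", "mean_grey",
             "min_grey", "max_grey")
  base <- c(area = area_mean, perimeter = 90, major = 40, minor = 15,
            circularity = 0.7, aspect_ratio = 2.5, roundness = 0.4,
            solidity = 0.95, mean_grey = 150, min_grey = 60, max_grey = 220)
  out <- data.frame(id = paste0(species, "-", seq_len(n) + seed_offset),
                    species = species)
  for (m in morph) {
    v <- stats::rnorm(n, base[[m]], 0.08 * abs(base[[m]]))
    out[[paste0("mean_", m)]] <- v
    out[[paste0("median_", m)]] <- v * stats::rnorm(n, 1, 0.01)
    out[[paste0("sd_", m)]] <- abs(stats::rnorm(n, 0.1 * abs(base[[m]]),
                                                0.02 * abs(base[[m]])))
  }
  step <- speed_mean / 25
  out$median_step <- stats::rnorm(n, step, 0.1 * step)
  out$mean_step <- stats::rnorm(n, step, 0.1 * step)
  out$sd_step <- abs(stats::rnorm(n, 0.2 * step, 0.05 * step))
  out$iqr_step <- abs(stats::rnorm(n, 0.25 * step, 0.05 * step))
  out$mean_speed <- stats::rnorm(n, speed_mean, 0.1 * speed_mean)
  out$mean_turning <- stats::rnorm(n, 0, 0.05)
  out$sd_turning <- abs(stats::rnorm(n, 0.4, 0.05))
  out$net_displacement <- stats::rnorm(n, speed_mean * 4, speed_mean * 0.5)
  out$gross_displacement <- stats::rnorm(n, speed_mean * 6, speed_mean * 0.5)
  out$duration <- stats::rnorm(n, 4, 0.3)
  out$detection_rate <- pmin(1, stats::rnorm(n, 0.95, 0.03))
  out$n_detections <- round(out$duration * 25 * out$detection_rate)
  out
}

# three size-graded species used by the recovery scenarios
recovery_species <- function() {
  list(
    species_spec("small",  major_mean = 40, major_sd = 3, aspect_mean = 1.5,
                 aspect_sd = 0.1, speed_mean = 150, speed_sd = 30,
                 turning_sd = 0.20, intensity = 200),
    species_spec("medium", major_mean = 50, major_sd = 4, aspect_mean = 2.0,
                 aspect_sd = 0.15, speed_mean = 200, speed_sd = 40,
                 turning_sd = 0.17, intensity = 200),
    species_spec("large",  major_mean = 60, major_sd = 5, aspect_mean = 2.5,
                 aspect_sd = 0.2, speed_mean = 250, speed_sd = 50,
                 turning_sd = 0.14, intensity = 200)
  )
}

# write small seeded image-sequence videos for pipeline-level tests
make_input_videos <- function(root, seeds = c(4, 5), n_frames = 50) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  sp <- species_spec("mover", major_mean = 18, aspect_mean = 1.6,
                     speed_mean = 120, speed_sd = 20, turning_sd = 0.2)
  for (k in seq_along(seeds)) {
    sim <- simulate_video(list(sp), n_per_species = 3, n_frames = n_frames,
                          field = c(128, 128), min_separation = 22,
                          seed = seeds[k],
                          source_name = sprintf("vid%02d", k))
    save_frames(sim$stack, file.path(root, sprintf("vid%02d", k)))
  }
  invisible(root)
}

tiny_config <- function(in_dir, out_dir, description_file = NULL) {
  list(video = list(fps = 25, scale = 1),
       segmentation = list(offset = 10, threshold = 40),
       linking = list(link_range = 5, max_disp = 20),
       filtering = list(min_net = 20, min_duration = 0.2,
                        min_detection_rate = 0.8, min_median_step = 1),
       io = list(input_dir = in_dir, output_dir = out_dir,
                 description_file = description_file))
}
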