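summ_of <- function(frames, x, y, fps = 25, scale = 1, extra = NULL) {
  tab <- make_traj_table(frames, x, y)
  if (!is.null(extra)) tab <- cbind(tab, extra)
  m <- compute_step_metrics(tab, fps, scale)
  summarize_trajectories(m, fps, scale)
}

test_that("duration, detection rate and displacement follow their definitions", {
  s <- summ_of(0:9, x = 4 * (0:9), y = rep(0, 10))
  expect_equal(s$duration, 9 / 25)        # 0.36 s across a 10-frame span
  expect_equal(s$detection_rate, 1)
  expect_equal(s$n_detections, 10)
  expect_equal(s$net_displacement, 36)
  expect_equal(s$gross_displacement, 36)  # ballistic: net = gross
  expect_equal(s$median_step, 4)
  expect_equal(s$mean_speed, 36 / 0.36)

  # 8 detections over a 10-frame inclusive span -> exactly 80%
  fr <- c(0, 1, 2, 3, 4, 5, 6, 9)
  s8 <- summ_of(fr, x = 10 * seq_along(fr), y = rep(0, 8))
  expect_equal(s8$detection_rate, 0.8)
})

test_that("single-detection trajectories degenerate gracefully", {
  s <- summ_of(3, x = 5, y = 5)
  expect_equal(s$duration, 0)
  expect_equal(s$net_displacement, 0)
  expect_equal(s$detection_rate, 1)
  expect_true(is.na(s$median_step))
  expect_true(is.na(s$mean_speed))
  expect_equal(nrow(filter_data(s)), 0)  # removed by the filters
})

test_that("morphology descriptors are averaged over the trajectory", {
  areas <- c(100, 120, 140)
  s <- summ_of(0:2, x = c(0, 30, 60), y = rep(0, 3),
               extra = data.frame(area = areas))
  expect_equal(s$mean_area, mean(areas))
  expect_equal(s$median_area, 120)
  expect_equal(s$sd_area, sd(areas))
})

test_that("empty input produces an empty summary, not an error", {
  empty <- compute_step_metrics(
    data.frame(video = character(0), traj_id = integer(0),
               frame = numeric(0), x = numeric(0), y = numeric(0)), 25, 1)
  s <- summarize_trajectories(empty, 25, 1)
  expect_equal(nrow(s), 0)
  expect_true(all(c("id", "net_displacement", "detection_rate") %in% names(s)))
})

test_that("filter boundaries: inclusive minima, strict median step", {
  base <- summ_of(0:9, x = 4 * (0:9), y = rep(0, 10))
  tweak <- function(...) {
    s <- base
    for (nm in names(list(...))) s[[nm]] <- list(...)[[nm]]
    s
  }
  expect_equal(nrow(filter_data(tweak(net_displacement = 50))), 1)
  expect_equal(nrow(filter_data(tweak(net_displacement = 49.99))), 0)
  expect_equal(nrow(filter_data(tweak(duration = 0.2, net_displacement = 60))), 1)
  expect_equal(nrow(filter_data(tweak(duration = 0.19, net_displacement = 60))), 0)
  expect_equal(nrow(filter_data(tweak(detection_rate = 0.8, net_displacement = 60))), 1)
  expect_equal(nrow(filter_data(tweak(detection_rate = 0.79, net_displacement = 60))), 0)
  expect_equal(nrow(filter_data(tweak(median_step = 2, net_displacement = 60))), 0)
  expect_equal(nrow(filter_data(tweak(median_step = 2.01, net_displacement = 60))), 1)
})

test_that("filtering is monotone and the zero filter is the identity", {
  set.seed(21)
  s <- make_summaries(40, "mix")
  s$duration <- stats::runif(40, 0, 0.5)
  s$detection_rate <- stats::runif(40, 0.5, 1)
  s$net_displacement <- stats::runif(40, 0, 120)
  s$median_step <- stats::runif(40, 0, 5)
  strict <- filter_data(s, 50, 0.2, 0.8, 2)
  relaxed <- filter_data(s, 30, 0.1, 0.6, 1)
  expect_true(all(strict$id %in% relaxed$id))
  ident <- filter_data(s, 0, 0, 0, -1)
  expect_equal(nrow(ident), nrow(s))
  expect_identical(ident$id, s$id)
})

test_that("planted debris is filtered out while movers are retained", {
  sp <- species_spec("mover", major_mean = 20, aspect_mean = 1.6,
                     speed_mean = 120, speed_sd = 20, turning_sd = 0.2)
  sim <- simulate_video(list(sp), n_per_species = 3, n_frames = 60,
                        field = c(160, 160), n_debris = 6, noise_sd = 2,
                        min_separation = 25, seed = 31)
  parts <- locate_and_measure_particles(
    sim$stack, segmentation_params(offset = 10, threshold = 40))
  traj <- compute_step_metrics(link_particles(parts, link_params(5, 20)),
                               25, 1)
  filt <- filter_data(summarize_trajectories(traj, 25, 1))
  # every retained trajectory matches a planted mover, none matches debris
  expect_gt(nrow(filt), 0)
  kept <- traj[traj$id %in% filt$id, ]
  sc <- score_against_truth(kept, sim$truth, match_radius = 8,
                            frame_range = c(0, 49))
  expect_equal(nrow(sc$matches), nrow(kept))
})
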