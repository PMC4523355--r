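test_that("an empty community renders only background", {
  sim <- simulate_video(list(), n_per_species = 0, n_frames = 12,
                        field = c(64, 64), seed = 3)
  expect_equal(n_frames(sim$stack), 12)
  expect_equal(nrow(sim$truth), 0)
  parts <- locate_and_measure_particles(
    sim$stack, segmentation_params(offset = 4, threshold = 40))
  expect_equal(nrow(parts), 0)
})

test_that("slow central individuals are present on every frame", {
  sp <- species_spec("slow", major_mean = 12, aspect_mean = 1.5,
                     speed_mean = 4, speed_sd = 1, turning_sd = 0.3)
  sim <- simulate_video(list(sp), n_per_species = 5, n_frames = 20,
                        field = c(128, 128), seed = 6)
  counts <- table(sim$truth$frame)
  expect_equal(length(counts), 20)
  expect_true(all(counts == 5))
  expect_true(all(sim$truth$rendered))
})

test_that("the same seed reproduces the video bit-exactly", {
  sp <- species_spec("a", major_mean = 15, speed_mean = 80)
  s1 <- simulate_video(list(sp), 3, 10, field = c(64, 64), seed = 42)
  s2 <- simulate_video(list(sp), 3, 10, field = c(64, 64), seed = 42)
  expect_identical(s1$stack$frames, s2$stack$frames)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_video(list(sp), 3, 10, field = c(64, 64), seed = 43)
  expect_false(identical(s1$stack$frames, s3$stack$frames))
})

test_that("zero turning gives ballistic truth paths with nsd = gross^2", {
  sp <- species_spec("straight", major_mean = 12, speed_mean = 60,
                     speed_sd = 0, turning_sd = 0)
  sim <- simulate_video(list(sp), n_per_species = 3, n_frames = 15,
                        field = c(256, 256), seed = 12)
  for (i in unique(sim$truth$id)) {
    tr <- sim$truth[sim$truth$id == i, ]
    m <- compute_step_metrics(
      make_traj_table(tr$frame, tr$x, tr$y, traj_id = i), 25, 1)
    expect_equal(m$nsd, m$gross^2, tolerance = 1e-9)
    expect_true(all(abs(m$turning_angle[-(1:2)]) < 1e-9))
  }
})

test_that("dropout removes renderings but not the true path", {
  sp <- species_spec("drop", major_mean = 14, speed_mean = 60,
                     turning_sd = 0.2)
  sim <- simulate_video(list(sp), n_per_species = 4, n_frames = 40,
                        field = c(128, 128), dropout_rate = 0.3, seed = 9)
  expect_gt(sum(!sim$truth$rendered), 0)
  per_id <- table(sim$truth$id)
  expect_true(all(per_id >= 1))
})

test_that("separated mode keeps every pair at distance", {
  sp <- species_spec("sep", major_mean = 14, speed_mean = 100,
                     turning_sd = 0.2)
  sim <- simulate_video(list(sp), n_per_species = 6, n_frames = 60,
                        field = c(256, 256), min_separation = 25, seed = 8)
  tr <- sim$truth
  for (t in unique(tr$frame)) {
    pos <- tr[tr$frame == t, c("x", "y")]
    if (nrow(pos) > 1) {
      d <- as.matrix(stats::dist(pos))
      expect_gte(min(d[upper.tri(d)]), 25)
    }
  }
  expect_error(
    simulate_video(list(sp), 2, 10, field = c(128, 128),
                   min_separation = 20, entry_rate = 1, seed = 1),
    "entry_rate")
})

test_that("scoring is exact on a constructed match", {
  truth <- data.frame(frame = rep(0:4, 2), id = rep(1:2, each = 5),
                      species = "s", x = c(10:14, 40:44),
                      y = rep(c(10, 40), each = 5),
                      major = 20, minor = 10, heading = 0, rendered = TRUE)
  det <- data.frame(id = rep(c("v-1", "v-2"), each = 5),
                    frame = rep(0:4, 2), x = c(10:14, 40:44),
                    y = rep(c(10, 40), each = 5), major = 19)
  sc <- score_against_truth(det, truth, match_radius = 5,
                            frame_range = c(0, 4))
  expect_equal(sc$identity$f1, 1)
  expect_equal(sc$position_rmse, 0)
  expect_equal(sc$counts$count_error_pct, 0)
  expect_equal(sc$morphology$major_recovery, 19 / 20)

  # splitting one true individual across two recovered ids lowers recall
  det2 <- det
  det2$id[3:5] <- "v-9"
  sc2 <- score_against_truth(det2, truth, match_radius = 5,
                             frame_range = c(0, 4))
  expect_lt(sc2$identity$f1, 1)
  expect_equal(sc2$identity$precision, 1)
})

test_that("oversized bodies are rejected", {
  sp <- species_spec("huge", major_mean = 500)
  expect_error(simulate_video(list(sp), 1, 5, field = c(64, 64), seed = 1),
               "too small")
})
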