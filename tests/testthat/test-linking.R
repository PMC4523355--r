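random_stage <- function(nT, nD, allow_p = 0.8) {
  sqd <- matrix(stats::runif(nT * nD, 0, 900), nT, nD)
  allowed <- matrix(stats::runif(nT * nD) < allow_p, nT, nD)
  list(sqd = sqd, allowed = allowed)
}

test_that("the assignment stage matches the exhaustive optimum", {
  set.seed(42)
  for (k in 1:120) {
    nT <- sample(1:4, 1); nD <- sample(1:4, 1)
    st <- random_stage(nT, nD)
    a <- trackmorph:::assign_stage(st$sqd, st$allowed, 400)
    b <- trackmorph:::assign_stage_exhaustive(st$sqd, st$allowed, 400)
    expect_equal(a$cost, b$cost, tolerance = 1e-9)
  }
})

test_that("well-separated movers are linked to the ground-truth partition", {
  frames <- 0:9
  a <- data.frame(video = "v", frame = frames, x = 10 + 3 * frames, y = 10)
  b <- data.frame(video = "v", frame = frames, x = 210 + 3 * frames, y = 150)
  traj <- link_particles(rbind(a, b), link_params(5, 20))
  expect_equal(length(unique(traj$traj_id)), 2)
  left <- traj$traj_id[traj$x < 100]
  expect_equal(length(unique(left)), 1)
  expect_equal(sum(traj$traj_id == left[1]), 10)
})

test_that("gaps are closed within the link range and split beyond it", {
  det <- data.frame(video = "v", frame = c(0, 1, 3, 4),
                    x = c(0, 3, 9, 12), y = 0)
  one <- link_particles(det, link_params(link_range = 2, max_disp = 20))
  expect_equal(length(unique(one$traj_id)), 1)
  two <- link_particles(det, link_params(link_range = 1, max_disp = 20))
  expect_equal(length(unique(two$traj_id)), 2)
  expect_equal(unname(table(two$traj_id)), c(2L, 2L), ignore_attr = TRUE)
})

test_that("detections are conserved and row permutations do not matter", {
  set.seed(9)
  det <- data.frame(video = "v",
                    frame = rep(0:5, each = 3),
                    x = stats::runif(18, 0, 100),
                    y = stats::runif(18, 0, 100))
  linked <- link_particles(det, link_params(5, 20))
  expect_equal(nrow(linked), nrow(det))
  signature <- function(tab) {
    parts <- split(paste(tab$frame, round(tab$x, 9), round(tab$y, 9)),
                   tab$traj_id)
    sort(vapply(parts, function(p) paste(sort(p), collapse = "|"),
                character(1)))
  }
  shuffled <- det[sample(nrow(det)), ]
  expect_identical(signature(link_particles(shuffled, link_params(5, 20))),
                   signature(linked))
})

test_that("occlusion terminates the losing trajectory conservatively", {
  # two particles converge on one shared detection, then separate beyond the
  # link range: the winner continues, the loser ends, nothing is recombined
  det <- rbind(
    data.frame(video = "v", frame = 0:4, x = c(0, 5, 10, 15, 20), y = 0),
    data.frame(video = "v", frame = 0:1, x = c(40, 33), y = c(30, 15)),
    data.frame(video = "v", frame = 2, x = 21, y = 1))
  linked <- link_particles(det, link_params(link_range = 1, max_disp = 20))
  expect_equal(nrow(linked), nrow(det))
  # the straight mover keeps a single identity through the crowded frame
  straight <- linked[linked$y == 0 & linked$x <= 20, ]
  expect_equal(length(unique(straight$traj_id)), 1)
})

test_that("staged linking with the hungarian solver equals the exhaustive one", {
  set.seed(77)
  for (rep in 1:8) {
    n_p <- sample(2:4, 1)
    n_f <- sample(3:6, 1)
    rows <- list()
    for (i in seq_len(n_p)) {
      x <- stats::runif(1, 0, 60); y <- stats::runif(1, 0, 60)
      for (t in 0:(n_f - 1)) {
        if (stats::runif(1) < 0.15) next  # detection dropout
        rows[[length(rows) + 1L]] <-
          data.frame(video = "v", frame = t, x = x + stats::rnorm(1, 0, 4),
                     y = y + stats::rnorm(1, 0, 4))
      }
    }
    det <- do.call(rbind, rows)
    h <- link_particles(det, link_params(3, 15), solver = "hungarian",
                        diagnostics = TRUE)
    e <- link_particles(det, link_params(3, 15), solver = "exhaustive",
                        diagnostics = TRUE)
    sh <- attr(h, "stages"); se <- attr(e, "stages")
    expect_equal(sh$cost, se$cost, tolerance = 1e-9)
    expect_equal(nrow(h), nrow(det))
  }
})

test_that("step metrics follow their closed forms", {
  tab <- make_traj_table(0:1, x = c(0, 3), y = c(0, -4))
  m <- compute_step_metrics(tab, fps = 25, scale = 1)
  expect_equal(m$step_length[2], 5)  # 3-4-5 triangle
  expect_equal(m$nsd[2], 25)
  expect_equal(m$gross, c(0, 5))
  expect_true(is.na(m$step_length[1]))

  # collinear equal steps: zero turning, ballistic nsd = gross^2
  k <- 6
  tab2 <- make_traj_table(0:k, x = 2 * (0:k), y = rep(0, k + 1))
  m2 <- compute_step_metrics(tab2, fps = 25, scale = 1.5)
  expect_true(all(abs(m2$turning_angle[-(1:2)]) < 1e-12))
  expect_equal(m2$nsd, m2$gross^2)
  expect_equal(m2$nsd[k + 1], (k * 2 * 1.5)^2)

  # zero-length step: undefined angles are propagated as missing
  tab3 <- make_traj_table(0:2, x = c(0, 0, 1), y = c(0, 0, 0))
  m3 <- compute_step_metrics(tab3, 25, 1)
  expect_true(is.na(m3$abs_angle[2]))
  expect_true(is.na(m3$turning_angle[3]))
  expect_equal(m3$step_length[2], 0)

  expect_error(compute_step_metrics(data.frame(x = 1), 25, 1), "missing")
})

test_that("unbiased random-walk turning angles average to zero", {
  set.seed(123)
  n <- 600
  turns <- stats::rnorm(n, 0, 0.6)
  heading <- cumsum(c(stats::runif(1, -pi, pi), turns))
  x <- cumsum(c(0, 3 * cos(heading[-1])))
  y <- cumsum(c(0, -3 * sin(heading[-1])))
  m <- compute_step_metrics(make_traj_table(0:n, x, y), 25, 1)
  tu <- m$turning_angle[!is.na(m$turning_angle)]
  se <- stats::sd(tu) / sqrt(length(tu))
  expect_lt(abs(mean(tu)), 3 * se)
  # and the recovered turning angles match the generating ones
  expect_equal(tu, wrap_angle(turns[-1]), tolerance = 1e-9)
})

test_that("linking validates its inputs", {
  expect_error(link_particles(data.frame(x = 1, y = 1), link_params()),
               "video")
  expect_error(link_params(link_range = 0), "link_range")
  expect_error(link_params(max_disp = -1), "max_disp")
  empty <- link_particles(data.frame(video = character(0), frame = numeric(0),
                                     x = numeric(0), y = numeric(0)),
                          link_params())
  expect_equal(nrow(empty), 0)
  expect_true(all(c("traj_id", "id") %in% names(empty)))
})
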