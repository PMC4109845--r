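test_that("trajectory tables load, validate and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_demo_trajectory(path)
  traj <- load_trajectory(path, fps = 10, body_length = 0.002)
  expect_s3_class(traj, "swarm_trajectory")
  expect_length(traj$frames, 2)
  expect_equal(nrow(traj$frames[[1]]$positions), 3)

  # duplicated (frame, id) row is an integrity error
  tab <- read.csv(path)
  write.csv(rbind(tab, tab[1, ]), path, row.names = FALSE)
  expect_error(load_trajectory(path, 10, 0.002),
               class = "swarm_integrity_error")

  # non-numeric coordinate is a parse error naming the line
  tab$x[3] <- "oops"
  write.csv(tab, path, row.names = FALSE)
  expect_error(load_trajectory(path, 10, 0.002), "line 3",
               class = "swarm_parse_error")

  # write -> load round-trip on a generated 10-frame trajectory
  traj10 <- correlated_trajectory(n = 20, n_frames = 10, seed = 5)
  out <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj10, out)
  back <- load_trajectory(out, traj10$fps, traj10$body_length)
  for (t in seq_along(traj10$frames))
    expect_equal(back$frames[[t]]$positions, traj10$frames[[t]]$positions,
                 tolerance = 1e-12)
})

test_that("event config files carry the acquisition metadata", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("fps: 170", "body_length: 0.0012",
               "species_label: Chironomidae sp.",
               "event_id: E1"), path)
  cfg <- read_event_config(path)
  expect_equal(cfg$fps, 170)
  expect_equal(cfg$body_length, 0.0012)
  writeLines("fps: 170", path)
  expect_error(read_event_config(path), class = "swarm_parse_error")
})

test_that("metadata invariants are enforced", {
  f <- swarm_frame(0L, matrix(rnorm(9), 3))
  expect_error(swarm_trajectory(list(f), fps = -1, body_length = 1),
               class = "swarm_integrity_error")
  expect_error(swarm_trajectory(list(f), fps = 1, body_length = 0),
               class = "swarm_integrity_error")
  expect_error(swarm_frame(0L, matrix(c(1, NA, 3, 4, 5, 6), 2)),
               class = "swarm_integrity_error")
})

test_that("forward-difference velocities match an independent loop", {
  # stationary points: zero velocity
  pos <- matrix(runif(15), 5)
  frames <- lapply(0:2, function(t) swarm_frame(t, pos))
  tr <- compute_velocities(swarm_trajectory(frames, 10, 0.002))
  expect_equal(tr$frames[[1]]$velocities, 0 * pos, ignore_attr = TRUE)

  # uniform motion x(t) = (t/fps, 0, 0): velocity (1, 0, 0)
  frames <- lapply(0:3, function(t)
    swarm_frame(t, cbind(t / 10 + 1:4, 0, 0)))
  tr <- compute_velocities(swarm_trajectory(frames, 10, 0.002))
  for (t in 1:3)
    expect_equal(tr$frames[[t]]$velocities,
                 cbind(rep(1, 4), 0, 0), ignore_attr = TRUE)

  # random walk: compare to a brute-force finite-difference loop
  set.seed(11)
  xs <- lapply(0:4, function(t) matrix(rnorm(18), 6))
  frames <- lapply(0:4, function(t) swarm_frame(t, xs[[t + 1]]))
  tr <- compute_velocities(swarm_trajectory(frames, 25, 0.002))
  for (t in 1:4) {
    manual <- matrix(NA_real_, 6, 3)
    for (i in 1:6) for (k in 1:3)
      manual[i, k] <- (xs[[t + 1]][i, k] - xs[[t]][i, k]) * 25
    expect_equal(tr$frames[[t]]$velocities, manual, ignore_attr = TRUE)
  }
  expect_null(tr$frames[[5]]$velocities)

  # individual absent at t+1 gets a missing velocity
  f0 <- swarm_frame(0L, matrix(1:9, 3, dimnames = list(c("a", "b", "c"))))
  f1 <- swarm_frame(1L, matrix(1:6, 2, 3,
                               dimnames = list(c("a", "b"))))
  tr <- compute_velocities(swarm_trajectory(list(f0, f1), 1, 1))
  expect_true(all(is.na(tr$frames[[1]]$velocities["c", ])))
  expect_false(anyNA(tr$frames[[1]]$velocities[c("a", "b"), ]))
})

test_that("velocity integration recovers positions up to the offset", {
  traj <- correlated_trajectory(n = 15, n_frames = 8, seed = 3)
  tr <- compute_velocities(traj)
  x <- tr$frames[[1]]$positions
  for (t in 1:7) {
    x <- x + tr$frames[[t]]$velocities / tr$fps
    expect_equal(x, tr$frames[[t + 1]]$positions, tolerance = 1e-10)
  }
})

test_that("nearest-neighbour distance matches oracle and its symmetries", {
  expect_equal(nearest_neighbour_distance(rbind(c(0, 0, 0), c(0.1, 0, 0))),
               0.1)
  lattice <- cbind(0:4, 0, 0)
  expect_equal(nearest_neighbour_distance(lattice), 1.0)
  expect_error(nearest_neighbour_distance(matrix(0, 1, 3)),
               class = "swarm_degenerate_error")

  set.seed(7)
  pts <- matrix(runif(150), 50)
  expect_equal(nearest_neighbour_distance(pts), oracle_r1(pts))

  # translation/rotation invariance, linear scaling (exact)
  r <- rotation_matrix(c(1, 2, 3), 0.7)
  moved <- sweep(pts %*% t(r), 2, c(5, -2, 1), `+`)
  expect_equal(nearest_neighbour_distance(moved),
               nearest_neighbour_distance(pts), tolerance = 1e-12)
  expect_equal(nearest_neighbour_distance(pts * 3.5),
               3.5 * nearest_neighbour_distance(pts), tolerance = 1e-12)
})

test_that("pairwise sample files parse exactly and report bad lines", {
  path <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.05 0.8", "0.30 -0.1"), path)
  s <- read_pairwise(path)
  expect_equal(s$distance, c(0.05, 0.30))
  expect_equal(s$dot, c(0.8, -0.1))

  writeLines(character(0), path)
  expect_equal(nrow(read_pairwise(path)), 0)

  writeLines(c("0.05 0.8", "bad row"), path)
  expect_error(read_pairwise(path), "line 2", class = "swarm_parse_error")

  # frame-generated pairwise samples match an independent double loop
  cs <- correlated_swarm(n = 12, seed = 2)
  samp <- pairwise_samples(cs$phi, cs$positions)
  manual <- data.frame(distance = numeric(0), dot = numeric(0))
  for (i in 1:12) for (j in 1:12) {
    if (i == j) next
    manual <- rbind(manual, data.frame(
      distance = sqrt(sum((cs$positions[i, ] - cs$positions[j, ])^2)),
      dot = sum(cs$phi[i, ] * cs$phi[j, ])))
  }
  expect_equal(sort(samp$distance), sort(manual$distance))
  expect_equal(sort(samp$dot), sort(manual$dot))

  # write -> read round trip
  write_pairwise(samp, path)
  back <- read_pairwise(path)
  expect_equal(back$distance, samp$distance, tolerance = 1e-9)
  expect_equal(back$dot, samp$dot, tolerance = 1e-9)

  # the shipped synthetic example file parses and binns into a curve
  shipped <- system.file("extdata", "pairwise_synthetic.dat",
                         package = "swarmcorr")
  s2 <- read_pairwise(shipped)
  expect_gt(nrow(s2), 10)
  expect_true(all(is.finite(s2$dot)))
  expect_s3_class(correlation_from_pairwise(s2), "correlation_curve")
})
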