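test_that("translation subtraction centres the fluctuation field", {
  set.seed(2)
  x0 <- matrix(rnorm(60), 20)
  # pure translation: all velocities equal -> zero fluctuations
  st <- subtract_translation(x0, x0 + rep(1, 20) %o% c(1, 2, 3))
  expect_equal(st$dv, 0 * x0, ignore_attr = TRUE)

  # symmetric pair: opposite velocities survive, sum to zero
  p0 <- rbind(c(0, 0, 0), c(1, 0, 0))
  u <- c(0, 0.3, 0)
  st <- subtract_translation(p0, p0 + rbind(u, -u))
  expect_equal(st$dv, rbind(u, -u), tolerance = 1e-12, ignore_attr = TRUE)

  # random field vs explicit mean-subtraction loop
  v <- matrix(rnorm(60), 20)
  st <- subtract_translation(x0, x0 + v)
  manual <- v
  for (k in 1:3) manual[, k] <- v[, k] - mean(v[, k])
  expect_equal(st$dv, manual, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(colSums(st$dv), c(0, 0, 0), tolerance = 1e-12)
})

test_that("optimal rotation: identity, planted, noisy vs grid oracle", {
  set.seed(5)
  y <- matrix(rnorm(18), 6)
  y <- sweep(y, 2, colMeans(y))
  fit <- fit_rotation(y, y)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$angle, 0, tolerance = 1e-9)

  r10 <- rotation_matrix(c(0, 0, 1), 10 * pi / 180)
  fit <- fit_rotation(y, y %*% t(r10))
  expect_equal(fit$rotation, r10, tolerance = 1e-9)
  expect_equal(fit$angle, 10 * pi / 180, tolerance = 1e-9)
  expect_equal(abs(sum(fit$axis * c(0, 0, 1))), 1, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)

  # planted rotation plus noise: agree with a coarse grid-search oracle
  y1 <- y %*% t(r10) + matrix(rnorm(18, sd = 0.01), 6)
  fit <- fit_rotation(y, y1)
  oracle <- oracle_grid_rotation(y, y1)
  # the SVD solution cannot be worse than the best grid point
  expect_lte(sum((y1 - y %*% t(fit$rotation))^2), oracle$rss + 1e-12)
  # agreement limited by the oracle's axis/angle grid resolution
  expect_lt(abs(fit$angle - oracle$angle), 3 * pi / 180)
  expect_gt(abs(sum(fit$axis * oracle$axis)), 0.98)

  # collinear points are rejected
  line <- cbind(-2:2, 0, 0)
  expect_error(fit_rotation(line, line), class = "swarm_rank_error")
})

test_that("optimal dilatation: closed form matches 1D minimization", {
  set.seed(6)
  y <- matrix(rnorm(60), 20)
  expect_equal(fit_dilatation(y, 1.5 * y), 1.5, tolerance = 1e-12)
  expect_equal(fit_dilatation(y, y), 1, tolerance = 1e-12)
  y1 <- 0.8 * y + matrix(rnorm(60, sd = 0.05), 20)
  expect_equal(fit_dilatation(y, y1), oracle_golden_dilatation(y, y1),
               tolerance = 1e-7)
  expect_error(fit_dilatation(0 * y, y), class = "swarm_degenerate_error")
})

test_that("decomposition removes exact rigid+dilatational motion", {
  ps <- planted_mode_swarm(n = 40, v_cm = c(0.2, -0.1, 0.05),
                          angle = 0.2, axis = c(1, 1, 0), alpha = 1.1,
                          noise_sd = 0, fps = 5, seed = 8)
  d <- decompose_modes(ps$x0, ps$x1, ps$fps)
  vmag <- sqrt(mean(rowSums(((ps$x1 - ps$x0) * ps$fps)^2)))
  expect_lt(max(abs(d$residuals)), 1e-9 * vmag)
  expect_equal(d$v_cm, ps$truth$v_cm, tolerance = 1e-9)
  expect_equal(d$rotation_angle, ps$truth$angle, tolerance = 1e-9)
  expect_equal(d$dilatation, ps$truth$alpha, tolerance = 1e-9)
})

test_that("pure noise field keeps its fluctuations, phi normalized", {
  set.seed(9)
  x0 <- matrix(rnorm(60), 20)
  d0 <- decompose_modes(x0, x0 + 1e-3 * matrix(rnorm(60), 20))
  expect_equal(mean(rowSums(d0$phi^2)), 1, tolerance = 1e-12)
  expect_equal(colSums(d0$residuals), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(colSums(d0$phi), c(0, 0, 0), tolerance = 1e-9)
})

test_that("planted modes are recovered unbiasedly under noise", {
  n_seeds <- 100
  err <- matrix(NA_real_, n_seeds, 3)
  for (s in seq_len(n_seeds)) {
    ps <- planted_mode_swarm(n = 50, v_cm = c(0.1, 0, 0), angle = 0.1,
                            axis = c(0, 0, 1), alpha = 1.05,
                            noise_sd = 0.01, seed = s)
    d <- decompose_modes(ps$x0, ps$x1, ps$fps)
    err[s, ] <- c(d$v_cm[1] - 0.1, d$rotation_angle - 0.1,
                  d$dilatation - 1.05)
  }
  for (k in 1:3) {
    se <- sd(err[, k]) / sqrt(n_seeds)
    expect_lt(abs(mean(err[, k])), 3 * se + 1e-12)
  }
})

test_that("residual objective is non-increasing along the subtraction", {
  for (s in 1:20) {
    ps <- planted_mode_swarm(n = 30, v_cm = rnorm(3, sd = 0.1),
                            angle = runif(1, 0, 0.3), axis = rnorm(3),
                            alpha = runif(1, 0.8, 1.2), noise_sd = 0.05,
                            seed = 100 + s)
    d <- decompose_modes(ps$x0, ps$x1, ps$fps)
    rss_t <- sum(d$dv^2)
    rss_tr <- sum(d$dv_rot^2)
    rss_trd <- sum(d$residuals^2)
    expect_lte(rss_tr, rss_t + 1e-9)
    expect_lte(rss_trd, rss_tr + 1e-9)
  }
})

test_that("order parameters hit their coherent-motion limits", {
  set.seed(10)
  x0 <- matrix(rnorm(36), 12)
  # identical velocities: polarization 1
  op <- order_parameters(x0, x0 + rep(1, 12) %o% c(0.1, 0, 0))
  expect_equal(op$polarization, 1, tolerance = 1e-12)

  # rigid rotation of a ring about z: rotational order 1
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  ring <- cbind(cos(th), sin(th), 0)
  rot <- rotation_matrix(c(0, 0, 1), 0.1)
  op <- order_parameters(ring, ring %*% t(rot))
  expect_equal(op$rotational, 1, tolerance = 1e-9)

  # coherent expansion / contraction: dilatational order +1 / -1
  y <- matrix(rnorm(45), 15)
  y <- sweep(y, 2, colMeans(y))
  op <- order_parameters(y, y * 1.2)    # dv_rot proportional to +y
  expect_equal(op$dilatational, 1, tolerance = 1e-9)
  op <- order_parameters(y, y * 0.8)
  expect_equal(op$dilatational, -1, tolerance = 1e-9)

  # zero-speed individuals are excluded with a warning
  x1 <- x0 + rep(1, 12) %o% c(0.1, 0, 0)
  x1[3, ] <- x0[3, ]
  expect_warning(op <- order_parameters(x0, x1), "zero-speed")
  expect_equal(op$polarization, 1, tolerance = 1e-12)
})

test_that("decomposition and order parameters are rotation equivariant", {
  g <- rotation_matrix(c(2, -1, 0.5), 1.1)
  for (s in 1:5) {
    ps <- planted_mode_swarm(n = 25, v_cm = c(0.05, 0, 0), angle = 0.15,
                            axis = c(0, 1, 0), alpha = 0.95,
                            noise_sd = 0.02, seed = 200 + s)
    a <- frame_pair_stats_for_test(ps$x0, ps$x1)
    b <- frame_pair_stats_for_test(ps$x0 %*% t(g), ps$x1 %*% t(g))
    expect_equal(a$order$polarization, b$order$polarization,
                 tolerance = 1e-9)
    expect_equal(a$order$rotational, b$order$rotational, tolerance = 1e-9)
    expect_equal(a$order$dilatational, b$order$dilatational,
                 tolerance = 1e-9)
    expect_equal(sort(rowSums(a$dec$residuals^2)),
                 sort(rowSums(b$dec$residuals^2)), tolerance = 1e-9)
  }
})

test_that("null band follows the random-unit-vector asymptotics", {
  nb <- null_band(1000, n_samples = 300, seed = 21)
  mc_se <- nb["polarization", "sd"] / sqrt(300)
  expect_lt(abs(nb["polarization", "mean"] - sqrt(8 / (3 * pi * 1000))),
            3 * mc_se)
  expect_gt(nb["polarization", "mean"], 0)

  # doubling N halves E[Phi]^2
  nb2 <- null_band(2000, n_samples = 300, seed = 22)
  ratio <- nb["polarization", "mean"]^2 / nb2["polarization", "mean"]^2
  expect_equal(ratio, 2, tolerance = 0.25)
})
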