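#' Collective-mode decomposition of swarm motion
#'
#' Disordered swarms still move collectively: the whole group can translate,
#' rotate and expand or contract. Before measuring how individuals influence
#' each other we must remove these collective modes, otherwise rigid group
#' motion masquerades as correlation. The decomposition is sequential:
#' translation (centre-of-mass velocity), then the optimal proper rotation
#' between the two centred configurations, then the optimal uniform
#' dilatation. What is left, the residual fluctuation `delta v_i`, is the
#' individual contribution; its dimensionless version
#' `phi_i = delta v_i / sqrt(mean |delta v|^2)` satisfies
#' `(1/N) sum phi_i . phi_i = 1` and `sum phi_i = 0` exactly, which is what
#' makes correlation functions comparable across swarms and models.
#'
#' @param x0,x1 N x 3 position matrices at consecutive frames (same
#'   individuals, row-aligned), N >= 3 and non-collinear.
#' @param fps frame rate; velocities are `(x1 - x0) * fps`.
#' @return A list of class `mode_decomposition` with elements
#'   `v_cm` (centre-of-mass velocity, m/s), `rotation` (3 x 3 proper
#'   orthogonal matrix), `rotation_axis` (unit vector, angle >= 0),
#'   `rotation_angle` (radians), `dilatation` (scalar per frame step),
#'   `y` (centred positions at t), `dv` (translation-subtracted
#'   fluctuations), `dv_rot` (translation+rotation-subtracted), `residuals`
#'   (`delta v`, all three modes subtracted), `phi` (dimensionless
#'   fluctuations; `NA` when the residual field is identically zero), `n`.
#' @export
decompose_modes <- function(x0, x1, fps = 1) {
  x0 <- as.matrix(x0); x1 <- as.matrix(x1)
  n <- nrow(x0)
  if (n < 2L)
    swarm_stop("mode decomposition needs N >= 2", "swarm_degenerate_error")
  if (!identical(dim(x0), dim(x1)))
    swarm_stop("frame pair must have matching dimensions",
               "swarm_integrity_error")
  cm0 <- colMeans(x0); cm1 <- colMeans(x1)
  y0 <- sweep(x0, 2L, cm0); y1 <- sweep(x1, 2L, cm1)
  v_cm <- (cm1 - cm0) * fps
  dv <- (y1 - y0) * fps                      # translation subtracted
  rot <- fit_rotation(y0, y1)
  y_rot <- y0 %*% t(rot$rotation)
  dv_rot <- (y1 - y_rot) * fps               # + rotation subtracted
  alpha <- fit_dilatation(y_rot, y1)
  residuals <- (y1 - alpha * y_rot) * fps    # + dilatation subtracted
  msq <- mean(rowSums(residuals^2))
  phi <- if (msq > 0) residuals / sqrt(msq) else
    matrix(NA_real_, n, 3L)
  structure(list(v_cm = v_cm, rotation = rot$rotation,
                 rotation_axis = rot$axis, rotation_angle = rot$angle,
                 dilatation = alpha, y = y0, dv = dv, dv_rot = dv_rot,
                 residuals = residuals, phi = phi, n = n),
            class = "mode_decomposition")
}

#' Translation subtraction
#'
#' Centre-of-mass frame positions and translation-subtracted velocity
#' fluctuations for a frame pair. The fluctuations sum to zero exactly.
#'
#' @inheritParams decompose_modes
#' @return list with `y` (centred positions at t) and `dv` (N x 3).
#' @export
subtract_translation <- function(x0, x1, fps = 1) {
  if (nrow(as.matrix(x0)) < 2L)
    swarm_stop("translation subtraction needs N >= 2",
               "swarm_degenerate_error")
  y0 <- sweep(as.matrix(x0), 2L, colMeans(x0))
  y1 <- sweep(as.matrix(x1), 2L, colMeans(x1))
  list(y = y0, dv = (y1 - y0) * fps)
}

#' Optimal proper rotation between two centred configurations
#'
#' Least-squares superposition: the proper orthogonal matrix R minimizing
#' `sum_i |y1_i - R y0_i|^2`, computed from the SVD of the cross-covariance
#' with the usual determinant correction so reflections are excluded. The
#' rotation axis is the invariant unit vector with sign fixed so the
#' rotation angle about it is non-negative.
#'
#' @param y0,y1 N x 3 matrices in the centre-of-mass frame, N >= 3,
#'   non-collinear.
#' @return list with `rotation` (3 x 3), `axis` (unit vector), `angle`
#'   (radians, >= 0).
#' @export
fit_rotation <- function(y0, y1) {
  y0 <- as.matrix(y0); y1 <- as.matrix(y1)
  if (nrow(y0) < 3L)
    swarm_stop("rotation fit needs N >= 3", "swarm_degenerate_error")
  sv <- svd(y0)$d
  if (sv[2] <= 1e-12 * max(sv[1], .Machine$double.eps))
    swarm_stop("rotation fit is rank deficient (collinear configuration)",
               "swarm_rank_error")
  m <- crossprod(y0, y1)                     # sum_i y0_i y1_i^T
  s <- svd(m)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- sum(diag(rot))
  angle <- acos(max(-1, min(1, (tr - 1) / 2)))
  if (angle < 1e-12) {
    axis <- c(0, 0, 1)                       # undefined axis at zero angle
  } else if (pi - angle < 1e-6) {
    # near 180 degrees the skew part vanishes; use the symmetric part
    b <- (rot + diag(3)) / 2
    axis <- sqrt(pmax(diag(b), 0))
    k <- which.max(axis)
    axis <- b[, k] / axis[k]
    axis <- axis / sqrt(sum(axis^2))
  } else {
    axis <- c(rot[3, 2] - rot[2, 3], rot[1, 3] - rot[3, 1],
              rot[2, 1] - rot[1, 2]) / (2 * sin(angle))
  }
  list(rotation = rot, axis = axis, angle = angle)
}

#' Optimal uniform dilatation
#'
#' The scalar minimizing `sum_i |y1_i - alpha * y0_i|^2`; closed form
#' `alpha = sum(y0 . y1) / sum(|y0|^2)`. `alpha > 1` is expansion,
#' `alpha < 1` contraction.
#'
#' @param y0 N x 3 centred (and typically rotation-aligned) configuration.
#' @param y1 N x 3 centred configuration at the next frame.
#' @return scalar `alpha`.
#' @export
fit_dilatation <- function(y0, y1) {
  denom <- sum(y0^2)
  if (denom <= 0)
    swarm_stop("dilatation undefined: all reference positions are zero",
               "swarm_degenerate_error")
  sum(y0 * y1) / denom
}

#' Order parameters of a frame pair
#'
#' Three scalars summarizing global order:
#' * polarization `Phi = |(1/N) sum_i v_i/|v_i||` in `[0,1]` — alignment of
#'   directions of motion (1 = all parallel, ~1/sqrt(N) = uncorrelated);
#' * rotational order `R = |(1/N) sum_i m_i|` where
#'   `m_i = (L_i . K)/|L_i|`, `L_i = y_perp,i x dv_i` is the angular
#'   momentum of the translation-subtracted fluctuation about the optimal
#'   rotation axis `K` and `y_perp,i` the position component orthogonal to
#'   `K`; coherent rotation gives 1, incoherent ~0;
#' * dilatational order `Lambda = (1/N) sum_i cos(dv_rot,i, y_i)` in
#'   `[-1,1]`, computed from the rotation-subtracted fluctuation; +1 for a
#'   coherent expansion, -1 for a coherent contraction.
#'
#' Individuals with zero speed (for `Phi`) or zero-norm factors (for `R`,
#' `Lambda`) are excluded from the affected sums; the number excluded is
#' reported. Frames with N < 4 return `NA` for `R` and `Lambda` (the
#' rotation fit is too poorly constrained to define an axis).
#'
#' @inheritParams decompose_modes
#' @return list of class `order_parameters`: `polarization`, `rotational`,
#'   `dilatational`, `n`, `n_excluded`.
#' @export
order_parameters <- function(x0, x1, fps = 1) {
  x0 <- as.matrix(x0); x1 <- as.matrix(x1)
  n <- nrow(x0)
  if (n < 2L)
    swarm_stop("order parameters need N >= 2", "swarm_degenerate_error")
  v <- (x1 - x0) * fps
  speed <- sqrt(rowSums(v^2))
  ok <- speed > 0
  n_excluded <- sum(!ok)
  if (n_excluded > 0)
    swarm_warn(sprintf("%d zero-speed individuals excluded from polarization",
                       n_excluded))
  pol <- if (any(ok))
    sqrt(sum(colMeans(v[ok, , drop = FALSE] / speed[ok])^2)) else NA_real_

  rotational <- dilatational <- NA_real_
  if (n >= 4L) {
    dec <- tryCatch(decompose_modes(x0, x1, fps), swarmcorr_error = identity)
    if (!inherits(dec, "error")) {
      k <- dec$rotation_axis
      y <- dec$y
      y_perp <- y - outer(drop(y %*% k), k)
      l <- cbind(y_perp[, 2] * dec$dv[, 3] - y_perp[, 3] * dec$dv[, 2],
                 y_perp[, 3] * dec$dv[, 1] - y_perp[, 1] * dec$dv[, 3],
                 y_perp[, 1] * dec$dv[, 2] - y_perp[, 2] * dec$dv[, 1])
      lnorm <- sqrt(rowSums(l^2))
      use <- lnorm > 0
      if (any(use))
        rotational <- abs(mean(drop(l[use, , drop = FALSE] %*% k) /
                                 lnorm[use]))
      dnorm <- sqrt(rowSums(dec$dv_rot^2)) * sqrt(rowSums(y^2))
      use <- dnorm > 0
      if (any(use))
        dilatational <- mean(rowSums(dec$dv_rot * y)[use] / dnorm[use])
      n_excluded <- n_excluded + sum(!use)
    }
  }
  structure(list(polarization = pol, rotational = rotational,
                 dilatational = dilatational, n = n,
                 n_excluded = n_excluded),
            class = "order_parameters")
}

#' Null band of the order parameters for an uncorrelated group
#'
#' Monte-Carlo reference: N independent individuals with uniformly random
#' unit velocities (and uniformly random positions in a ball, for the
#' rotational and dilatational parameters) have small but non-zero order
#' parameters, e.g. `E[Phi] ~ sqrt(8/(3 pi N))`. The band (mean and sd per
#' parameter) is what a measured time series must exceed before any claim
#' of collective order.
#'
#' @param n group size, >= 2.
#' @param n_samples Monte-Carlo draws.
#' @param seed RNG seed.
#' @return data.frame with rows `polarization`, `rotational`,
#'   `dilatational` and columns `mean`, `sd`.
#' @export
null_band <- function(n, n_samples = 200, seed = 1) {
  if (n < 2L || n_samples < 2L)
    swarm_stop("null_band needs n >= 2 and n_samples >= 2",
               "swarm_degenerate_error")
  set.seed(seed)
  draws <- matrix(NA_real_, n_samples, 3L)
  for (s in seq_len(n_samples)) {
    x0 <- runif_ball(n, radius = 1)
    u <- random_unit_vectors(n)
    op <- suppressWarnings(order_parameters(x0, x0 + 0.05 * u, fps = 1))
    draws[s, ] <- c(op$polarization, op$rotational, op$dilatational)
  }
  data.frame(
    row.names = c("polarization", "rotational", "dilatational"),
    mean = colMeans(draws, na.rm = TRUE),
    sd = apply(draws, 2L, stats::sd, na.rm = TRUE))
}

# Uniform points in a ball of given radius.
runif_ball <- function(n, radius = 1) {
  u <- random_unit_vectors(n)
  r <- radius * stats::runif(n)^(1 / 3)
  u * r
}

# Isotropic random unit vectors (rows).
random_unit_vectors <- function(n) {
  g <- matrix(stats::rnorm(3L * n), n, 3L)
  g / sqrt(rowSums(g^2))
}
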