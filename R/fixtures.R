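#' Frame pair with planted collective modes
#'
#' Ground-truth generator for the mode decomposition: positions uniform in
#' a ball; the second frame applies a known translation, rotation and
#' uniform dilatation to the first, plus iid Gaussian residual velocities
#' re-centred to sum zero. With zero noise the decomposition must recover
#' the planted modes to machine precision.
#'
#' @param n individuals (>= 4 recommended).
#' @param radius ball radius (m).
#' @param v_cm planted centre-of-mass velocity (m/s, length 3).
#' @param angle planted rotation angle (radians).
#' @param axis planted rotation axis (length 3, any norm).
#' @param alpha planted dilatation factor per frame step.
#' @param noise_sd residual velocity noise sd (m/s).
#' @param fps frame rate.
#' @param seed RNG seed.
#' @return list with `x0`, `x1`, `fps` and `truth`
#'   (`v_cm`, `angle`, `axis`, `alpha`).
#' @export
planted_mode_swarm <- function(n = 50, radius = 1, v_cm = c(0, 0, 0),
                               angle = 0, axis = c(0, 0, 1), alpha = 1,
                               noise_sd = 0, fps = 1, seed = 1) {
  set.seed(seed)
  y0 <- runif_ball(n, radius)
  y0 <- sweep(y0, 2L, colMeans(y0))          # centre of mass exactly at 0
  rot <- rotation_matrix(axis, angle)
  noise <- matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
  noise <- sweep(noise, 2L, colMeans(noise)) # residuals sum to zero
  x0 <- y0
  x1 <- sweep(alpha * (y0 %*% t(rot)) + noise / fps, 2L, v_cm / fps, `+`)
  rownames(x0) <- rownames(x1) <- as.character(seq_len(n))
  list(x0 = x0, x1 = x1, fps = fps,
       truth = list(v_cm = v_cm, angle = angle,
                    axis = axis / sqrt(sum(axis^2)), alpha = alpha))
}

#' Rotation matrix from axis and angle (Rodrigues form)
#'
#' @param axis length-3 vector (any norm).
#' @param angle rotation angle in radians.
#' @return 3 x 3 proper orthogonal matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * kx + (1 - cos(angle)) * (kx %*% kx)
}

#' Frame with a direction-fluctuation field of planted correlation length
#'
#' Builds a spatially correlated dimensionless fluctuation field by
#' assigning one common random unit vector to spatial blobs of radius
#' about `L` (points share the vector of their nearest blob seed), adding
#' isotropic noise, then enforcing `sum phi = 0` and the normalization
#' `(1/N) sum phi.phi = 1`, exactly as the estimators assume.
#'
#' @param n individuals.
#' @param radius ball radius of the group (m).
#' @param L planted correlation length (m), < group diameter.
#' @param noise_sd isotropic noise added to the blob vectors.
#' @param seed RNG seed.
#' @return list with `positions`, `phi`, `L`.
#' @export
correlated_swarm <- function(n = 200, radius = 1, L = 0.3, noise_sd = 0.25,
                             seed = 1) {
  if (L >= 2 * radius)
    swarm_stop("planted correlation length must be below the group diameter",
               "swarm_integrity_error")
  set.seed(seed)
  positions <- runif_ball(n, radius)
  phi <- correlated_field(positions, radius, L, noise_sd)
  list(positions = positions, phi = phi, L = L)
}

# Blob-based correlated unit field on given positions: the group is
# partitioned into spatial blobs of radius ~L (k-means on the positions,
# k chosen so blobs tile the ball at scale L), each blob shares one random
# unit vector, isotropic noise is added, and the field is re-centred and
# normalized to (1/N) sum phi.phi = 1. Consumes the active RNG stream.
correlated_field <- function(positions, radius, L, noise_sd) {
  n <- nrow(positions)
  k <- max(2L, ceiling((2 * radius / max(L, 1e-9))^3 / 8))
  cl <- stats::kmeans(positions, centers = min(k, n - 1L),
                      nstart = 5, iter.max = 20)$cluster
  blob_dir <- random_unit_vectors(max(cl))
  phi <- blob_dir[cl, , drop = FALSE] +
    matrix(stats::rnorm(3 * n, sd = noise_sd), n, 3)
  phi <- sweep(phi, 2L, colMeans(phi))
  phi / sqrt(mean(rowSums(phi^2)))
}

#' Uniform (Poisson) point set at a given density
#'
#' @param n number of points.
#' @param density points per unit volume; the cube side is
#'   `(n / density)^(1/3)`.
#' @param seed RNG seed.
#' @return N x 3 position matrix.
#' @export
poisson_swarm <- function(n, density, seed = 1) {
  if (density <= 0) swarm_stop("density must be positive",
                               "swarm_integrity_error")
  set.seed(seed)
  side <- (n / density)^(1 / 3)
  matrix(stats::runif(3 * n, 0, side), n, 3)
}

#' Multi-frame trajectory with persistent correlated fluctuations
#'
#' Builds a `swarm_trajectory` whose consecutive-frame displacement field
#' is a correlated fluctuation field (plus collective drift), so the whole
#' pipeline — velocities, mode subtraction, correlation, susceptibility,
#' percolation — can run on a field-format input with known structure.
#'
#' @inheritParams correlated_swarm
#' @param n_frames number of frames.
#' @param speed fluctuation speed scale (m/s).
#' @param fps frame rate.
#' @param body_length body length metadata (m).
#' @param event_id,species_label metadata.
#' @return A [swarm_trajectory()].
#' @export
correlated_trajectory <- function(n = 100, n_frames = 6, radius = 1,
                                  L = 0.4, noise_sd = 0.25, speed = 0.05,
                                  fps = 10, body_length = 0.002,
                                  event_id = "fixture", species_label = "",
                                  seed = 1) {
  set.seed(seed)
  x <- runif_ball(n, radius)
  rownames(x) <- as.character(seq_len(n))
  frames <- vector("list", n_frames)
  frames[[1]] <- swarm_frame(0L, x)
  for (t in seq_len(n_frames - 1L)) {
    phi <- correlated_field(x, radius, L, noise_sd)
    x <- x + speed * phi / fps
    rownames(x) <- as.character(seq_len(n))
    frames[[t + 1L]] <- swarm_frame(t, x)
  }
  swarm_trajectory(frames, fps = fps, body_length = body_length,
                   species_label = species_label, event_id = event_id)
}
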