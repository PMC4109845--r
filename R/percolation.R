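#' Largest-cluster fraction at linking scale lambda
#'
#' Links every pair of points closer than `lam` (strict inequality) and
#' returns the fraction of points in the largest connected component,
#' computed with a union-find structure. As `lam` grows past the
#' percolation threshold a giant cluster spanning the group appears.
#'
#' @param positions N x 3 matrix, N >= 2.
#' @param lam linking scale (same units as positions), > 0.
#' @return fraction in `[1/N, 1]`.
#' @export
cluster_fraction <- function(positions, lam) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2L) swarm_stop("cluster fraction needs N >= 2",
                         "swarm_degenerate_error")
  if (!is.finite(lam) || lam <= 0)
    swarm_stop("lam must be positive", "swarm_integrity_error")
  d <- as.vector(stats::dist(positions))
  pair_i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- sequence((n - 1L):1L) + rep.int(seq_len(n - 1L), (n - 1L):1L)
  sel <- d < lam
  uf_largest_component(n, pair_i[sel], pair_j[sel]) / n
}

# Union-find (path halving + union by size); returns the largest
# component size after all unions. Plain loops, no closures, for speed.
uf_largest_component <- function(n, from, to) {
  parent <- seq_len(n)
  size <- rep.int(1L, n)
  best <- 1L
  for (e in seq_along(from)) {
    a <- from[e]
    while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
    b <- to[e]
    while (parent[b] != b) { parent[b] <- parent[parent[b]]; b <- parent[b] }
    if (a != b) {
      if (size[a] < size[b]) { tmp <- a; a <- b; b <- tmp }
      parent[b] <- a
      size[a] <- size[a] + size[b]
      if (size[a] > best) best <- size[a]
    }
  }
  best
}

# The largest-cluster fraction as a function of lambda is a step function
# with jumps only at pairwise distances: one sorted union-find sweep gives
# the whole curve. Returns sorted edge distances and the fraction attained
# once all edges with d <= dist[k] are linked; n(lambda) with the strict
# r_ij < lambda rule is then fractions[ findInterval(lambda - , dist) ].
percolation_step_function <- function(positions) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  d <- as.vector(stats::dist(positions))
  pair_i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- sequence((n - 1L):1L) + rep.int(seq_len(n - 1L), (n - 1L):1L)
  ord <- order(d)
  from <- pair_i[ord]; to <- pair_j[ord]
  parent <- seq_len(n)
  size <- rep.int(1L, n)
  best <- 1L
  frac <- numeric(length(ord))
  for (e in seq_along(ord)) {
    a <- from[e]
    while (parent[a] != a) { parent[a] <- parent[parent[a]]; a <- parent[a] }
    b <- to[e]
    while (parent[b] != b) { parent[b] <- parent[parent[b]]; b <- parent[b] }
    if (a != b) {
      if (size[a] < size[b]) { tmp <- a; a <- b; b <- tmp }
      parent[b] <- a
      size[a] <- size[a] + size[b]
      if (size[a] > best) best <- size[a]
    }
    frac[e] <- best / n
  }
  list(dist = d[ord], frac = frac, n = n)
}

# n(lambda) lookups against the precomputed step function (strict < rule).
step_fraction <- function(sf, lambda) {
  k <- findInterval(lambda, sf$dist, left.open = TRUE)
  # left.open: counts dist < lambda when lambda coincides with a jump
  ifelse(k > 0, sf$frac[pmax(k, 1L)], 1 / sf$n)
}

#' Percolation threshold of a spatial point set
#'
#' The smallest linking scale at which the largest cluster reaches a
#' fraction `theta` of the group (formation of a giant cluster). Located
#' on a grid of scales and refined by bisection between the straddling
#' grid points to a relative tolerance of `tol`. Because the percolation
#' transition is sharp, the threshold depends only weakly on `theta`.
#'
#' @inheritParams cluster_fraction
#' @param theta giant-cluster fraction defining the threshold (default
#'   0.6).
#' @param lambda_grid scales to probe; default 40 values spanning the
#'   min-max pair distances.
#' @param tol relative bisection tolerance.
#' @return Object of class `percolation_curve`: `lambdas`, `fractions`
#'   (both over the probe grid), `threshold` (lambda_c),
#'   `threshold_fraction` (theta).
#' @export
percolation_threshold <- function(positions, theta = 0.6,
                                  lambda_grid = NULL, tol = 1e-3) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2L) swarm_stop("percolation needs N >= 2", "swarm_degenerate_error")
  if (theta <= 0 || theta > 1)
    swarm_stop("theta must be in (0, 1]", "swarm_integrity_error")
  sf <- percolation_step_function(positions)
  dmin <- sf$dist[1]; dmax <- sf$dist[length(sf$dist)]
  if (is.null(lambda_grid))
    lambda_grid <- seq(dmin, dmax * (1 + 1e-9), length.out = 40L)
  fractions <- step_fraction(sf, lambda_grid)
  hit <- which(fractions >= theta)
  if (!length(hit)) {
    lo <- lambda_grid[length(lambda_grid)]
    hi <- dmax * (1 + 10 * tol)
    if (step_fraction(sf, hi) < theta)
      swarm_stop("no giant cluster below the probe range",
                 "swarm_no_threshold_error")
  } else if (hit[1] == 1L) {
    lo <- dmin / 2
    hi <- lambda_grid[1]
  } else {
    lo <- lambda_grid[hit[1] - 1L]
    hi <- lambda_grid[hit[1]]
  }
  while ((hi - lo) / hi > tol) {
    mid <- (hi + lo) / 2
    if (step_fraction(sf, mid) >= theta) hi <- mid else lo <- mid
  }
  structure(list(lambdas = lambda_grid, fractions = fractions,
                 threshold = hi, threshold_fraction = theta),
            class = "percolation_curve")
}

#' Scaling of the percolation threshold with nearest-neighbour distance
#'
#' Across swarming events the percolation threshold is proportional to the
#' nearest-neighbour distance; the through-origin least-squares slope
#' `s = lambda_c / r1` is the dimensionless constant that converts the
#' nearest-neighbour distance at the ordering transition into an
#' interaction range. The confidence interval is a bootstrap over events.
#'
#' @param events data.frame with columns `r1` and `lambda_c`, >= 3 rows.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param level confidence level.
#' @return list with `slope`, `ci` (length 2), `se`, `n_events`.
#' @export
threshold_scaling <- function(events, n_boot = 1000, seed = 1, level = 0.95) {
  if (nrow(events) < 3L)
    swarm_stop("threshold scaling needs >= 3 events",
               "swarm_insufficient_data")
  slope_of <- function(df) sum(df$r1 * df$lambda_c) / sum(df$r1^2)
  slope <- slope_of(events)
  set.seed(seed)
  boot <- replicate(n_boot, {
    idx <- sample.int(nrow(events), replace = TRUE)
    slope_of(events[idx, , drop = FALSE])
  })
  alpha <- (1 - level) / 2
  list(slope = slope,
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       se = stats::sd(boot), n_events = nrow(events))
}
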