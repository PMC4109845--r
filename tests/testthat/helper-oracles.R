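# Independent brute-force oracles used across test files. These are kept
# deliberately naive (double loops, dense grids) and independent of the
# package's own code paths.

# O(N^2) binned connected correlation: mean of phi_i . phi_j over unordered
# pairs whose distance falls in each contiguous bin of width bw from 0.
oracle_binned_correlation <- function(phi, positions, bw) {
  n <- nrow(positions)
  nbins <- 0L
  sums <- counts <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((positions[i, ] - positions[j, ])^2))
      b <- max(1L, ceiling(d / bw))
      if (b > nbins) {
        sums <- c(sums, numeric(b - nbins))
        counts <- c(counts, numeric(b - nbins))
        nbins <- b
      }
      sums[b] <- sums[b] + sum(phi[i, ] * phi[j, ])
      counts[b] <- counts[b] + 1
    }
  }
  list(values = ifelse(counts > 0, sums / counts, NA_real_), counts = counts)
}

# Exhaustive nearest-neighbour distance.
oracle_r1 <- function(positions) {
  n <- nrow(positions)
  mean(vapply(seq_len(n), function(i) {
    min(vapply(setdiff(seq_len(n), i), function(j)
      sqrt(sum((positions[i, ] - positions[j, ])^2)), numeric(1)))
  }, numeric(1)))
}

# Largest connected component fraction by breadth-first search over the
# explicit adjacency matrix (links: distance strictly below lam).
oracle_cluster_fraction <- function(positions, lam) {
  n <- nrow(positions)
  adj <- as.matrix(stats::dist(positions)) < lam
  diag(adj) <- FALSE
  seen <- rep(FALSE, n)
  best <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; size <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; size <- size + 1L
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    best <- max(best, size)
  }
  best / n
}

# Coarse grid search over axis-angle space for the best proper rotation.
oracle_grid_rotation <- function(y0, y1, n_axis = 200, n_angle = 181) {
  set.seed(4321)
  g <- matrix(stats::rnorm(3 * n_axis), n_axis, 3)
  axes <- g / sqrt(rowSums(g^2))
  angles <- seq(0, pi, length.out = n_angle)
  best <- list(rss = Inf)
  for (a in seq_len(n_axis)) {
    for (th in angles) {
      r <- rotation_matrix(axes[a, ], th)
      rss <- sum((y1 - y0 %*% t(r))^2)
      if (rss < best$rss) best <- list(rss = rss, axis = axes[a, ], angle = th)
    }
  }
  best
}

# Golden-section minimization of the dilatation objective.
oracle_golden_dilatation <- function(y0, y1, lo = -10, hi = 10,
                                     tol = 1e-10) {
  f <- function(a) sum((y1 - a * y0)^2)
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  while (b - a > tol) {
    if (f(c1) < f(c2)) { b <- c2 } else { a <- c1 }
    c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  }
  (a + b) / 2
}

# Small well-formed trajectory table on disk; returns the path.
write_demo_trajectory <- function(path, n_frames = 2, n = 3) {
  rows <- expand.grid(frame = seq_len(n_frames) - 1L, id = seq_len(n))
  rows$x <- rows$frame * 0.1 + rows$id
  rows$y <- rows$id * 2
  rows$z <- 0.5
  utils::write.csv(rows[order(rows$frame, rows$id), ], path,
                   row.names = FALSE, quote = FALSE)
  path
}

# Decomposition + order parameters for one frame pair (test convenience).
frame_pair_stats_for_test <- function(x0, x1, fps = 1) {
  list(dec = decompose_modes(x0, x1, fps),
       order = suppressWarnings(order_parameters(x0, x1, fps)))
}
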