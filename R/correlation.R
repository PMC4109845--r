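#' Connected correlation function C(r)
#'
#' Measures how much the (dimensionless) velocity fluctuation of one
#' individual is aligned with that of another at distance r:
#' `C(r) = sum_{i != j} phi_i . phi_j 1(r_ij in bin) / sum_{i != j}
#' 1(r_ij in bin)`, with self-pairs excluded. Because the fluctuations are
#' normalized so that `(1/N) sum phi.phi = 1` and sum to zero, C needs no
#' further normalization and is comparable across swarms and models.
#'
#' @param phi N x 3 matrix of dimensionless velocity fluctuations
#'   (see [decompose_modes()]).
#' @param positions N x 3 position matrix for the same individuals.
#' @param bin_width spatial bin width `delta r`; default
#'   (max pair distance)/50.
#' @return Object of class `correlation_curve`: `bin_centers`, `values`
#'   (`NA` on empty bins), `pair_counts`, `bin_width`, `r0` (first zero,
#'   filled by [correlation_length()]).
#' @export
connected_correlation <- function(phi, positions, bin_width = NULL) {
  phi <- as.matrix(phi); positions <- as.matrix(positions)
  n <- nrow(phi)
  if (n < 2L)
    swarm_stop("correlation needs N >= 2", "swarm_degenerate_error")
  d <- as.vector(stats::dist(positions))
  dots <- tcrossprod(phi)[lower.tri(matrix(0, n, n))]
  curve <- bin_pair_samples(d, dots, bin_width)
  curve$r0 <- correlation_length(curve)
  curve
}

#' Correlation curve from precomputed pairwise samples
#'
#' Same estimator as [connected_correlation()], starting from rows of
#' (pair distance, scalar product) as read by [read_pairwise()] — e.g. the
#' published per-pair supplementary data for one frame of a swarm.
#'
#' @param samples data.frame with columns `distance`, `dot`.
#' @inheritParams connected_correlation
#' @return A `correlation_curve` (empty input gives an empty curve).
#' @export
correlation_from_pairwise <- function(samples, bin_width = NULL) {
  if (nrow(samples) == 0L) {
    curve <- structure(list(bin_centers = numeric(0), values = numeric(0),
                            pair_counts = integer(0), bin_width = NA_real_,
                            r0 = NA_real_),
                       class = "correlation_curve")
    return(curve)
  }
  curve <- bin_pair_samples(samples$distance, samples$dot, bin_width)
  curve$r0 <- correlation_length(curve)
  curve
}

# Shared binned estimator: contiguous bins from 0 of width bin_width; the
# value in each bin is the mean scalar product over pairs falling in it,
# and empty bins are NA (absent), never zero.
bin_pair_samples <- function(d, dots, bin_width = NULL) {
  if (is.null(bin_width)) bin_width <- max(d) / 50
  if (!is.finite(bin_width) || bin_width <= 0)
    swarm_stop("bin_width must be positive", "swarm_integrity_error")
  nbins <- max(1L, ceiling(max(d) / bin_width + 1e-12))
  idx <- pmin(pmax(1L, ceiling(d / bin_width)), nbins)
  idx[d == 0] <- 1L
  counts <- tabulate(idx, nbins)
  sums <- vapply(seq_len(nbins), function(b) sum(dots[idx == b]), numeric(1))
  values <- ifelse(counts > 0, sums / counts, NA_real_)
  structure(list(bin_centers = (seq_len(nbins) - 0.5) * bin_width,
                 values = values, pair_counts = counts,
                 bin_width = bin_width, r0 = NA_real_),
            class = "correlation_curve")
}

#' Correlation length r0: first zero of C(r)
#'
#' The smallest distance where the correlation curve crosses zero, located
#' by linear interpolation between the straddling populated bins. If the
#' first populated bin is already non-positive, r0 is that bin's lower
#' edge; if the curve never changes sign, r0 is `NA`.
#'
#' @param curve a `correlation_curve` with >= 2 populated bins.
#' @return r0 in metres, or `NA_real_` when no crossing exists.
#' @export
correlation_length <- function(curve) {
  pop <- which(!is.na(curve$values))
  if (length(pop) < 2L) return(NA_real_)
  v <- curve$values[pop]
  r <- curve$bin_centers[pop]
  if (v[1] <= 0) return(r[1] - curve$bin_width / 2)
  for (k in seq_len(length(v) - 1L)) {
    if (v[k] > 0 && v[k + 1L] <= 0) {
      if (v[k + 1L] == 0) return(r[k + 1L])
      return(r[k] + v[k] / (v[k] - v[k + 1L]) * (r[k + 1L] - r[k]))
    }
  }
  NA_real_
}

#' Cumulative correlation Q(r) and susceptibility chi
#'
#' `Q(r) = (1/N) sum_{i != j} phi_i . phi_j theta(r - r_ij)` integrates the
#' correlation up to scale r; its maximum over r is the susceptibility
#' `chi`, the total amount of correlation in the system (in the equilibrium
#' analogy, the response to an external perturbation). Because `sum phi = 0`
#' and `(1/N) sum |phi|^2 = 1`, `Q` evaluated beyond the largest pair
#' distance equals exactly -1 for every frame — a built-in self check.
#'
#' @inheritParams connected_correlation
#' @param grid radii at which to evaluate Q; default the bin edges of the
#'   default C(r) binning, so the maximum of Q and the zero of C can be
#'   compared on the same grid.
#' @return Object of class `susceptibility_result`: `grid`, `q`, `chi`,
#'   `argmax_r`, `q_inf`.
#' @export
susceptibility <- function(phi, positions, grid = NULL, bin_width = NULL) {
  phi <- as.matrix(phi); positions <- as.matrix(positions)
  n <- nrow(phi)
  if (n < 2L)
    swarm_stop("susceptibility needs N >= 2", "swarm_degenerate_error")
  d <- as.vector(stats::dist(positions))
  dots <- tcrossprod(phi)[lower.tri(matrix(0, n, n))]
  if (is.null(grid)) {
    if (is.null(bin_width)) bin_width <- max(d) / 50
    grid <- seq(0, max(d) + bin_width, by = bin_width)
  }
  ord <- order(d)
  dcum <- cumsum(dots[ord])
  # theta(r - r_ij) with theta(0) = 1: count pairs with r_ij <= r
  kmax <- findInterval(grid, d[ord])
  q <- (2 / n) * ifelse(kmax > 0, dcum[pmax(kmax, 1L)], 0)
  q[kmax == 0] <- 0
  chi <- max(q)
  structure(list(grid = grid, q = q, chi = chi,
                 argmax_r = grid[which.max(q)],
                 q_inf = (2 / n) * dcum[length(dcum)]),
            class = "susceptibility_result")
}

# Single shared analysis path for one frame pair: decomposition ->
# dimensionless fluctuations -> C(r), r0 -> Q, chi. Used identically for
# field-format trajectories and for simulator output.
frame_pair_stats <- function(x0, x1, fps = 1, bin_width = NULL) {
  dec <- decompose_modes(x0, x1, fps)
  if (anyNA(dec$phi))
    swarm_stop("zero residual fluctuation field: phi undefined",
               "swarm_degenerate_error")
  curve <- connected_correlation(dec$phi, dec$y, bin_width)
  sus <- susceptibility(dec$phi, dec$y, bin_width = bin_width)
  op <- suppressWarnings(order_parameters(x0, x1, fps))
  list(decomposition = dec, curve = curve, susceptibility = sus,
       order = op, chi = sus$chi, r0 = curve$r0,
       r1 = nearest_neighbour_distance(x0))
}

# Shared driver over a list of frame pairs (see traj_frame_pairs /
# run_frame_pairs); frames failing the decomposition are skipped & counted.
analyze_frame_pairs <- function(pairs, bin_width = NULL) {
  rows <- list(); skipped <- 0L
  for (p in pairs) {
    st <- tryCatch(frame_pair_stats(p$x0, p$x1, p$fps, bin_width),
                   swarmcorr_error = function(e) NULL)
    if (is.null(st)) { skipped <- skipped + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      time_index = if (!is.null(p$time_index)) p$time_index else NA,
      n = nrow(p$x0), chi = st$chi, r0 = st$r0, r1 = st$r1,
      polarization = st$order$polarization,
      rotational = st$order$rotational,
      dilatational = st$order$dilatational,
      q_inf = st$susceptibility$q_inf)
  }
  per_frame <- if (length(rows)) do.call(rbind, rows) else
    data.frame(time_index = numeric(0), n = integer(0), chi = numeric(0),
               r0 = numeric(0), r1 = numeric(0), polarization = numeric(0),
               rotational = numeric(0), dilatational = numeric(0),
               q_inf = numeric(0))
  list(per_frame = per_frame, n_skipped = skipped)
}

#' Susceptibility time series over an acquisition
#'
#' Applies the full decomposition -> phi -> chi chain to every usable
#' consecutive frame pair and aggregates: the event-level susceptibility is
#' the time average of per-frame chi and its error bar the standard
#' deviation over frames.
#'
#' @param traj a [swarm_trajectory()] with >= 2 frames.
#' @param bin_width spatial bin width passed to the estimators.
#' @return Object of class `susceptibility_series`: `per_frame`
#'   (data.frame), `mean`, `sd`, `n_skipped`.
#' @export
susceptibility_timeseries <- function(traj, bin_width = NULL) {
  pairs <- traj_frame_pairs(traj)
  if (length(pairs) < 1L)
    swarm_stop("need at least 2 frames", "swarm_insufficient_data")
  res <- analyze_frame_pairs(pairs, bin_width)
  structure(list(per_frame = res$per_frame,
                 mean = mean(res$per_frame$chi),
                 sd = stats::sd(res$per_frame$chi),
                 n_skipped = res$n_skipped),
            class = "susceptibility_series")
}

#' All ordered-pair samples of one frame
#'
#' Expands a frame into the per-pair rows (distance, scalar product) used
#' by the pairwise file format: one row for each ordered pair i != j.
#'
#' @inheritParams connected_correlation
#' @return data.frame with columns `distance`, `dot`.
#' @export
pairwise_samples <- function(phi, positions) {
  n <- nrow(as.matrix(phi))
  dm <- as.matrix(stats::dist(positions))
  dots <- tcrossprod(as.matrix(phi))
  ij <- which(row(dm) != col(dm))
  data.frame(distance = dm[ij], dot = dots[ij])
}
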