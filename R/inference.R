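#' Spearman rank correlation with a permutation P-value
#'
#' Tests dependence between two paired variables without a noise model:
#' the observed Spearman coefficient `rho` (ties by average ranks) is
#' compared with its distribution under `m` random permutations of `y`.
#' The P-value is two-sided on `|rho|` with the small-sample correction,
#' `P = (1 + #{|rho_perm| >= |rho_obs|}) / (m + 1)`, so P is never zero
#' and is calibrated (uniform) under the exchangeable null.
#'
#' @param x,y paired numeric vectors, length >= 5.
#' @param m number of permutations, >= 100.
#' @param seed RNG seed.
#' @param perm_idx optional integer matrix (length(y) x m) of precomputed
#'   permutations; used to compare two tests on identical permutations.
#' @return Object of class `permutation_test`: `rho`, `p_value`, `m`,
#'   `seed`.
#' @export
permutation_pvalue <- function(x, y, m = 10000, seed = 1, perm_idx = NULL) {
  n <- length(x)
  if (n != length(y) || n < 5L)
    swarm_stop("need >= 5 complete pairs", "swarm_insufficient_data")
  if (m < 100L) swarm_stop("need m >= 100 permutations",
                           "swarm_insufficient_data")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    swarm_stop("Spearman rho undefined for a constant variable",
               "swarm_undefined_statistic")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (is.null(perm_idx)) {
    set.seed(seed)
    perm_idx <- replicate(m, sample.int(n))
  } else {
    m <- ncol(perm_idx)
  }
  # Pearson on ranks == Spearman with average ranks; linear in the
  # permuted ranks, so precompute the standardization once.
  zx <- (rx - mean(rx)) / stats::sd(rx)
  zy <- (ry - mean(ry)) / stats::sd(ry)
  rho_perm <- as.vector(crossprod(zx, matrix(zy[perm_idx], n))) / (n - 1)
  p <- (1 + sum(abs(rho_perm) >= abs(rho) - 1e-12)) / (m + 1)
  structure(list(rho = rho, p_value = p, m = m, seed = seed),
            class = "permutation_test")
}

#' Metric vs density scaling of the susceptibility
#'
#' If midges interact within a fixed metric range proportional to the body
#' length, the natural variable for the susceptibility is `r1 / BL`, not
#' `r1`: correlation of `chi` with the body-length-rescaled
#' nearest-neighbour distance should be stronger than with the raw one.
#' Both permutation tests use the same permutation set, so with constant
#' body length the two P-values coincide exactly.
#'
#' @param events data.frame with columns `r1`, `body_length`, `chi`;
#'   >= 5 rows.
#' @param m permutations per test.
#' @param seed RNG seed.
#' @return list with the two `permutation_test` objects `scaled`
#'   (chi vs r1/BL) and `raw` (chi vs r1).
#' @export
compare_scaling_variables <- function(events, m = 10000, seed = 1) {
  if (nrow(events) < 5L)
    swarm_stop("need >= 5 events", "swarm_insufficient_data")
  set.seed(seed)
  perm_idx <- replicate(m, sample.int(nrow(events)))
  list(scaled = permutation_pvalue(events$r1 / events$body_length,
                                   events$chi, perm_idx = perm_idx),
       raw = permutation_pvalue(events$r1, events$chi, perm_idx = perm_idx))
}

#' Fit the critical scaling law of the susceptibility
#'
#' On the disordered side of an ordering transition the susceptibility
#' follows `chi = a * (x - x_c)^(-gamma)` with `gamma > 0`. The fit is
#' least squares on `log chi` with the transition point profiled out: for
#' fixed `x_c` the model is linear in `(log a, gamma)`, and `x_c` is found
#' by 1D minimization of the profiled residual, then polished jointly with
#' a Levenberg-Marquardt pass. Confidence intervals are a bootstrap over
#' points, because with scattered data the nonlinear fit is unstable and a
#' single point estimate would be over-confident.
#'
#' Guards: the fit refuses data whose susceptibility is not significantly
#' *decreasing* in x (Spearman trend via [permutation_pvalue()]); this is
#' what keeps a non-interacting control from yielding a spurious
#' transition. It also refuses an `x_c` estimate at or above `min(x)`.
#'
#' @param x control variable (e.g. r1/BL or r1/rc), all on the disordered
#'   branch; length >= 6.
#' @param chi susceptibility values, > 0.
#' @param n_boot bootstrap replicates for the confidence intervals.
#' @param seed RNG seed.
#' @param require_trend require a significant decreasing trend (permutation
#'   P < `trend_alpha`) before fitting.
#' @param trend_alpha significance level of the trend guard.
#' @param level confidence level of the bootstrap intervals.
#' @return Object of class `scaling_fit`: `amplitude`, `x_c`, `gamma`,
#'   `ci` (3 x 2 matrix), `boot_se`, `residuals`, `n`.
#' @export
fit_critical_scaling <- function(x, chi, n_boot = 200, seed = 1,
                                 require_trend = TRUE, trend_alpha = 0.05,
                                 level = 0.95) {
  if (length(x) < 6L)
    swarm_stop("need >= 6 points", "swarm_insufficient_data")
  if (any(chi <= 0))
    swarm_stop("chi must be positive", "swarm_integrity_error")
  rho <- stats::cor(x, chi, method = "spearman")
  if (rho >= 0)
    swarm_stop("chi does not decrease with x: not on the disordered branch",
               "swarm_invalid_branch")
  if (require_trend) {
    tst <- permutation_pvalue(x, chi, m = 999, seed = seed)
    if (tst$p_value > trend_alpha)
      swarm_stop(sprintf(
        "no significant decreasing trend (permutation P = %.3f): transition not identifiable",
        tst$p_value), "swarm_non_identifiable")
  }
  fit <- scaling_fit_core(x, chi)
  if (!is.finite(fit$x_c) || fit$x_c >= min(x))
    swarm_stop("x_c estimate not below the fitted range: not identifiable",
               "swarm_non_identifiable")
  set.seed(seed)
  boot <- matrix(NA_real_, max(n_boot, 1L), 3L)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(length(x), replace = TRUE)
    if (length(unique(x[idx])) < 4L) next
    bf <- tryCatch(scaling_fit_core(x[idx], chi[idx]),
                   error = function(e) NULL)
    if (!is.null(bf) && is.finite(bf$x_c) && bf$x_c < min(x[idx]))
      boot[b, ] <- c(bf$a, bf$x_c, bf$gamma)
  }
  alpha <- (1 - level) / 2
  ci <- t(apply(boot, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE))
  dimnames(ci) <- list(c("amplitude", "x_c", "gamma"), c("lower", "upper"))
  res <- log(chi) - (log(fit$a) - fit$gamma * log(x - fit$x_c))
  structure(list(amplitude = fit$a, x_c = fit$x_c, gamma = fit$gamma,
                 ci = ci,
                 boot_se = apply(boot, 2L, stats::sd, na.rm = TRUE),
                 residuals = res, n = length(x)),
            class = "scaling_fit")
}

# Profile fit on log chi: inner linear LS in (log a, gamma) at fixed x_c,
# outer 1D minimization, then a Levenberg-Marquardt polish.
scaling_fit_core <- function(x, chi) {
  lx_min <- min(x)
  span <- max(diff(range(x)), 1e-8 * abs(lx_min), .Machine$double.eps)
  lchi <- log(chi)
  prof_rss <- function(xc) {
    lf <- log(x - xc)
    f <- stats::lm.fit(cbind(1, lf), lchi)
    sum(f$residuals^2)
  }
  lower <- lx_min - 20 * span
  upper <- lx_min - 1e-9 * span
  # multi-start: coarse grid, then local refinement around the best cell
  grid <- seq(lower, upper, length.out = 60L)
  vals <- vapply(grid, prof_rss, numeric(1))
  k <- which.min(vals)
  o <- stats::optimize(prof_rss,
                       interval = c(grid[max(1L, k - 1L)],
                                    grid[min(length(grid), k + 1L)]),
                       tol = 1e-12)
  xc <- o$minimum
  f <- stats::lm.fit(cbind(1, log(x - xc)), lchi)
  a <- exp(unname(f$coefficients[1])); gam <- -unname(f$coefficients[2])
  # nlsLM probes parameter values where log(x - xc) is undefined while it
  # converges; those NaN warnings are expected and uninformative
  polished <- tryCatch(suppressWarnings({
    nf <- minpack.lm::nlsLM(
      lchi ~ la - g * log(x - xc),
      start = list(la = log(a), g = gam, xc = xc),
      upper = c(la = Inf, g = Inf, xc = upper),
      lower = c(la = -Inf, g = 1e-12, xc = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(nf)
    list(a = unname(exp(cf[["la"]])), x_c = unname(cf[["xc"]]),
         gamma = unname(cf[["g"]]))
  }), error = function(e) NULL)
  if (!is.null(polished)) polished else list(a = a, x_c = xc, gamma = gam)
}

#' Combine the two transition estimates into an interaction range
#'
#' The critical fit of chi against `x = r1/BL` locates the ordering
#' transition at `r1_c = xc_bl * BL`; the percolation analysis says the
#' transition happens where the network at scale rc stops percolating,
#' `r1_c = rc / s` with `s = lambda_c / r1`. Eliminating `r1_c` gives the
#' metric interaction range in body lengths, `rc / BL = xc_bl * s`, with
#' the uncertainty propagated from both inputs by the delta method.
#'
#' @param xc_bl transition point in body-length units (> 0).
#' @param s percolation slope lambda_c / r1 (> 0).
#' @param xc_ci,s_ci optional length-2 confidence intervals for the two
#'   inputs (same level); treated as +/- 1.96 se.
#' @param level confidence level represented by the input intervals.
#' @return list with `rc_bl` and `ci`.
#' @export
estimate_interaction_range <- function(xc_bl, s, xc_ci = NULL, s_ci = NULL,
                                       level = 0.95) {
  if (!is.finite(xc_bl) || xc_bl <= 0 || !is.finite(s) || s <= 0)
    swarm_stop("xc_bl and s must be positive", "swarm_domain_error")
  rc_bl <- xc_bl * s
  z <- stats::qnorm(1 - (1 - level) / 2)
  se_xc <- if (is.null(xc_ci)) 0 else diff(range(xc_ci)) / (2 * z)
  se_s <- if (is.null(s_ci)) 0 else diff(range(s_ci)) / (2 * z)
  se <- sqrt(s^2 * se_xc^2 + xc_bl^2 * se_s^2)
  list(rc_bl = rc_bl, ci = c(rc_bl - z * se, rc_bl + z * se), se = se)
}
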