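#' Configuration for the 3D Vicsek model in a central potential
#'
#' Self-propelled particles at fixed speed `v0` align with every neighbour
#' within the metric radius `rc` (self included), are pulled towards the
#' origin by a harmonic force of strength `beta` (which also grants
#' cohesion, so boundaries are open), and are perturbed by a directional
#' noise: the updated direction is drawn uniformly from the spherical cap
#' of solid angle `4 pi eta` around the deterministic one. With `beta = 0`
#' the standard Vicsek model is recovered. The control parameter of the
#' ordering transition is `x = r1 / rc`, the nearest-neighbour distance in
#' units of the interaction radius; `beta` tunes it by setting the density.
#'
#' @param n particle count, >= 2.
#' @param v0 speed (length units per step).
#' @param rc interaction radius.
#' @param eta noise in `[0, 1]` (0 = deterministic, 1 = fully random).
#' @param beta central-force strength per step, >= 0.
#' @param steps sampled portion length in steps.
#' @param transient steps discarded before sampling.
#' @param sample_every sampling interval in steps (large enough that
#'   sampled fluctuations are uncorrelated in time).
#' @param n_samples number of sampled configurations.
#' @param init_radius radius of the initial uniform sphere.
#' @param use_cells use the cell-list neighbour search (exact; the
#'   brute-force path is for verification).
#' @param seed RNG seed.
#' @return list of class `vicsek_config`.
#' @export
vicsek_config <- function(n, v0 = 0.05, rc = 1, eta = 0.35, beta = 2e-4,
                          steps = 10000, transient = 5000,
                          sample_every = 100, n_samples = 100,
                          init_radius = NULL, use_cells = TRUE, seed = 1) {
  if (n < 2L) swarm_stop("Vicsek needs n >= 2", "swarm_integrity_error")
  if (rc <= 0 || v0 <= 0)
    swarm_stop("v0 and rc must be positive", "swarm_integrity_error")
  if (eta < 0 || eta > 1)
    swarm_stop("eta must be in [0, 1]", "swarm_integrity_error")
  if (beta < 0) swarm_stop("beta must be >= 0", "swarm_integrity_error")
  if (is.null(init_radius)) init_radius <- max(rc, sqrt(v0 / max(beta, 1e-12)))
  structure(list(n = as.integer(n), v0 = v0, rc = rc, eta = eta, beta = beta,
                 steps = as.integer(steps), transient = as.integer(transient),
                 sample_every = as.integer(sample_every),
                 n_samples = as.integer(n_samples),
                 init_radius = init_radius, use_cells = use_cells,
                 seed = seed),
            class = "vicsek_config")
}

#' Simulate the Vicsek model
#'
#' @param config a [vicsek_config()].
#' @param init optional list with `positions` and `velocities` matrices to
#'   start from (otherwise uniform sphere / uniform directions).
#' @return Object of class `simulation_run` with `config` and `samples`
#'   (list of `(x0, x1, fps = 1)` consecutive-step position pairs).
#' @export
simulate_vicsek <- function(config, init = NULL) {
  stopifnot(inherits(config, "vicsek_config"))
  set.seed(config$seed)
  samples <- vicsek_sim_cpp(
    config$n, config$v0, config$rc, config$eta, config$beta,
    config$steps, config$transient, config$sample_every, config$n_samples,
    config$init_radius, config$use_cells,
    if (is.null(init)) NULL else init$positions,
    if (is.null(init)) NULL else init$velocities)
  structure(list(config = config, samples = samples, model = "vicsek"),
            class = "simulation_run")
}

#' Scan the Vicsek model across the ordering transition
#'
#' Runs one simulation per control value (the central-force strength
#' `beta`, or the size `n`), and measures on the sampled configurations —
#' with the same estimators used on field data — the rescaled
#' nearest-neighbour distance `x = r1/rc`, the polarization and the
#' susceptibility. A stationarity flag tests for residual drift of r1 over
#' the sampling window.
#'
#' @param base a [vicsek_config()] used as template.
#' @param values numeric vector of control values.
#' @param vary which field the values set: `"beta"` or `"n"`.
#' @param bin_width passed to the correlation estimators.
#' @param keep_frames also return the per-sample statistics of every run
#'   (attribute `"frames"`), e.g. for frame-level susceptibility-vs-x
#'   scatter as measured on single configurations.
#' @return data.frame with one row per control value: `value`, `n`, `x`
#'   (mean r1/rc), `phi_mean`, `phi_sd`, `chi_mean`, `chi_sd`,
#'   `r1_mean`, `stationary`.
#' @export
scan_vicsek <- function(base, values, vary = c("beta", "n"),
                        bin_width = NULL, keep_frames = FALSE) {
  vary <- match.arg(vary)
  frames <- list()
  rows <- lapply(values, function(val) {
    cfg <- base
    cfg[[vary]] <- if (vary == "n") as.integer(val) else val
    cfg <- do.call(vicsek_config, cfg[setdiff(names(cfg), character(0))])
    run <- simulate_vicsek(cfg)
    res <- analyze_run(run, bin_width)
    pf <- res$per_frame
    if (keep_frames) {
      pf2 <- pf; pf2$value <- val; pf2$rc <- cfg$rc
      frames[[length(frames) + 1L]] <<- pf2
    }
    drift <- stats::cor.test(seq_len(nrow(pf)), pf$r1, method = "spearman",
                             exact = FALSE)
    data.frame(value = val, n = cfg$n, x = mean(pf$r1) / cfg$rc,
               phi_mean = mean(pf$polarization),
               phi_sd = stats::sd(pf$polarization),
               chi_mean = mean(pf$chi), chi_sd = stats::sd(pf$chi),
               r1_mean = mean(pf$r1),
               stationary = drift$p.value > 0.01)
  })
  out <- do.call(rbind, rows)
  if (keep_frames) attr(out, "frames") <- do.call(rbind, frames)
  out
}

#' Susceptibility peak location per system size (finite-size scaling)
#'
#' For each size, locates the maximum of the susceptibility over the scan
#' in `x = r1/rc` and its position. Plotted parametrically in `n`, the
#' curve `chi_max(x_max)` traces the critical scaling law without needing
#' to know the transition point in advance.
#'
#' @param scans named list (names = n) of scan tables from [scan_vicsek()].
#' @return data.frame with columns `n`, `x_max`, `chi_max`.
#' @export
finite_size_scaling <- function(scans) {
  rows <- lapply(names(scans), function(nm) {
    sc <- scans[[nm]]
    sc <- sc[order(sc$x), ]
    k <- which.max(sc$chi_mean)
    if (k == 1L || k == nrow(sc))
      swarm_stop(sprintf(
        "susceptibility peak at the scan boundary for n = %s: widen the scan",
        nm), "swarm_bracketing_error")
    data.frame(n = as.integer(nm), x_max = sc$x[k], chi_max = sc$chi_mean[k])
  })
  do.call(rbind, rows)
}
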