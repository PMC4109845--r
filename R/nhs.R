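#' Configuration for the Non-interacting Harmonic Swarm (NHS)
#'
#' The NHS is the null model for swarming without interaction: independent
#' particles performing a random walk in a three-dimensional harmonic
#' potential, `m dv = (-friction * v - spring_k * x) dt + sigma sqrt(dt) xi`
#' with `sigma = sqrt(2 * friction * temperature)` (fluctuation-dissipation
#' form, Boltzmann constant absorbed into `temperature`), so the stationary
#' positional variance per component is `temperature / spring_k`. The
#' default friction is the critically damped value `2 sqrt(mass spring_k)`,
#' the regime that looks most like a real swarm.
#'
#' @param n particle count.
#' @param mass particle mass (kg).
#' @param spring_k harmonic constant (kg/s^2).
#' @param friction drag coefficient (kg/s); default critically damped.
#' @param temperature noise strength (m^2 kg/s^2 scale).
#' @param dt integration step (s); must satisfy `friction * dt / mass < 2`.
#' @param steps sampled portion length, in integration steps.
#' @param transient steps discarded before sampling.
#' @param sample_every sampling interval in steps.
#' @param seed RNG seed.
#' @return list of class `nhs_config`.
#' @export
nhs_config <- function(n, mass = 1, spring_k = 1,
                       friction = 2 * sqrt(mass * spring_k),
                       temperature = 1,
                       dt = 0.01 * sqrt(mass / spring_k),
                       steps = 5000, transient = 2000,
                       sample_every = 10, seed = 1) {
  cfg <- list(n = n, mass = mass, spring_k = spring_k, friction = friction,
              temperature = temperature, dt = dt, steps = steps,
              transient = transient, sample_every = sample_every, seed = seed)
  vals <- unlist(cfg[c("n", "mass", "spring_k", "friction", "temperature",
                       "dt")])
  if (any(!is.finite(vals)) || any(vals <= 0))
    swarm_stop("all NHS physical parameters must be positive",
               "swarm_integrity_error")
  if (friction * dt / mass >= 2)
    swarm_stop("Euler step unstable: friction * dt / mass must be < 2",
               "swarm_stability_error")
  structure(cfg, class = "nhs_config")
}

#' Simulate the Non-interacting Harmonic Swarm
#'
#' Euler-Maruyama integration of the overdamped-to-underdamped Langevin
#' dynamics of [nhs_config()]. Sampled frames are stored as consecutive
#' position pairs one integration step apart, so the downstream velocity
#' and fluctuation estimators treat the simulation exactly as they treat
#' field trajectories (fps = 1/dt).
#'
#' @param config an [nhs_config()].
#' @param init optional N x 3 matrix of starting positions; by default
#'   positions are drawn from the stationary law (sd `sqrt(T/k)` per
#'   component).
#' @return Object of class `simulation_run` with `config` and `samples`,
#'   a list of `(x0, x1, fps)` frame pairs.
#' @export
simulate_nhs <- function(config, init = NULL) {
  stopifnot(inherits(config, "nhs_config"))
  set.seed(config$seed)
  n <- config$n; dt <- config$dt; m <- config$mass
  gam <- config$friction; k <- config$spring_k
  sig <- sqrt(2 * gam * config$temperature)
  sd_x0 <- sqrt(config$temperature / k)
  x <- if (is.null(init)) matrix(stats::rnorm(3 * n, sd = sd_x0), n, 3)
       else as.matrix(init)                  # default: start near stationarity
  v <- matrix(0, n, 3)
  total <- config$transient + config$steps
  samples <- list()
  for (step in seq_len(total)) {
    x_prev <- x
    noise <- matrix(stats::rnorm(3 * n), n, 3)
    v <- v + (dt / m) * (-gam * v - k * x) + (sig * sqrt(dt) / m) * noise
    x <- x + v * dt
    if (step > config$transient &&
        (step - config$transient) %% config$sample_every == 0L)
      samples[[length(samples) + 1L]] <-
        list(x0 = x_prev, x1 = x, fps = 1 / dt,
             time_index = step)
    if (!all(is.finite(x)))
      swarm_stop(sprintf("non-finite NHS state at step %d", step),
                 "swarm_numerical_error")
  }
  structure(list(config = config, samples = samples, model = "nhs"),
            class = "simulation_run")
}

# Frame pairs of a simulation run, in the shape the shared analysis
# drivers consume (same code path as field data).
run_frame_pairs <- function(run) {
  stopifnot(inherits(run, "simulation_run"))
  run$samples
}

#' Analyse a simulation run with the field-data estimators
#'
#' Runs the identical decomposition -> phi -> C(r) -> chi chain used for
#' field trajectories over every sampled frame pair of a simulation run.
#'
#' @param run a `simulation_run` from [simulate_nhs()] or
#'   [simulate_vicsek()].
#' @param bin_width spatial bin width for the correlation estimators.
#' @return list with `per_frame` (data.frame of per-sample statistics) and
#'   `n_skipped`.
#' @export
analyze_run <- function(run, bin_width = NULL) {
  analyze_frame_pairs(run_frame_pairs(run), bin_width)
}

#' Non-interacting susceptibility baseline
#'
#' The susceptibility of the NHS measured with the same estimator chain as
#' the data; the benchmark an interacting swarm must exceed. Extremely
#' small and density-independent by construction.
#'
#' @inheritParams simulate_nhs
#' @inheritParams analyze_run
#' @return list with `mean`, `sd`, `per_frame`, `n_skipped`.
#' @export
nhs_baseline_chi <- function(config, bin_width = NULL) {
  res <- analyze_run(simulate_nhs(config), bin_width)
  list(mean = mean(res$per_frame$chi), sd = stats::sd(res$per_frame$chi),
       per_frame = res$per_frame, n_skipped = res$n_skipped)
}
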