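#' Per-event analysis: order parameters, correlation, susceptibility,
#' percolation
#'
#' Runs the full chain over every usable consecutive frame pair of one
#' swarming event — mode decomposition, dimensionless fluctuations,
#' connected correlation C(r) and its first zero r0, cumulative
#' correlation and susceptibility chi, nearest-neighbour distance r1 and
#' percolation threshold lambda_c — and aggregates them into an event
#' summary (time means with standard deviations over frames).
#'
#' @param traj a [swarm_trajectory()] with metadata set.
#' @param bin_width spatial bin width for the correlation estimators.
#' @param theta giant-cluster fraction for the percolation threshold.
#' @return Object of class `event_summary`; see [cross_event_report()].
#' @export
analyze_event <- function(traj, bin_width = NULL, theta = 0.6) {
  pairs <- traj_frame_pairs(traj)
  if (length(pairs) < 2L)
    swarm_stop("event rejected: fewer than 2 usable frame pairs",
               "swarm_insufficient_data")
  res <- analyze_frame_pairs(pairs, bin_width)
  if (nrow(res$per_frame) < 2L)
    swarm_stop("event rejected: fewer than 2 analysable frame pairs",
               "swarm_insufficient_data")
  lambda_c <- vapply(pairs, function(p)
    tryCatch(percolation_threshold(p$x0, theta = theta)$threshold,
             swarmcorr_error = function(e) NA_real_), numeric(1))
  summarize_event(res$per_frame, lambda_c, res$n_skipped,
                  event_id = traj$event_id, species = traj$species_label,
                  body_length = traj$body_length, theta = theta)
}

# Shared aggregation into an event_summary, used for field-format events
# and simulator pseudo-events alike.
summarize_event <- function(per_frame, lambda_c, n_skipped, event_id,
                            species, body_length, theta) {
  m <- function(v) mean(v, na.rm = TRUE)
  s <- function(v) stats::sd(v, na.rm = TRUE)
  structure(list(
    event_id = event_id, species = species,
    n = stats::median(per_frame$n), body_length = body_length,
    r1 = m(per_frame$r1), r1_bl = m(per_frame$r1) / body_length,
    polarization = m(per_frame$polarization),
    polarization_sd = s(per_frame$polarization),
    rotational = m(per_frame$rotational),
    rotational_sd = s(per_frame$rotational),
    dilatational = m(per_frame$dilatational),
    dilatational_sd = s(per_frame$dilatational),
    r0 = m(per_frame$r0), chi = m(per_frame$chi), chi_sd = s(per_frame$chi),
    lambda_c = m(lambda_c), theta = theta,
    frames_used = nrow(per_frame), frames_skipped = n_skipped,
    per_frame = per_frame),
    class = "event_summary")
}

#' @export
print.event_summary <- function(x, ...) {
  cat(sprintf("event %s (%s): N = %d, %d frames (+%d skipped)\n",
              x$event_id, x$species, as.integer(x$n), x$frames_used,
              x$frames_skipped))
  cat(sprintf("  r1 = %.4g m (r1/BL = %.3g), r0 = %.4g m\n",
              x$r1, x$r1_bl, x$r0))
  cat(sprintf("  Phi = %.3g +/- %.3g, R = %.3g, Lambda = %.3g\n",
              x$polarization, x$polarization_sd, x$rotational,
              x$dilatational))
  cat(sprintf("  chi = %.3g +/- %.3g, lambda_c = %.4g m (theta = %g)\n",
              x$chi, x$chi_sd, x$lambda_c, x$theta))
  invisible(x)
}

#' Event summaries as a table
#'
#' @param summaries list of `event_summary` objects.
#' @return data.frame with one row per event.
#' @export
event_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s)
    data.frame(event_id = s$event_id, species = s$species, n = s$n,
               body_length = s$body_length, r1 = s$r1, r1_bl = s$r1_bl,
               polarization = s$polarization, rotational = s$rotational,
               dilatational = s$dilatational, r0 = s$r0, chi = s$chi,
               chi_sd = s$chi_sd, lambda_c = s$lambda_c)))
}

#' Pseudo-event from a Vicsek simulation run
#'
#' Treats the sampled configurations of one simulation as the frames of a
#' swarming event and summarizes them with the identical estimator chain
#' used for field data. The body length is a proxy: in the model the only
#' intrinsic scale is the interaction radius `rc`, so a body length is
#' assigned as `rc / rc_bl_true` to emulate a species of known relative
#' perception range.
#'
#' @param run a `simulation_run` from [simulate_vicsek()].
#' @param body_length body-length proxy in simulation length units.
#' @param bin_width,theta estimator settings as in [analyze_event()].
#' @param event_id identifier.
#' @return An `event_summary`.
#' @export
summarize_run_event <- function(run, body_length, bin_width = NULL,
                                theta = 0.6, event_id = "sim") {
  res <- analyze_run(run, bin_width)
  if (nrow(res$per_frame) < 2L)
    swarm_stop("event rejected: fewer than 2 analysable samples",
               "swarm_insufficient_data")
  pairs <- run_frame_pairs(run)
  lambda_c <- vapply(pairs, function(p)
    tryCatch(percolation_threshold(p$x0, theta = theta)$threshold,
             swarmcorr_error = function(e) NA_real_), numeric(1))
  summarize_event(res$per_frame, lambda_c, res$n_skipped,
                  event_id = event_id, species = run$model,
                  body_length = body_length, theta = theta)
}

#' Cross-event inference: metric interaction and interaction range
#'
#' Combines the per-event summaries into the group-level conclusions:
#' (i) the metric-interaction test — is chi more correlated with r1/BL
#' than with r1 (permutation P-values on the same permutation set);
#' (ii) the critical scaling fit of chi vs r1/BL on the disordered branch;
#' (iii) the percolation slope lambda_c = s * r1 across events; and
#' (iv) the combined estimate of the interaction range in body lengths,
#' `rc/BL = x_c * s`, with delta-method error propagation. Components that
#' fail (e.g. no identifiable transition) are reported as errors in a
#' partial report rather than aborting the rest.
#'
#' @param summaries list of `event_summary` objects, >= 5.
#' @param m permutations for the rank tests.
#' @param n_boot bootstrap replicates for the fits.
#' @param seed RNG seed.
#' @return Object of class `cross_event_report` with elements `events`,
#'   `scaling_comparison`, `critical_fit`, `percolation_fit`,
#'   `interaction_range` (each possibly a condition object under
#'   `$error`), and `errors` (character).
#' @export
cross_event_report <- function(summaries, m = 10000, n_boot = 500,
                               seed = 1) {
  if (length(summaries) < 5L)
    swarm_stop("cross-event inference needs >= 5 events",
               "swarm_insufficient_data")
  ev <- event_table(summaries)
  errors <- character(0)
  grab <- function(expr) tryCatch(expr, swarmcorr_error = function(e) {
    errors <<- c(errors, conditionMessage(e))
    structure(list(error = conditionMessage(e),
                   condition = class(e)[1]), class = "component_error")
  })
  comparison <- grab(compare_scaling_variables(
    data.frame(r1 = ev$r1, body_length = ev$body_length, chi = ev$chi),
    m = m, seed = seed))
  critical <- grab(fit_critical_scaling(ev$r1_bl, ev$chi,
                                        n_boot = n_boot, seed = seed))
  perc <- grab(threshold_scaling(ev, n_boot = n_boot, seed = seed))
  range_est <- if (inherits(critical, "component_error") ||
                   inherits(perc, "component_error")) {
    structure(list(error = "missing inputs: transition or percolation fit failed",
                   condition = "swarm_partial_report"),
              class = "component_error")
  } else {
    grab(estimate_interaction_range(critical$x_c, perc$slope,
                                    xc_ci = critical$ci["x_c", ],
                                    s_ci = perc$ci))
  }
  structure(list(events = ev, scaling_comparison = comparison,
                 critical_fit = critical, percolation_fit = perc,
                 interaction_range = range_est, errors = errors),
            class = "cross_event_report")
}

#' @export
print.cross_event_report <- function(x, ...) {
  cat(sprintf("cross-event report over %d events\n", nrow(x$events)))
  if (!inherits(x$scaling_comparison, "component_error")) {
    cat(sprintf("  P(chi ~ r1/BL) = %.4g, P(chi ~ r1) = %.4g\n",
                x$scaling_comparison$scaled$p_value,
                x$scaling_comparison$raw$p_value))
  }
  if (!inherits(x$critical_fit, "component_error")) {
    cat(sprintf("  critical fit: x_c = %.3g [%.3g, %.3g], gamma = %.3g\n",
                x$critical_fit$x_c, x$critical_fit$ci["x_c", 1],
                x$critical_fit$ci["x_c", 2], x$critical_fit$gamma))
  }
  if (!inherits(x$percolation_fit, "component_error")) {
    cat(sprintf("  percolation slope: s = %.3g [%.3g, %.3g]\n",
                x$percolation_fit$slope, x$percolation_fit$ci[1],
                x$percolation_fit$ci[2]))
  }
  if (!inherits(x$interaction_range, "component_error")) {
    cat(sprintf("  interaction range: rc/BL = %.3g [%.3g, %.3g]\n",
                x$interaction_range$rc_bl, x$interaction_range$ci[1],
                x$interaction_range$ci[2]))
  }
  if (length(x$errors))
    cat("  partial report; failed components:\n   ",
        paste(x$errors, collapse = "\n    "), "\n")
  invisible(x)
}

#' Generate Vicsek pseudo-events across the disordered branch
#'
#' Convenience wrapper for end-to-end exercises: one pseudo-event per
#' central-force strength, all with the same known interaction radius and
#' body-length proxy, spanning a range of densities on the disordered side
#' of the transition.
#'
#' @param betas central-force strengths (one event each).
#' @param base a [vicsek_config()] template.
#' @param rc_bl_true true interaction range in body lengths; the
#'   body-length proxy is `rc / rc_bl_true`.
#' @param bin_width,theta estimator settings.
#' @return list of `event_summary` objects.
#' @export
vicsek_pseudo_events <- function(betas, base, rc_bl_true = 5,
                                 bin_width = NULL, theta = 0.6) {
  lapply(seq_along(betas), function(k) {
    cfg <- base
    cfg$beta <- betas[k]
    cfg$seed <- base$seed + k
    cfg <- do.call(vicsek_config, unclass(cfg))
    run <- simulate_vicsek(cfg)
    summarize_run_event(run, body_length = cfg$rc / rc_bl_true,
                        bin_width = bin_width, theta = theta,
                        event_id = sprintf("vicsek-beta-%g", betas[k]))
  })
}
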