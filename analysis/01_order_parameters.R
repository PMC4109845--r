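#!/usr/bin/env Rscript
# Order parameters of a disordered but correlated swarm.
#
# Generates a synthetic swarming event (correlated direction fluctuations,
# no global order), runs the per-frame order parameters, and compares them
# with the uncorrelated null band. Finding: all three order parameters sit
# at the scale expected for an uncorrelated group — the swarm is genuinely
# disordered — which is what makes the correlations of 02 interesting.

library(swarmcorr)
dir.create("results", showWarnings = FALSE)
seed <- 1

traj <- correlated_trajectory(n = 150, n_frames = 10, L = 0.45,
                              noise_sd = 0.25, speed = 0.08, fps = 10,
                              body_length = 0.002,
                              event_id = "synthetic-swarm", seed = seed)
ev <- analyze_event(traj)
nb <- null_band(150, n_samples = 300, seed = seed + 1)

series <- ev$per_frame[, c("time_index", "polarization", "rotational",
                           "dilatational")]
series$null_phi_mean <- nb["polarization", "mean"]
series$null_phi_sd <- nb["polarization", "sd"]
write.csv(series, "results/order_parameter_series.csv", row.names = FALSE)

cat(sprintf("Polarization %.3f +/- %.3f (null band %.3f +/- %.3f)\n",
            ev$polarization, ev$polarization_sd,
            nb["polarization", "mean"], nb["polarization", "sd"]))
cat(sprintf("Rotational order %.3f, dilatational order %.3f\n",
            ev$rotational, ev$dilatational))
cat("-> the swarm shows no collective order beyond uncorrelated noise\n")
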