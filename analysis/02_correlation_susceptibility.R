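#!/usr/bin/env Rscript
# Connected correlation and susceptibility of the synthetic swarm versus
# the non-interacting harmonic swarm (NHS) baseline.
#
# Finding: despite the absence of order (01), the swarm's velocity
# fluctuations are correlated well beyond the nearest-neighbour distance
# (r0 >> r1) and the susceptibility far exceeds the NHS value, which is the
# signature of genuine inter-individual interaction.

library(swarmcorr)
dir.create("results", showWarnings = FALSE)
seed <- 1

traj <- correlated_trajectory(n = 150, n_frames = 10, L = 0.45,
                              noise_sd = 0.25, speed = 0.08, fps = 10,
                              body_length = 0.002, seed = seed)
ev <- analyze_event(traj)

# one representative frame's C(r) and Q(r)
pair <- swarmcorr:::traj_frame_pairs(traj)[[1]]
dec <- decompose_modes(pair$x0, pair$x1, pair$fps)
cc <- connected_correlation(dec$phi, dec$y)
ss <- susceptibility(dec$phi, dec$y)
write.csv(data.frame(r = cc$bin_centers, C = cc$values,
                     pairs = cc$pair_counts),
          "results/correlation_curve.csv", row.names = FALSE)
write.csv(data.frame(r = ss$grid, Q = ss$q),
          "results/cumulative_correlation.csv", row.names = FALSE)

nhs <- nhs_baseline_chi(nhs_config(n = 150, steps = 3000, transient = 2000,
                                   sample_every = 300, seed = seed + 1))

write.csv(data.frame(quantity = c("chi_swarm", "chi_nhs", "r0", "r1"),
                     value = c(ev$chi, nhs$mean, ev$r0, ev$r1)),
          "results/susceptibility_summary.csv", row.names = FALSE)

cat(sprintf("r0 = %.3f m vs r1 = %.3f m (ratio %.1f)\n",
            ev$r0, ev$r1, ev$r0 / ev$r1))
cat(sprintf("chi_swarm = %.2f vs chi_NHS = %.3f (ratio %.0f)\n",
            ev$chi, nhs$mean, ev$chi / nhs$mean))
cat("-> correlation without order; incompatible with non-interacting particles\n")
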