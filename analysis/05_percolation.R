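#!/usr/bin/env Rscript
# Percolation threshold of spatial point sets and its scaling with the
# nearest-neighbour distance. Finding: across a 125-fold density range the
# dimensionless threshold lambda_c / r1 is constant (~1.7), so a single
# slope converts nearest-neighbour distances into linking scales — the
# geometric ingredient of the interaction-range estimate (06).

library(swarmcorr)
dir.create("results", showWarnings = FALSE)

dens <- c(400, 2000, 10000, 50000)
rows <- list()
for (k in seq_along(dens)) {
  for (s in 1:4) {
    pts <- poisson_swarm(250, dens[k], seed = 100 * k + s)
    pc <- percolation_threshold(pts, theta = 0.6)
    rows[[length(rows) + 1]] <- data.frame(
      density = dens[k], replicate = s,
      r1 = nearest_neighbour_distance(pts), lambda_c = pc$threshold)
  }
}
events <- do.call(rbind, rows)
events$ratio <- events$lambda_c / events$r1
write.csv(events, "results/percolation_events.csv", row.names = FALSE)

fit <- threshold_scaling(events, n_boot = 1000, seed = 5)
cat(sprintf("lambda_c / r1 by density: %s\n",
            paste(round(tapply(events$ratio, events$density, mean), 3),
                  collapse = ", ")))
cat(sprintf("-> through-origin slope s = %.3f [%.3f, %.3f]\n",
            fit$slope, fit$ci[1], fit$ci[2]))
write.csv(data.frame(slope = fit$slope, lower = fit$ci[1],
                     upper = fit$ci[2]),
          "results/percolation_slope.csv", row.names = FALSE)
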