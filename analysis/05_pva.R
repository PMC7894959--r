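#!/usr/bin/env Rscript
# Stochastic viability projection of the monitored population: growth
# distribution from the census ratios, 10- and 50-year horizons, and
# per-subpopulation projections.

library(endemica)
dir.create("results", showWarnings = FALSE)

mon <- read_monitoring(system.file("extdata", "asperula_monitoring.csv",
                                   package = "endemica"))
tot <- census_totals(mon)
fg <- fit_growth(tot$n_mature)
cat(sprintf("Growth multipliers: arithmetic mean %.3f (sd %.3f), log-scale mean %.4f (sd %.3f)\n",
            fg$arith_mean, fg$arith_sd, fg$log_mean, fg$log_sd))

run <- function(n0, label) {
  cfg <- pva_config(n0 = n0, horizon_years = 50, n_replicates = 10000,
                    growth_log_mean = fg$log_mean,
                    growth_log_sd = fg$log_sd, seed = 424242)
  res <- simulate_pva(cfg)
  r10 <- extinction_risk(res, 10)
  r50 <- extinction_risk(res, 50)
  cat(sprintf("%s (n0 = %d): risk(10y) = %.3f [%.3f, %.3f], risk(50y) = %.3f [%.3f, %.3f]\n",
              label, n0, r10$risk, r10$ci[1], r10$ci[2],
              r50$risk, r50$ci[1], r50$ci[2]))
  res
}

res_total <- run(tot$n_mature[1], "Total population")
for (p in unique(mon$subpopulation)) {
  n0 <- mon$n_mature[mon$subpopulation == p & mon$year == min(mon$year)]
  run(n0, paste("Subpopulation", p))
}
cat("The published RAMAS risks (0.1% / 47.8%) used an unstated variance\n",
    "structure; the diffusion parameterised from the census ratios is\n",
    "qualitatively consistent (risk rises steeply between horizons) but\n",
    "not numerically comparable.\n")

write.csv(res_total$summary, "results/pva_trajectory_summary.csv",
          row.names = FALSE)
pdf("results/pva_projection.pdf", width = 7, height = 5)
s <- res_total$summary
plot(s$year, s$mean, type = "l", lwd = 2, ylim = c(0, max(s$max)),
     xlab = "Year", ylab = "Mature individuals",
     main = "Stochastic projection (mean, +/-1 sd, min/max)")
lines(s$year, pmax(s$mean - s$sd, 0), lty = 2)
lines(s$year, s$mean + s$sd, lty = 2)
points(s$year, s$min, pch = 20, cex = 0.5)
points(s$year, s$max, pch = 20, cex = 0.5)
dev.off()
cat("Trajectory summary and plot written under results/\n")
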