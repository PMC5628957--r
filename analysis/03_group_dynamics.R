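#!/usr/bin/env Rscript
# Between-group structure and movement dynamics: simulated groups graded in
# mean intrinsic speed, frame-wise schooling classification under the
# primary criteria (IID <= 160 mm, centroid speed >= 0.5 BL/s,
# polarization >= 0.6, no outlier/split), and the 125-combination
# threshold robustness scan of the schooling-proportion correlation.

suppressPackageStartupMessages(library(shoaldyn))
dir.create("results", showWarnings = FALSE)

trial_speeds <- seq(0.2, 2.0, length.out = 12)
sims <- lapply(seq_along(trial_speeds), function(i) {
  run_experiment(sim_config(speed_mean = trial_speeds[i]), seed = 300 + i)
})
tabs <- lapply(sims, function(s) schooling_table(sim_to_mm(s)))
covariate <- vapply(sims, function(s) mean(s$agents$speed), numeric(1))

trial <- data.frame(
  speed_mean = trial_speeds,
  realized_mean_speed = covariate,
  mean_iid_mm = vapply(tabs, function(t) mean(t$iid), numeric(1)),
  mean_rho = vapply(tabs, function(t) mean(t$rho, na.rm = TRUE),
                    numeric(1)),
  schooling_prop = vapply(tabs, function(t) {
    schooling_proportion(t$schooling)
  }, numeric(1)))
write.csv(trial, "results/group_dynamics_trials.csv", row.names = FALSE)

grid <- robustness_grid(tabs, covariate)
write.csv(grid, "results/robustness_grid.csv", row.names = FALSE)

cat(sprintf("faster groups are more aligned: rho_s(speed, polarization) = %+.2f\n",
            cor(covariate, trial$mean_rho, method = "spearman")))
cat(sprintf("and more spaced: rho_s(speed, IID) = %+.2f\n",
            cor(covariate, trial$mean_iid_mm, method = "spearman")))
cat(sprintf("robustness scan: %d combinations, %d alternatives; %.0f%% of defined cells have a positive schooling~speed correlation\n",
            nrow(grid), attr(robustness_thresholds(), "n_alternatives"),
            100 * mean(grid$rho_s > 0, na.rm = TRUE)))
cat("wrote results/group_dynamics_trials.csv, results/robustness_grid.csv\n")
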