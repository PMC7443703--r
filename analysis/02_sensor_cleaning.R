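#!/usr/bin/env Rscript
# Stage 2: sensor-level comparison of the four artefact rejection
# methods on the DSMW condition.
#
# Sweeps each method over its strength parameter (Hampel C, S3P noise
# subspace k, ICA-MI rejection rate R, tSSS correlation limit CL),
# computes the three band RMSEs (dipole 11.5-12.5 Hz, movement 1-15 Hz
# excluding the dipole band, DBS peak +/- 1 Hz) against the Reference,
# adds the wide-band Hampel/S3P variants and baseline-corrected tSSS,
# and summarizes robustness (mean +/- SD of RMSE over each method's
# parameter range) plus the optimal parameter per method.
#
# Reads:   results/condition_set.rds   (from 01_simulate.R)
# Outputs: results/rmse_sweeps.csv, results/robustness.csv,
#          results/optimal_parameters.csv, results/wideband_variants.csv

library(megdbs)

set <- read_container("results/condition_set.rds", "condition_set")
bands <- band_set(detect_dbs_peak(welch_psd(set$dsmw)))
message("DBS band centred at ", bands$f_peak, " Hz")

grids <- list(hampel = 1:8, s3p = 1:9, icami = c(5, 10, 20, 30, 40),
              tsss = seq(0.95, 0.60, by = -0.05))
sweeps <- list()
for (m in names(grids)) {
  message("sweeping ", m, " over ", length(grids[[m]]), " values...")
  sweeps[[m]] <- sweep_method(m, grids[[m]], set, bands)
  print(sweeps[[m]])
}

rep <- study_report(set, sweeps)
write.csv(rep$rmse, "results/rmse_sweeps.csv", row.names = FALSE)
write.csv(rep$robustness, "results/robustness.csv", row.names = FALSE)
write.csv(rep$optimal, "results/optimal_parameters.csv", row.names = FALSE)

# wide-band variants and baseline-corrected tSSS at representative values
ref_spec <- welch_psd(set$reference)
variants <- list(
  hampel_wb = evaluate_cleaning(set, clean_with("hampel", set, 5,
                                                list(mode = "wide_band")),
                                bands),
  s3p_wb = evaluate_cleaning(set, clean_with("s3p", set, 1,
                                             list(mode = "wide_band")),
                             bands),
  tsss_bl = evaluate_cleaning(set,
                              baseline_correct(
                                welch_psd(clean_with("tsss", set, 0.95)),
                                ref_spec),
                              bands)
)
var_tbl <- do.call(rbind, lapply(names(variants), function(nm) {
  cbind(variant = nm, variants[[nm]]$rmse)
}))
write.csv(var_tbl, "results/wideband_variants.csv", row.names = FALSE)

message("\nRobustness (mean +/- SD of RMSE over the parameter range):")
print(rep$robustness)
message("\nOptimal sensor-level parameters (lowest average RMSE):")
print(rep$optimal)
message("wrote results/rmse_sweeps.csv, robustness.csv, ",
        "optimal_parameters.csv, wideband_variants.csv")
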