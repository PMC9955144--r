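#!/usr/bin/env Rscript
# Step 4 — calibrate the mechanistic secretion/dilution model so its
# class-wise modified-LI means reproduce the reference cohort moments, then
# run a calibrated cohort through the pipeline.

library(avsli)
dir.create("results", showWarnings = FALSE)

cal <- calibrate_mechanistic(seed = 20230103)
print(cal)

params <- data.frame(parameter = names(unclass(cal$params))[1:10],
                     value = unlist(unclass(cal$params)[1:10]))
write.csv(params, "results/calibrated_params.csv", row.names = FALSE)
write.csv(merge(cal$target, cal$achieved, by = "class",
                suffixes = c("_target", "_achieved")),
          "results/calibration_moments.csv", row.names = FALSE)

co <- draw_cohort(cohort_spec(8, 12, 24, seed = 20230104), cal$params)
report <- run_pipeline(co)
cat("\nCalibrated 44-patient cohort, class-wise modified LI:\n")
print(report$group_stats[, c("class", "n", "modified_li_mean", "modified_li_sd")],
      row.names = FALSE, digits = 3)
cat("Calibration results written to results/calibrated_params.csv and results/calibration_moments.csv\n")
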