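#!/usr/bin/env Rscript
# Step 4 — out-of-sample neuromonitoring of the intervention sample.
#
# The frozen ensemble scores every patient's baseline and follow-up scan
# (no retraining); Platt scaling fitted on the diagnostic sample's
# decision scores calibrates probabilities. The per-subject score change
# (FU - T0) is the psychosis-likeness change: negative = shift toward the
# healthy side of the hyperplane. Shift direction is then cross-tabulated
# against the sensory-processing subgroups.

source("analysis/common.R")

cohort <- read_cohort_csv(res_path("cohort_diagnostic.csv"))
iv_cohort <- read_cohort_csv(res_path("cohort_intervention.csv"))
features <- read_feature_matrix_csv(scratch_path("features_diag.csv"))
f0 <- read_feature_matrix_csv(scratch_path("features_interv_T0.csv"))
rownames(f0) <- iv_cohort$subject_id
f1 <- read_feature_matrix_csv(scratch_path("features_interv_FU.csv"))
rownames(f1) <- iv_cohort$subject_id
ens <- readRDS(scratch_path("ensemble.rds"))

cal <- platt_calibrate(
  predict_ensemble(ens, features, cohort, mode = "cv2")$mean_score,
  cohort$group)
recs <- decision_records(ens, f0, f1, iv_cohort, cal)
write_decisions_csv(recs, res_path("decisions.csv"))

oocv_sens_t0 <- 100 * mean(recs$score_T0 > 0)
oocv_sens_fu <- 100 * mean(recs$score_FU > 0)
cat(sprintf("OOCV sensitivity (fraction of patients voted ROP): %.2f%% at T0, %.2f%% at FU\n",
            oocv_sens_t0, oocv_sens_fu))
cat(sprintf("psychosis-likeness change: mean %.3f (healthy-like in %d/%d patients)\n",
            mean(recs$delta), sum(recs$direction == "healthy-like"),
            nrow(recs)))
cat(sprintf("recovery of planted shift: cor(shift, -delta) = %.2f\n",
            cor(iv_cohort$shift, -recs$delta)))

ct <- shift_contingency(recs, iv_cohort$subgroup)
print(ct$table)
print(ct$test)
if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(
    list(counts = as.data.frame(ct$table),
         chisq = ct$test$statistic, p = ct$test$p,
         oocv_sensitivity_T0 = oocv_sens_t0,
         oocv_sensitivity_FU = oocv_sens_fu),
    res_path("contingency.json"), auto_unbox = TRUE, digits = NA)
}
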