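#!/usr/bin/env Rscript
# Step 2 — preprocess scans into connectivity feature vectors.
#
# For every scan: zero-phase 0.01-0.08 Hz band-pass, regression of the
# (identically filtered) Friston-24 motion expansion plus WM/CSF traces,
# ROI-pairwise Pearson correlation, upper-triangle vectorization, and
# framewise-displacement QC. Feature matrices go to scratch/, the QC table
# to results/.

source("analysis/common.R")

read_cohort_scans <- function(dir, cohort, session) {
  lapply(cohort$subject_id, function(id)
    read_scan_tsv(dir, id, session, tr_seconds = 2))
}

diag_cohort <- read_cohort_csv(res_path("cohort_diagnostic.csv"))
iv_cohort <- read_cohort_csv(res_path("cohort_intervention.csv"))

cc <- cohort_connectivity(read_cohort_scans(scratch_path("scans_diag"),
                                            diag_cohort, "T0"))
cc0 <- cohort_connectivity(read_cohort_scans(scratch_path("scans_interv"),
                                             iv_cohort, "T0"))
cc1 <- cohort_connectivity(read_cohort_scans(scratch_path("scans_interv"),
                                             iv_cohort, "FU"))

write_feature_matrix_csv(cc$features, scratch_path("features_diag.csv"))
write_feature_matrix_csv(cc0$features, scratch_path("features_interv_T0.csv"))
write_feature_matrix_csv(cc1$features, scratch_path("features_interv_FU.csv"))
qc <- rbind(cc$qc, cc0$qc, cc1$qc)
utils::write.csv(qc, res_path("qc.csv"), row.names = FALSE)

cat(sprintf("connectivity vectors: %d edges per scan\n", ncol(cc$features)))
cat(sprintf("QC: mean FD %.3f mm (max %.3f); %d of %d scans excluded at 0.5 mm\n",
            mean(qc$mean_fd), max(qc$max_fd), sum(!qc$included), nrow(qc)))
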