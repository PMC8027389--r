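#!/usr/bin/env Rscript
# Step 1 — simulate the two study cohorts.
#
# Generates (a) the diagnostic sample (56 healthy controls, 35 recent-onset
# psychosis patients; one baseline scan each) used to build the HC-ROP
# classifier, with a planted connectivity contrast on 100 edges, and (b)
# the paired-session intervention sample (14 maintainers, 12 improvers)
# whose follow-up covariance interpolates toward the healthy pattern by a
# per-subject latent shift, plus behavioral outcomes coupled to that shift.
# Phenotype tables go to results/, scan TSVs to scratch/.

source("analysis/common.R")

sim <- simulate_cohort(diag_config(), seed = SEED)
iv <- simulate_intervention_cohort(interv_config(), sim$hc_cov,
                                   sim$rop_cov, seed = SEED + 1)

write_cohort_csv(sim$cohort, res_path("cohort_diagnostic.csv"))
write_cohort_csv(iv$cohort, res_path("cohort_intervention.csv"))
write_sim_config(diag_config(), res_path("sim_config_diagnostic.yaml"))

for (sc in sim$scans) write_scan_tsv(sc, scratch_path("scans_diag"))
for (sc in iv$scans_t0) write_scan_tsv(sc, scratch_path("scans_interv"))
for (sc in iv$scans_fu) write_scan_tsv(sc, scratch_path("scans_interv"))

cat(sprintf("diagnostic cohort: %d subjects (%d HC, %d ROP)\n",
            nrow(sim$cohort), sum(sim$cohort$group == "HC"),
            sum(sim$cohort$group == "ROP")))
cat(sprintf("intervention cohort: %d patients (%d maintainers, %d improvers)\n",
            nrow(iv$cohort), sum(iv$cohort$subgroup == "maintainer"),
            sum(iv$cohort$subgroup == "improver")))
cat(sprintf("planted contrast: %d affected edges, delta = %.2f; PD projection applied to patient covariance: %s\n",
            nrow(sim$cov_spec$affected_edges), sim$cov_spec$delta,
            sim$cov_spec$rop_projected))
cat(sprintf("mean planted shift: improvers %.2f, maintainers %.2f\n",
            mean(iv$cohort$shift[iv$cohort$subgroup == "improver"]),
            mean(iv$cohort$shift[iv$cohort$subgroup == "maintainer"])))
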