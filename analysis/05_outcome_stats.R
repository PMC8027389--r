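#!/usr/bin/env Rscript
# Step 5 — statistical battery over the intervention outcomes.
#
# z-scores the cognitive domains against the study sample and masks >2 SD
# outliers; tests cognitive change over time by sensory-processing
# subgroup, shift direction, and their interaction (mixed-design ANOVA);
# follows up with paired t-tests and Cohen's d within cells; controls the
# follow-up social-cognition group contrast for baseline (ANCOVA); and
# applies Benjamini-Hochberg FDR across the ANOVA interaction p-values.

source("analysis/common.R")

iv <- read_cohort_csv(res_path("cohort_intervention.csv"))
recs <- utils::read.csv(res_path("decisions.csv"))
recs$direction <- factor(recs$direction,
                         levels = c("healthy-like", "psychosis-like", "none"))
domains <- c("attention", "working_memory", "verbal_learning",
             "processing_speed", "social_cognition")

zs <- zscore_and_exclude(iv, paste0(domains, "_T0"))
rows <- list()
for (d in domains) {
  keep <- !zs$mask[, paste0(d, "_T0")] & recs$direction != "none"
  res <- mixed_anova_2x2(
    iv[[paste0(d, "_T0")]][keep], iv[[paste0(d, "_FU")]][keep],
    data.frame(subgroup = droplevels(factor(iv$subgroup[keep])),
               direction = droplevels(recs$direction[keep])))
  for (nm in names(res)) {
    r <- as.data.frame(res[[nm]])
    r$name <- paste(d, nm, sep = ".")
    rows[[length(rows) + 1]] <- r
  }
}
tab <- do.call(rbind, rows)

# FDR over the subgroup-by-direction interaction family
int_rows <- grepl("time:subgroup:direction", tab$name)
tab$p_fdr <- NA_real_
tab$p_fdr[int_rows] <- fdr_bh(tab$p[int_rows])

cat("subgroup x direction x time interactions:\n")
print(tab[int_rows, c("name", "statistic", "df1", "df2", "p", "p_fdr")],
      row.names = FALSE)

# post-hoc paired contrasts on attention within each subgroup/direction cell
extra <- list()
for (sg in c("maintainer", "improver")) for (dir in levels(recs$direction)[1:2]) {
  sel <- iv$subgroup == sg & recs$direction == dir
  if (sum(sel) >= 2) {
    ph <- paired_t_cohens_d(iv$attention_T0[sel], iv$attention_FU[sel],
                            name = sprintf("attention %s/%s", sg, dir))
    print(ph)
    extra[[length(extra) + 1]] <- as.data.frame(ph)
  }
}

# follow-up social cognition by subgroup, controlling baseline
anc <- ancova_oneway(iv$social_cognition_FU, iv$subgroup,
                     iv$social_cognition_T0, name = "social_cognition_FU")
print(anc)
extra[[length(extra) + 1]] <- as.data.frame(anc)

extra_tab <- do.call(rbind, extra)
extra_tab$p_fdr <- NA_real_
utils::write.csv(rbind(tab, extra_tab), res_path("outcome_stats.csv"),
                 row.names = FALSE)
cat("wrote results/outcome_stats.csv\n")
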