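# Shared settings for the numbered analysis drivers. The connectome is run
# at a 40-ROI scale (780 edges) with the study's sample sizes; the methods
# vignette discusses this choice. Large intermediates (scans, feature
# matrices) live under scratch/, small result tables under results/.

suppressMessages(library(psylikeness))

SEED <- 20260401 %% 100000
N_ROIS <- 40

diag_config <- function() {
  cohort_config(n_rois = N_ROIS, n_affected_edges = 100, delta = 0.4)
}

interv_config <- function() {
  intervention_config(n_rois = N_ROIS)
}

cv_scheme_params <- function() {
  list(k_outer = 5, perm_outer = 2, k_inner = 5, perm_inner = 2)
}

res_path <- function(...) {
  dir.create("results", showWarnings = FALSE)
  file.path("results", ...)
}
scratch_path <- function(...) {
  dir.create("scratch", showWarnings = FALSE, recursive = TRUE)
  file.path("scratch", ...)
}
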