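# Small in-code fixtures shared across test files.

# Quiet motion/nuisance settings for tests that care about the signal only.
quiet_params <- function() {
  list(motion_params = list(spike_prob = 0, spike_sd_mm = 0, spike_gain = 0,
                            drift_sd_mm = 0.005),
       nuisance_params = list(amplitude = 0))
}

# Tiny diagnostic cohort with a planted contrast, run through the full
# connectivity pipeline. Returns cohort, feature matrix and covariances.
tiny_study <- function(seed = 42, n_rois = 16, n_hc = 18, n_rop = 14,
                       n_affected_edges = 24, delta = 0.4,
                       n_timepoints = 128) {
  cfg <- cohort_config(n_rois = n_rois, n_hc = n_hc, n_rop = n_rop,
                       n_affected_edges = n_affected_edges, delta = delta,
                       n_timepoints = n_timepoints)
  sim <- simulate_cohort(cfg, seed = seed)
  cc <- cohort_connectivity(sim$scans)
  list(cohort = sim$cohort, features = cc$features, qc = cc$qc,
       hc_cov = sim$hc_cov, rop_cov = sim$rop_cov)
}

tiny_scheme <- function() {
  list(k_outer = 3, perm_outer = 1, k_inner = 2, perm_inner = 1)
}

# Hand-built fold model with an identity preprocessing chain over p edges:
# no pruning, zero covariate betas, identity PCA basis, unit 0-1 scaling.
# Its score is simply w . x + b for x in [-0.5, 1.5].
identity_fold_model <- function(w, b, p = length(w)) {
  structure(list(variance_mask = rep(TRUE, p),
                 covariate_betas = matrix(0, 3, p),
                 pca_mean = rep(0, p), pca_basis = diag(p),
                 n_components = p, pc_min = rep(0, p),
                 pc_range = rep(1, p),
                 scale_degenerate = rep(FALSE, p),
                 w = w, b = b,
                 class_weights = c(HC = 1, ROP = 1),
                 levels = c("HC", "ROP")),
            class = "fold_model")
}

# Minimal ensemble wrapper around hand-built models (oocv mode only).
identity_ensemble <- function(models) {
  structure(list(models = models,
                 coords = data.frame(outer_perm = 1,
                                     outer_fold = seq_along(models),
                                     inner_perm = 1, inner_fold = 1),
                 scheme = list(n = NA_integer_),
                 levels = c("HC", "ROP")),
            class = "svm_ensemble")
}

no_covars <- function(n) data.frame(sex = rep("F", n), premorbid_iq = rep(0, n))
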