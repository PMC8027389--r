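#' Project a symmetric matrix to the positive-definite cone
#'
#' Eigenvalue clipping: eigenvalues below `min_eig` are raised to `min_eig`
#' and the matrix is reconstructed and re-symmetrized. Used to repair group
#' covariance matrices after edgewise perturbation, which can push small
#' eigenvalues negative when perturbed edges share nodes.
#'
#' @param mat symmetric numeric matrix.
#' @param min_eig eigenvalue floor (default `1e-6`).
#' @return The (possibly repaired) matrix, with attributes `pd_projected`
#'   (logical, whether clipping was applied) and `pd_max_adjust` (largest
#'   absolute entrywise change).
#' @export
project_pd <- function(mat, min_eig = 1e-6) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  mat <- (mat + t(mat)) / 2
  es <- eigen(mat, symmetric = TRUE)
  if (min(es$values) >= min_eig) {
    attr(mat, "pd_projected") <- FALSE
    attr(mat, "pd_max_adjust") <- 0
    return(mat)
  }
  vals <- pmax(es$values, min_eig)
  out <- es$vectors %*% (vals * t(es$vectors))
  out <- (out + t(out)) / 2
  attr(out, "pd_projected") <- TRUE
  attr(out, "pd_max_adjust") <- max(abs(out - mat))
  out
}

#' Build healthy-control and patient group covariance matrices
#'
#' Constructs a pair of R x R spatial covariance matrices that differ only on
#' a set of randomly chosen "affected" ROI pairs, where the patient (ROP)
#' matrix is offset by `delta` in correlation units. This plants the kind of
#' group-specific connectivity contrast (predominantly stronger coupling in
#' patients for positive `delta`) that the downstream classifier is built to
#' detect. Both matrices are projected back to positive definite if the
#' perturbation breaks definiteness; the projection is reported in the
#' returned spec.
#'
#' @param n_rois number of ROIs (default 160, the size of the Dosenbach
#'   functional atlas).
#' @param n_affected_edges how many upper-triangle edges receive the offset.
#' @param delta signed coupling perturbation per affected edge, |delta| < 1.
#' @param seed integer seed controlling which edges are affected.
#' @param base_covariance optional symmetric PD base matrix (default
#'   identity).
#' @return list with `spec` (n_rois, affected edge table, delta, projection
#'   flags), `hc_cov` and `rop_cov`.
#' @export
build_group_covariance <- function(n_rois = 160, n_affected_edges, delta,
                                   seed = NULL, base_covariance = NULL) {
  n_edges <- n_rois * (n_rois - 1) / 2
  stopifnot(n_affected_edges >= 0, n_affected_edges <= n_edges,
            abs(delta) < 1)
  if (is.null(base_covariance)) base_covariance <- diag(n_rois)
  stopifnot(nrow(base_covariance) == n_rois,
            isTRUE(all.equal(base_covariance, t(base_covariance))))
  if (!is.null(seed)) set.seed(seed)

  edges <- edge_index_table(n_rois)
  sel <- if (n_affected_edges > 0) {
    sort(sample.int(n_edges, n_affected_edges))
  } else integer(0)
  affected <- edges[sel, , drop = FALSE]

  hc <- project_pd(base_covariance)
  rop0 <- base_covariance
  for (k in seq_len(nrow(affected))) {
    i <- affected$i[k]; j <- affected$j[k]
    rop0[i, j] <- rop0[i, j] + delta
    rop0[j, i] <- rop0[j, i] + delta
  }
  rop <- project_pd(rop0)
  for (m in list(hc, rop)) {
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("covariance not positive definite after projection")
  }
  list(
    spec = list(n_rois = n_rois, affected_edges = affected, delta = delta,
                hc_projected = attr(hc, "pd_projected"),
                rop_projected = attr(rop, "pd_projected"),
                rop_max_adjust = attr(rop, "pd_max_adjust")),
    hc_cov = hc, rop_cov = rop
  )
}

# Slow background signals used as synthetic WM/CSF nuisance traces: a slow
# sinusoid with random phase plus AR(1) noise, unit-variance scaled.
.nuisance_signals <- function(n_timepoints, tr_seconds) {
  t_sec <- (seq_len(n_timepoints) - 1) * tr_seconds
  make_one <- function() {
    f <- stats::runif(1, 0.005, 0.02)
    s <- sin(2 * pi * f * t_sec + stats::runif(1, 0, 2 * pi)) +
      as.numeric(stats::filter(stats::rnorm(n_timepoints, sd = 0.5), 0.9,
                               method = "recursive"))
    as.numeric(scale(s))
  }
  cbind(wm = make_one(), csf = make_one())
}

#' Simulate a single resting-state scan
#'
#' Draws a T x R BOLD-like time series from a zero-mean stationary Gaussian
#' process with the given spatial covariance, then adds scaled nuisance
#' signals (synthetic WM/CSF traces with random ROI loadings) and
#' motion-locked global spikes. Head motion is modelled as occasional random
#' translation/rotation steps (Bernoulli per timepoint), so framewise
#' displacement QC paths are exercised.
#'
#' @param cov positive-definite R x R spatial covariance.
#' @param n_timepoints scan length T (>= 64).
#' @param tr_seconds repetition time in seconds.
#' @param motion_params list: `spike_prob` (per-timepoint step probability),
#'   `spike_sd_mm` (translation step SD, mm; rotations use 1/100 of this in
#'   radians), `spike_gain` (BOLD units added per mm of step).
#' @param nuisance_params list: `amplitude` (loading SD of the two nuisance
#'   signals onto ROIs; 0 disables).
#' @param seed integer seed; same seed gives a bit-identical scan.
#' @param subject_id,session identifiers carried on the scan.
#' @return object of class `sim_scan`: list with `timeseries` (T x R),
#'   `motion` (T x 6, starts at zeros), `nuisance` (T x 2), `tr_seconds`,
#'   `subject_id`, `session`.
#' @export
simulate_scan <- function(cov, n_timepoints = 190, tr_seconds = 2,
                          motion_params = list(spike_prob = 0.03,
                                               spike_sd_mm = 0.3,
                                               spike_gain = 1,
                                               drift_sd_mm = 0.005),
                          nuisance_params = list(amplitude = 1),
                          seed = NULL, subject_id = "sub", session = "T0") {
  stopifnot(n_timepoints >= 64)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("degenerate covariance: not positive definite")
  if (!is.null(seed)) set.seed(seed)
  n_rois <- nrow(cov)

  ts <- MASS::mvrnorm(n_timepoints, mu = rep(0, n_rois), Sigma = cov)

  nuis <- .nuisance_signals(n_timepoints, tr_seconds)
  amp <- nuisance_params$amplitude %||% 0
  if (amp > 0) {
    loadings <- matrix(stats::rnorm(2 * n_rois, sd = amp), 2, n_rois)
    ts <- ts + nuis %*% loadings
  }

  p <- motion_params$spike_prob %||% 0
  sd_mm <- motion_params$spike_sd_mm %||% 0
  gain <- motion_params$spike_gain %||% 0
  drift <- motion_params$drift_sd_mm %||% 0
  steps <- matrix(0, n_timepoints, 6)
  if (drift > 0) {
    # continuous low-amplitude drift (breathing/settling); keeps the
    # Friston-24 design generically full rank
    steps[, 1:3] <- matrix(stats::rnorm(3 * n_timepoints, sd = drift),
                           n_timepoints, 3)
    steps[, 4:6] <- matrix(stats::rnorm(3 * n_timepoints, sd = drift / 100),
                           n_timepoints, 3)
    steps[1, ] <- 0
  }
  if (p > 0 && sd_mm > 0) {
    hit <- stats::rbinom(n_timepoints, 1, p)
    hit[1] <- 0  # motion trace starts at zeros
    jump <- hit * matrix(stats::rnorm(3 * n_timepoints, sd = sd_mm),
                         n_timepoints, 3)
    steps[, 1:3] <- steps[, 1:3] + jump
    steps[, 4:6] <- steps[, 4:6] +
      hit * matrix(stats::rnorm(3 * n_timepoints, sd = sd_mm / 100),
                   n_timepoints, 3)
    spike <- rowSums(abs(jump))
    ts <- ts + gain * spike  # motion-locked global intensity spike
  }
  motion <- apply(steps, 2, cumsum)

  structure(list(subject_id = subject_id, session = session,
                 timeseries = ts, motion = motion, nuisance = nuis,
                 tr_seconds = tr_seconds),
            class = "sim_scan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default diagnostic-cohort configuration
#'
#' Group sizes and covariate distributions mirror the diagnostic sample used
#' to build the classifier (35 ROP patients, 56 healthy controls; female
#' proportions 13/35 and 36/56; per-group premorbid IQ and age moments as
#' reported for that sample), so the premorbid-IQ/diagnosis confound the
#' deconfounding step has to handle is present by default. The planted
#' connectivity contrast defaults to the strong-effect regime (100 affected
#' edges at delta = 0.4); set `delta = 0` for null cohorts.
#'
#' @param ... named overrides of any default field.
#' @return config list.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_hc = 56, n_rop = 35,
    n_rois = 160, n_affected_edges = 100, delta = 0.4,
    n_timepoints = 190, tr_seconds = 2,
    female_prop_hc = 36 / 56, female_prop_rop = 13 / 35,
    iq_mean_hc = 109.64, iq_sd_hc = 13.24,
    iq_mean_rop = 100.29, iq_sd_rop = 18.59,
    age_mean_hc = 30.64, age_sd_hc = 6.78,
    age_mean_rop = 30.43, age_sd_rop = 6.15,
    confound_strength = 0,
    motion_params = list(spike_prob = 0.03, spike_sd_mm = 0.3,
                         spike_gain = 1, drift_sd_mm = 0.005),
    nuisance_params = list(amplitude = 1)
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  cfg
}

#' Simulate a diagnostic cohort (one baseline scan per subject)
#'
#' Draws per-subject covariates from the configured group distributions and
#' one T0 scan per subject from the group-specific covariance.
#' `confound_strength` adds an extra downward premorbid-IQ shift (in
#' within-group SD units) to patients on top of the configured group means,
#' to exercise the covariate-deconfounding step at controlled strength.
#'
#' @param config list from [cohort_config()].
#' @param seed integer seed; identical (config, seed) gives a bit-identical
#'   cohort.
#' @return list with `cohort` (data.frame: subject_id, group, sex, age,
#'   premorbid_iq, subgroup, shift), `scans` (list of `sim_scan`), `hc_cov`,
#'   `rop_cov`, `cov_spec`.
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(config$n_hc >= 1, config$n_rop >= 1)
  set.seed(seed)
  gc_seed <- sample.int(2^31 - 1, 1)
  gc <- build_group_covariance(config$n_rois, config$n_affected_edges,
                               config$delta, seed = gc_seed)
  set.seed(seed + 1)
  n <- config$n_hc + config$n_rop
  group <- factor(rep(c("HC", "ROP"), c(config$n_hc, config$n_rop)),
                  levels = c("HC", "ROP"))
  is_rop <- group == "ROP"
  sex <- ifelse(stats::runif(n) < ifelse(is_rop, config$female_prop_rop,
                                         config$female_prop_hc), "F", "M")
  iq <- ifelse(is_rop,
               stats::rnorm(n, config$iq_mean_rop, config$iq_sd_rop),
               stats::rnorm(n, config$iq_mean_hc, config$iq_sd_hc))
  iq <- iq - config$confound_strength * config$iq_sd_rop * is_rop
  age <- ifelse(is_rop,
                stats::rnorm(n, config$age_mean_rop, config$age_sd_rop),
                stats::rnorm(n, config$age_mean_hc, config$age_sd_hc))
  cohort <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = group, sex = factor(sex, levels = c("F", "M")),
    age = age, premorbid_iq = iq,
    subgroup = factor(rep("none", n),
                      levels = c("maintainer", "improver", "none")),
    shift = 0, stringsAsFactors = FALSE
  )
  scan_seeds <- sample.int(2^31 - 1, n)
  scans <- lapply(seq_len(n), function(k) {
    simulate_scan(if (is_rop[k]) gc$rop_cov else gc$hc_cov,
                  config$n_timepoints, config$tr_seconds,
                  config$motion_params, config$nuisance_params,
                  seed = scan_seeds[k],
                  subject_id = cohort$subject_id[k], session = "T0")
  })
  list(cohort = cohort, scans = scans,
       hc_cov = gc$hc_cov, rop_cov = gc$rop_cov, cov_spec = gc$spec)
}

#' Simulate the follow-up scan of an intervention subject
#'
#' The follow-up spatial covariance interpolates between the patient and
#' healthy-control matrices: `cov_FU = rop_cov + shift * (hc_cov - rop_cov)`,
#' PD-projected. A shift of 1 yields the healthy covariance (full
#' normalization of the disease perturbation), 0 the patient covariance, and
#' negative values a worsening beyond the patient pattern.
#'
#' @param subject one row of an intervention cohort (must be ROP with a
#'   non-"none" subgroup).
#' @param hc_cov,rop_cov group covariances from [build_group_covariance()].
#' @param shift per-subject normalization fraction in \[-1, 1\].
#' @param seed integer seed.
#' @param ... passed to [simulate_scan()].
#' @return a `sim_scan` with `session = "FU"`.
#' @export
simulate_followup_pair <- function(subject, hc_cov, rop_cov, shift,
                                   seed = NULL, ...) {
  stopifnot(shift >= -1, shift <= 1)
  if (!identical(as.character(subject$group), "ROP") ||
      identical(as.character(subject$subgroup), "none"))
    stop("follow-up scans are only simulated for ROP intervention subjects")
  fu_cov <- project_pd(rop_cov + shift * (hc_cov - rop_cov))
  simulate_scan(fu_cov, seed = seed, subject_id = subject$subject_id,
                session = "FU", ...)
}

#' Default behavioral effect specification
#'
#' `a` is the attention gain of maintainers irrespective of hyperplane
#' shift direction; `b` couples the improvers' attention gain to their
#' planted normalization shift; `noise_sd` is the gain noise SD;
#' `learning_gap` separates improver from maintainer learning scores (in
#' noise-SD units). Defaults define the strong-effect regime used by the
#' recovery checks and were fixed by an upfront power analysis (see the
#' methods vignette).
#'
#' @param ... named overrides.
#' @export
behavioral_effect_spec <- function(...) {
  spec <- list(a = 0.4, b = 2.0, noise_sd = 0.4, learning_gap = 3,
               domains = c("attention", "working_memory", "verbal_learning",
                           "processing_speed", "social_cognition"))
  over <- list(...)
  stopifnot(all(names(over) %in% names(spec)))
  spec[names(over)] <- over
  spec
}

#' Simulate behavioral outcomes for an intervention cohort
#'
#' Learning scores are drawn N(0, 1) for maintainers and
#' N(`learning_gap`, 1) for improvers. The attention gain (FU - T0) follows
#' `a * 1[maintainer] + b * shift * 1[improver] + noise`; all other domains
#' change by pure noise. Baseline (T0) domain scores are independent
#' standard normals. This is the generator's own minimal structure matching
#' a subgroup-by-shift-direction interaction; it is synthetic and not a
#' claim about real training data.
#'
#' @param cohort intervention cohort data.frame carrying `subgroup` and
#'   `shift`.
#' @param effect_spec list from [behavioral_effect_spec()].
#' @param seed integer seed.
#' @return the cohort with `learning_score` and `<domain>_T0`/`<domain>_FU`
#'   columns appended.
#' @export
simulate_behavioral_outcomes <- function(cohort,
                                         effect_spec = behavioral_effect_spec(),
                                         seed = 1) {
  stopifnot(all(cohort$subgroup != "none"), !is.null(cohort$shift))
  set.seed(seed)
  n <- nrow(cohort)
  imp <- cohort$subgroup == "improver"
  cohort$learning_score <- stats::rnorm(n) + effect_spec$learning_gap * imp
  for (d in effect_spec$domains) {
    t0 <- stats::rnorm(n)
    gain <- if (d == "attention") {
      effect_spec$a * (!imp) + effect_spec$b * cohort$shift * imp +
        stats::rnorm(n, sd = effect_spec$noise_sd)
    } else {
      stats::rnorm(n, sd = effect_spec$noise_sd)
    }
    cohort[[paste0(d, "_T0")]] <- t0
    cohort[[paste0(d, "_FU")]] <- t0 + gain
  }
  cohort
}

#' Default intervention-cohort configuration
#'
#' 26 patients split 14 maintainers / 12 improvers as in the training
#' sample. Improver shifts are drawn N(0.25, 0.6) and maintainer shifts
#' N(0, 0.45) (clipped to \[-1, 1\]): improvers tend to normalize toward
#' the healthy covariance (about one third still shift in the
#' psychosis-like direction) while maintainers hover around no change, so
#' both shift directions occur in both subgroups.
#'
#' @param ... named overrides.
#' @export
intervention_config <- function(...) {
  cfg <- list(
    n_maintainer = 14, n_improver = 12,
    shift_mean_improver = 0.25, shift_sd_improver = 0.6,
    shift_mean_maintainer = 0, shift_sd_maintainer = 0.45,
    n_rois = 160, n_timepoints = 190, tr_seconds = 2,
    iq_mean = 99, iq_sd = 15, age_mean = 26.8, age_sd = 6.4,
    female_prop = 11 / 26,
    motion_params = list(spike_prob = 0.03, spike_sd_mm = 0.3,
                         spike_gain = 1, drift_sd_mm = 0.005),
    nuisance_params = list(amplitude = 1),
    effect_spec = behavioral_effect_spec()
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  cfg
}

#' Simulate a paired-session intervention cohort
#'
#' All subjects are patients; each receives a T0 scan drawn from the patient
#' covariance and an FU scan drawn from the per-subject shift-interpolated
#' covariance ([simulate_followup_pair()]), plus behavioral outcomes
#' ([simulate_behavioral_outcomes()]).
#'
#' @param config list from [intervention_config()].
#' @param hc_cov,rop_cov the group covariances the diagnostic classifier was
#'   trained against (must match `config$n_rois`).
#' @param seed integer seed.
#' @return list with `cohort`, `scans_t0`, `scans_fu`.
#' @export
simulate_intervention_cohort <- function(config = intervention_config(),
                                         hc_cov, rop_cov, seed = 1) {
  stopifnot(nrow(hc_cov) == config$n_rois, nrow(rop_cov) == config$n_rois)
  set.seed(seed)
  n <- config$n_maintainer + config$n_improver
  subgroup <- factor(rep(c("maintainer", "improver"),
                         c(config$n_maintainer, config$n_improver)),
                     levels = c("maintainer", "improver", "none"))
  imp <- subgroup == "improver"
  shift <- stats::rnorm(n,
                        ifelse(imp, config$shift_mean_improver,
                               config$shift_mean_maintainer),
                        ifelse(imp, config$shift_sd_improver,
                               config$shift_sd_maintainer))
  shift <- pmin(pmax(shift, -1), 1)
  cohort <- data.frame(
    subject_id = sprintf("I%03d", seq_len(n)),
    group = factor("ROP", levels = c("HC", "ROP")),
    sex = factor(ifelse(stats::runif(n) < config$female_prop, "F", "M"),
                 levels = c("F", "M")),
    age = stats::rnorm(n, config$age_mean, config$age_sd),
    premorbid_iq = stats::rnorm(n, config$iq_mean, config$iq_sd),
    subgroup = subgroup, shift = shift, stringsAsFactors = FALSE
  )
  seeds <- matrix(sample.int(2^31 - 1, 2 * n), n, 2)
  scans_t0 <- lapply(seq_len(n), function(k) {
    simulate_scan(rop_cov, config$n_timepoints, config$tr_seconds,
                  config$motion_params, config$nuisance_params,
                  seed = seeds[k, 1], subject_id = cohort$subject_id[k],
                  session = "T0")
  })
  scans_fu <- lapply(seq_len(n), function(k) {
    simulate_followup_pair(cohort[k, ], hc_cov, rop_cov, shift = shift[k],
                           seed = seeds[k, 2],
                           n_timepoints = config$n_timepoints,
                           tr_seconds = config$tr_seconds,
                           motion_params = config$motion_params,
                           nuisance_params = config$nuisance_params)
  })
  beh_seed <- sample.int(2^31 - 1, 1)
  cohort <- simulate_behavioral_outcomes(cohort, config$effect_spec,
                                         seed = beh_seed)
  list(cohort = cohort, scans_t0 = scans_t0, scans_fu = scans_fu)
}
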