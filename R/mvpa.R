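# Internal: covariate design matrix (intercept, male indicator, premorbid
# IQ). The same construction is used at training and at application time so
# stored betas transfer to new subjects.
.covar_design <- function(covariates) {
  sex <- covariates$sex
  male <- if (is.numeric(sex)) sex else as.numeric(factor(sex, levels = c("F", "M"))) - 1
  cbind(intercept = 1, male = male, premorbid_iq = covariates$premorbid_iq)
}

# Internal: stratified fold assignment. Returns an integer fold id per
# element of `labels`, each class dealt out as evenly as possible.
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Build a repeated nested double cross-validation scheme
#'
#' An outer cycle (CV2) estimates generalizability; within each outer
#' training partition an inner cycle (CV1) generates the model ensemble.
#' Both cycles are stratified by class and repeated over independent fold
#' permutations. If a class is too small for the requested fold count, k is
#' reduced with a warning (never silently).
#'
#' @param labels factor with levels `c("HC", "ROP")`.
#' @param k_outer,perm_outer outer folds and permutations (default 10, 10).
#' @param k_inner,perm_inner inner folds and permutations (default 10, 10).
#' @param seed integer seed; assignments are reproducible from it.
#' @return object of class `cv_scheme`: list with `outer` (list per outer
#'   permutation of fold-id vectors over all subjects), `inner` (nested list
#'   `[[perm]][[fold]][[inner_perm]]` of fold-id vectors over that branch's
#'   outer-training subjects), the effective fold counts, and `n`.
#' @export
build_nested_cv <- function(labels, k_outer = 10, perm_outer = 10,
                            k_inner = 10, perm_inner = 10, seed = 1) {
  labels <- droplevels(as.factor(labels))
  stopifnot(nlevels(labels) == 2)
  set.seed(seed)
  n <- length(labels)
  min_class <- min(table(labels))
  if (min_class < 2) stop("need at least 2 subjects per class")
  if (k_outer > min_class) {
    warning(sprintf("k_outer reduced from %d to %d (smallest class)",
                    k_outer, min_class))
    k_outer <- min_class
  }
  # the smallest inner training class has about min_class * (k_outer-1)/k_outer
  min_inner <- floor(min_class * (k_outer - 1) / k_outer)
  if (k_inner > min_inner) {
    warning(sprintf("k_inner reduced from %d to %d (smallest inner class)",
                    k_inner, max(2, min_inner)))
    k_inner <- max(2, min_inner)
  }
  outer <- lapply(seq_len(perm_outer), function(p) .stratified_folds(labels, k_outer))
  inner <- lapply(seq_len(perm_outer), function(p) {
    lapply(seq_len(k_outer), function(f) {
      train_idx <- which(outer[[p]] != f)
      lapply(seq_len(perm_inner), function(q)
        .stratified_folds(droplevels(labels[train_idx]), k_inner))
    })
  })
  structure(list(outer = outer, inner = inner, n = n,
                 k_outer = k_outer, perm_outer = perm_outer,
                 k_inner = k_inner, perm_inner = perm_inner, seed = seed),
            class = "cv_scheme")
}

#' Fit the in-fold preprocessing and linear SVM of one CV1 training partition
#'
#' The full chain is fitted exclusively on the supplied training rows:
#' zero-variance feature pruning, per-feature ordinary-least-squares
#' residualization of sex and premorbid IQ (the deconfounding step; betas
#' are stored and reapplied to test subjects), PCA retaining the leading
#' components explaining `pca_var` of training variance, 0-1 scaling of the
#' component scores by training min/max, and a soft-margin linear SVM with
#' class weights inversely proportional to class frequency
#' (`n_total / (2 n_class)`) at fixed cost `C`. The stored hyperplane is
#' oriented so positive decision scores mean ROP.
#'
#' @param train_features n x p matrix.
#' @param train_labels factor, levels `c("HC", "ROP")`, both present.
#' @param train_covariates data.frame with `sex` and `premorbid_iq`.
#' @param C SVM cost (default 1).
#' @param pca_var fraction of training variance retained (default 0.8).
#' @return object of class `fold_model` holding every parameter needed to
#'   score an arbitrary vector: `variance_mask`, `covariate_betas`,
#'   `pca_mean`, `pca_basis`, `n_components`, `pc_min`, `pc_range`, `w`,
#'   `b`, `class_weights`.
#' @export
fit_fold_pipeline <- function(train_features, train_labels, train_covariates,
                              C = 1, pca_var = 0.8) {
  X <- as.matrix(train_features)
  y <- factor(train_labels, levels = c("HC", "ROP"))
  if (nlevels(droplevels(y)) < 2) stop("training partition needs both classes")
  n <- nrow(X)

  v <- apply(X, 2, stats::var)
  mask <- is.finite(v) & v > 1e-12
  if (!any(mask)) stop("all features pruned as zero-variance")
  X <- X[, mask, drop = FALSE]

  D <- .covar_design(train_covariates)
  betas <- qr.coef(qr(D), X)
  betas[is.na(betas)] <- 0      # collinear covariate directions contribute 0
  Xr <- X - D %*% betas

  mu <- colMeans(Xr)
  Xc <- sweep(Xr, 2, mu)
  sv <- svd(Xc, nu = 0)
  var_share <- sv$d^2 / sum(sv$d^2)
  k <- which(cumsum(var_share) >= pca_var)[1]
  if (is.na(k)) k <- length(sv$d)
  k <- max(1, min(k, sum(sv$d > 1e-10)))
  basis <- sv$v[, seq_len(k), drop = FALSE]

  scores <- Xc %*% basis
  pc_min <- apply(scores, 2, min)
  pc_range <- apply(scores, 2, max) - pc_min
  flat <- pc_range < 1e-12
  pc_range[flat] <- 1           # degenerate component: carried but inert
  S <- sweep(sweep(scores, 2, pc_min), 2, pc_range, "/")

  tab <- table(y)
  cw <- as.numeric(n / (2 * tab)); names(cw) <- names(tab)
  fit <- e1071::svm(S, y, kernel = "linear", cost = C, scale = FALSE,
                    class.weights = cw)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm's positive decision side is the first class seen in the data;
  # read it off the decision-value column name and enforce positive = ROP.
  dv <- attr(stats::predict(fit, S[1, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  pos_class <- strsplit(colnames(dv), "/")[[1]][1]
  if (pos_class != "ROP") { w <- -w; b <- -b }

  structure(list(variance_mask = mask, covariate_betas = betas,
                 pca_mean = mu, pca_basis = basis, n_components = k,
                 pc_min = pc_min, pc_range = pc_range,
                 scale_degenerate = flat, w = w, b = b,
                 class_weights = cw, levels = c("HC", "ROP")),
            class = "fold_model")
}

# Internal: score a matrix of raw edge vectors with one fold model.
# `D` is the precomputed covariate design for the rows of `X`.
.apply_fold_matrix <- function(model, X, D) {
  X <- X[, model$variance_mask, drop = FALSE]
  Xr <- X - D %*% model$covariate_betas
  pc <- sweep(Xr, 2, model$pca_mean) %*% model$pca_basis
  S <- sweep(sweep(pc, 2, model$pc_min), 2, model$pc_range, "/")
  S[S < -0.5] <- -0.5          # bound extrapolation outside training range
  S[S > 1.5] <- 1.5
  as.numeric(S %*% model$w + model$b)
}

#' Score one feature vector with a fold model
#'
#' Applies the stored preprocessing (variance mask, covariate
#' residualization with the subject's own sex/IQ, PCA projection, 0-1
#' scaling with training bounds, scaled values clamped to \[-0.5, 1.5\])
#' and returns the linear decision score `w . z + b`. Positive scores mean
#' the ROP side of the hyperplane.
#'
#' @param model a `fold_model`.
#' @param feature_vector raw edge vector, same length as the training
#'   feature space.
#' @param covariates one-row data.frame (or list) with `sex` and
#'   `premorbid_iq`.
#' @return decision score (numeric scalar).
#' @export
apply_fold_model <- function(model, feature_vector, covariates) {
  if (length(feature_vector) != length(model$variance_mask))
    stop("feature vector length does not match the training edge space")
  if (is.null(covariates$sex) || is.null(covariates$premorbid_iq) ||
      is.na(covariates$premorbid_iq))
    stop("missing covariates (sex, premorbid_iq)")
  D <- .covar_design(covariates)
  .apply_fold_matrix(model, matrix(feature_vector, 1), D)
}

#' Train the repeated nested cross-validated classifier ensemble
#'
#' Fits one [fit_fold_pipeline()] model per CV1 training partition of every
#' CV2 branch, giving `k_outer * perm_outer * k_inner * perm_inner` fold
#' models when all partitions are trainable.
#'
#' @param features n x p edge matrix.
#' @param labels factor, levels `c("HC", "ROP")`.
#' @param covariates data.frame with `sex`, `premorbid_iq` (n rows).
#' @param scheme a `cv_scheme` from [build_nested_cv()], or NULL to build
#'   one from `scheme_params` and `seed`.
#' @param scheme_params list of `k_outer`, `perm_outer`, `k_inner`,
#'   `perm_inner` used when `scheme` is NULL.
#' @param C,pca_var hyperparameters passed to [fit_fold_pipeline()].
#' @param seed integer seed for the scheme.
#' @return object of class `svm_ensemble`: `models` (list of `fold_model`),
#'   `coords` (data.frame outer_perm/outer_fold/inner_perm/inner_fold),
#'   `scheme`, `levels`.
#' @export
train_rsfc_classifier <- function(features, labels, covariates,
                                  scheme = NULL,
                                  scheme_params = list(k_outer = 10,
                                                       perm_outer = 10,
                                                       k_inner = 10,
                                                       perm_inner = 10),
                                  C = 1, pca_var = 0.8, seed = 1) {
  X <- as.matrix(features)
  y <- factor(labels, levels = c("HC", "ROP"))
  if (is.null(scheme))
    scheme <- build_nested_cv(y, scheme_params$k_outer, scheme_params$perm_outer,
                              scheme_params$k_inner, scheme_params$perm_inner,
                              seed = seed)
  models <- list(); coords <- list(); m <- 0L
  for (p in seq_len(scheme$perm_outer)) {
    for (f in seq_len(scheme$k_outer)) {
      train_idx <- which(scheme$outer[[p]] != f)
      for (q in seq_len(scheme$perm_inner)) {
        inner_fold <- scheme$inner[[p]][[f]][[q]]
        for (g in seq_len(scheme$k_inner)) {
          cv1_train <- train_idx[inner_fold != g]
          m <- m + 1L
          models[[m]] <- fit_fold_pipeline(X[cv1_train, , drop = FALSE],
                                           y[cv1_train],
                                           covariates[cv1_train, , drop = FALSE],
                                           C = C, pca_var = pca_var)
          coords[[m]] <- data.frame(outer_perm = p, outer_fold = f,
                                    inner_perm = q, inner_fold = g)
        }
      }
    }
  }
  structure(list(models = models, coords = do.call(rbind, coords),
                 scheme = scheme, levels = c("HC", "ROP"),
                 C = C, pca_var = pca_var),
            class = "svm_ensemble")
}

#' Ensemble prediction by majority voting
#'
#' In `cv2` mode each subject is scored only by fold models from outer
#' branches whose test fold contained that subject (so no model ever scores
#' a subject it was trained with); in `oocv` mode every fold model scores
#' every subject. The vote is the majority of model-wise decision-score
#' signs; a tied vote falls to the sign of the mean score, and an exactly
#' zero mean is called HC (the negative class).
#'
#' @param ensemble an `svm_ensemble`.
#' @param features n x p edge matrix.
#' @param covariates data.frame with `sex`, `premorbid_iq`.
#' @param mode `"cv2"` (held-out scoring within the training sample) or
#'   `"oocv"` (external application of the frozen ensemble).
#' @return data.frame with `mean_score`, `vote` (factor HC/ROP),
#'   `n_models`.
#' @export
predict_ensemble <- function(ensemble, features, covariates,
                             mode = c("cv2", "oocv")) {
  mode <- match.arg(mode)
  X <- as.matrix(features)
  n <- nrow(X)
  D <- .covar_design(covariates)
  scores <- vapply(ensemble$models,
                   function(m) .apply_fold_matrix(m, X, D),
                   numeric(n))
  scores <- matrix(scores, nrow = n)   # n x n_models
  if (mode == "cv2") {
    if (n != ensemble$scheme$n)
      stop("cv2 mode requires the original training sample")
    keep <- vapply(seq_len(nrow(ensemble$coords)), function(m) {
      co <- ensemble$coords[m, ]
      ensemble$scheme$outer[[co$outer_perm]] == co$outer_fold
    }, logical(n))
    keep <- matrix(keep, nrow = n)
  } else {
    keep <- matrix(TRUE, n, ncol(scores))
  }
  if (any(rowSums(keep) == 0)) stop("subject scored by zero models")
  mean_score <- rowSums(scores * keep) / rowSums(keep)
  pos <- rowSums((scores > 0) & keep)
  neg <- rowSums((scores < 0) & keep)
  vote <- ifelse(pos > neg, "ROP",
                 ifelse(pos < neg, "HC",
                        ifelse(mean_score > 0, "ROP", "HC")))
  data.frame(mean_score = mean_score,
             vote = factor(vote, levels = c("HC", "ROP")),
             n_models = rowSums(keep))
}

#' Classification performance report
#'
#' Sensitivity is recall on ROP, specificity recall on HC, and balanced
#' accuracy their mean; all reported in percent.
#'
#' @param votes factor of predicted classes (HC/ROP).
#' @param scores per-subject mean decision scores (carried through).
#' @param labels true classes.
#' @param permutation_p optional permutation p-value to attach.
#' @param n_permutations optional permutation count.
#' @return list of class `classification_report` with `bac`, `sensitivity`,
#'   `specificity` (percent), `per_subject` table, `permutation_p`,
#'   `n_permutations`.
#' @export
classification_report <- function(votes, scores, labels,
                                  permutation_p = NA_real_,
                                  n_permutations = NA_integer_) {
  labels <- factor(labels, levels = c("HC", "ROP"))
  votes <- factor(votes, levels = c("HC", "ROP"))
  if (any(table(labels) == 0)) stop("a class is absent from the labels")
  sens <- 100 * mean(votes[labels == "ROP"] == "ROP")
  spec <- 100 * mean(votes[labels == "HC"] == "HC")
  structure(list(bac = (sens + spec) / 2, sensitivity = sens,
                 specificity = spec,
                 per_subject = data.frame(label = labels, vote = votes,
                                          mean_score = scores),
                 permutation_p = permutation_p,
                 n_permutations = n_permutations),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("BAC %.2f%% (sensitivity %.2f%%, specificity %.2f%%)\n",
              x$bac, x$sensitivity, x$specificity))
  if (is.finite(x$permutation_p))
    cat(sprintf("permutation p = %.4g (%d permutations)\n",
                x$permutation_p, x$n_permutations))
  invisible(x)
}

# Internal: one full nested-CV run -> cross-validated BAC.
.nested_cv_bac <- function(X, y, covariates, scheme_params, C, pca_var, seed) {
  ens <- train_rsfc_classifier(X, y, covariates,
                               scheme_params = scheme_params,
                               C = C, pca_var = pca_var, seed = seed)
  pred <- predict_ensemble(ens, X, covariates, mode = "cv2")
  rep <- classification_report(pred$vote, pred$mean_score, y)
  rep$bac
}

#' Permutation test of classifier significance
#'
#' Class labels are permuted across the whole sample and the full nested-CV
#' balanced accuracy is recomputed for each permutation (fold schemes are
#' re-stratified on the permuted labels). The p-value uses the add-one
#' estimator `p = (1 + #[BAC_perm >= BAC_obs]) / (1 + n_perm)`, which is
#' never exactly zero.
#'
#' @param features,labels,covariates as in [train_rsfc_classifier()].
#' @param scheme_params nested-CV shape.
#' @param C,pca_var pipeline hyperparameters.
#' @param n_perm number of label permutations (>= 1).
#' @param seed integer seed (also seeds the observed run's scheme).
#' @return list with `p_value`, `observed_bac`, `perm_bac` (vector),
#'   `n_perm`.
#' @export
permutation_test <- function(features, labels, covariates,
                             scheme_params = list(k_outer = 10,
                                                  perm_outer = 10,
                                                  k_inner = 10,
                                                  perm_inner = 10),
                             C = 1, pca_var = 0.8, n_perm = 1000, seed = 1) {
  stopifnot(n_perm >= 1)
  X <- as.matrix(features)
  y <- factor(labels, levels = c("HC", "ROP"))
  obs <- .nested_cv_bac(X, y, covariates, scheme_params, C, pca_var, seed)
  perm_bac <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(seed + 7919 * b)
    y_b <- sample(y)
    perm_bac[b] <- .nested_cv_bac(X, y_b, covariates, scheme_params,
                                  C, pca_var, seed = seed + b)
  }
  list(p_value = (1 + sum(perm_bac >= obs)) / (1 + n_perm),
       observed_bac = obs, perm_bac = perm_bac, n_perm = n_perm)
}

#' Cross-validation-ratio feature reliability map
#'
#' Each fold model's hyperplane weight vector is back-projected from
#' component space to the edge space (un-scaled through the stored 0-1
#' scaling slope, then through the PCA basis); edges pruned by that model's
#' variance mask contribute weight 0. Reliability of an edge is the mean
#' back-projected weight across all models divided by its standard error
#' (the CV ratio). Under the positive-score-means-ROP convention, a
#' positive mean weight marks an edge whose stronger connectivity pushes
#' toward the ROP side.
#'
#' @param ensemble an `svm_ensemble` with at least 2 models.
#' @return data.frame (one row per edge): `edge`, `i`, `j`, `mean_weight`,
#'   `se`, `cv_ratio`, `percentile` (of |CV ratio|; NA for flagged edges),
#'   `direction` (`ROP>HC` / `HC>ROP`), `flagged` (TRUE where SE = 0 gave a
#'   non-finite ratio; excluded from percentile ranking with a warning).
#' @export
feature_reliability <- function(ensemble) {
  n_models <- length(ensemble$models)
  if (n_models < 2) stop("need at least 2 models for a standard error")
  p <- length(ensemble$models[[1]]$variance_mask)
  W <- matrix(0, n_models, p)
  for (m in seq_len(n_models)) {
    mod <- ensemble$models[[m]]
    w_pc <- mod$w / mod$pc_range
    W[m, mod$variance_mask] <- as.numeric(mod$pca_basis %*% w_pc)
  }
  mean_w <- colMeans(W)
  se <- apply(W, 2, stats::sd) / sqrt(n_models)
  cv_ratio <- ifelse(se > 0, mean_w / se,
                     ifelse(mean_w == 0, 0, Inf * sign(mean_w)))
  flagged <- !is.finite(cv_ratio)
  if (any(flagged))
    warning(sprintf("%d edge(s) with zero weight SE flagged and excluded from percentile ranking",
                    sum(flagged)))
  percentile <- rep(NA_real_, p)
  ok <- !flagged
  percentile[ok] <- 100 * rank(abs(cv_ratio[ok])) / sum(ok)
  n_rois <- (1 + sqrt(1 + 8 * p)) / 2
  ei <- if (n_rois == round(n_rois)) edge_index_table(n_rois) else
    data.frame(edge = seq_len(p), i = NA_integer_, j = NA_integer_)
  data.frame(ei, mean_weight = mean_w, se = se, cv_ratio = cv_ratio,
             percentile = percentile,
             direction = factor(ifelse(mean_w >= 0, "ROP>HC", "HC>ROP"),
                                levels = c("HC>ROP", "ROP>HC")),
             flagged = flagged)
}

#' Top-k most reliable edges
#'
#' Ranks edges by absolute CV ratio (flagged edges excluded) and returns
#' the leading `k` rows of the reliability table.
#'
#' @param reliability output of [feature_reliability()].
#' @param k number of edges (default 20).
#' @export
top_reliable_edges <- function(reliability, k = 20) {
  ok <- reliability[!reliability$flagged, ]
  ok[order(-abs(ok$cv_ratio)), ][seq_len(min(k, nrow(ok))), ]
}
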