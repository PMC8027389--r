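#' Out-of-sample scoring with a frozen ensemble
#'
#' Applies every fold model of the ensemble, unmodified, to external
#' subjects and returns the per-subject mean decision score. No ensemble
#' parameter is ever updated: the call is a pure function of
#' (ensemble, data). Each fold model residualizes covariates with its own
#' stored training betas applied to the external subject's sex and IQ.
#'
#' @param ensemble an `svm_ensemble` trained on the diagnostic sample.
#' @param session_features n x p edge matrix for one session.
#' @param covariates data.frame with `sex`, `premorbid_iq`.
#' @return numeric vector of mean decision scores (positive = more
#'   psychosis-like).
#' @export
score_oocv <- function(ensemble, session_features, covariates) {
  if (ncol(as.matrix(session_features)) !=
      length(ensemble$models[[1]]$variance_mask))
    stop("feature space does not match the trained ensemble")
  predict_ensemble(ensemble, session_features, covariates,
                   mode = "oocv")$mean_score
}

#' Platt calibration of decision scores
#'
#' Maximum-likelihood fit of the two-parameter logistic map
#' `p(ROP | s) = 1 / (1 + exp(A s + B))` to labelled decision scores, with
#' Platt's smoothed targets `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)` so the fit
#' stays finite even for perfectly separated scores. Fitted by Newton
#' iterations with step halving on the cross-entropy objective. The fit is
#' performed on the diagnostic sample only and then applied unchanged to
#' external scores.
#'
#' @param train_scores decision scores of the diagnostic sample.
#' @param train_labels factor HC/ROP (ROP is the positive class).
#' @return object of class `platt_model` with `A`, `B`.
#' @export
platt_calibrate <- function(train_scores, train_labels) {
  y <- factor(train_labels, levels = c("HC", "ROP"))
  if (any(table(y) == 0)) stop("both classes are required for calibration")
  s <- as.numeric(train_scores)
  n_pos <- sum(y == "ROP"); n_neg <- sum(y == "HC")
  t_hi <- (n_pos + 1) / (n_pos + 2); t_lo <- 1 / (n_neg + 2)
  t <- ifelse(y == "ROP", t_hi, t_lo)

  nll <- function(a, b) {
    f <- a * s + b
    # -sum(t*log(p) + (1-t)*log(1-p)) with p = 1/(1+exp(f)), stable form:
    # log(1+exp(f)) - (1-t)*f
    sum(log1p(exp(-abs(f))) + pmax(f, 0) - (1 - t) * f)
  }
  a <- 0; b <- log((n_neg + 1) / (n_pos + 1))
  obj <- nll(a, b)
  for (it in 1:200) {
    f <- a * s + b
    p <- 1 / (1 + exp(f))
    g <- c(sum(s * (t - p)), sum(t - p))  # d nll / d(a,b)
    wgt <- p * (1 - p)
    H <- matrix(c(sum(s^2 * wgt), sum(s * wgt),
                  sum(s * wgt), sum(wgt) + 1e-12), 2, 2)
    step <- tryCatch(solve(H, -g), error = function(e) -g)
    lambda <- 1
    repeat {
      a2 <- a + lambda * step[1]; b2 <- b + lambda * step[2]
      o2 <- nll(a2, b2)
      if (o2 <= obj + 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (abs(obj - o2) < 1e-12 && max(abs(c(a2 - a, b2 - b))) < 1e-10) {
      a <- a2; b <- b2; break
    }
    a <- a2; b <- b2; obj <- o2
  }
  structure(list(A = a, B = b), class = "platt_model")
}

#' Apply a Platt calibration model
#'
#' @param model a `platt_model`.
#' @param scores decision scores.
#' @return calibrated probabilities of ROP in (0, 1), monotone in the
#'   score.
#' @export
platt_apply <- function(model, scores) {
  1 / (1 + exp(model$A * scores + model$B))
}

#' Psychosis-likeness change between two sessions
#'
#' `delta = score_FU - score_T0` under the frozen classifier. A positive
#' delta is a shift in the more psychosis-like direction across the
#' hyperplane, a negative delta a shift in the more healthy-like direction;
#' an exact zero is direction "none".
#'
#' @param score_T0,score_FU decision-score vectors (finite).
#' @return data.frame with `delta` and `direction` (factor
#'   healthy-like/psychosis-like/none).
#' @export
likeness_change <- function(score_T0, score_FU) {
  stopifnot(length(score_T0) == length(score_FU),
            all(is.finite(score_T0)), all(is.finite(score_FU)))
  delta <- score_FU - score_T0
  direction <- ifelse(delta > 0, "psychosis-like",
                      ifelse(delta < 0, "healthy-like", "none"))
  data.frame(delta = delta,
             direction = factor(direction,
                                levels = c("healthy-like", "psychosis-like",
                                           "none")))
}

#' Per-subject decision records for paired sessions
#'
#' Scores both sessions out-of-sample with the frozen ensemble, calibrates
#' scores to probabilities, and attaches the likeness change and shift
#' direction. Subjects missing either session are excluded with a message.
#'
#' @param ensemble trained `svm_ensemble`.
#' @param features_T0,features_FU edge matrices with matching rownames
#'   (subject ids).
#' @param covariates data.frame with `subject_id`, `sex`, `premorbid_iq`.
#' @param calibration a `platt_model` (from the diagnostic sample), or NULL
#'   to skip probabilities.
#' @return data.frame: `subject_id`, `score_T0`, `score_FU`, `prob_T0`,
#'   `prob_FU`, `delta`, `direction`.
#' @export
decision_records <- function(ensemble, features_T0, features_FU, covariates,
                             calibration = NULL) {
  ids <- covariates$subject_id
  have <- ids %in% rownames(features_T0) & ids %in% rownames(features_FU)
  if (any(!have))
    message(sprintf("%d subject(s) excluded: missing a session", sum(!have)))
  ids <- ids[have]
  cov <- covariates[have, , drop = FALSE]
  s0 <- score_oocv(ensemble, features_T0[ids, , drop = FALSE], cov)
  s1 <- score_oocv(ensemble, features_FU[ids, , drop = FALSE], cov)
  lc <- likeness_change(s0, s1)
  out <- data.frame(subject_id = ids, score_T0 = s0, score_FU = s1,
                    prob_T0 = NA_real_, prob_FU = NA_real_,
                    delta = lc$delta, direction = lc$direction)
  if (!is.null(calibration)) {
    out$prob_T0 <- platt_apply(calibration, s0)
    out$prob_FU <- platt_apply(calibration, s1)
  }
  out
}

#' Shift-direction by subgroup contingency analysis
#'
#' Cross-tabulates sensory-processing subgroup against the direction of the
#' hyperplane shift and tests the association with an uncorrected
#' chi-square ([chi_square_2x2()]). Records with direction "none" are
#' excluded from the test with a message; a warning is raised if any
#' expected count is below 5.
#'
#' @param records output of [decision_records()].
#' @param subgroup factor (maintainer/improver) aligned with `records`.
#' @return list with `table` (2 x 2 counts), `n_excluded_none`, `test` (a
#'   `stat_result`).
#' @export
shift_contingency <- function(records, subgroup) {
  stopifnot(nrow(records) == length(subgroup))
  subgroup <- droplevels(factor(subgroup))
  keep <- records$direction != "none"
  if (any(!keep))
    message(sprintf("%d record(s) with zero delta excluded from the contingency test",
                    sum(!keep)))
  tab <- table(subgroup[keep], droplevels(records$direction[keep]))
  if (!all(dim(tab) == c(2, 2)))
    stop("contingency table is not 2x2 (a subgroup or direction is empty)")
  test <- chi_square_2x2(unclass(tab))
  list(table = tab, n_excluded_none = sum(!keep), test = test)
}
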