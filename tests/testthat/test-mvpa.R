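test_that("nested CV schemes partition and stratify correctly", {
  y <- factor(rep(c("HC", "ROP"), c(56, 35)), levels = c("HC", "ROP"))
  sch <- build_nested_cv(y, seed = 3)
  expect_equal(length(sch$outer), 10)
  expect_equal(sch$k_outer, 10)
  for (p in seq_along(sch$outer)) {
    # every subject sits in exactly one outer test fold per permutation
    expect_equal(sort(unique(sch$outer[[p]])), 1:10)
    expect_equal(length(sch$outer[[p]]), 91)
    # stratification: every fold holds subjects of both classes
    tab <- table(sch$outer[[p]], y)
    expect_true(all(tab > 0))
  }
  sch2 <- build_nested_cv(y, seed = 3)
  expect_identical(sch, sch2)

  small <- factor(rep(c("HC", "ROP"), c(12, 4)), levels = c("HC", "ROP"))
  expect_warning(build_nested_cv(small, k_outer = 10, perm_outer = 1,
                                 k_inner = 2, perm_inner = 1, seed = 1),
                 "k_outer reduced")
})

test_that("no subject appears in both CV1 training and its CV2 test fold", {
  y <- factor(rep(c("HC", "ROP"), c(14, 10)), levels = c("HC", "ROP"))
  sch <- build_nested_cv(y, k_outer = 4, perm_outer = 2, k_inner = 3,
                         perm_inner = 2, seed = 5)
  for (p in seq_len(sch$perm_outer)) for (f in seq_len(sch$k_outer)) {
    train_idx <- which(sch$outer[[p]] != f)
    test_idx <- which(sch$outer[[p]] == f)
    for (q in seq_len(sch$perm_inner)) {
      inner <- sch$inner[[p]][[f]][[q]]
      expect_equal(length(inner), length(train_idx))
      for (g in seq_len(sch$k_inner)) {
        cv1_train <- train_idx[inner != g]
        expect_length(intersect(cv1_train, test_idx), 0)
      }
    }
  }
})

test_that("the fold pipeline separates blobs, prunes and deconfounds", {
  set.seed(7)
  n <- 40
  X <- rbind(matrix(rnorm(n, -2, 0.3), n / 2, 2),
             matrix(rnorm(n, 2, 0.3), n / 2, 2))
  y <- factor(rep(c("HC", "ROP"), each = n / 2), levels = c("HC", "ROP"))
  cov <- data.frame(sex = sample(c("F", "M"), n, TRUE),
                    premorbid_iq = rnorm(n, 100, 10))
  m <- fit_fold_pipeline(X, y, cov, pca_var = 0.99)
  s <- vapply(seq_len(n), function(i)
    apply_fold_model(m, X[i, ], cov[i, ]), 0)
  vote <- ifelse(s > 0, "ROP", "HC")
  expect_equal(mean(vote == y), 1)  # training BAC 100% on separable blobs

  # constant feature is pruned by the variance mask
  X2 <- cbind(X, 7)
  m2 <- fit_fold_pipeline(X2, y, cov, pca_var = 0.99)
  expect_false(m2$variance_mask[3])

  # a feature built from IQ is decorrelated from IQ after residualization
  X3 <- cbind(X, 2 * cov$premorbid_iq + rnorm(n, sd = 0.1))
  m3 <- fit_fold_pipeline(X3, y, cov, pca_var = 0.99)
  D <- cbind(1, as.numeric(cov$sex == "M"), cov$premorbid_iq)
  resid3 <- X3[, 3] - D %*% m3$covariate_betas[, 3]
  expect_lt(abs(cor(resid3, cov$premorbid_iq)), 0.01)

  expect_error(fit_fold_pipeline(matrix(1, 10, 3),
                                 factor(rep(c("HC", "ROP"), 5),
                                        levels = c("HC", "ROP")),
                                 no_covars(10)), "pruned")
})

test_that("fold-model scores are the stated affine chain", {
  m <- identity_fold_model(w = c(1, 0), b = -0.5)
  expect_equal(apply_fold_model(m, c(0.7, 0.3), no_covars(1)), 0.2)

  # brute-force re-implementation of the preprocessing chain
  set.seed(11)
  n <- 30; p <- 12
  X <- matrix(rnorm(n * p), n, p)
  X[, 4] <- 0  # exercised variance mask
  y <- factor(rep(c("HC", "ROP"), each = n / 2), levels = c("HC", "ROP"))
  cov <- data.frame(sex = sample(c("F", "M"), n, TRUE),
                    premorbid_iq = rnorm(n, 100, 10))
  mod <- fit_fold_pipeline(X, y, cov, pca_var = 0.8)
  oracle_score <- function(x, cv) {
    z <- x[mod$variance_mask]
    d <- c(1, as.numeric(cv$sex == "M"), cv$premorbid_iq)
    z <- z - as.numeric(d %*% mod$covariate_betas)
    pc <- as.numeric((z - mod$pca_mean) %*% mod$pca_basis)
    s <- (pc - mod$pc_min) / mod$pc_range
    s <- pmin(pmax(s, -0.5), 1.5)
    sum(mod$w * s) + mod$b
  }
  for (r in 1:10) {
    x <- rnorm(p); cv <- data.frame(sex = "M", premorbid_iq = rnorm(1, 100))
    expect_equal(apply_fold_model(mod, x, cv), oracle_score(x, cv),
                 tolerance = 1e-10)
  }

  # the most ROP-ward training subject has the largest positive score
  scores <- vapply(seq_len(n), function(i)
    apply_fold_model(mod, X[i, ], cov[i, ]), 0)
  expect_equal(which.max(scores),
               which.max(vapply(seq_len(n), function(i)
                 oracle_score(X[i, ], cov[i, ]), 0)))

  expect_error(apply_fold_model(mod, rnorm(p + 1), cov[1, ]), "length")
  expect_error(apply_fold_model(mod, rnorm(p),
                                data.frame(sex = "F",
                                           premorbid_iq = NA_real_)),
               "covariates")
})

test_that("majority voting follows the tie rules", {
  ens_agree <- identity_ensemble(list(identity_fold_model(1, 0.5),
                                      identity_fold_model(1, 0.2)))
  x <- matrix(0.5, 1, 1)
  pr <- predict_ensemble(ens_agree, x, no_covars(1), mode = "oocv")
  expect_equal(as.character(pr$vote), "ROP")

  # 50/50 split with negative mean -> HC
  ens_tie <- identity_ensemble(list(identity_fold_model(1, -1.4),
                                    identity_fold_model(1, 0)))
  pr2 <- predict_ensemble(ens_tie, x, no_covars(1), mode = "oocv")
  expect_equal(pr2$mean_score, -0.2, tolerance = 1e-12)
  expect_equal(as.character(pr2$vote), "HC")

  # mean of +1 and -1 is zero -> HC by the exact-zero rule
  ens_zero <- identity_ensemble(list(identity_fold_model(1, 0.5),
                                     identity_fold_model(1, -1.5)))
  pr3 <- predict_ensemble(ens_zero, x, no_covars(1), mode = "oocv")
  expect_equal(pr3$mean_score, 0)
  expect_equal(as.character(pr3$vote), "HC")
})

test_that("classification reports compute balanced accuracy", {
  y <- factor(rep(c("HC", "ROP"), each = 10), levels = c("HC", "ROP"))
  rp <- classification_report(y, rep(0, 20), y)
  expect_equal(rp$bac, 100)

  set.seed(13)
  n <- 2000
  yl <- factor(sample(rep(c("HC", "ROP"), n / 2)), levels = c("HC", "ROP"))
  vt <- sample(yl)  # shuffled votes: chance-level
  rs <- classification_report(vt, rep(0, n), yl)
  expect_gt(rs$bac, 46); expect_lt(rs$bac, 54)

  expect_error(classification_report(y, rep(0, 20),
                                     factor(rep("ROP", 20),
                                            levels = c("HC", "ROP"))),
               "absent")
})

test_that("permutation p-values follow the add-one estimator", {
  st <- tiny_study(seed = 77)
  res <- permutation_test(st$features, st$cohort$group, st$cohort,
                          scheme_params = tiny_scheme(), n_perm = 19,
                          seed = 4)
  expect_equal(res$p_value,
               (1 + sum(res$perm_bac >= res$observed_bac)) / 20)
  # the planted strong effect clearly beats the permuted labels
  expect_gt(res$observed_bac, max(res$perm_bac))
  expect_equal(res$p_value, 1 / 20)
})

test_that("feature reliability matches a hand computation", {
  W <- rbind(c(1, 2, 0), c(3, 2, 0), c(5, 2, 0), c(7, 2, 0), c(9, 2, 0))
  models <- lapply(seq_len(nrow(W)), function(m)
    identity_fold_model(W[m, ], b = 0))
  ens <- identity_ensemble(models)
  rel <- suppressWarnings(feature_reliability(ens))
  expect_equal(rel$mean_weight, c(5, 2, 0))
  expect_equal(rel$se, c(sd(c(1, 3, 5, 7, 9)) / sqrt(5), 0, 0))
  expect_equal(rel$cv_ratio[1], 5 / (sd(c(1, 3, 5, 7, 9)) / sqrt(5)),
               tolerance = 1e-12)
  # SE = 0 with nonzero mean is flagged; zero mean with zero spread is 0
  expect_true(rel$flagged[2])
  expect_false(rel$flagged[3])
  expect_equal(rel$cv_ratio[3], 0)
  expect_warning(feature_reliability(ens), "flagged")

  # opposite weights across two models: mean 0, CV ratio 0
  ens2 <- identity_ensemble(list(identity_fold_model(c(1, 1, 0), 0),
                                 identity_fold_model(c(-1, 1, 0), 0)))
  rel2 <- suppressWarnings(feature_reliability(ens2))
  expect_equal(rel2$mean_weight[1], 0)
  expect_equal(rel2$cv_ratio[1], 0)

  expect_error(feature_reliability(identity_ensemble(
    list(identity_fold_model(1, 0)))), "2 models")
})

test_that("back-projected edge weights reproduce the PC-space score", {
  st <- tiny_study(seed = 19)
  ens <- train_rsfc_classifier(st$features, st$cohort$group, st$cohort,
                               scheme_params = list(k_outer = 2,
                                                    perm_outer = 1,
                                                    k_inner = 2,
                                                    perm_inner = 1),
                               seed = 2)
  mod <- ens$models[[1]]
  w_edge <- as.numeric(mod$pca_basis %*% (mod$w / mod$pc_range))
  const <- mod$b - sum(mod$w * mod$pc_min / mod$pc_range)
  # score a training-range vector (no clamping active) both ways
  i <- 5
  x <- st$features[i, ]
  d <- cbind(1, as.numeric(st$cohort$sex[i] == "M"),
             st$cohort$premorbid_iq[i])
  z <- x[mod$variance_mask] - as.numeric(d %*% mod$covariate_betas)
  s_edge <- sum((z - mod$pca_mean) * w_edge) + const
  s_chain <- apply_fold_model(mod, x, st$cohort[i, ])
  expect_equal(s_edge, s_chain, tolerance = 1e-8)
})

test_that("test-partition rows never influence fitted fold models", {
  skip_if_not_installed("rlang")
  st <- tiny_study(seed = 23, n_hc = 12, n_rop = 10)
  sp <- list(k_outer = 2, perm_outer = 1, k_inner = 2, perm_inner = 1)
  ens1 <- train_rsfc_classifier(st$features, st$cohort$group, st$cohort,
                                scheme_params = sp, seed = 6)
  # corrupt the features of outer fold 1's test subjects only
  test_rows <- which(ens1$scheme$outer[[1]] == 1)
  X2 <- st$features
  X2[test_rows, ] <- matrix(rnorm(length(test_rows) * ncol(X2)),
                            length(test_rows))
  ens2 <- train_rsfc_classifier(X2, st$cohort$group, st$cohort,
                                scheme_params = sp, seed = 6)
  affected <- which(ens1$coords$outer_fold == 1)
  for (m in affected) {
    expect_identical(rlang::hash(ens1$models[[m]]),
                     rlang::hash(ens2$models[[m]]))
  }
})

test_that("cross-validated BAC rises monotonically with the planted effect", {
  med_bac <- function(delta) {
    median(vapply(1:5, function(s) {
      st <- tiny_study(seed = 100 + s, n_rois = 12, n_hc = 20, n_rop = 20,
                       n_affected_edges = 20, delta = delta,
                       n_timepoints = 96)
      ens <- train_rsfc_classifier(st$features, st$cohort$group, st$cohort,
                                   scheme_params = tiny_scheme(), seed = s)
      pred <- predict_ensemble(ens, st$features, st$cohort, mode = "cv2")
      classification_report(pred$vote, pred$mean_score,
                            st$cohort$group)$bac
    }, 0))
  }
  b0 <- med_bac(0); b1 <- med_bac(0.25); b2 <- med_bac(0.5)
  expect_lte(b0, b1)
  expect_lte(b1, b2)
  expect_gte(b2, 80)
})
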