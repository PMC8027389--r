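test_that("pooled t agrees between summary and raw-vector routes", {
  # identical summaries: t = 0, p = 1
  r0 <- pooled_t(mean1 = 5, sd1 = 2, n1 = 10, mean2 = 5, sd2 = 2, n2 = 12)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  # hand-checkable case: pooled SD 1, SE 1
  r1 <- pooled_t(mean1 = 1, sd1 = 1, n1 = 2, mean2 = 0, sd2 = 1, n2 = 2)
  expect_equal(r1$statistic, 1)
  expect_equal(r1$df, 2)

  set.seed(41)
  x <- rnorm(14, 1); y <- rnorm(19)
  r_raw <- pooled_t(x, y)
  r_sum <- pooled_t(mean1 = mean(x), sd1 = sd(x), n1 = length(x),
                    mean2 = mean(y), sd2 = sd(y), n2 = length(y))
  expect_equal(r_raw$statistic, r_sum$statistic, tolerance = 1e-10)
  expect_equal(r_raw$p, r_sum$p, tolerance = 1e-10)
  # oracle: base t.test with equal variances
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r_raw$statistic, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r_raw$p, tt$p.value, tolerance = 1e-10)

  expect_error(pooled_t(mean1 = 1, sd1 = 0, n1 = 5, mean2 = 2, sd2 = 0,
                        n2 = 5), "infinite")
})

test_that("2x2 chi-square equals the score-statistic formula", {
  formula_chisq <- function(m) {
    sum(m) * (m[1, 1] * m[2, 2] - m[1, 2] * m[2, 1])^2 /
      prod(rowSums(m), colSums(m))
  }
  m1 <- matrix(c(10, 0, 0, 10), 2)
  expect_equal(chi_square_2x2(m1)$statistic, 20, tolerance = 1e-12)
  expect_equal(chi_square_2x2(m1)$statistic, formula_chisq(m1),
               tolerance = 1e-12)

  prop <- matrix(c(10, 20, 5, 10), 2)  # proportional rows
  expect_equal(chi_square_2x2(prop)$statistic, 0, tolerance = 1e-12)

  set.seed(42)
  for (r in 1:10) {
    m <- matrix(rpois(4, 20) + 5, 2)
    expect_equal(suppressWarnings(chi_square_2x2(m))$statistic,
                 formula_chisq(m), tolerance = 1e-10)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_warning(chi_square_2x2(matrix(c(2, 3, 3, 2), 2)), "below 5")
})

test_that("mixed ANOVA matches the aov split-plot oracle on balanced data", {
  set.seed(43)
  n <- 40
  grp <- factor(rep(c("a", "b"), each = n / 2))
  gain <- ifelse(grp == "a", 1, 0)
  t0 <- rnorm(n, sd = 0.5)
  fu <- t0 + gain + rnorm(n, sd = 0.5)
  res <- mixed_anova_2x2(t0, fu, data.frame(grp = grp))

  # independent split-plot oracle via aov with an Error stratum
  long <- data.frame(y = c(t0, fu),
                     time = factor(rep(c("T0", "FU"), each = n)),
                     grp = rep(grp, 2), id = factor(rep(1:n, 2)))
  or <- summary(stats::aov(y ~ grp * time + Error(id), data = long))
  f_grp <- or[["Error: id"]][[1]]["grp", "F value"]
  f_time <- or[["Error: Within"]][[1]]["time", "F value"]
  f_int <- or[["Error: Within"]][[1]]["grp:time", "F value"]
  expect_equal(res$grp$statistic, f_grp, tolerance = 1e-8)
  expect_equal(res$time$statistic, f_time, tolerance = 1e-8)
  expect_equal(res[["time:grp"]]$statistic, f_int, tolerance = 1e-8)

  # sums of squares partition the total variation
  ss_effects <- sum(vapply(res, function(r) r$ss, 0))
  ss_err <- sum(attr(res, "ss_error"))
  expect_equal(ss_effects + ss_err, attr(res, "grand_ss_total"),
               tolerance = 1e-8)
})

test_that("mixed ANOVA interaction F matches a brute-force cell-means oracle", {
  set.seed(44)
  n <- 40
  a <- factor(rep(c("m", "i"), each = n / 2))
  b <- factor(rep(c("h", "p"), n / 2))
  gain <- ifelse(a == "i" & b == "h", 1, 0)
  t0 <- rnorm(n, sd = 0.5)
  fu <- t0 + gain + rnorm(n, sd = 0.5)
  res <- mixed_anova_2x2(t0, fu, data.frame(a = a, b = b))

  # brute-force: the three-way (time x a x b) interaction from the
  # difference scores' cell means, balanced design
  d <- fu - t0
  cell <- tapply(d, list(a, b), mean)
  contrast <- (cell["i", "h"] - cell["i", "p"]) -
    (cell["m", "h"] - cell["m", "p"])
  nc <- n / 4
  ss_int <- nc * contrast^2 / 4
  ss_err <- sum((d - ave(d, interaction(a, b)))^2)
  f_oracle <- (ss_int / 1) / (ss_err / (n - 4))
  expect_equal(res[["time:a:b"]]$statistic, f_oracle, tolerance = 1e-8)

  # identical cell means (with residual noise): all F effectively zero
  flat0 <- rnorm(n); flat1 <- rnorm(n)
  flat0 <- flat0 - ave(flat0, a)
  flat1 <- flat1 - ave(flat1, a)
  res_flat <- mixed_anova_2x2(flat0, flat1, data.frame(a = a))
  expect_lt(res_flat$a$statistic, 1e-20)
  expect_lt(res_flat[["time:a"]]$statistic, 1e-20)

  expect_error(mixed_anova_2x2(t0[1:5], fu[1:5],
                               data.frame(a = factor(c("m", "m", "m", "m",
                                                       "i")))),
               "fewer than 2")
})

test_that("mixed ANOVA p-values are uniform under label permutation", {
  set.seed(45)
  n <- 32
  t0 <- rnorm(n); fu <- t0 + rnorm(n)
  grp <- factor(rep(c("a", "b"), each = n / 2))
  ps <- vapply(1:200, function(k) {
    g <- sample(grp)
    mixed_anova_2x2(t0, fu, data.frame(g = g))[["time:g"]]$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("ANCOVA matches the nested-model oracle", {
  set.seed(46)
  n <- 26
  grp <- factor(rep(c("m", "i"), each = n / 2))
  cov0 <- rnorm(n)
  y <- 0.5 * cov0 + 1.0 * (grp == "i") + rnorm(n, sd = 0.5)
  res <- ancova_oneway(y, grp, cov0)
  or <- anova(lm(y ~ cov0), lm(y ~ cov0 + grp))
  expect_equal(res$statistic, or$F[2], tolerance = 1e-8)
  expect_equal(res$p, or$`Pr(>F)`[2], tolerance = 1e-8)
  expect_equal(res$df, c(1, n - 3))

  # identical groups -> exactly zero group effect
  v <- rnorm(n / 2); w <- rnorm(n / 2)
  res0 <- ancova_oneway(c(v, v), grp, c(w, w))
  expect_lt(res0$statistic, 1e-16)

  expect_error(ancova_oneway(y, grp, as.numeric(grp == "i")), "collinear")
})

test_that("paired t and Cohen's d handle change scores and degenerates", {
  r0 <- paired_t_cohens_d(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$effect_size, 0)

  r1 <- paired_t_cohens_d(rep(0, 4), c(2, 0, 2, 0))
  expect_equal(r1$effect_size, 1 / sd(c(2, 0, 2, 0)), tolerance = 1e-12)
  expect_equal(round(r1$effect_size, 3), 0.866)
  # oracle: base paired t.test
  tt <- t.test(c(2, 0, 2, 0), rep(0, 4), paired = TRUE)
  expect_equal(r1$statistic, unname(tt$statistic), tolerance = 1e-10)

  expect_error(paired_t_cohens_d(c(1, 2, 3), c(2, 3, 4)), "undefined")
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(fdr_bh(0.03), 0.03)
  expect_equal(fdr_bh(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(fdr_bh(rep(1, 5)), rep(1, 5))

  # brute-force step-up oracle with monotonicity enforcement
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n); out[o] <- pmin(adj, 1); out
  }
  set.seed(47)
  for (r in 1:10) {
    p <- runif(12)^2
    expect_equal(fdr_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
  # order-preserving, monotone and capped at 1
  p <- runif(10)
  adj <- fdr_bh(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  expect_true(all(adj <= 1) && all(adj >= p))
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("z-scoring masks only beyond-threshold outliers", {
  tab <- data.frame(attention = c(0, 0, 0, 10))
  z <- zscore_and_exclude(tab, "attention")
  expect_equal(z$z$attention[4], 1.5)
  expect_equal(unname(z$n_excluded["attention"]), 0)

  set.seed(48)
  big <- data.frame(attention = rnorm(50))
  big$attention[50] <- mean(big$attention[1:49]) + 3 * sd(big$attention[1:49])
  z2 <- suppressMessages(zscore_and_exclude(big, "attention"))
  expect_true(z2$mask[50, "attention"])

  expect_error(zscore_and_exclude(data.frame(a = rep(1, 5)), "a"),
               "variance")
})

test_that("median split follows the maintainer tie rule", {
  s <- median_split(c(1, 2, 3, 4))
  expect_equal(as.character(s), c("maintainer", "maintainer", "improver",
                                  "improver"))
  expect_warning(s2 <- median_split(c(1, 2, 2, 3)), "tie")
  expect_equal(sum(s2 == "maintainer"), 3)
  expect_equal(sum(s2 == "improver"), 1)
  expect_error(median_split(rep(3, 4)), "identical")

  set.seed(49)
  planted <- rep(c("maintainer", "improver"), each = 13)
  scores <- rnorm(26, sd = 1) + 6 * (planted == "improver")
  expect_equal(as.character(median_split(scores)), planted)
})

test_that("stat results round-trip through their tabular form", {
  r <- pooled_t(mean1 = 1, sd1 = 2, n1 = 10, mean2 = 0, sd2 = 2, n2 = 12,
                name = "demo")
  row <- as.data.frame(r)
  back <- stat_result_from_row(row)
  expect_equal(back$statistic, r$statistic)
  expect_equal(back$df, r$df)
  expect_equal(back$p, r$p)
  expect_equal(back$name, r$name)

  r2 <- ancova_oneway(rnorm(10), factor(rep(c("a", "b"), 5)), rnorm(10))
  back2 <- stat_result_from_row(as.data.frame(r2))
  expect_equal(back2$df, r2$df)
})
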