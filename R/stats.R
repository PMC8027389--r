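#' Construct a named statistical result
#'
#' Light container used across the battery: a named statistic with its
#' value, degrees of freedom (one or two numbers), p-value, optional effect
#' size (Cohen's d where applicable) and a multiple-testing correction tag.
#'
#' @param name label of the test.
#' @param statistic numeric test statistic.
#' @param df degrees of freedom (length 1 or 2).
#' @param p p-value in \[0, 1\].
#' @param effect_size optional Cohen's d (NA when not applicable).
#' @param correction `"raw"` or `"fdr"`.
#' @param ss optional sums of squares carried by ANOVA results.
#' @export
stat_result <- function(name, statistic, df, p, effect_size = NA_real_,
                        correction = "raw", ss = NULL) {
  stopifnot(p >= 0, p <= 1 + 1e-12, all(df > 0))
  structure(list(name = name, statistic = statistic, df = df,
                 p = min(p, 1), effect_size = effect_size,
                 correction = correction, ss = ss),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: stat = %.4g, df = %s, p = %.4g%s [%s]\n", x$name,
              x$statistic, paste(round(x$df, 2), collapse = ","), x$p,
              if (is.finite(x$effect_size))
                sprintf(", d = %.3f", x$effect_size) else "",
              x$correction))
  invisible(x)
}

#' @export
as.data.frame.stat_result <- function(x, ...) {
  data.frame(name = x$name, statistic = x$statistic,
             df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
             p = x$p, effect_size = x$effect_size,
             correction = x$correction, stringsAsFactors = FALSE)
}

#' Rebuild a stat_result from its one-row data.frame form
#'
#' Inverse of the `as.data.frame` method (sums of squares are not carried
#' through the tabular form).
#'
#' @param row one-row data.frame as produced by `as.data.frame`.
#' @export
stat_result_from_row <- function(row) {
  df <- if (is.na(row$df2)) row$df1 else c(row$df1, row$df2)
  stat_result(row$name, row$statistic, df, row$p, row$effect_size,
              row$correction)
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance and `df = n1 + n2 - 2`, two-sided.
#' Accepts either raw vectors (`x`, `y`) or summary statistics; the two
#' routes agree exactly. Zero pooled variance with equal means gives t = 0;
#' with unequal means the (infinite) statistic is flagged as an error.
#'
#' @param x,y optional raw sample vectors.
#' @param mean1,sd1,n1,mean2,sd2,n2 summary statistics, used when `x` is
#'   missing.
#' @param name result label.
#' @return a `stat_result`.
#' @export
pooled_t <- function(x, y, mean1, sd1, n1, mean2, sd2, n2,
                     name = "pooled_t") {
  if (!missing(x)) {
    stopifnot(!missing(y))
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2)
      return(stat_result(name, 0, df, 1))
    stop("zero pooled variance with unequal means: infinite t")
  }
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  stat_result(name, t, df, 2 * stats::pt(-abs(t), df))
}

#' Pearson chi-square test for a 2x2 table (no continuity correction)
#'
#' @param counts 2 x 2 matrix of nonnegative integer counts with positive
#'   margins.
#' @param name result label.
#' @return a `stat_result` with df = 1. Warns if any expected count is
#'   below 5.
#' @export
chi_square_2x2 <- function(counts, name = "chi_square") {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == 2), all(counts >= 0),
            all(abs(counts - round(counts)) < 1e-9))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in contingency table")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5))
    warning("expected count below 5; chi-square approximation may be poor")
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  stat_result(name, as.numeric(res$statistic), 1, res$p.value)
}

#' Mixed-design (split-plot) ANOVA with two timepoints
#'
#' Two-level within factor (time: T0 vs FU) crossed with one or two
#' two-level between-subject factors. With exactly two timepoints the
#' design decomposes exactly: between-subject effects are tested on the
#' per-subject session mean and within-subject (time and time-by-group)
#' effects on the session difference, both with Type III sums of squares
#' (car). Complete cases only; every cell must hold at least 2 subjects.
#'
#' @param outcome_T0,outcome_FU numeric vectors (paired by position).
#' @param between_factors data.frame of 1 or 2 two-level factors.
#' @return named list of `stat_result`s: one per between effect, `time`,
#'   and one `time:<effect>` per between effect/interaction. Each result
#'   carries its sums of squares (observation scale) in `$ss`; `attr(,
#'   "ss_error")` holds the between and within error SS so the full
#'   partition can be checked.
#' @export
mixed_anova_2x2 <- function(outcome_T0, outcome_FU, between_factors) {
  bf <- as.data.frame(between_factors)
  stopifnot(ncol(bf) %in% 1:2, length(outcome_T0) == length(outcome_FU),
            nrow(bf) == length(outcome_T0))
  cc <- stats::complete.cases(outcome_T0, outcome_FU, bf)
  outcome_T0 <- outcome_T0[cc]; outcome_FU <- outcome_FU[cc]
  bf <- droplevels(bf[cc, , drop = FALSE])
  for (k in seq_len(ncol(bf))) {
    bf[[k]] <- factor(bf[[k]])
    if (nlevels(bf[[k]]) != 2) stop("between factors must have 2 levels")
  }
  cells <- interaction(bf, drop = FALSE)
  if (any(table(cells) < 2))
    stop(sprintf("cell(s) with fewer than 2 subjects: %s",
                 paste(names(which(table(cells) < 2)), collapse = ", ")))

  avg <- (outcome_T0 + outcome_FU) / 2
  dif <- outcome_FU - outcome_T0
  fml <- stats::as.formula(paste("y ~", paste(names(bf), collapse = "*")))
  ctr <- lapply(bf, function(f) "contr.sum")  # Type III needs sum contrasts

  dat_b <- cbind(y = avg, bf)
  fit_b <- stats::lm(fml, data = dat_b, contrasts = ctr)
  an_b <- car::Anova(fit_b, type = 3)
  dat_w <- cbind(y = dif, bf)
  fit_w <- stats::lm(fml, data = dat_w, contrasts = ctr)
  an_w <- car::Anova(fit_w, type = 3)

  out <- list()
  rows_b <- setdiff(rownames(an_b), c("(Intercept)", "Residuals"))
  for (r in rows_b)
    out[[r]] <- stat_result(r, an_b[r, "F value"],
                            c(an_b[r, "Df"], an_b["Residuals", "Df"]),
                            an_b[r, "Pr(>F)"],
                            ss = 2 * an_b[r, "Sum Sq"])
  out[["time"]] <- stat_result("time", an_w["(Intercept)", "F value"],
                               c(1, an_w["Residuals", "Df"]),
                               an_w["(Intercept)", "Pr(>F)"],
                               ss = 0.5 * an_w["(Intercept)", "Sum Sq"])
  for (r in rows_b)
    out[[paste0("time:", r)]] <-
      stat_result(paste0("time:", r), an_w[r, "F value"],
                  c(an_w[r, "Df"], an_w["Residuals", "Df"]),
                  an_w[r, "Pr(>F)"],
                  ss = 0.5 * an_w[r, "Sum Sq"])
  attr(out, "ss_error") <- c(between = 2 * an_b["Residuals", "Sum Sq"],
                             within = 0.5 * an_w["Residuals", "Sum Sq"])
  attr(out, "grand_ss_total") <-
    sum((c(outcome_T0, outcome_FU) - mean(c(outcome_T0, outcome_FU)))^2)
  out
}

#' One-way ANCOVA (group effect adjusted for a baseline covariate)
#'
#' F test of the two-level group factor on the follow-up outcome while
#' controlling for the baseline score, via the standard nested linear-model
#' decomposition (residual-sum-of-squares comparison).
#'
#' @param outcome_FU numeric outcome at follow-up.
#' @param group two-level factor.
#' @param covariate_T0 numeric baseline covariate.
#' @param name result label.
#' @return a `stat_result` with df = (1, n - 3).
#' @export
ancova_oneway <- function(outcome_FU, group, covariate_T0,
                          name = "ancova_group") {
  group <- droplevels(factor(group))
  stopifnot(nlevels(group) == 2,
            length(outcome_FU) == length(group),
            length(covariate_T0) == length(group))
  # perfect confounding between covariate and group makes the group effect
  # unidentifiable
  if (any(tapply(covariate_T0, group, stats::var) < 1e-24) ||
      abs(stats::cor(covariate_T0, as.numeric(group))) > 1 - 1e-12)
    stop("covariate is collinear with the group indicator")
  fit1 <- stats::lm(outcome_FU ~ covariate_T0 + group)
  fit0 <- stats::lm(outcome_FU ~ covariate_T0)
  rss1 <- sum(stats::resid(fit1)^2)
  rss0 <- sum(stats::resid(fit0)^2)
  df2 <- stats::df.residual(fit1)
  f <- (rss0 - rss1) / (rss1 / df2)
  stat_result(name, f, c(1, df2), stats::pf(f, 1, df2, lower.tail = FALSE))
}

#' Paired t-test with Cohen's d on change scores
#'
#' t on the within-subject changes; Cohen's d is the mean change divided by
#' the SD of the change. All-zero changes give t = 0, d = 0; a nonzero
#' constant change (zero change SD) is flagged as an error because d is
#' undefined.
#'
#' @param x_T0,x_FU paired numeric vectors.
#' @param name result label.
#' @return a `stat_result` with df = n - 1 and `effect_size` = d.
#' @export
paired_t_cohens_d <- function(x_T0, x_FU, name = "paired_t") {
  stopifnot(length(x_T0) == length(x_FU), length(x_T0) >= 2)
  ch <- x_FU - x_T0
  n <- length(ch)
  if (stats::sd(ch) == 0) {
    if (mean(ch) == 0) return(stat_result(name, 0, n - 1, 1, 0))
    stop("zero change variance with nonzero mean change: d undefined")
  }
  tt <- stats::t.test(ch)
  stat_result(name, as.numeric(tt$statistic), n - 1, tt$p.value,
              effect_size = mean(ch) / stats::sd(ch))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @export
fdr_bh <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Z-score cognitive domains and mask outliers
#'
#' Each domain column is z-scored against the study sample; subjects with
#' |z| > `threshold` (strictly) on a domain are masked for analyses of that
#' domain. Masking is reported via a message.
#'
#' @param outcomes data.frame.
#' @param domains character vector of domain column names.
#' @param threshold outlier cut in SD units (default 2).
#' @return list with `z` (data.frame of z-scored domains), `mask` (logical
#'   matrix, TRUE = excluded), `n_excluded` per domain.
#' @export
zscore_and_exclude <- function(outcomes, domains, threshold = 2) {
  stopifnot(all(domains %in% names(outcomes)))
  z <- outcomes
  mask <- matrix(FALSE, nrow(outcomes), length(domains),
                 dimnames = list(NULL, domains))
  for (d in domains) {
    v <- outcomes[[d]]
    if (sum(is.finite(v)) < 3) stop("need at least 3 subjects per domain")
    s <- stats::sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop(sprintf("zero variance in domain %s", d))
    z[[d]] <- (v - mean(v, na.rm = TRUE)) / s
    mask[, d] <- is.finite(z[[d]]) & abs(z[[d]]) > threshold
  }
  n_ex <- colSums(mask)
  if (any(n_ex > 0))
    message(sprintf("outlier masking (> %g SD): %s", threshold,
                    paste(sprintf("%s=%d", names(n_ex[n_ex > 0]),
                                  n_ex[n_ex > 0]), collapse = ", ")))
  list(z = z, mask = mask, n_excluded = n_ex)
}

#' Median split of learning scores into maintainers and improvers
#'
#' Scores strictly above the sample median are labelled improver, strictly
#' below maintainer; scores exactly at the median go to the maintainer
#' group with a warning.
#'
#' @param learning_scores numeric vector, n >= 2, not all identical.
#' @return factor with levels maintainer/improver.
#' @export
median_split <- function(learning_scores) {
  stopifnot(length(learning_scores) >= 2)
  if (max(learning_scores) == min(learning_scores))
    stop("all learning scores identical: no split possible")
  med <- stats::median(learning_scores)
  if (any(learning_scores == med))
    warning(sprintf("%d score(s) tie the median; assigned to maintainer",
                    sum(learning_scores == med)))
  factor(ifelse(learning_scores > med, "improver", "maintainer"),
         levels = c("maintainer", "improver"))
}
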