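# The statistical battery for background-subtracted intensity scores:
# group summaries with coefficients of variation, pooled and Welch
# t-tests, standard and Welch one-way ANOVA, Levene's test, Tukey HSD and
# Games-Howell post-hoc comparisons, contingency chi-squared, the
# sqrt-transform decision, Cohen's d, and noncentral-t power analysis.
#
# Every location test accepts either raw data or (n, mean, sd) summaries.
# Summary mode matters in practice: published group statistics rarely come
# with raw per-embryo data, yet t, F, effect size and power are all
# functions of the summaries alone.

#' Group summary: n, mean, sd and coefficient of variation
#'
#' Either computes the summary from raw values or wraps published
#' statistics.  The sd uses the n - 1 denominator and the CV is sd/mean
#' (undefined, `NA`, when the mean is 0).
#'
#' @param x Raw numeric values (optional if `n`, `mean`, `sd` given).
#' @param n,mean,sd Summary statistics, used when `x` is missing.
#' @param label Group label.
#' @return Object of class `"group_summary"`.
#' @export
group_summary <- function(x = NULL, n = NULL, mean = NULL, sd = NULL,
                          label = NA_character_) {
  if (!is.null(x)) {
    x <- x[!is.na(x)]
    if (length(x) < 2L) stop("need at least 2 values per group")
    n <- length(x); mean <- base::mean(x); sd <- stats::sd(x)
  } else {
    if (is.null(n) || is.null(mean) || is.null(sd))
      stop("supply raw values or all of n, mean, sd")
    if (n < 2L) stop("need n >= 2")
    if (sd < 0) stop("sd must be non-negative")
  }
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd,
                 cv = if (mean != 0) sd / mean else NA_real_),
            class = "group_summary")
}

as_group_summary <- function(x, label = NA_character_) {
  if (inherits(x, "group_summary")) x
  else group_summary(x = as.numeric(x), label = label)
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%s: n = %d, mean = %.4g, sd = %.4g, CV = %s\n",
              if (is.na(x$label)) "group" else x$label, x$n, x$mean, x$sd,
              if (is.na(x$cv)) "undefined" else sprintf("%.3g", x$cv)))
  invisible(x)
}

#' Summarize scores by group
#' @param values Numeric scores.
#' @param groups Group labels (same length).
#' @return data.frame with `group`, `n`, `mean`, `sd`, `cv`.
#' @export
summarize_groups <- function(values, groups) {
  groups <- as.character(groups)
  out <- lapply(split(values, groups), function(v)
    unclass(group_summary(v))[c("n", "mean", "sd", "cv")])
  df <- data.frame(group = names(out), do.call(rbind, lapply(out, as.data.frame)),
                   stringsAsFactors = FALSE, row.names = NULL)
  df[order(match(df$group, unique(groups))), , drop = FALSE]
}

new_test_result <- function(method, statistic, df, p_value, ...) {
  structure(c(list(method = method, statistic = statistic, df = df,
                   p_value = p_value), list(...)),
            class = "ish_test")
}

#' @export
print.ish_test <- function(x, ...) {
  dftxt <- if (length(x$df) == 2L)
    sprintf("df = %.4g, %.4g", x$df[1], x$df[2])
  else sprintf("df = %.4g", x$df)
  cat(sprintf("%s: %s = %.4g, %s, p = %.4g\n", x$method,
              if (!is.null(x$statistic_name)) x$statistic_name else "stat",
              x$statistic, dftxt, x$p_value))
  invisible(x)
}

## ---- two-sample t ------------------------------------------------------

#' Pooled-variance two-sample t-test (raw data or summaries)
#'
#' Classic equal-variance t with df = n1 + n2 - 2 and a two-sided p-value.
#' Degenerate case: zero pooled variance gives t = 0 (equal means) or an
#' infinite t, flagged in the result (unequal means).
#'
#' @param a,b Numeric vectors or [group_summary()] objects.
#' @return `"ish_test"` with `statistic` (t), `df`, `p_value`, `mean_diff`.
#' @export
pooled_t <- function(a, b) {
  a <- as_group_summary(a); b <- as_group_summary(b)
  df <- a$n + b$n - 2L
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
  diff <- a$mean - b$mean
  if (sp2 == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    t <- diff / sqrt(sp2 * (1 / a$n + 1 / b$n))
  }
  new_test_result("two-sample t-test (pooled variance)", t, df,
                  2 * stats::pt(-abs(t), df), statistic_name = "t",
                  mean_diff = diff, degenerate = !is.finite(t))
}

#' Welch two-sample t-test (raw data or summaries)
#'
#' Unequal-variance t with Welch-Satterthwaite fractional df.  When one
#' group has zero variance the df collapses towards n_other - 1.
#'
#' @inheritParams pooled_t
#' @return `"ish_test"` as for [pooled_t()].
#' @export
welch_t <- function(a, b) {
  a <- as_group_summary(a); b <- as_group_summary(b)
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  diff <- a$mean - b$mean
  if (va + vb == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    df <- a$n + b$n - 2
  } else {
    t <- diff / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  new_test_result("Welch two-sample t-test", t, df,
                  2 * stats::pt(-abs(t), df), statistic_name = "t",
                  mean_diff = diff, degenerate = !is.finite(t))
}

## ---- one-way ANOVA -----------------------------------------------------

summaries_from_groups <- function(groups) {
  if (inherits(groups, "group_summary")) groups <- list(groups)
  labs <- names(groups)
  if (is.null(labs)) labs <- paste0("group", seq_along(groups))
  out <- lapply(seq_along(groups), function(i)
    as_group_summary(groups[[i]], label = labs[i]))
  if (length(out) < 2L) stop("need at least 2 groups")
  out
}

#' Standard one-way ANOVA (raw data or summaries)
#'
#' Fixed-effects F with df (k - 1, N - k).  All between/within sums of
#' squares are functions of the group summaries, so summary input is exact.
#'
#' @param groups List of numeric vectors and/or [group_summary()] objects.
#' @return `"ish_test"` with `statistic` (F), `df` (length 2), `p_value`.
#' @export
one_way_anova <- function(groups) {
  s <- summaries_from_groups(groups)
  n <- vapply(s, `[[`, 0, "n"); m <- vapply(s, `[[`, 0, "mean")
  v <- vapply(s, `[[`, 0, "sd")^2
  k <- length(s); N <- sum(n)
  grand <- sum(n * m) / N
  ssb <- sum(n * (m - grand)^2)
  ssw <- sum((n - 1) * v)
  df <- c(k - 1, N - k)
  f <- if (ssw == 0) { if (ssb == 0) 0 else Inf }
       else (ssb / df[1]) / (ssw / df[2])
  new_test_result("one-way ANOVA", f, df,
                  stats::pf(f, df[1], df[2], lower.tail = FALSE),
                  statistic_name = "F", degenerate = !is.finite(f))
}

#' Welch one-way ANOVA (raw data or summaries)
#'
#' Variance-weighted means with numerator df k - 1 and a fractional
#' Satterthwaite-type denominator df; robust to unequal group variances.
#' A zero-variance group makes the weights infinite; this is flagged and
#' the statistic returned as `Inf`.
#'
#' @inheritParams one_way_anova
#' @return `"ish_test"` with `statistic` (F), `df` = c(k - 1, df2), `p_value`.
#' @export
welch_anova <- function(groups) {
  s <- summaries_from_groups(groups)
  n <- vapply(s, `[[`, 0, "n"); m <- vapply(s, `[[`, 0, "mean")
  v <- vapply(s, `[[`, 0, "sd")^2
  k <- length(s)
  if (any(v == 0)) {
    return(new_test_result("Welch one-way ANOVA", Inf, c(k - 1, NA_real_),
                           0, statistic_name = "F", degenerate = TRUE))
  }
  w <- n / v
  mw <- sum(w * m) / sum(w)
  a <- sum(w * (m - mw)^2) / (k - 1)
  lambda <- sum((1 - w / sum(w))^2 / (n - 1))
  b <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  f <- a / b
  df2 <- (k^2 - 1) / (3 * lambda)
  new_test_result("Welch one-way ANOVA", f, c(k - 1, df2),
                  stats::pf(f, k - 1, df2, lower.tail = FALSE),
                  statistic_name = "F", degenerate = FALSE)
}

#' Levene's test for equality of variances
#'
#' F-test on absolute deviations from the group center.  The default
#' center is the group mean (the SPSS default); `center = "median"` gives
#' the Brown-Forsythe variant.  Requires raw data.  All-constant input
#' returns W = 0 by convention.
#'
#' @param values Numeric scores.
#' @param groups Group labels.
#' @param center `"mean"` or `"median"`.
#' @return `"ish_test"` with `statistic` (W), `df`, `p_value`.
#' @export
levene <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  ctr <- if (center == "mean") tapply(values, groups, mean)
         else tapply(values, groups, stats::median)
  z <- abs(values - ctr[as.integer(groups)])
  k <- nlevels(groups); N <- length(values)
  if (all(z == 0) || stats::var(z) == 0) {
    return(new_test_result("Levene's test", 0, c(k - 1, N - k), 1,
                           statistic_name = "W", center = center))
  }
  fit <- stats::anova(stats::lm(z ~ groups))
  new_test_result("Levene's test", fit$`F value`[1],
                  c(fit$Df[1], fit$Df[2]), fit$`Pr(>F)`[1],
                  statistic_name = "W", center = center)
}

## ---- post-hoc ----------------------------------------------------------

pairwise_frame <- function(s, fun) {
  k <- length(s)
  rows <- list()
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    rows[[length(rows) + 1L]] <- fun(s[[i]], s[[j]])
  }
  do.call(rbind, rows)
}

#' Tukey HSD post-hoc comparisons (raw data or summaries)
#'
#' All pairwise comparisons using the studentized-range distribution with
#' the pooled within-group variance and df = N - k.  Unequal group sizes
#' use the Tukey-Kramer standard error.
#'
#' @param groups List of numeric vectors and/or [group_summary()] objects.
#' @param alpha Family significance level for the `reject` column.
#' @return data.frame: `group1`, `group2`, `diff`, `se`, `q`, `df`,
#'   `p_value`, `reject`; class `c("posthoc_result", "data.frame")`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  s <- summaries_from_groups(groups)
  k <- length(s)
  n <- vapply(s, `[[`, 0, "n")
  v <- vapply(s, `[[`, 0, "sd")^2
  dfw <- sum(n) - k
  msw <- sum((n - 1) * v) / dfw
  idx <- stats::setNames(seq_along(s), vapply(s, `[[`, "", "label"))
  out <- pairwise_frame(s, function(a, b) {
    se <- sqrt(msw / 2 * (1 / a$n + 1 / b$n))
    q <- abs(a$mean - b$mean) / se
    p <- stats::ptukey(q, k, dfw, lower.tail = FALSE)
    data.frame(group1 = a$label, group2 = b$label,
               diff = a$mean - b$mean, se = se, q = q, df = dfw,
               p_value = p, reject = p < alpha, stringsAsFactors = FALSE)
  })
  class(out) <- c("posthoc_result", "data.frame")
  attr(out, "method") <- "Tukey HSD"
  out
}

#' Games-Howell post-hoc comparisons (raw data or summaries)
#'
#' Pairwise comparisons for unequal variances: unpooled standard errors,
#' per-pair Welch-Satterthwaite df, and p-values from the studentized
#' range distribution with q = |t| * sqrt(2).
#'
#' @inheritParams tukey_hsd
#' @return data.frame as for [tukey_hsd()].
#' @export
games_howell <- function(groups, alpha = 0.05) {
  s <- summaries_from_groups(groups)
  k <- length(s)
  out <- pairwise_frame(s, function(a, b) {
    va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
    q <- abs(a$mean - b$mean) / se * sqrt(2)
    p <- stats::ptukey(q, k, df, lower.tail = FALSE)
    data.frame(group1 = a$label, group2 = b$label,
               diff = a$mean - b$mean, se = se, q = q, df = df,
               p_value = p, reject = p < alpha, stringsAsFactors = FALSE)
  })
  class(out) <- c("posthoc_result", "data.frame")
  attr(out, "method") <- "Games-Howell"
  out
}

#' @export
print.posthoc_result <- function(x, ...) {
  cat(attr(x, "method"), "post-hoc comparisons:\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

## ---- chi-squared -------------------------------------------------------

#' Contingency chi-squared test
#'
#' Pearson chi-squared on an r x c count table with df (r-1)(c-1); the
#' Yates continuity correction is applied iff the table is 2 x 2 and
#' `correct = TRUE` (the default).
#'
#' @param tab Matrix/table of non-negative integer counts, at least 2 x 2.
#' @param correct Apply the continuity correction to 2 x 2 tables.
#' @return `"ish_test"` with `statistic` (X-squared), `df`, `p_value`.
#' @export
chi_square <- function(tab, correct = TRUE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("table must be at least 2 x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal: expected counts undefined")
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  new_test_result(
    if (correct && all(dim(tab) == 2L))
      "chi-squared test (Yates continuity correction)"
    else "Pearson chi-squared test",
    unname(res$statistic), unname(res$parameter), res$p.value,
    statistic_name = "X-squared")
}

## ---- transform decision ------------------------------------------------

#' Decide and apply a square-root variance-stabilising transform
#'
#' Proxy for the visual Q-Q normality check: Shapiro-Wilk at `alpha`.
#' The transform is applied only when the sample is non-normal *and*
#' non-negative; data containing negative scores are never transformed
#' (sqrt is undefined there) and the rationale records this.
#'
#' @param values Numeric vector.
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @return List: `values` (possibly transformed), `transformed` (flag),
#'   `shapiro_p`, `rationale` (text).
#' @export
sqrt_transform_if_needed <- function(values, alpha = 0.05) {
  p <- stats::shapiro.test(values)$p.value
  if (p >= alpha) {
    return(list(values = values, transformed = FALSE, shapiro_p = p,
                rationale = sprintf(
                  "Shapiro-Wilk p = %.3g >= %.2g: consistent with normality, no transform", p, alpha)))
  }
  if (min(values) < 0) {
    warning("non-normal sample contains negative values; sqrt transform not applicable",
            call. = FALSE)
    return(list(values = values, transformed = FALSE, shapiro_p = p,
                rationale = sprintf(
                  "Shapiro-Wilk p = %.3g < %.2g but negative values present: sqrt transform skipped", p, alpha)))
  }
  list(values = sqrt(values), transformed = TRUE, shapiro_p = p,
       rationale = sprintf(
         "Shapiro-Wilk p = %.3g < %.2g: sqrt transform applied", p, alpha))
}

## ---- effect size and power --------------------------------------------

#' Cohen's d from two group summaries
#'
#' Absolute standardized mean difference with the pooled
#' (n - 1)-weighted standard deviation.
#'
#' @param a,b Numeric vectors or [group_summary()] objects.
#' @return Cohen's d (non-negative double).
#' @export
cohen_d <- function(a, b) {
  a <- as_group_summary(a); b <- as_group_summary(b)
  sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (sp2 == 0) stop("zero pooled sd: effect size undefined")
  abs(a$mean - b$mean) / sqrt(sp2)
}

#' Power of the two-sample t-test (noncentral t)
#'
#' Post-hoc power for a balanced two-sample t-test: noncentrality
#' delta = d * sqrt(n/2), df = 2n - 2, two-sided rejection region at
#' `alpha` (the G*Power post-hoc procedure).
#'
#' @param d Cohen's d (>= 0).
#' @param n Sample size per group (>= 2).
#' @param alpha Significance level.
#' @param tails 1 or 2 (default 2).
#' @return Power in (0, 1); equals `alpha` when `d = 0`.
#' @export
power_two_sample_t <- function(d, n, alpha = 0.05, tails = 2) {
  stopifnot(d >= 0, n >= 2, alpha > 0, alpha < 1, tails %in% c(1, 2))
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  if (tails == 2) {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE) + stats::pt(-crit, df, ncp)
  } else {
    stats::pt(stats::qt(1 - alpha, df), df, ncp, lower.tail = FALSE)
  }
}

#' Smallest per-group n reaching a target power
#'
#' Incremental search from n = 2 upwards, guaranteeing exact minimality:
#' the returned n satisfies power(n) >= target and power(n - 1) < target.
#'
#' @param d Cohen's d (> 0).
#' @param target_power Required power in (0, 1).
#' @param alpha Significance level.
#' @param tails 1 or 2.
#' @param n_max Search cap (error beyond it).
#' @return Integer n per group.
#' @export
required_n_two_sample_t <- function(d, target_power = 0.9, alpha = 0.05,
                                    tails = 2, n_max = 1e6) {
  if (d <= 0) stop("d must be positive: no finite n reaches the target under d = 0")
  stopifnot(target_power > 0, target_power < 1)
  n <- 2L
  while (power_two_sample_t(d, n, alpha, tails) < target_power) {
    n <- n + 1L
    if (n > n_max) stop("no n <= n_max reaches the target power")
  }
  n
}
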