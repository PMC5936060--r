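# The central analysis: compare background-subtracted ISH intensity
# scores across genotype groups, reproducing a blinded
# quantify-then-genotype workflow.  ish_fit() is the one fitting entry
# point; it returns a classed object with print/summary/coef/plot
# methods.

#' Compare ISH intensity scores across genotype groups
#'
#' Fits the full decision tree used for score-by-genotype comparisons:
#' group summaries with coefficients of variation; a Shapiro-Wilk-guided
#' square-root transform (never applied when scores go negative);
#' Levene's test for equal variances; then, for two groups, a pooled or
#' Welch t-test, and for three or more groups both the standard and the
#' Welch one-way ANOVA with the variant chosen by Levene's p < 0.05 and
#' the matching post-hoc family (Tukey HSD for equal variances,
#' Games-Howell otherwise).  For two groups a power block is added:
#' Cohen's d, post-hoc power at `alpha`, and the per-group n required for
#' `target_power`.
#'
#' Embryos whose genotype is `"UNKNOWN"` or `NA` are excluded from
#' inference but counted in the accounting table.
#'
#' @param formula Model formula `score ~ genotype`.
#' @param data data.frame holding the two variables.
#' @param alpha Significance level (default 0.05).
#' @param target_power Target power for the sample-size block (default 0.9).
#' @param transform `"auto"` (Shapiro-Wilk decision), `"never"` or
#'   `"always"`.
#' @param levene_center `"mean"` (default) or `"median"`.
#' @return Object of class `"ish_fit"`.
#' @examples
#' set.seed(42)
#' d <- data.frame(
#'   score = c(rnorm(20, 54, 13), rnorm(20, 26, 6)),
#'   genotype = rep(c("WT", "MUT"), each = 20))
#' fit <- ish_fit(score ~ genotype, d)
#' print(fit)
#' @export
ish_fit <- function(formula, data, alpha = 0.05, target_power = 0.9,
                    transform = c("auto", "never", "always"),
                    levene_center = "mean") {
  transform <- match.arg(transform)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  score <- mf[[1]]
  genotype <- as.character(mf[[2]])
  n_total <- length(score)
  excluded <- is.na(score) | is.na(genotype) | genotype == "UNKNOWN"
  accounting <- table(factor(ifelse(excluded, "excluded", genotype)))
  score <- score[!excluded]; genotype <- genotype[!excluded]
  counts <- table(genotype)
  if (length(counts) < 2L || any(counts < 2L))
    stop("need at least 2 groups with n >= 2 after excluding UNKNOWN genotypes")
  # keep first-appearance group order (WT/HET/MUT tables read naturally)
  glev <- unique(genotype)

  tr <- switch(transform,
    auto = sqrt_transform_if_needed(score, alpha = alpha),
    never = list(values = score, transformed = FALSE, shapiro_p = NA_real_,
                 rationale = "transform disabled"),
    always = list(values = sqrt(score), transformed = TRUE,
                  shapiro_p = NA_real_, rationale = "transform forced"))
  y <- tr$values

  summaries_raw <- summarize_groups(score, genotype)
  summaries <- summarize_groups(y, genotype)
  lev <- levene(y, genotype, center = levene_center)
  unequal <- lev$p_value < alpha
  gs <- lapply(glev, function(g)
    group_summary(y[genotype == g], label = g))
  names(gs) <- glev
  k <- length(glev)

  if (k == 2L) {
    test <- if (unequal) welch_t(gs[[1]], gs[[2]])
            else pooled_t(gs[[1]], gs[[2]])
    anova_std <- NULL; anova_welch <- NULL; posthoc <- NULL
    d <- cohen_d(gs[[1]], gs[[2]])
    n_h <- round(exp(mean(log(vapply(gs, `[[`, 0, "n")))))  # balanced-equivalent n
    power_block <- list(
      cohen_d = d,
      power = power_two_sample_t(d, n_h, alpha = alpha),
      n_per_group = n_h,
      required_n = required_n_two_sample_t(d, target_power, alpha = alpha),
      target_power = target_power)
  } else {
    anova_std <- one_way_anova(gs)
    anova_welch <- welch_anova(gs)
    test <- if (unequal) anova_welch else anova_std
    posthoc <- if (unequal) games_howell(gs, alpha = alpha)
               else tukey_hsd(gs, alpha = alpha)
    power_block <- NULL
  }

  structure(list(
    call = match.call(), formula = formula,
    n_total = n_total, accounting = accounting,
    groups = glev, alpha = alpha,
    transform = tr[c("transformed", "shapiro_p", "rationale")],
    summaries_raw = summaries_raw, summaries = summaries,
    levene = lev, unequal_variances = unequal,
    test = test, anova_standard = anova_std, anova_welch = anova_welch,
    posthoc = posthoc, power = power_block,
    data = data.frame(score = score, genotype = genotype,
                      analysed = y, stringsAsFactors = FALSE)),
    class = "ish_fit")
}

#' @export
print.ish_fit <- function(x, ...) {
  cat("ISH intensity comparison (", deparse(x$formula), ")\n", sep = "")
  cat(sprintf("  %d embryos, %d analysed in %d groups\n",
              x$n_total, nrow(x$data), length(x$groups)))
  cat("  ", x$transform$rationale, "\n", sep = "")
  print(x$test)
  invisible(x)
}

#' @method summary ish_fit
#' @export
summary.ish_fit <- function(object, ...) {
  structure(object, class = c("summary.ish_fit", "ish_fit"))
}

#' @export
print.summary.ish_fit <- function(x, ...) {
  cat("ISH intensity comparison (", deparse(x$formula), ")\n\n", sep = "")
  cat("Accounting:\n"); print(x$accounting)
  cat("\nGroup summaries (raw score scale):\n")
  print(x$summaries_raw, digits = 4, row.names = FALSE)
  if (x$transform$transformed)
    cat("\nAnalysis performed on sqrt-transformed scores.\n")
  cat("\n", x$transform$rationale, "\n", sep = "")
  print(x$levene)
  cat(sprintf("Variances treated as %s (Levene p %s %.2g)\n",
              if (x$unequal_variances) "unequal" else "equal",
              if (x$unequal_variances) "<" else ">=", x$alpha))
  cat("\nPrimary test:\n"); print(x$test)
  if (!is.null(x$anova_standard)) {
    cat("\nBoth ANOVA variants:\n")
    print(x$anova_standard); print(x$anova_welch)
  }
  if (!is.null(x$posthoc)) { cat("\n"); print(x$posthoc) }
  if (!is.null(x$power)) {
    cat(sprintf(
      "\nPower block: Cohen's d = %.3f; post-hoc power at alpha %.2g (n = %d/group) = %.1f%%;\n  required n per group for %.0f%% power = %d\n",
      x$power$cohen_d, x$alpha, x$power$n_per_group, 100 * x$power$power,
      100 * x$power$target_power, x$power$required_n))
  }
  invisible(x)
}

#' @method coef ish_fit
#' @export
coef.ish_fit <- function(object, ...) {
  stats::setNames(object$summaries_raw$mean, object$summaries_raw$group)
}

#' Strip chart of scores by genotype with mean +/- sd bars
#' @param x An `"ish_fit"`.
#' @param ... Passed to [graphics::stripchart()].
#' @method plot ish_fit
#' @export
plot.ish_fit <- function(x, ...) {
  d <- x$data
  d$genotype <- factor(d$genotype, levels = x$groups)
  graphics::stripchart(score ~ genotype, data = d, vertical = TRUE,
                       method = "jitter", pch = 19,
                       col = grDevices::adjustcolor("steelblue", 0.6),
                       ylab = "background-subtracted intensity score", ...)
  s <- x$summaries_raw
  at <- match(s$group, x$groups)
  graphics::segments(at - 0.2, s$mean, at + 0.2, s$mean, lwd = 2)
  graphics::arrows(at, s$mean - s$sd, at, s$mean + s$sd,
                   angle = 90, code = 3, length = 0.06)
  invisible(x)
}
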