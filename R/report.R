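#' Group summary of fitted diffusion coefficients
#'
#' Holds either raw replicate values or a summary triple (n, mean, sd).
#' The coefficient of variation is reported as a percentage.
#'
#' @param label Group label.
#' @param values Raw replicate values (optional if summaries given).
#' @param n,mean,sd Summary statistics (ignored when `values` given).
#' @return Object of class `group_summary`.
#' @export
group_summary <- function(label, values = NULL, n = NULL, mean = NULL,
                          sd = NULL) {
  if (!is.null(values)) {
    n <- length(values)
    mean <- base::mean(values)
    sd <- stats::sd(values)
  }
  if (is.null(n) || is.null(mean) || is.null(sd)) {
    stop("supply either raw values or all of n, mean, sd")
  }
  if (n < 2) stop("need n >= 2")
  structure(list(label = label, values = values, n = n, mean = mean,
                 sd = sd, cv_percent = 100 * sd / mean),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("<group_summary> %s: n = %d, mean = %.4g, sd = %.4g (CV %.1f%%)%s\n",
              x$label, x$n, x$mean, x$sd, x$cv_percent,
              if (is.null(x$values)) " [summary only]" else ""))
  invisible(x)
}

stats_report <- function(comparison, test_used, statistic, p_value,
                         gates = list(), alpha = 0.05, extra = list()) {
  structure(c(list(comparison = comparison, test_used = test_used,
                   statistic = statistic, p_value = p_value,
                   gates = gates, alpha = alpha,
                   significant = p_value <= alpha), extra),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("<stats_report> %s: %s, statistic = %.4g, p = %.4g%s\n",
              x$comparison, x$test_used, x$statistic, x$p_value,
              if (x$significant) " (*)" else ""))
  invisible(x)
}

# pooled / Welch two-sample t from summary statistics
t_from_summaries <- function(n1, m1, s1, n2, m2, s2, pooled = TRUE) {
  if (pooled) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Compare two groups of diffusion coefficients
#'
#' Follows the analysis decision tree used for the chip data. With raw
#' replicate values: Shapiro-Wilk normality per group (alpha 0.05); if
#' either group fails, a Mann-Whitney (Wilcoxon rank-sum) test is used;
#' if both pass, an F-test compares variances and an unpaired pooled
#' t-test (equal variances) or Welch t-test (unequal) is applied. With
#' summary triples the gates cannot be evaluated, so the t-test flavour
#' must be named explicitly.
#'
#' @param a,b [group_summary] objects.
#' @param alpha Gate and significance level (default 0.05).
#' @param test With summary-only input: `"pooled"` or `"welch"`.
#' @return A `stats_report`; `gates` records the normality/variance gate
#'   outcomes.
#' @export
compare_two_groups <- function(a, b, alpha = 0.05,
                               test = c("auto", "pooled", "welch")) {
  test <- match.arg(test)
  comparison <- paste(a$label, "vs", b$label)
  if (is.null(a$values) || is.null(b$values)) {
    if (test == "auto") {
      stop("summary-only input: specify test = 'pooled' or 'welch'")
    }
    res <- t_from_summaries(a$n, a$mean, a$sd, b$n, b$mean, b$sd,
                            pooled = (test == "pooled"))
    return(stats_report(comparison,
                        if (test == "pooled") "pooled t-test (from summaries)"
                        else "Welch t-test (from summaries)",
                        res$t, res$p,
                        gates = list(normality = NA, equal_variance = NA),
                        alpha = alpha, extra = list(df = res$df)))
  }
  if (a$n < 3 || b$n < 3) stop("Shapiro-Wilk gate needs n >= 3 per group")
  swa <- stats::shapiro.test(a$values)$p.value
  swb <- stats::shapiro.test(b$values)$p.value
  normal <- swa > alpha && swb > alpha
  if (!normal) {
    wt <- stats::wilcox.test(a$values, b$values, exact = FALSE)
    return(stats_report(comparison, "Mann-Whitney", unname(wt$statistic),
                        wt$p.value,
                        gates = list(normality = FALSE,
                                     shapiro_p = c(swa, swb)),
                        alpha = alpha))
  }
  ft <- stats::var.test(a$values, b$values)
  equal_var <- ft$p.value > alpha
  tt <- stats::t.test(a$values, b$values, var.equal = equal_var)
  stats_report(comparison,
               if (equal_var) "pooled t-test" else "Welch t-test",
               unname(tt$statistic), tt$p.value,
               gates = list(normality = TRUE, shapiro_p = c(swa, swb),
                            equal_variance = equal_var,
                            f_test_p = ft$p.value),
               alpha = alpha, extra = list(df = unname(tt$parameter)))
}

#' Compare the variability of two groups
#'
#' Two-sided F-test on the variances, reporting the coefficients of
#' variation alongside (used to test whether adding cells increases the
#' spread of fitted diffusion coefficients).
#'
#' @param a,b [group_summary] objects (raw values or summaries).
#' @param alpha Significance level (default 0.05).
#' @return A `stats_report` with `cv_percent` for both groups.
#' @export
compare_variability <- function(a, b, alpha = 0.05) {
  if (a$sd <= 0 || b$sd <= 0) stop("zero variance in a group")
  f <- (a$sd / b$sd)^2
  df1 <- a$n - 1
  df2 <- b$n - 1
  p <- 2 * min(stats::pf(f, df1, df2), 1 - stats::pf(f, df1, df2))
  p <- min(p, 1)
  stats_report(paste(a$label, "vs", b$label, "(variances)"),
               "F-test (two-sided)", f, p, alpha = alpha,
               extra = list(df = c(df1, df2),
                            cv_percent = c(a$cv_percent, b$cv_percent)))
}

#' Compare several groups against a control
#'
#' Kruskal-Wallis omnibus test over all groups followed by Dunn's
#' post hoc z-tests of each group against the control, with
#' Bonferroni-corrected two-sided p values (the family is the set of
#' against-control comparisons). Requires raw values.
#'
#' @param groups List of [group_summary] objects with raw values
#'   (at least 3 groups).
#' @param control_label Label of the control group.
#' @param alpha Significance level (default 0.05).
#' @return List with `omnibus` (a `stats_report`) and `posthoc` (list of
#'   `stats_report`, one per non-control group).
#' @export
compare_many_groups <- function(groups, control_label, alpha = 0.05) {
  if (length(groups) == 2) {
    stop("two groups: use compare_two_groups()")
  }
  if (length(groups) < 3) stop("need at least 3 groups")
  labels <- vapply(groups, function(g) g$label, character(1))
  if (!control_label %in% labels) stop("control_label not among groups")
  for (g in groups) {
    if (is.null(g$values)) stop("compare_many_groups needs raw values")
    if (g$n < 2) stop("every group needs n >= 2")
  }
  values <- unlist(lapply(groups, function(g) g$values))
  gf <- factor(rep(labels, vapply(groups, function(g) g$n, numeric(1))),
               levels = labels)
  kw <- stats::kruskal.test(values, gf)
  omnibus <- stats_report("Kruskal-Wallis omnibus", "Kruskal-Wallis",
                          unname(kw$statistic), kw$p.value, alpha = alpha)
  # Dunn's z statistics on mean ranks, with tie correction
  N <- length(values)
  rk <- rank(values)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mean_rank <- tapply(rk, gf, mean)
  ns <- tapply(rk, gf, length)
  others <- setdiff(labels, control_label)
  m <- length(others)
  posthoc <- lapply(others, function(lb) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) *
               (1 / ns[[lb]] + 1 / ns[[control_label]]))
    z <- (mean_rank[[lb]] - mean_rank[[control_label]]) / se
    p <- min(1, 2 * stats::pnorm(-abs(z)) * m)   # Bonferroni family
    stats_report(paste(lb, "vs", control_label),
                 "Dunn post hoc (Bonferroni-adjusted)", z, p,
                 alpha = alpha, extra = list(n_comparisons = m))
  })
  names(posthoc) <- others
  list(omnibus = omnibus, posthoc = posthoc)
}
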