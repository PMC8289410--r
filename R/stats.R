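#' Cohen's d with a noncentral-t confidence interval
#'
#' Two-sample d = (mean1 - mean2) / pooled SD; one-sample d = (mean - null)
#' / SD. The confidence interval is obtained by inverting the noncentral-t
#' distribution of the observed t statistic (finding the noncentrality
#' parameters whose tail probabilities match the interval level) and
#' rescaling to the d scale.
#'
#' @param x,y numeric vectors; omit `y` for the one-sample version.
#' @param null one-sample null value (default 0).
#' @param conf_level confidence level (0.95, or 0.975 under the times-two
#'   Bonferroni policy).
#' @return List with `d`, `ci` (length-2), `conf_level`.
#' @export
cohens_d <- function(x, y = NULL, null = 0, conf_level = 0.95) {
  stopifnot(conf_level > 0, conf_level < 1)
  if (is.null(y)) {
    n <- length(x)
    stopifnot(n >= 2)
    sd_x <- stats::sd(x)
    if (sd_x == 0) stop("zero standard deviation")
    d <- (mean(x) - null) / sd_x
    scale <- sqrt(n)          # t = d * sqrt(n)
    df <- n - 1
  } else {
    n1 <- length(x); n2 <- length(y)
    stopifnot(n1 >= 2, n2 >= 2)
    sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
                 (n1 + n2 - 2))
    if (sp == 0) stop("zero pooled standard deviation")
    d <- (mean(x) - mean(y)) / sp
    scale <- sqrt(n1 * n2 / (n1 + n2))   # t = d * scale
    df <- n1 + n2 - 2
  }
  t_obs <- d * scale
  alpha <- 1 - conf_level
  ncp_bound <- function(prob) {
    # ncp at which P(T_df,ncp <= t_obs) = prob; pt's noncentral tail
    # warning concerns precision far beyond the 1e-8 root tolerance
    f <- function(ncp) suppressWarnings(stats::pt(t_obs, df, ncp)) - prob
    lo <- t_obs - 10 - 10 * abs(t_obs)
    hi <- t_obs + 10 + 10 * abs(t_obs)
    stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  }
  ci <- c(ncp_bound(1 - alpha / 2), ncp_bound(alpha / 2)) / scale
  list(d = d, ci = ci, conf_level = conf_level)
}

comparison_record <- function(name, t, df, p_raw, adjust, d, d_ci,
                              conf_level, n) {
  p_adj <- if (adjust == "bonferroni2") min(1, 2 * p_raw) else p_raw
  structure(list(statistic = name, t = t, df = df, p_raw = p_raw,
                 p_adjusted = p_adj, adjust = adjust, cohens_d = d,
                 d_ci = d_ci, conf_level = conf_level, n_per_group = n),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "%s: t(%d) = %.3f, p = %.4g%s, d = %.3f, %s%% CI [%.3f, %.3f]\n",
    x$statistic, x$df, x$t, x$p_adjusted,
    if (x$adjust == "bonferroni2") " (x2 Bonferroni)" else "",
    x$cohens_d, format(100 * x$conf_level), x$d_ci[1], x$d_ci[2]))
  invisible(x)
}

#' Two-sample pooled-variance t test with effect size
#'
#' Student's t with pooled variance (df = n1 + n2 - 2), two-tailed, plus
#' Cohen's d with a noncentral-t confidence interval. Under the times-two
#' Bonferroni policy (`adjust = "bonferroni2"`, used for the two history
#' coefficients) the p-value is doubled (capped at 1) and the interval is
#' reported at 97.5% instead of 95%.
#'
#' @param x,y the two groups.
#' @param name label carried into the result.
#' @param adjust `"none"` or `"bonferroni2"`.
#' @return A `group_comparison` record.
#' @export
two_sample_t <- function(x, y, name = "two-sample",
                         adjust = c("none", "bonferroni2")) {
  adjust <- match.arg(adjust)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("zero variance in both groups")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  conf <- if (adjust == "bonferroni2") 0.975 else 0.95
  dd <- cohens_d(x, y, conf_level = conf)
  comparison_record(name, unname(tt$statistic),
                    as.integer(unname(tt$parameter)),
                    tt$p.value, adjust, dd$d, dd$ci, conf,
                    c(length(x), length(y)))
}

#' One-sample t test with effect size
#'
#' @param x values.
#' @param null null-hypothesis mean.
#' @inheritParams two_sample_t
#' @return A `group_comparison` record.
#' @export
one_sample_t <- function(x, null = 0, name = "one-sample",
                         adjust = c("none", "bonferroni2")) {
  adjust <- match.arg(adjust)
  stopifnot(length(x) >= 2)
  if (stats::sd(x) == 0) stop("zero variance")
  tt <- stats::t.test(x, mu = null)
  conf <- if (adjust == "bonferroni2") 0.975 else 0.95
  dd <- cohens_d(x, null = null, conf_level = conf)
  comparison_record(name, unname(tt$statistic),
                    as.integer(unname(tt$parameter)),
                    tt$p.value, adjust, dd$d, dd$ci, conf, length(x))
}

#' Pearson correlation with two-tailed p
#'
#' Sample Pearson r with p from the t transform at df = n - 2.
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @return List with `r`, `df`, `p`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}
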