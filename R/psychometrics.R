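#' Psychometric function with lapse rate
#'
#' Probability of a rightward choice as a function of the stimulus:
#' \deqn{\phi(s) = \lambda + (1 - 2\lambda)\,F(s; \mu, \sigma)}
#' where F is the cumulative Gaussian. The mean mu is the point of
#' subjective equality (PSE), sigma the psychophysical threshold, and lambda
#' a symmetric lapse rate flattening both asymptotes.
#'
#' @param s stimulus values (degrees), vectorized.
#' @param mu PSE (degrees).
#' @param sigma threshold (degrees), > 0.
#' @param lapse lapse rate in `[0, 0.5)`.
#' @return Probability of a rightward choice.
#' @export
psychometric_prob <- function(s, mu, sigma, lapse = 0) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (lapse < 0 || lapse >= 0.5) stop("lapse must be in [0, 0.5)")
  lapse + (1 - 2 * lapse) * stats::pnorm((s - mu) / sigma)
}

#' Likelihood-ratio pseudo-R-squared
#'
#' Proportional reduction in deviance of the fitted psychometric model
#' relative to the null (stimulus-independent) model:
#' R2L = 1 - D_fitted / D_null. Deviances are twice the log-likelihood gap
#' to the saturated model (the model fitting each stimulus level its
#' empirical proportion, as grouped psychometric software computes them).
#' Used to screen participants: only those whose curves all exceed 0.5 are
#' analyzed.
#'
#' @param deviance_fitted,deviance_null model deviances (>= 0; null > 0).
#' @return Scalar pseudo-R-squared (<= 1).
#' @export
pseudo_r2 <- function(deviance_fitted, deviance_null) {
  stopifnot(deviance_fitted >= 0)
  if (!is.finite(deviance_null) || deviance_null <= 0)
    stop("null deviance must be > 0")
  1 - deviance_fitted / deviance_null
}

psych_nll <- function(par, s, y) {
  p <- psychometric_prob(s, par[1], par[2], par[3])
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -sum(y * log(p) + (1 - y) * log(1 - p))
}

# log-likelihood of the saturated (grouped) model: each stimulus level
# (staircase magnitudes repeat exactly up to float noise) gets its
# empirical rightward proportion
saturated_loglik <- function(s, y) {
  lev <- factor(signif(s, 10))
  p_hat <- tapply(y, lev, mean)[lev]
  p_hat <- pmin(pmax(as.numeric(p_hat), 1e-12), 1 - 1e-12)
  sum(y * log(p_hat) + (1 - y) * log(1 - p_hat))
}

#' Fit a psychometric function by maximum likelihood
#'
#' Bounded Bernoulli MLE of (mu, sigma, lambda) with a fixed multi-start
#' grid, so the fit is deterministic given the data. Bounds: mu in
#' `[-45, 45]` deg, sigma in `[0.05, 100]` deg, lambda in `[0, 0.25]`.
#' Goodness of fit is the likelihood-ratio pseudo-R-squared against a
#' constant-probability null at the empirical rightward rate.
#'
#' @param s stimulus values (degrees).
#' @param choice choices coded +1 (right) / -1 (left).
#' @return An object of class `psychfit`: list with `pse_deg`,
#'   `threshold_deg`, `lapse`, `r2l`, `nll`, `deviance`, `null_deviance`,
#'   `n_obs`, `converged`. Data with a single response class (or fewer than
#'   two distinct stimulus values) yield `converged = FALSE` with NA
#'   parameters; such fits are excluded downstream.
#' @export
fit_psychometric <- function(s, choice) {
  stopifnot(length(s) == length(choice), all(choice %in% c(-1, 1)))
  y <- as.integer(choice == 1)
  n <- length(y)
  bad <- length(unique(y)) < 2L || length(unique(s)) < 2L
  if (bad) {
    return(structure(list(pse_deg = NA_real_, threshold_deg = NA_real_,
                          lapse = NA_real_, r2l = NA_real_, nll = NA_real_,
                          deviance = NA_real_, null_deviance = NA_real_,
                          n_obs = n, converged = FALSE),
                     class = "psychfit"))
  }
  lower <- c(-45, 0.05, 0)
  upper <- c(45, 100, 0.25)
  # fixed multi-start grid: PSE near the data's center, thresholds spanning
  # the plausible range on a log scale
  mu0 <- unique(pmin(pmax(stats::quantile(s, c(0.25, 0.5, 0.75),
                                          names = FALSE), -45), 45))
  sig0 <- c(0.5, 2, 8, 32)
  lam0 <- c(0.01, 0.1)
  best <- NULL
  for (m in mu0) for (sg in sig0) for (lm in lam0) {
    fit <- try(stats::optim(c(m, sg, lm), psych_nll, s = s, y = y,
                            method = "L-BFGS-B", lower = lower,
                            upper = upper,
                            control = list(factr = 1e5, maxit = 500)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("psychometric optimization failed on all starts")
  p0 <- mean(y)
  ll_sat <- saturated_loglik(s, y)
  null_dev <- 2 * (ll_sat - (sum(y) * log(p0) + (n - sum(y)) * log(1 - p0)))
  dev <- max(2 * (ll_sat + best$value), 0)
  structure(list(pse_deg = best$par[1], threshold_deg = best$par[2],
                 lapse = best$par[3],
                 r2l = if (null_dev > 0) pseudo_r2(dev, null_dev)
                       else NA_real_,
                 nll = best$value, deviance = dev,
                 null_deviance = null_dev, n_obs = n,
                 converged = best$convergence == 0),
            class = "psychfit")
}

#' @export
print.psychfit <- function(x, ...) {
  if (!x$converged && is.na(x$pse_deg)) {
    cat("Psychometric fit: degenerate data, not fitted (n =",
        x$n_obs, ")\n")
    return(invisible(x))
  }
  cat(sprintf(
    "Psychometric fit (n = %d): PSE = %.3f deg, threshold = %.3f deg, lapse = %.3f, R2L = %.3f\n",
    x$n_obs, x$pse_deg, x$threshold_deg, x$lapse, x$r2l))
  invisible(x)
}

#' Participant inclusion screen
#'
#' A participant is kept only if *every* supplied psychometric fit has
#' pseudo-R-squared strictly greater than the cutoff (default 0.5).
#' Non-converged fits fail the screen.
#'
#' @param fits a list of [fit_psychometric()] results (or a numeric vector
#'   of pseudo-R-squared values).
#' @param cutoff inclusion cutoff (strict inequality).
#' @return Logical: keep this participant?
#' @export
screen_participant <- function(fits, cutoff = 0.5) {
  if (length(fits) == 0) stop("no fits supplied")
  r2 <- if (is.numeric(fits)) fits
        else vapply(fits, function(f) {
          if (!f$converged) return(NA_real_)
          f$r2l
        }, numeric(1))
  all(!is.na(r2) & r2 > cutoff)
}

# chronological order of a single participant-condition table
order_session <- function(session) {
  session[order(session$trial_index, session$step_index), , drop = FALSE]
}

#' PSE shift between prior types
#'
#' Fits separate psychometric functions to the test stimuli preceded by
#' left- and right-biased priors and returns
#' delta = PSE_left - PSE_right. Positive values indicate attraction toward
#' the priors (choices pulled to the same side as the prior bias), negative
#' values repulsion.
#'
#' @param session a session table for one participant and condition.
#' @param prior_typing `"designed_bias"`: use the trial's designed
#'   `prior_type` label; `"previous_choice"`: type each test trial by the
#'   choice made on the chronologically previous discrimination (the
#'   heading-style n = 1 convention).
#' @param min_trials a prior type with fewer test trials is flagged
#'   (`flagged = TRUE`) and yields NA PSEs.
#' @return List of class `delta_pse`: `pse_left`, `pse_right`, `delta`,
#'   per-type fits, `flagged`.
#' @export
delta_pse <- function(session, prior_typing = c("designed_bias",
                                                "previous_choice"),
                      min_trials = 10L) {
  prior_typing <- match.arg(prior_typing)
  ses <- order_session(session)
  if (prior_typing == "designed_bias") {
    tests <- ses[ses$role == "test", , drop = FALSE]
    type <- tests$prior_type
  } else {
    prev_choice <- c(NA, ses$choice[-nrow(ses)])
    keep <- ses$role == "test" & !is.na(prev_choice)
    tests <- ses[keep, , drop = FALSE]
    type <- ifelse(prev_choice[keep] == 1, "right", "left")
  }
  if (!all(c("left", "right") %in% type))
    stop("both prior types must be represented among test trials")
  fit_one <- function(tp) {
    sub <- tests[type == tp, , drop = FALSE]
    if (nrow(sub) < min_trials) return(NULL)
    fit_psychometric(sub$stimulus_deg, sub$choice)
  }
  fl <- fit_one("left"); fr <- fit_one("right")
  flagged <- is.null(fl) || is.null(fr) ||
    !fl$converged || !fr$converged
  pse_l <- if (is.null(fl)) NA_real_ else fl$pse_deg
  pse_r <- if (is.null(fr)) NA_real_ else fr$pse_deg
  structure(list(pse_left = pse_l, pse_right = pse_r,
                 delta = pse_l - pse_r,
                 fit_left = fl, fit_right = fr, flagged = flagged),
            class = "delta_pse")
}

#' @export
print.delta_pse <- function(x, ...) {
  cat(sprintf("Delta-PSE = %.3f deg (PSE left %.3f, PSE right %.3f)%s\n",
              x$delta, x$pse_left, x$pse_right,
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Mean log threshold
#'
#' Thresholds are non-negative and scale logarithmically, so per-participant
#' averaging (and group statistics) are done on natural-log thresholds.
#'
#' @param thresholds positive thresholds (degrees), e.g. one per prior type.
#' @return Mean of `log(thresholds)`.
#' @export
mean_log_threshold <- function(thresholds) {
  if (any(!is.finite(thresholds) | thresholds <= 0))
    stop("thresholds must be positive and finite")
  mean(log(thresholds))
}

#' Percent correct on easy discriminations
#'
#' Correctness independent of psychometric fits: among discriminations whose
#' stimulus magnitude exceeds the participant-condition's 66th percentile of
#' |s|, the percentage where the choice sign matches the stimulus sign.
#' Discriminations at exactly s = 0 have no correct side and are excluded.
#'
#' @param session a session table for one participant and condition.
#' @param percentile magnitude percentile defining "easy" (default 66).
#' @return Percent correct (0-100).
#' @export
easy_percent_correct <- function(session, percentile = 66) {
  stopifnot(nrow(session) > 0)
  ses <- session[session$stimulus_deg != 0, , drop = FALSE]
  thr <- stats::quantile(abs(ses$stimulus_deg), percentile / 100,
                         names = FALSE)
  easy <- ses[abs(ses$stimulus_deg) > thr, , drop = FALSE]
  100 * mean(sign(easy$stimulus_deg) == easy$choice)
}

#' Plot a psychometric fit
#'
#' Binned proportion-rightward data with the fitted curve overlaid.
#' Requires ggplot2.
#'
#' @param fit a [fit_psychometric()] result.
#' @param s,choice the observations the fit was computed from.
#' @param bins number of stimulus bins for the empirical points.
#' @return A ggplot object.
#' @export
plot_psychometric <- function(fit, s, choice, bins = 9) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  y <- as.integer(choice == 1)
  brk <- stats::quantile(s, seq(0, 1, length.out = bins + 1))
  grp <- cut(s, unique(brk), include.lowest = TRUE)
  pts <- data.frame(s = tapply(s, grp, mean), p = tapply(y, grp, mean))
  grid <- data.frame(s = seq(min(s), max(s), length.out = 200))
  grid$p <- psychometric_prob(grid$s, fit$pse_deg, fit$threshold_deg,
                              fit$lapse)
  ggplot2::ggplot(pts, ggplot2::aes(x = s, y = p)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid) +
    ggplot2::geom_vline(xintercept = fit$pse_deg, linetype = 2) +
    ggplot2::labs(x = "stimulus (deg)", y = "P(rightward choice)")
}
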