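#' RMS-normalize a session's stimuli
#'
#' Divides every stimulus of a participant-condition table (priors and
#' tests alike) by the root-mean-square of all its stimulus values, so
#' stimulus regressors are on the same scale as the +/-1 choice regressors
#' (both with RMS = 1).
#'
#' @param session a session table for one participant and condition.
#' @return The session with an added `stimulus_norm` column; the RMS is
#'   attached as attribute `"rms"`.
#' @export
normalize_stimuli_rms <- function(session) {
  s <- session$stimulus_deg
  stopifnot(length(s) > 0)
  if (all(s == 0)) stop("all stimuli are zero; RMS undefined")
  rms <- sqrt(mean(s^2))
  session$stimulus_norm <- s / rms
  attr(session, "rms") <- rms
  session
}

#' Build the averaged-history design
#'
#' One design row per test response for the choice-history model: the
#' current normalized stimulus, the mean of the trial's prior (normalized)
#' stimuli, the mean of the trial's prior choices (+1/-1), and the observed
#' choice.
#'
#' @param session a session table with a `stimulus_norm` column (see
#'   [normalize_stimuli_rms()]).
#' @param mode `"per_trial_priors"`: one row per test trial, history
#'   averaged over that trial's designed priors; `"n_back_1"`: one row per
#'   discrimination after the first, history = the single previous
#'   discrimination (heading-style).
#' @return data.frame with columns `s_t`, `prev_stim_avg`,
#'   `prev_choice_avg`, `y` (choice, +1/-1), `n_priors`.
#' @export
build_design <- function(session, mode = c("per_trial_priors", "n_back_1")) {
  mode <- match.arg(mode)
  if (is.null(session$stimulus_norm))
    stop("session must be RMS-normalized first (normalize_stimuli_rms)")
  ses <- order_session(session)
  if (mode == "n_back_1") {
    k <- nrow(ses)
    if (k < 2) stop("need at least two discriminations")
    idx <- 2:k
    return(data.frame(s_t = ses$stimulus_norm[idx],
                      prev_stim_avg = ses$stimulus_norm[idx - 1L],
                      prev_choice_avg = ses$choice[idx - 1L],
                      y = ses$choice[idx],
                      n_priors = 1L))
  }
  trial_f <- factor(ses$trial_index, levels = unique(ses$trial_index))
  is_test <- ses$role == "test"
  n_test <- tapply(is_test, trial_f, sum)
  if (any(n_test != 1L)) stop("each trial must have exactly one test row")
  n_pri <- tapply(!is_test, trial_f, sum)
  if (any(n_pri == 0L))
    stop("trial(s) without priors in per_trial_priors mode: ",
         paste(utils::head(levels(trial_f)[n_pri == 0], 5), collapse = ", "))
  pri_f <- factor(ses$trial_index[!is_test], levels = levels(trial_f))
  out <- data.frame(
    s_t = ses$stimulus_norm[is_test],
    prev_stim_avg = as.numeric(
      tapply(ses$stimulus_norm[!is_test], pri_f, mean)),
    prev_choice_avg = as.numeric(tapply(ses$choice[!is_test], pri_f, mean)),
    y = ses$choice[is_test],
    n_priors = as.integer(n_pri))
  rownames(out) <- NULL
  out
}

#' Build the lagged-history design
#'
#' Treats all of a participant-condition's discriminations (priors and
#' tests) as one long sequence and builds, for each discrimination after the
#' first `lags`, one row with the current normalized stimulus and the `lags`
#' preceding choices as separate regressors (optionally also the `lags`
#' preceding stimuli, used for the preliminary 2-lag check). Only meaningful
#' where priors and tests share a response set (the primary condition).
#'
#' @inheritParams build_design
#' @param lags number of lagged regressors (default 5).
#' @param stimulus_lags also include lagged stimulus regressors?
#' @return data.frame with `s_t`, `prev_choice_1..lags` (and optionally
#'   `prev_stim_1..lags`) and `y`.
#' @export
build_design_lagged <- function(session, lags = 5L, stimulus_lags = FALSE) {
  if (is.null(session$stimulus_norm))
    stop("session must be RMS-normalized first (normalize_stimuli_rms)")
  ses <- order_session(session)
  k <- nrow(ses)
  if (k <= lags) stop("sequence must be longer than the number of lags")
  idx <- (lags + 1L):k
  out <- data.frame(s_t = ses$stimulus_norm[idx])
  for (l in seq_len(lags))
    out[[paste0("prev_choice_", l)]] <- ses$choice[idx - l]
  if (stimulus_lags)
    for (l in seq_len(lags))
      out[[paste0("prev_stim_", l)]] <- ses$stimulus_norm[idx - l]
  out$y <- ses$choice[idx]
  out
}

# Bernoulli negative log-likelihood of a logistic model; y01 in {0,1}
logistic_nll <- function(beta, X, y01) {
  z <- drop(X %*% beta)
  -sum(y01 * stats::plogis(z, log.p = TRUE) +
         (1 - y01) * stats::plogis(-z, log.p = TRUE))
}

#' Fit the choice-history logistic model
#'
#' Unregularized Bernoulli maximum likelihood for the choice-history model:
#' P(rightward) = logistic(b0 + b_curr s_t + b_ps prev_stim_avg +
#' b_pc prev_choice_avg), or its lagged variant when the design carries
#' `prev_choice_1..k` (and optionally `prev_stim_1..k`) columns. Fitted by
#' Newton-Raphson from a zero start with gradient-norm tolerance 1e-8 (the
#' NLL is convex, so the optimum is unique when it exists). Perfect
#' separation or collinearity is detected (diverging coefficients or a
#' singular Hessian) and flagged as non-converged; such fits are excluded
#' downstream rather than regularized.
#'
#' @param design a design from [build_design()] or [build_design_lagged()].
#' @param max_iter,tol Newton iteration cap and gradient-norm tolerance.
#' @return An object of class `history_fit`: `coef` (named vector with
#'   `beta0`, `beta_curr`, then `beta_prev_stim`/`beta_prev_choice` or the
#'   lagged names), `se`, `nll`, `converged`, `n_obs`, `diagnostic`.
#' @export
fit_history_logistic <- function(design, max_iter = 200L, tol = 1e-8) {
  stopifnot(is.data.frame(design), "s_t" %in% names(design),
            "y" %in% names(design))
  reg_names <- setdiff(names(design), c("y", "n_priors"))
  X <- cbind(1, as.matrix(design[reg_names]))
  rename <- function(v) vapply(v, function(x) switch(
    x,
    prev_stim_avg = "beta_prev_stim",
    prev_choice_avg = "beta_prev_choice",
    sub("^prev_choice_", "beta_prev_choice_",
        sub("^prev_stim_", "beta_prev_stim_", x))), character(1),
    USE.NAMES = FALSE)
  nm <- c("beta0", "beta_curr", rename(setdiff(reg_names, "s_t")))
  colnames(X) <- nm
  y01 <- as.integer(design$y == 1)
  stopifnot(all(design$y %in% c(-1, 1)))
  fail <- function(msg) structure(
    list(coef = stats::setNames(rep(NA_real_, ncol(X)), colnames(X)),
         se = NULL, nll = NA_real_, converged = FALSE,
         n_obs = nrow(X), diagnostic = msg), class = "history_fit")
  if (length(unique(y01)) < 2L) return(fail("single response class"))
  beta <- rep(0, ncol(X))
  ok <- FALSE
  diagnostic <- ""
  for (it in seq_len(max_iter)) {
    p <- stats::plogis(drop(X %*% beta))
    g <- drop(crossprod(X, y01 - p))
    if (sqrt(sum(g^2)) < tol) { ok <- TRUE; break }
    w <- p * (1 - p)
    H <- crossprod(X * w, X)
    step <- try(solve(H, g), silent = TRUE)
    if (inherits(step, "try-error"))
      return(fail("singular Hessian (collinear design)"))
    beta <- beta + step
    if (any(!is.finite(beta)) || max(abs(beta)) > 30)
      return(fail("coefficients diverged (perfect separation)"))
  }
  if (!ok) diagnostic <- "iteration cap reached"
  p <- stats::plogis(drop(X %*% beta))
  H <- crossprod(X * (p * (1 - p)), X)
  se <- sqrt(diag(solve(H)))
  structure(list(coef = stats::setNames(drop(beta), colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 nll = logistic_nll(beta, X, y01),
                 converged = ok, n_obs = nrow(X),
                 diagnostic = diagnostic),
            class = "history_fit")
}

#' @export
print.history_fit <- function(x, ...) {
  cat("Choice-history logistic fit (n =", x$n_obs, "):\n")
  if (!x$converged) cat("  NOT converged:", x$diagnostic, "\n")
  print(round(x$coef, 4))
  cat(sprintf("  NLL = %.4f\n", x$nll))
  invisible(x)
}
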