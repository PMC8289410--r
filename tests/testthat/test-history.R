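test_that("RMS normalization scales all stimuli to unit root-mean-square", {
  ses <- tiny_session()
  ses$stimulus_deg <- c(3, -4, 0, 0, 0)
  norm <- normalize_stimuli_rms(ses)
  rms <- sqrt(mean(c(3, -4, 0, 0, 0)^2))
  expect_equal(attr(norm, "rms"), rms)
  expect_equal(norm$stimulus_norm[1:2], c(3, -4) / rms, tolerance = 1e-12)
  expect_equal(sqrt(mean(norm$stimulus_norm^2)), 1, tolerance = 1e-12)
  # idempotent on already-unit input
  ses2 <- ses; ses2$stimulus_deg <- norm$stimulus_norm
  expect_equal(normalize_stimuli_rms(ses2)$stimulus_norm,
               norm$stimulus_norm, tolerance = 1e-12)
  ses$stimulus_deg <- rep(0, 5)
  expect_error(normalize_stimuli_rms(ses), "zero")
})

test_that("the averaged design takes per-trial means of priors", {
  ses <- normalize_stimuli_rms(tiny_session())
  d <- build_design(ses)
  expect_equal(nrow(d), 2L)
  expect_equal(d$prev_stim_avg,
               c(mean(ses$stimulus_norm[1:2]), ses$stimulus_norm[4]))
  expect_equal(d$prev_choice_avg, c(0, -1))
  expect_equal(d$y, c(1, -1))
  expect_equal(d$n_priors, c(2L, 1L))
  # n_back_1: one row per discrimination after the first
  d1 <- build_design(ses, "n_back_1")
  expect_equal(nrow(d1), nrow(ses) - 1L)
  expect_equal(d1$prev_stim_avg, ses$stimulus_norm[-nrow(ses)])
  expect_equal(d1$prev_choice_avg, ses$choice[-nrow(ses)])
  # per-trial mode refuses trials without designed priors
  no_priors <- ses[ses$role == "test", ]
  expect_error(build_design(no_priors), "without priors")
})

test_that("the lagged design drops the first lags and flags degenerate columns", {
  set.seed(31)
  ses <- simulate_session(observer_params(beta_curr = 2), quick_config(30L))
  ses <- normalize_stimuli_rms(ses)
  k <- nrow(ses)
  d5 <- build_design_lagged(ses, lags = 5)
  expect_equal(nrow(d5), k - 5L)
  expect_named(d5, c("s_t", paste0("prev_choice_", 1:5), "y"))
  d2 <- build_design_lagged(ses, lags = 2, stimulus_lags = TRUE)
  expect_true(all(c("prev_stim_1", "prev_stim_2") %in% names(d2)))
  expect_error(build_design_lagged(ses[1:4, ], lags = 5), "longer")
  # a constant choice history is perfectly collinear with the intercept
  const <- ses; const$choice <- 1
  dd <- build_design_lagged(normalize_stimuli_rms(const), lags = 5)
  expect_true(all(dd$prev_choice_1 == 1))
  expect_false(fit_history_logistic(dd)$converged)
})

test_that("the logistic MLE matches glm and is never beaten by grid search", {
  set.seed(32)
  for (rep in 1:3) {
    n <- 40
    d <- data.frame(s_t = rnorm(n), prev_stim_avg = rnorm(n, sd = 0.7),
                    prev_choice_avg = sample(c(-1, 1), n, TRUE))
    z <- 0.2 + 1.1 * d$s_t - 0.4 * d$prev_stim_avg + 0.6 * d$prev_choice_avg
    d$y <- ifelse(runif(n) < plogis(z), 1, -1)
    fit <- fit_history_logistic(d)
    ref <- glm(I(y == 1) ~ s_t + prev_stim_avg + prev_choice_avg,
               binomial(), data = d)
    expect_true(fit$converged)
    expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  }
  # exhaustive-search oracle on a small design: the MLE's NLL is not beaten
  # by any beta on a coarse grid over [-3, 3]^4
  set.seed(33)
  n <- 12
  d <- data.frame(s_t = rnorm(n), prev_stim_avg = rnorm(n, sd = 0.7),
                  prev_choice_avg = sample(c(-1, 1), n, TRUE))
  d$y <- ifelse(runif(n) < plogis(0.5 * d$s_t + 0.5 * d$prev_choice_avg),
                1, -1)
  fit <- fit_history_logistic(d)
  X <- cbind(1, d$s_t, d$prev_stim_avg, d$prev_choice_avg)
  y01 <- as.integer(d$y == 1)
  g <- seq(-3, 3, by = 0.3)
  grid <- as.matrix(expand.grid(g, g, g, g))
  Z <- X %*% t(grid)                       # n x n_grid decision variables
  nll_all <- -colSums(y01 * plogis(Z, log.p = TRUE) +
                        (1 - y01) * plogis(-Z, log.p = TRUE))
  expect_lte(fit$nll, min(nll_all) + 1e-8)
})

test_that("betas are recovered without cross-leakage from simulated rows", {
  set.seed(34)
  # fixed regressor geometry taken from one simulated session
  ses <- normalize_stimuli_rms(
    simulate_session(observer_params(beta_curr = 2.5), paradigm_config()))
  base <- build_design(ses)
  X <- cbind(1, base$s_t, base$prev_stim_avg, base$prev_choice_avg)
  simfit <- function(beta, reps, nrows) {
    co <- matrix(NA_real_, reps, 4)
    for (i in seq_len(reps)) {
      idx <- sample(nrow(X), nrows, replace = TRUE)
      d <- base[idx, ]
      z <- drop(X[idx, ] %*% beta)
      d$y <- ifelse(runif(nrows) < plogis(z), 1, -1)
      co[i, ] <- fit_history_logistic(d)$coef
    }
    co
  }
  true <- c(0, 2, -0.3, 0.5)
  co <- simfit(true, reps = 20, nrows = 2000)
  expect_true(all(abs(colMeans(co) - true) < 0.1))
  # a pure consistency observer leaks nothing into the stimulus weight
  co0 <- simfit(c(0, 2, 0, 0.5), reps = 30, nrows = 1000)
  mcse <- sd(co0[, 3]) / sqrt(nrow(co0))
  expect_lt(abs(mean(co0[, 3])), 3 * mcse)
})

test_that("separation and single-class responses are flagged, not fitted", {
  d <- data.frame(s_t = rnorm(20), prev_stim_avg = 0, prev_choice_avg = 1,
                  y = 1)
  expect_false(fit_history_logistic(d)$converged)
  set.seed(35)
  d2 <- data.frame(s_t = c(rnorm(10, 5), rnorm(10, -5)),
                   prev_stim_avg = rnorm(20), prev_choice_avg = 0,
                   y = rep(c(1, -1), each = 10))
  fit2 <- fit_history_logistic(d2)
  expect_false(fit2$converged)
  expect_match(fit2$diagnostic, "separation|Hessian")
})

test_that("fitted betas are invariant to the raw stimulus scale", {
  set.seed(36)
  ses <- simulate_session(observer_params(beta_curr = 2.5,
                                          beta_prev_choice = 0.4),
                          quick_config(40L))
  f1 <- fit_history_logistic(build_design(normalize_stimuli_rms(ses)))
  scaled <- ses
  scaled$stimulus_deg <- ses$stimulus_deg * 17.3
  f2 <- fit_history_logistic(build_design(normalize_stimuli_rms(scaled)))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
})

test_that("averaged and lagged models agree when per-lag weights are equal", {
  set.seed(37)
  n <- 6000; b <- 0.2; lags <- 3
  s <- rnorm(n)
  ch <- numeric(n)
  ch[1:lags] <- sample(c(-1, 1), lags, TRUE)
  for (t in (lags + 1):n) {
    z <- 1.5 * s[t] + b * sum(ch[(t - lags):(t - 1)])
    ch[t] <- if (runif(1) < plogis(z)) 1 else -1
  }
  idx <- (lags + 1):n
  avg <- data.frame(s_t = s[idx],
                    prev_choice_avg = vapply(idx, function(t)
                      mean(ch[(t - lags):(t - 1)]), numeric(1)),
                    y = ch[idx])
  fit <- fit_history_logistic(avg)
  expect_equal(fit$coef[["beta_prev_choice"]], lags * b, tolerance = 0.15)
})

test_that("a lag-1-only observer shows its effect at lag 1 and none deeper", {
  set.seed(38)
  par <- observer_params(beta_curr = 2, beta_prev_choice = 0.5,
                         history_horizon = "n_back_1")
  cfg <- paradigm_config(trials_per_staircase = 2500L, mode = "heading_n1")
  ses <- normalize_stimuli_rms(simulate_session(par, cfg))
  fit <- fit_history_logistic(build_design_lagged(ses, lags = 5))
  expect_true(fit$converged)
  expect_equal(fit$coef[["beta_prev_choice_1"]], 0.5, tolerance = 0.15)
  deeper <- fit$coef[paste0("beta_prev_choice_", 2:5)]
  expect_true(all(abs(deeper) < 3 * fit$se[paste0("beta_prev_choice_", 2:5)]))
})
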