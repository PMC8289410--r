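test_that("session tables round-trip losslessly and reject schema violations", {
  set.seed(41)
  co <- simulate_cohort(cohort_spec(n_asd = 1L, n_control = 1L),
                        quick_config(8L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sessions(co$sessions, path)
  back <- read_sessions(path)
  expect_equal(back, co$sessions[, names(back)], tolerance = 1e-12,
               ignore_attr = TRUE)
  bad <- co$sessions
  bad$choice[3] <- 0
  expect_error(write_sessions(bad, path), "choice")
  expect_error(validate_sessions <- serialdep:::validate_sessions(
    co$sessions[, -3]), "missing")
  # mixed conditions in one table are fine
  mixed <- co$sessions
  mixed$condition[mixed$participant_id == "ctl01"] <- "response_invariant"
  expect_silent(serialdep:::validate_sessions(mixed))
  # duplicate trial/step keys are not
  dup <- rbind(co$sessions, co$sessions[1, ])
  expect_error(serialdep:::validate_sessions(dup), "duplicate")
})

test_that("pooled t statistics match the textbook formulas", {
  r <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$df, 4L)
  expect_equal(r$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$cohens_d, -1)
  expect_equal(r$p_adjusted, r$p_raw)
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_raw, 1)
  expect_error(one_sample_t(c(1, 1, 1)), "variance")
  o <- one_sample_t(c(1, 3), null = 0)
  expect_equal(o$cohens_d, 2 / sqrt(2), tolerance = 1e-12)
  # against the closed-form pooled t on random data
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(5 + i %% 4); y <- rnorm(7, 0.3)
    r <- two_sample_t(x, y)
    sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
                 (length(x) + length(y) - 2))
    t_manual <- (mean(x) - mean(y)) /
      (sp * sqrt(1 / length(x) + 1 / length(y)))
    expect_equal(r$t, t_manual, tolerance = 1e-10)
    expect_equal(r$p_raw, 2 * pt(-abs(t_manual), r$df), tolerance = 1e-10)
  }
})

test_that("the x2 Bonferroni policy doubles p and widens the interval", {
  set.seed(43)
  x <- rnorm(10, 0.8); y <- rnorm(12)
  raw <- two_sample_t(x, y)
  adj <- two_sample_t(x, y, adjust = "bonferroni2")
  expect_equal(adj$p_adjusted, min(1, 2 * raw$p_raw))
  expect_equal(adj$conf_level, 0.975)
  expect_equal(adj$cohens_d, raw$cohens_d)
  # 97.5% interval strictly contains the 95% one
  expect_lt(adj$d_ci[1], raw$d_ci[1])
  expect_gt(adj$d_ci[2], raw$d_ci[2])
  # p is capped at 1
  z <- two_sample_t(c(1, 2, 3, 4), c(1.1, 2.1, 2.9, 4.2),
                    adjust = "bonferroni2")
  expect_lte(z$p_adjusted, 1)
})

test_that("Cohen's d intervals match brute-force inversion of the noncentral-t CDF", {
  grid_invert <- function(t_obs, df, prob, scale) {
    # scan ncp on a fine grid for P(T <= t_obs) = prob, then interpolate
    ncps <- seq(t_obs - 8, t_obs + 8, by = 1e-3)
    vals <- suppressWarnings(pt(t_obs, df, ncps))
    i <- which(diff(sign(vals - prob)) != 0)[1]
    ncp <- ncps[i] + 1e-3 * (vals[i] - prob) / (vals[i] - vals[i + 1])
    ncp / scale
  }
  set.seed(44)
  x <- rnorm(9, 1); y <- rnorm(11)
  r <- cohens_d(x, y)
  n1 <- 9; n2 <- 11
  scale <- sqrt(n1 * n2 / (n1 + n2))
  t_obs <- r$d * scale
  expect_equal(r$ci[1], grid_invert(t_obs, 18, 0.975, scale),
               tolerance = 1e-3)
  expect_equal(r$ci[2], grid_invert(t_obs, 18, 0.025, scale),
               tolerance = 1e-3)
  o <- cohens_d(rnorm(8, 0.5), conf_level = 0.975)
  t_o <- o$d * sqrt(8)
  expect_equal(o$ci[1], grid_invert(t_o, 7, 1 - 0.0125, sqrt(8)),
               tolerance = 1e-3)
  expect_equal(o$ci[2], grid_invert(t_o, 7, 0.0125, sqrt(8)),
               tolerance = 1e-3)
  expect_error(cohens_d(c(1, 1, 1)), "zero")
})

test_that("Pearson correlation uses the t transform at df = n - 2", {
  expect_equal(pearson_r(1:5, 1:5)$r, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1))$r, -1)
  set.seed(45)
  x <- rnorm(18); y <- 0.3 * x + rnorm(18)
  r <- pearson_r(x, y)
  expect_equal(r$df, 16)
  t_manual <- r$r * sqrt(16 / (1 - r$r^2))
  expect_equal(r$p, 2 * pt(-abs(t_manual), 16), tolerance = 1e-10)
  big <- pearson_r(rnorm(2000), rnorm(2000))
  expect_lt(abs(big$r), 0.08)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
})

test_that("the pipeline reconciles exclusions and applies the x2 policy selectively", {
  set.seed(46)
  cfg <- paradigm_config(trials_per_staircase = 60L)
  spec <- cohort_spec(n_asd = 3L, n_control = 3L)
  co <- simulate_cohort(spec, cfg)
  # append a stimulus-blind participant who must fail the R2L screen
  blind <- simulate_session(observer_params(beta_curr = 0), cfg,
                            participant_id = "blind01", group = "control")
  sessions <- rbind(co$sessions, blind)
  res <- run_pipeline(sessions, min_trials = 5L)
  expect_s3_class(res, "serialdep_results")
  expect_equal(res$log$n_input, res$log$n_analyzed + res$log$n_excluded)
  expect_true("blind01" %in% res$excluded$participant_id)
  cm <- res$comparisons
  hist_rows <- cm$statistic %in% c("beta_prev_stim_group",
                                   "beta_prev_choice_group")
  expect_equal(sum(hist_rows), 2L)
  expect_equal(cm$p_adjusted[hist_rows],
               pmin(1, 2 * cm$p_raw[hist_rows]))
  expect_true(all(cm$conf_level[hist_rows] == 0.975))
  expect_equal(cm$p_adjusted[!hist_rows], cm$p_raw[!hist_rows])
  expect_true(all(cm$conf_level[!hist_rows] == 0.95))
  expect_true(all(cm$p_adjusted <= 1))
  # determinism: the same seed reproduces the tables exactly
  set.seed(46)
  co2 <- simulate_cohort(spec, cfg)
  blind2 <- simulate_session(observer_params(beta_curr = 0), cfg,
                             participant_id = "blind01", group = "control")
  res2 <- run_pipeline(rbind(co2$sessions, blind2), min_trials = 5L)
  expect_identical(res$participants, res2$participants)
  expect_identical(res$comparisons, res2$comparisons)
  # report writing
  dir <- withr::local_tempdir()
  write_report(res, dir)
  rep_lines <- readLines(file.path(dir, "report.txt"))
  expect_true(any(grepl("blind01", rep_lines)))
  expect_true(file.exists(file.path(dir, "participants.csv")))
  # single participant per group: pipeline runs, contrasts flagged
  one <- run_pipeline(co$sessions[co$sessions$participant_id %in%
                                    c("asd01", "ctl01"), ],
                      min_trials = 5L)
  expect_true(any(grepl("underpowered", one$notes)))
})
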