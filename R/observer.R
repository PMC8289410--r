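#' Generative observer parameters
#'
#' Parameters of the synthetic observer's decision model. The probability of
#' a rightward choice on discrimination t is
#' \deqn{p_t = \lambda + (1 - 2\lambda) \, \mathrm{logistic}(z_t)}
#' \deqn{z_t = \beta_0 + \beta_{curr} s_t + \beta_{ps} \bar{s}_{prev}
#'       + \beta_{pc} \bar{c}_{prev}}
#' where s_t is the current stimulus on the RMS-normalized scale,
#' \eqn{\bar{s}_{prev}} and \eqn{\bar{c}_{prev}} are the mean prior stimulus
#' and mean prior choice (choices coded +1 right / -1 left), and
#' \eqn{\lambda} is a symmetric lapse probability. A negative
#' \eqn{\beta_{ps}} produces adaptation (repulsion from prior stimuli); a
#' positive \eqn{\beta_{pc}} produces a consistency bias (attraction toward
#' prior choices).
#'
#' @param beta0 baseline right/left bias.
#' @param beta_curr weight of the current (normalized) stimulus.
#' @param beta_prev_stim weight of the mean prior stimulus.
#' @param beta_prev_choice weight of the mean prior choice.
#' @param lapse_gen generative lapse probability, in `[0, 0.5)`.
#' @param history_horizon `"per_trial_priors"`: the history terms of a test
#'   response are that trial's designed priors (prior stimuli themselves are
#'   answered from baseline + current stimulus only); `"n_back_1"`: every
#'   discrimination's history is the single previous discrimination.
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(beta0 = 0, beta_curr = 2.5,
                            beta_prev_stim = 0, beta_prev_choice = 0,
                            lapse_gen = 0,
                            history_horizon = c("per_trial_priors",
                                                "n_back_1")) {
  history_horizon <- match.arg(history_horizon)
  stopifnot(lapse_gen >= 0, lapse_gen < 0.5,
            all(is.finite(c(beta0, beta_curr, beta_prev_stim,
                            beta_prev_choice))))
  structure(list(beta0 = beta0, beta_curr = beta_curr,
                 beta_prev_stim = beta_prev_stim,
                 beta_prev_choice = beta_prev_choice,
                 lapse_gen = lapse_gen,
                 history_horizon = history_horizon),
            class = "observer_params")
}

#' Probability of a rightward choice
#'
#' Evaluates the observer's decision model (see [observer_params()]).
#' Vectorized over the stimulus/history inputs.
#'
#' @param params an [observer_params()].
#' @param s_t current stimulus on the normalized scale.
#' @param prev_stim_avg mean prior (normalized) stimulus; 0 for no history.
#' @param prev_choice_avg mean prior choice in `[-1, 1]`; 0 for no history.
#' @return Probability of choosing "right" (+1).
#' @export
choice_probability <- function(params, s_t, prev_stim_avg = 0,
                               prev_choice_avg = 0) {
  stopifnot(inherits(params, "observer_params"),
            all(is.finite(s_t)), all(is.finite(prev_stim_avg)),
            all(is.finite(prev_choice_avg)))
  z <- params$beta0 + params$beta_curr * s_t +
    params$beta_prev_stim * prev_stim_avg +
    params$beta_prev_choice * prev_choice_avg
  params$lapse_gen + (1 - 2 * params$lapse_gen) * stats::plogis(z)
}

# Evaluate expr with a temporarily fixed RNG state, restoring the caller's
# stream afterwards. Used where a quantity must be deterministic per config
# (the nominal RMS) without consuming user-visible randomness.
with_fixed_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.rms_cache <- new.env(parent = emptyenv())

#' Nominal stimulus RMS of a paradigm
#'
#' The fitted history model normalizes stimuli by the RMS of all stimuli a
#' participant actually saw; during closed-loop simulation that RMS is not
#' yet known, so the generative observer uses a nominal RMS fixed per
#' configuration: the prior contribution is analytic
#' (E[s^2] = mu^2 + sigma^2) and the test contribution is a Monte-Carlo
#' average over staircases driven by a reference cumulative-Gaussian
#' observer typical of the task (threshold `sigma_ref_deg`), the two
#' combined with weights proportional to the expected numbers of prior and
#' test discriminations per trial. Deterministic given the configuration.
#'
#' @inheritParams prior_count_pmf
#' @param n_mc_staircases staircase replicates for the test-magnitude term.
#' @param sigma_ref_deg threshold of the reference observer driving the
#'   Monte-Carlo staircases, degrees.
#' @return Scalar RMS in degrees.
#' @export
nominal_rms <- function(config = paradigm_config(), n_mc_staircases = 50L,
                        sigma_ref_deg = 3) {
  key <- paste(c(unlist(unclass(config)), n_mc_staircases, sigma_ref_deg),
               collapse = "|")
  hit <- .rms_cache[[key]]
  if (!is.null(hit)) return(hit)
  test_ms <- with_fixed_seed(760L, {
    unlist(lapply(seq_len(n_mc_staircases), function(i)
      run_staircase(function(m) stats::pnorm(m / sigma_ref_deg),
                    config$trials_per_staircase,
                    config)$magnitude_deg))
  })
  rms_test2 <- mean(test_ms^2)
  out <- if (config$mode == "heading_n1") sqrt(rms_test2) else {
    pmf <- prior_count_pmf(config)
    e_n <- sum(as.numeric(names(pmf)) * pmf)
    rms_prior2 <- config$prior_mu_deg^2 + config$prior_sigma_deg^2
    w_prior <- e_n / (e_n + 1)
    sqrt(w_prior * rms_prior2 + (1 - w_prior) * rms_test2)
  }
  .rms_cache[[key]] <- out
  out
}

condition_label <- function(mode) {
  switch(mode,
         location_primary = "primary",
         location_response_invariant = "response_invariant",
         heading_n1 = "heading_vestibular")
}

#' Simulate one closed-loop session
#'
#' Runs the full paradigm for one synthetic observer: the observer answers
#' every prior and test discrimination via its decision model
#' ([choice_probability()]), and its test responses drive the two
#' interleaved one-up/two-down staircases. In `heading_n1` mode the session
#' is a single sequence of staircase discriminations without designed
#' priors.
#'
#' @param params an [observer_params()].
#' @inheritParams prior_count_pmf
#' @param participant_id,group,condition session labels; `condition`
#'   defaults from the paradigm mode.
#' @return A session table (data.frame) with columns `participant_id`,
#'   `group`, `condition`, `coherence`, `trial_index`, `step_index`, `role`,
#'   `stimulus_deg`, `choice`, `prior_type`, `response_set`. The nominal RMS
#'   used by the generative model is attached as attribute `"rms_nominal"`.
#' @examples
#' set.seed(1)
#' ses <- simulate_session(observer_params(beta_prev_choice = 0.5),
#'                         paradigm_config(trials_per_staircase = 10))
#' head(ses)
#' @export
simulate_session <- function(params, config = paradigm_config(),
                             participant_id = "p01", group = "control",
                             condition = condition_label(config$mode)) {
  stopifnot(inherits(params, "observer_params"),
            inherits(config, "paradigm_config"))
  rms <- nominal_rms(config)
  plan <- generate_trial_plan(config)
  n_trials <- nrow(plan$trials)
  alt_priors <- config$mode == "location_response_invariant"

  if (config$mode == "heading_n1") {
    st <- staircase_init(config)
    st$trials_total <- n_trials
    stim <- numeric(n_trials); cho <- numeric(n_trials)
    prev_s <- 0; prev_c <- 0  # first discrimination has no history
    for (i in seq_len(n_trials)) {
      s_t <- next_test_stimulus(st, config)
      use_hist <- params$history_horizon == "n_back_1" && i > 1L
      p <- choice_probability(params, s_t / rms,
                              if (use_hist) prev_s else 0,
                              if (use_hist) prev_c else 0)
      ch <- if (stats::runif(1) < p) 1 else -1
      st <- staircase_update(st, sign(s_t) == ch)
      prev_s <- s_t / rms; prev_c <- ch
      stim[i] <- s_t; cho[i] <- ch
    }
    out <- data.frame(trial_index = seq_len(n_trials), step_index = 1L,
                      role = "test", stimulus_deg = stim, choice = cho,
                      prior_type = NA_character_, response_set = "main")
  } else {
    stairs <- list(left = staircase_init(config),
                   right = staircase_init(config))
    n_rows <- sum(plan$trials$n_priors) + n_trials
    trial_i <- integer(n_rows); step_i <- integer(n_rows)
    role_v <- character(n_rows); stim <- numeric(n_rows)
    cho <- numeric(n_rows); ptype <- character(n_rows)
    prev_s <- 0; prev_c <- 0
    at <- 0L
    for (i in seq_len(n_trials)) {
      pt <- plan$trials$prior_type[i]
      ps <- plan$priors[[i]]
      n_p <- length(ps)
      if (params$history_horizon == "per_trial_priors") {
        # priors answered from baseline + stimulus alone
        pp <- choice_probability(params, ps / rms)
        p_choice <- ifelse(stats::runif(n_p) < pp, 1, -1)
        hs <- mean(ps) / rms; hc <- mean(p_choice)
      } else {
        p_choice <- numeric(n_p)
        for (j in seq_len(n_p)) {
          pp <- choice_probability(params, ps[j] / rms, prev_s, prev_c)
          p_choice[j] <- if (stats::runif(1) < pp) 1 else -1
          prev_s <- ps[j] / rms; prev_c <- p_choice[j]
        }
        hs <- prev_s; hc <- prev_c
      }
      s_t <- next_test_stimulus(stairs[[pt]], config)
      p <- choice_probability(params, s_t / rms, hs, hc)
      ch <- if (stats::runif(1) < p) 1 else -1
      stairs[[pt]] <- staircase_update(stairs[[pt]], sign(s_t) == ch)
      if (params$history_horizon == "n_back_1") {
        prev_s <- s_t / rms; prev_c <- ch
      }
      idx <- at + seq_len(n_p + 1L)
      trial_i[idx] <- i
      step_i[idx] <- seq_len(n_p + 1L)
      role_v[idx] <- c(rep("prior", n_p), "test")
      stim[idx] <- c(ps, s_t)
      cho[idx] <- c(p_choice, ch)
      ptype[idx] <- pt
      at <- at + n_p + 1L
    }
    out <- data.frame(trial_index = trial_i, step_index = step_i,
                      role = role_v, stimulus_deg = stim, choice = cho,
                      prior_type = ptype,
                      response_set = ifelse(
                        alt_priors & role_v == "prior", "alternate",
                        "main"))
  }
  out <- cbind(data.frame(participant_id = participant_id, group = group,
                          condition = condition, coherence = NA_real_,
                          stringsAsFactors = FALSE),
               out)
  attr(out, "rms_nominal") <- rms
  attr(out, "observer_params") <- params
  out
}

#' Cohort specification
#'
#' Per-group sampling distributions (mean, SD) of the observer parameters
#' for a synthetic two-group cohort. The default cohort emulates the group
#' contrast of interest: a larger mean prior-choice weight in the ASD group
#' (0.6 vs 0.3, SD 0.15) with equal current-stimulus weight, a small
#' negative prior-stimulus weight, and a ~3% lapse rate in both groups.
#'
#' @param n_asd,n_control participants per group.
#' @param asd,control named lists of `c(mean, sd)` pairs for `beta0`,
#'   `beta_curr`, `beta_prev_stim`, `beta_prev_choice`, `lapse_gen`.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_asd = 18L, n_control = 20L,
                        asd = list(beta0 = c(0, 0.1),
                                   beta_curr = c(2.5, 0.5),
                                   beta_prev_stim = c(-0.15, 0.1),
                                   beta_prev_choice = c(0.6, 0.15),
                                   lapse_gen = c(0.03, 0.015)),
                        control = list(beta0 = c(0, 0.1),
                                       beta_curr = c(2.5, 0.5),
                                       beta_prev_stim = c(-0.15, 0.1),
                                       beta_prev_choice = c(0.3, 0.15),
                                       lapse_gen = c(0.03, 0.015))) {
  stopifnot(n_asd >= 1, n_control >= 1)
  check <- function(g) {
    stopifnot(setequal(names(g), c("beta0", "beta_curr", "beta_prev_stim",
                                   "beta_prev_choice", "lapse_gen")),
              all(vapply(g, function(v) length(v) == 2 && v[2] >= 0,
                         logical(1))))
  }
  check(asd); check(control)
  structure(list(n_asd = as.integer(n_asd),
                 n_control = as.integer(n_control),
                 asd = asd, control = control),
            class = "cohort_spec")
}

draw_params <- function(g, history_horizon) {
  draw <- function(v) stats::rnorm(1, v[1], v[2])
  lapse <- min(max(draw(g$lapse_gen), 0), 0.25)
  observer_params(beta0 = draw(g$beta0),
                  beta_curr = draw(g$beta_curr),
                  beta_prev_stim = draw(g$beta_prev_stim),
                  beta_prev_choice = draw(g$beta_prev_choice),
                  lapse_gen = lapse,
                  history_horizon = history_horizon)
}

#' Simulate a synthetic cohort
#'
#' Draws observer parameters per participant from the group distributions of
#' a [cohort_spec()] and simulates one session each, recording the
#' ground-truth parameters for recovery scoring.
#'
#' @param spec a [cohort_spec()].
#' @inheritParams prior_count_pmf
#' @param history_horizon passed to [observer_params()].
#' @return A list with `sessions` (one stacked session table) and `truth`
#'   (data.frame: participant_id, group, the true parameters).
#' @export
simulate_cohort <- function(spec = cohort_spec(),
                            config = paradigm_config(),
                            history_horizon = "per_trial_priors") {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- c(sprintf("asd%02d", seq_len(spec$n_asd)),
           sprintf("ctl%02d", seq_len(spec$n_control)))
  groups <- rep(c("ASD", "control"), c(spec$n_asd, spec$n_control))
  sessions <- vector("list", length(ids))
  truth <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- if (groups[i] == "ASD") spec$asd else spec$control
    par <- draw_params(g, history_horizon)
    sessions[[i]] <- simulate_session(par, config, ids[i], groups[i])
    truth[[i]] <- data.frame(participant_id = ids[i], group = groups[i],
                             beta0 = par$beta0, beta_curr = par$beta_curr,
                             beta_prev_stim = par$beta_prev_stim,
                             beta_prev_choice = par$beta_prev_choice,
                             lapse_gen = par$lapse_gen)
  }
  list(sessions = do.call(rbind, sessions), truth = do.call(rbind, truth))
}
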