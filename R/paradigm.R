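#' Paradigm configuration
#'
#' Bundles every constant of the biased-prior staircase paradigm: the two
#' prior-location distributions, the discrete-normal distribution of the
#' number of priors per trial, and the one-up/two-down staircase parameters.
#' Defaults reproduce the location-discrimination task: priors drawn from
#' N(+3.82, 3.82) degrees (right bias) or N(-3.82, 3.82) (left bias), 1-9
#' priors per trial with discrete-normal weights (mu 5, sigma 2), and two
#' interleaved 100-trial staircases starting at 6.36 deg with multiplicative
#' step 0.6 and a 25.46 deg cap.
#'
#' @param prior_mu_deg absolute mean of the biased prior-location
#'   distribution, degrees.
#' @param prior_sigma_deg SD of the prior-location distribution, degrees.
#' @param count_lo,count_hi support of the prior-count distribution.
#' @param count_mu,count_sigma mean and SD of the underlying normal density
#'   for the prior count.
#' @param start_magnitude_deg initial staircase test magnitude, degrees.
#' @param step_factor multiplicative staircase step in (0, 1); magnitude is
#'   multiplied by it after two successive correct responses and divided by
#'   it after an error.
#' @param max_magnitude_deg staircase magnitude cap, degrees.
#' @param trials_per_staircase test trials per prior type.
#' @param test_sign_prob probability that a test stimulus is positive
#'   (rightward).
#' @param mode `"location_primary"` (different colours/keys are not
#'   simulated, so `"location_response_invariant"` is an alias differing only
#'   in its condition label), or `"heading_n1"`: single discriminations with
#'   no designed priors, prior type defined post hoc by the previous choice.
#' @return An object of class `paradigm_config` (a named list).
#' @examples
#' cfg <- paradigm_config()
#' cfg$step_factor
#' @export
paradigm_config <- function(prior_mu_deg = 3.82,
                            prior_sigma_deg = 3.82,
                            count_lo = 1L, count_hi = 9L,
                            count_mu = 5, count_sigma = 2,
                            start_magnitude_deg = 6.36,
                            step_factor = 0.6,
                            max_magnitude_deg = 25.46,
                            trials_per_staircase = 100L,
                            test_sign_prob = 0.5,
                            mode = c("location_primary",
                                     "location_response_invariant",
                                     "heading_n1")) {
  mode <- match.arg(mode)
  stopifnot(prior_sigma_deg > 0, count_lo <= count_hi,
            count_sigma > 0, start_magnitude_deg > 0,
            step_factor > 0, step_factor < 1,
            max_magnitude_deg >= start_magnitude_deg,
            trials_per_staircase >= 1,
            test_sign_prob >= 0, test_sign_prob <= 1)
  structure(list(
    prior_mu_deg = prior_mu_deg,
    prior_sigma_deg = prior_sigma_deg,
    count_lo = as.integer(count_lo), count_hi = as.integer(count_hi),
    count_mu = count_mu, count_sigma = count_sigma,
    start_magnitude_deg = start_magnitude_deg,
    step_factor = step_factor,
    max_magnitude_deg = max_magnitude_deg,
    trials_per_staircase = as.integer(trials_per_staircase),
    test_sign_prob = test_sign_prob,
    mode = mode
  ), class = "paradigm_config")
}

#' Read / write a paradigm configuration as flat YAML
#'
#' @param path file path.
#' @return `read_paradigm_config()` returns a [paradigm_config()];
#'   `write_paradigm_config()` returns `path` invisibly.
#' @export
read_paradigm_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(paradigm_config, vals)
}

#' @rdname read_paradigm_config
#' @param config a [paradigm_config()].
#' @export
write_paradigm_config <- function(config, path) {
  stopifnot(inherits(config, "paradigm_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Probability mass function of the prior count
#'
#' Number of prior stimuli per trial: a discrete normal on the integers
#' `lo..hi`, i.e. pmf(k) proportional to exp(-(k - mu)^2 / (2 sigma^2)),
#' normalized over the support.
#'
#' @param config a [paradigm_config()].
#' @return Named numeric vector of probabilities over `lo..hi`, summing to 1.
#' @export
prior_count_pmf <- function(config = paradigm_config()) {
  k <- config$count_lo:config$count_hi
  w <- exp(-(k - config$count_mu)^2 / (2 * config$count_sigma^2))
  stats::setNames(w / sum(w), k)
}

#' Sample the number of priors for one trial
#'
#' @inheritParams prior_count_pmf
#' @param n number of draws.
#' @return Integer vector in `lo..hi`. Uses the current RNG stream
#'   (`set.seed()` for reproducibility).
#' @export
sample_prior_count <- function(n = 1L, config = paradigm_config()) {
  pmf <- prior_count_pmf(config)
  sample(config$count_lo:config$count_hi, n, replace = TRUE, prob = pmf)
}

#' Sample biased prior locations
#'
#' Prior stimuli are drawn from a normal distribution whose mean sits to the
#' left or right of the reference (0 deg); with the default mean equal to its
#' SD, about 16% of priors (Phi(-1) = 0.159) fall on the side opposite the
#' bias.
#'
#' @param n number of draws.
#' @param direction `"left"` or `"right"`.
#' @inheritParams prior_count_pmf
#' @return Numeric vector of signed stimulus locations in degrees.
#' @export
sample_prior_location <- function(n = 1L, direction = c("right", "left"),
                                  config = paradigm_config()) {
  direction <- match.arg(direction)
  mu <- if (direction == "right") config$prior_mu_deg else -config$prior_mu_deg
  stats::rnorm(n, mean = mu, sd = config$prior_sigma_deg)
}

#' Create a fresh staircase state
#'
#' @inheritParams prior_count_pmf
#' @return A list with fields `magnitude_deg`, `consec_correct`,
#'   `trials_done`, `trials_total`, plus the step parameters.
#' @export
staircase_init <- function(config = paradigm_config()) {
  list(magnitude_deg = config$start_magnitude_deg,
       consec_correct = 0L,
       trials_done = 0L,
       trials_total = config$trials_per_staircase,
       step_factor = config$step_factor,
       max_magnitude_deg = config$max_magnitude_deg)
}

#' One-up/two-down staircase update
#'
#' After a single incorrect response the test magnitude is divided by the
#' step factor (easier), capped at the maximum; after two successive correct
#' responses it is multiplied by the step factor (harder). This rule
#' converges to the ~70.7% correct point (p with p^2 = 0.5). Prior
#' discriminations never pass through this function; only test responses
#' drive the staircase.
#'
#' @param state a staircase state from [staircase_init()].
#' @param correct logical, was the test response correct?
#' @return The updated state.
#' @export
staircase_update <- function(state, correct) {
  stopifnot(is.logical(correct), length(correct) == 1L, !is.na(correct))
  if (!correct) {
    state$magnitude_deg <- min(state$magnitude_deg / state$step_factor,
                               state$max_magnitude_deg)
    state$consec_correct <- 0L
  } else if (state$consec_correct == 1L) {
    state$magnitude_deg <- state$magnitude_deg * state$step_factor
    state$consec_correct <- 0L
  } else {
    state$consec_correct <- 1L
  }
  state$trials_done <- state$trials_done + 1L
  state
}

#' Draw the next test stimulus from a staircase
#'
#' The magnitude comes from the staircase; the sign is drawn at random
#' (positive with probability `test_sign_prob`) so test locations are
#' left/right balanced.
#'
#' @param state a staircase state.
#' @inheritParams prior_count_pmf
#' @return Signed stimulus in degrees.
#' @export
next_test_stimulus <- function(state, config = paradigm_config()) {
  if (state$trials_done >= state$trials_total)
    stop("staircase exhausted: ", state$trials_total, " trials already run")
  sgn <- if (stats::runif(1) < config$test_sign_prob) 1 else -1
  sgn * state$magnitude_deg
}

#' Plan the trial order and prior stimuli of one session
#'
#' Interleaves the two prior-type staircases pseudo-randomly: each next trial
#' is drawn without replacement from the remaining trial budget of the two
#' staircases. For every location trial the plan carries the prior type, the
#' sampled number of priors (1-9) and their sampled locations. Test
#' magnitudes are *not* in the plan: they depend on the observer's running
#' responses and are produced trial by trial by the staircases
#' ([next_test_stimulus()], [staircase_update()]).
#'
#' In `heading_n1` mode trials are single discriminations without designed
#' priors (the plan has one trial per staircase trial, two staircase budgets
#' merged into one sequence); prior type is assigned post hoc from the
#' previous choice during analysis.
#'
#' @inheritParams prior_count_pmf
#' @return A list with `trials` (a data.frame: trial, prior_type, n_priors)
#'   and `priors` (list of numeric vectors of prior locations per trial;
#'   empty in heading mode).
#' @export
generate_trial_plan <- function(config = paradigm_config()) {
  n_per <- config$trials_per_staircase
  if (config$mode == "heading_n1") {
    n_tot <- 2L * n_per
    trials <- data.frame(trial = seq_len(n_tot),
                         prior_type = NA_character_,
                         n_priors = 0L)
    return(list(trials = trials, priors = rep(list(numeric(0)), n_tot)))
  }
  # pseudo-random interleaving: draw the staircase of each successive trial
  # without replacement from the remaining budgets
  order <- sample(rep(c("left", "right"), each = n_per))
  n_priors <- sample_prior_count(length(order), config)
  priors <- lapply(seq_along(order), function(i)
    sample_prior_location(n_priors[i], order[i], config))
  trials <- data.frame(trial = seq_along(order),
                       prior_type = order,
                       n_priors = n_priors)
  list(trials = trials, priors = priors)
}

#' Drive one staircase with an arbitrary performance function
#'
#' Runs a single one-up/two-down staircase for `n_trials` test responses,
#' where the probability of a correct response at magnitude m is
#' `p_correct(m)`. Used for convergence diagnostics: for any stationary
#' observer with a monotone psychometric function and no lapses, the
#' staircase converges to ~70.7% correct.
#'
#' @param p_correct function mapping magnitude (deg) to P(correct).
#' @param n_trials number of test trials.
#' @inheritParams prior_count_pmf
#' @return data.frame with columns `trial`, `magnitude_deg`, `correct`.
#' @export
run_staircase <- function(p_correct, n_trials = 100L,
                          config = paradigm_config()) {
  st <- staircase_init(config)
  st$trials_total <- as.integer(n_trials)
  mag <- numeric(n_trials)
  cor <- logical(n_trials)
  for (i in seq_len(n_trials)) {
    mag[i] <- st$magnitude_deg
    cor[i] <- stats::runif(1) < p_correct(st$magnitude_deg)
    st <- staircase_update(st, cor[i])
  }
  data.frame(trial = seq_len(n_trials), magnitude_deg = mag, correct = cor)
}

#' Asymptotic staircase percent correct
#'
#' Simulates many independent sessions of the interleaved one-up/two-down
#' staircase driven by a stationary cumulative-Gaussian observer with zero
#' lapse, discards a burn-in, and returns the overall percent correct. The
#' one-up/two-down rule targets the magnitude where P(correct)^2 = 0.5, i.e.
#' ~70.7% correct.
#'
#' @param n_sessions number of simulated sessions (two staircases each).
#' @param sigma_deg SD of the observer's cumulative-Gaussian psychometric
#'   function (P(correct at magnitude m) = pnorm(m / sigma_deg)).
#' @param burn_in staircase trials discarded from the start of each
#'   staircase.
#' @inheritParams prior_count_pmf
#' @return Percent correct (scalar, 0-100) across all retained trials.
#' @export
staircase_convergence <- function(n_sessions = 100L, sigma_deg = 3,
                                  burn_in = 20L,
                                  config = paradigm_config()) {
  stopifnot(n_sessions >= 1, burn_in < config$trials_per_staircase)
  p_correct <- function(m) stats::pnorm(m / sigma_deg)
  keep <- (burn_in + 1L):config$trials_per_staircase
  correct <- vapply(seq_len(n_sessions), function(i) {
    a <- run_staircase(p_correct, config$trials_per_staircase, config)
    b <- run_staircase(p_correct, config$trials_per_staircase, config)
    mean(c(a$correct[keep], b$correct[keep]))
  }, numeric(1))
  100 * mean(correct)
}
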