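# Small deterministic fixtures built in code.

# a hand-written two-trial session (left and right prior types)
tiny_session <- function() {
  data.frame(
    participant_id = "p1", group = "control", condition = "primary",
    coherence = NA_real_,
    trial_index = c(1L, 1L, 1L, 2L, 2L),
    step_index = c(1L, 2L, 3L, 1L, 2L),
    role = c("prior", "prior", "test", "prior", "test"),
    stimulus_deg = c(3, -4, 1.5, -2, -1),
    choice = c(1, -1, 1, -1, -1),
    prior_type = c("right", "right", "right", "left", "left"),
    response_set = "main")
}

# fast paradigm for structural tests
quick_config <- function(n = 30L, mode = "location_primary") {
  paradigm_config(trials_per_staircase = n, mode = mode)
}

# session with designed prior types but hand-chosen test observations, for
# exact delta-PSE arithmetic (identical per-type test sets etc.)
typed_test_session <- function(s_left, c_left, s_right, c_right) {
  n_l <- length(s_left); n_r <- length(s_right)
  data.frame(
    participant_id = "p1", group = "control", condition = "primary",
    coherence = NA_real_,
    trial_index = seq_len(n_l + n_r), step_index = 1L, role = "test",
    stimulus_deg = c(s_left, s_right),
    choice = c(c_left, c_right),
    prior_type = rep(c("left", "right"), c(n_l, n_r)),
    response_set = "main")
}

# simulate a psychometric data set on a fixed grid
grid_psych_data <- function(n, mu, sigma, lapse,
                            grid = seq(-12, 12, by = 1.5)) {
  s <- sample(grid, n, replace = TRUE)
  p <- psychometric_prob(s, mu, sigma, lapse)
  choice <- ifelse(stats::runif(n) < p, 1, -1)
  list(s = s, choice = choice)
}
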