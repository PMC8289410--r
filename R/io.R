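session_columns <- c("participant_id", "group", "condition", "coherence",
                     "trial_index", "step_index", "role", "stimulus_deg",
                     "choice", "prior_type", "response_set")

valid_conditions <- c("primary", "response_invariant", "heading_vestibular",
                      "heading_visual", "heading_combined")

validate_sessions <- function(tab) {
  missing <- setdiff(session_columns, names(tab))
  if (length(missing))
    stop("missing session columns: ", paste(missing, collapse = ", "))
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop(what, " (rows ", paste(utils::head(i, 5), collapse = ", "),
           if (length(i) > 5) ", ..." else "", ")")
  }
  bad_row(!tab$choice %in% c(-1, 1), "choice must be -1 or +1")
  bad_row(!tab$role %in% c("prior", "test"), "role must be prior/test")
  bad_row(!tab$condition %in% valid_conditions,
          paste("condition must be one of",
                paste(valid_conditions, collapse = "/")))
  bad_row(!is.na(tab$prior_type) & !tab$prior_type %in% c("left", "right"),
          "prior_type must be left/right or NA")
  bad_row(!tab$response_set %in% c("main", "alternate"),
          "response_set must be main/alternate")
  bad_row(!is.finite(tab$stimulus_deg), "stimulus_deg must be finite")
  key <- paste(tab$participant_id, tab$condition, tab$trial_index,
               tab$step_index)
  if (anyDuplicated(key))
    stop("duplicate (participant_id, condition, trial_index, step_index)")
  invisible(tab)
}

#' Read / write session tables
#'
#' Sessions are exchanged as UTF-8 comma-separated text with a fixed header
#' (participant_id, group, condition, coherence, trial_index, step_index,
#' role, stimulus_deg, choice, prior_type, response_set). Reading validates
#' the schema (choices +/-1, roles prior/test, unique trial/step keys) and
#' rejects violations with row-level messages; write-then-read is lossless.
#'
#' @param path file path.
#' @return `read_sessions()`: a validated session data.frame;
#'   `write_sessions()`: `path`, invisibly.
#' @export
read_sessions <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(prior_type = "character",
                                        coherence = "numeric"))
  tab$prior_type[!is.na(tab$prior_type) & tab$prior_type == ""] <-
    NA_character_
  validate_sessions(tab)
  tab[session_columns]
}

#' @rdname read_sessions
#' @param sessions a session table (e.g. from [simulate_session()] or
#'   [simulate_cohort()]).
#' @export
write_sessions <- function(sessions, path) {
  validate_sessions(sessions)
  utils::write.csv(sessions[session_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read / write ground-truth observer parameters
#'
#' Sidecar table mapping participant id to the generative observer
#' parameters of a synthetic cohort, for parameter-recovery scoring.
#'
#' @param path file path.
#' @param truth the `truth` data.frame from [simulate_cohort()].
#' @return `read_truth()` returns the data.frame; `write_truth()` returns
#'   `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
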