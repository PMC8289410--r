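history_mode_for <- function(condition) {
  if (condition %in% c("primary", "response_invariant")) "per_trial_priors"
  else "n_back_1"
}

prior_typing_for <- function(condition) {
  if (condition %in% c("primary", "response_invariant")) "designed_bias"
  else "previous_choice"
}

analyze_participant <- function(ses, screen_cutoff, min_trials) {
  cond <- ses$condition[1]
  ses <- normalize_stimuli_rms(ses)
  res <- list(participant_id = ses$participant_id[1],
              group = ses$group[1], condition = cond,
              rms = attr(ses, "rms"))
  dp <- try(delta_pse(ses, prior_typing_for(cond), min_trials),
            silent = TRUE)
  if (inherits(dp, "try-error")) {
    res$excluded <- TRUE
    res$exclusion_reason <- "delta-PSE not computable"
    return(res)
  }
  res$pse_left <- dp$pse_left
  res$pse_right <- dp$pse_right
  res$delta_pse <- dp$delta
  r2 <- c(left = if (is.null(dp$fit_left)) NA_real_ else dp$fit_left$r2l,
          right = if (is.null(dp$fit_right)) NA_real_ else dp$fit_right$r2l)
  res$r2l_min <- suppressWarnings(min(r2, na.rm = FALSE))
  thr <- c(if (!is.null(dp$fit_left)) dp$fit_left$threshold_deg,
           if (!is.null(dp$fit_right)) dp$fit_right$threshold_deg)
  res$log_threshold <- if (length(thr) && all(is.finite(thr) & thr > 0))
    mean_log_threshold(thr) else NA_real_
  # lapse: pooled over all discriminations of the condition
  pooled <- fit_psychometric(ses$stimulus_deg, ses$choice)
  res$lapse <- pooled$lapse
  res$easy_pc <- easy_percent_correct(ses)
  keep <- !dp$flagged && !is.na(res$r2l_min) &&
    screen_participant(c(r2["left"], r2["right"]), screen_cutoff)
  hf <- fit_history_logistic(build_design(ses, history_mode_for(cond)))
  res$beta0 <- hf$coef[["beta0"]]
  res$beta_curr <- hf$coef[["beta_curr"]]
  res$beta_prev_stim <- hf$coef[["beta_prev_stim"]]
  res$beta_prev_choice <- hf$coef[["beta_prev_choice"]]
  res$history_converged <- hf$converged
  res$excluded <- !keep || !hf$converged
  res$exclusion_reason <- if (!keep) "psychometric screen (R2L)"
    else if (!hf$converged) paste("history fit:", hf$diagnostic)
    else ""
  res
}

as_row <- function(res) {
  cols <- c("participant_id", "group", "condition", "rms", "pse_left",
            "pse_right", "delta_pse", "r2l_min", "log_threshold", "lapse",
            "easy_pc", "beta0", "beta_curr", "beta_prev_stim",
            "beta_prev_choice", "history_converged", "excluded",
            "exclusion_reason")
  vals <- lapply(cols, function(cc)
    if (is.null(res[[cc]])) NA else res[[cc]])
  stats::setNames(as.data.frame(vals, stringsAsFactors = FALSE), cols)
}

comparison_row <- function(cmp, condition) {
  data.frame(condition = condition, statistic = cmp$statistic, t = cmp$t,
             df = cmp$df, p_raw = cmp$p_raw, p_adjusted = cmp$p_adjusted,
             cohens_d = cmp$cohens_d, d_lo = cmp$d_ci[1],
             d_hi = cmp$d_ci[2], conf_level = cmp$conf_level,
             stringsAsFactors = FALSE)
}

group_comparisons <- function(part) {
  cond <- part$condition[1]
  out <- list(); notes <- character()
  add <- function(expr, label) {
    cmp <- try(expr, silent = TRUE)
    if (inherits(cmp, "try-error"))
      notes <<- c(notes, paste0(label, ": not computed (",
                                attr(cmp, "condition")$message, ")"))
    else out[[length(out) + 1L]] <<- comparison_row(cmp, cond)
  }
  for (g in intersect(c("ASD", "control"), part$group)) {
    v <- part$delta_pse[part$group == g]
    if (length(v) >= 2)
      add(one_sample_t(v, name = paste0("delta_pse_vs0_", g)),
          paste0("delta_pse_vs0_", g))
    else notes <- c(notes,
                    paste0("delta_pse_vs0_", g, ": underpowered (n = ",
                           length(v), ")"))
  }
  a <- part[part$group == "ASD", ]
  c_ <- part[part$group == "control", ]
  if (nrow(a) >= 2 && nrow(c_) >= 2) {
    add(two_sample_t(a$delta_pse, c_$delta_pse, "delta_pse_group"),
        "delta_pse_group")
    add(two_sample_t(a$beta_prev_stim, c_$beta_prev_stim,
                     "beta_prev_stim_group", adjust = "bonferroni2"),
        "beta_prev_stim_group")
    add(two_sample_t(a$beta_prev_choice, c_$beta_prev_choice,
                     "beta_prev_choice_group", adjust = "bonferroni2"),
        "beta_prev_choice_group")
    add(two_sample_t(a$beta0, c_$beta0, "beta0_group"), "beta0_group")
    add(two_sample_t(a$beta_curr, c_$beta_curr, "beta_curr_group"),
        "beta_curr_group")
    add(two_sample_t(a$lapse, c_$lapse, "lapse_group"), "lapse_group")
    add(two_sample_t(a$easy_pc, c_$easy_pc, "easy_pc_group"),
        "easy_pc_group")
    add(two_sample_t(a$log_threshold, c_$log_threshold,
                     "log_threshold_group"), "log_threshold_group")
  } else {
    notes <- c(notes, sprintf(
      "group contrasts underpowered (ASD n = %d, control n = %d)",
      nrow(a), nrow(c_)))
  }
  list(table = if (length(out)) do.call(rbind, out) else NULL,
       notes = notes)
}

#' Run the full serial-dependence analysis pipeline
#'
#' Per participant and condition: RMS-normalize stimuli, fit per-prior-type
#' psychometric functions and the pooled-lapse fit, apply the
#' pseudo-R-squared inclusion screen, compute the PSE shift (delta-PSE),
#' fit the choice-history logistic model, then run the group-level
#' statistics. The two history coefficients (prior stimuli, prior choices)
#' are compared between groups under the times-two Bonferroni policy (97.5%
#' CIs); all other comparisons carry raw p-values. Excluded participants
#' (failed screen or non-converged history fit) are enumerated, and the
#' counts reconcile: analyzed + excluded = input.
#'
#' @param sessions a session table (possibly many participants/conditions).
#' @param screen_cutoff pseudo-R-squared inclusion cutoff.
#' @param min_trials minimum test trials per prior type.
#' @return An object of class `serialdep_results`: `participants`
#'   (per-participant table, all rows, with `excluded` flags),
#'   `comparisons` (tidy group-statistics table), `excluded` (ids +
#'   reasons), `notes`, `log`.
#' @export
run_pipeline <- function(sessions, screen_cutoff = 0.5, min_trials = 10L) {
  validate_sessions(sessions)
  parts <- split(sessions,
                 list(sessions$participant_id, sessions$condition),
                 drop = TRUE)
  # stable order: by condition then participant id
  key <- vapply(parts, function(p)
    paste(p$condition[1], p$participant_id[1]), character(1))
  parts <- parts[order(key)]
  rows <- do.call(rbind, lapply(parts, function(p)
    as_row(analyze_participant(p, screen_cutoff, min_trials))))
  rownames(rows) <- NULL
  analyzed <- rows[!rows$excluded, , drop = FALSE]
  comp <- NULL; notes <- character()
  for (cond in unique(analyzed$condition)) {
    gc <- group_comparisons(analyzed[analyzed$condition == cond, ,
                                     drop = FALSE])
    comp <- rbind(comp, gc$table)
    notes <- c(notes, gc$notes)
  }
  if (nrow(analyzed) == 0)
    stop("no participants survive the inclusion screen")
  structure(list(
    participants = rows,
    comparisons = comp,
    excluded = rows[rows$excluded,
                    c("participant_id", "condition", "exclusion_reason")],
    notes = notes,
    log = list(package_version = as.character(
                 utils::packageVersion("serialdep")),
               screen_cutoff = screen_cutoff,
               n_input = nrow(rows),
               n_analyzed = nrow(analyzed),
               n_excluded = sum(rows$excluded))),
    class = "serialdep_results")
}

#' @export
print.serialdep_results <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' Plain-text analysis report
#'
#' @param results a [run_pipeline()] result.
#' @return Character vector of report lines.
#' @export
report_text <- function(results) {
  stopifnot(inherits(results, "serialdep_results"))
  l <- results$log
  lines <- c(
    "Serial-dependence analysis report",
    sprintf("serialdep %s | participants in: %d, analyzed: %d, excluded: %d",
            l$package_version, l$n_input, l$n_analyzed, l$n_excluded),
    sprintf("inclusion screen: every psychometric R2L > %g", l$screen_cutoff),
    "")
  if (nrow(results$excluded)) {
    lines <- c(lines, "Excluded participants:",
               sprintf("  %s [%s]: %s", results$excluded$participant_id,
                       results$excluded$condition,
                       results$excluded$exclusion_reason), "")
  }
  if (!is.null(results$comparisons)) {
    cm <- results$comparisons
    lines <- c(lines, "Group statistics:",
               sprintf("  [%s] %s: t(%d) = %.2f, p = %.4g%s, d = %.2f, %s%% CI [%.2f, %.2f]",
                       cm$condition, cm$statistic, cm$df, cm$t,
                       cm$p_adjusted,
                       ifelse(cm$conf_level > 0.95, " (x2 Bonferroni)", ""),
                       cm$cohens_d, format(100 * cm$conf_level), cm$d_lo,
                       cm$d_hi))
  }
  if (length(results$notes))
    lines <- c(lines, "", "Notes:", paste0("  ", results$notes))
  lines <- c(lines, "",
             "Omnibus MANOVA / mixed-ANOVA and Bayes factors are outside",
             "this pipeline; use standard statistical software on the",
             "participants table if needed.")
  lines
}

#' Write the analysis report and tidy result tables
#'
#' Writes `report.txt`, `participants.csv` and `comparisons.csv` into a
#' directory.
#'
#' @param results a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(results, dir) {
  stopifnot(inherits(results, "serialdep_results"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(report_text(results), file.path(dir, "report.txt"))
  utils::write.csv(results$participants,
                   file.path(dir, "participants.csv"), row.names = FALSE)
  if (!is.null(results$comparisons))
    utils::write.csv(results$comparisons,
                     file.path(dir, "comparisons.csv"), row.names = FALSE)
  invisible(dir)
}
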