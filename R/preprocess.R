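# Inclusion/exclusion filters applied to session logs before release:
# first-assessment selection, the 24-hour pause rule, the interleaved-test
# rule, and the 15-minute trail-making rule. All thresholds are strict
# ("more than" / "longer than"); pauses are measured end-of-subtest to
# start-of-next-subtest.

exclusion_reasons <- function() {
  c("pause_gt_24h", "interleaved_tests", "slow_trails",
    "not_first_assessment", "missing_required_demographics")
}

new_exclusion_report <- function() {
  r <- stats::setNames(vector("list", length(exclusion_reasons())),
                       exclusion_reasons())
  for (k in names(r)) r[[k]] <- character()
  structure(list(users = r), class = "exclusion_report")
}

add_excluded <- function(report, reason, user_ids) {
  report$users[[reason]] <- sort(unique(c(report$users[[reason]],
                                          as.character(user_ids))))
  report
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion report\n")
  for (k in names(x$users)) {
    cat(sprintf("  %-32s %d user(s)\n", k, length(x$users[[k]])))
  }
  invisible(x)
}

#' Counts per exclusion reason
#' @param report an exclusion report.
#' @return named integer vector of excluded-user counts per reason.
#' @export
exclusion_counts <- function(report) {
  vapply(report$users, length, integer(1))
}

# Per-run summary used by the time-based filters.
run_spans <- function(logs) {
  runs <- unique(logs[, c("user_id", "test_run_id", "battery_id")])
  runs$first_start <- tapply(logs$start_time, logs$test_run_id,
                             min)[runs$test_run_id]
  runs$last_end <- tapply(logs$end_time, logs$test_run_id,
                          max)[runs$test_run_id]
  runs
}

#' Keep only each participant's first assessment
#'
#' Retains, for each user, the test run whose earliest subtest start time is
#' minimal; ties are broken by the lexicographically smaller test_run_id so
#' the result is invariant under input reordering.
#'
#' @param logs a session-log data.frame (see [session_log()]).
#' @param report an exclusion report to extend (optional).
#' @return list with \code{kept} (session logs) and \code{report}.
#' @export
select_first_assessment <- function(logs, report = new_exclusion_report()) {
  if (nrow(logs) == 0L) return(list(kept = logs, report = report))
  if (anyNA(logs$start_time)) {
    stop("select_first_assessment requires start_time on every entry",
         call. = FALSE)
  }
  runs <- run_spans(logs)
  runs <- runs[order(runs$user_id, runs$first_start, runs$test_run_id), ]
  keep_run <- runs$test_run_id[!duplicated(runs$user_id)]
  dropped <- runs[!runs$test_run_id %in% keep_run, ]
  report <- add_excluded(report, "not_first_assessment", dropped$user_id)
  list(kept = logs[logs$test_run_id %in% keep_run, , drop = FALSE],
       report = report)
}

#' Exclude runs paused for more than 24 hours between subtests
#'
#' A pause is the gap from the end of one subtest to the start of the next
#' within the same run. A gap strictly greater than 24 h excludes the whole
#' run (and flags the user). A gap of exactly 24 h is kept.
#'
#' @inheritParams select_first_assessment
#' @param threshold_hours pause threshold, default 24.
#' @return list with \code{kept} and \code{report}.
#' @export
filter_pauses <- function(logs, report = new_exclusion_report(),
                          threshold_hours = 24) {
  if (nrow(logs) == 0L) return(list(kept = logs, report = report))
  if (anyNA(logs$start_time) || anyNA(logs$end_time)) {
    stop("filter_pauses requires timestamps; session logs, not bare score ",
         "records, must be supplied", call. = FALSE)
  }
  ord <- order(logs$test_run_id, logs$start_time)
  lo <- logs[ord, ]
  same_run <- lo$test_run_id[-1L] == lo$test_run_id[-nrow(lo)]
  gap <- lo$start_time[-1L] - lo$end_time[-nrow(lo)]
  over <- same_run & gap > threshold_hours * 3600
  bad_runs <- unique(lo$test_run_id[-1L][over])
  bad_users <- unique(lo$user_id[lo$test_run_id %in% bad_runs])
  report <- add_excluded(report, "pause_gt_24h", bad_users)
  list(kept = logs[!logs$test_run_id %in% bad_runs, , drop = FALSE],
       report = report)
}

#' Exclude users who interleaved two assessments
#'
#' A user is excluded when one of their runs started strictly inside the
#' time span of another run that was completed after the second one began
#' (start one test, pause, start a different test, then return and finish
#' the first). A run starting exactly at another's last end is sequential,
#' not interleaved.
#'
#' @inheritParams select_first_assessment
#' @return list with \code{kept} and \code{report}.
#' @export
filter_interleaved <- function(logs, report = new_exclusion_report()) {
  if (nrow(logs) == 0L) return(list(kept = logs, report = report))
  if (anyNA(logs$start_time) || anyNA(logs$end_time)) {
    stop("filter_interleaved requires timestamps", call. = FALSE)
  }
  runs <- run_spans(logs)
  bad_users <- character()
  for (u in unique(runs$user_id)) {
    ru <- runs[runs$user_id == u, ]
    if (nrow(ru) < 2L) next
    for (a in seq_len(nrow(ru))) {
      inside <- ru$first_start > ru$first_start[a] &
        ru$first_start < ru$last_end[a]
      inside[a] <- FALSE
      if (any(inside)) {
        bad_users <- c(bad_users, u)
        break
      }
    }
  }
  report <- add_excluded(report, "interleaved_tests", bad_users)
  list(kept = logs[!logs$user_id %in% bad_users, , drop = FALSE],
       report = report)
}

#' Exclude users with slow trail-making subtests
#'
#' If either trail-making subtest (IDs 39, 40) took strictly longer than 15
#' minutes, all of that user's data are excluded. Runs without trail-making
#' subtests are unaffected.
#'
#' @inheritParams select_first_assessment
#' @param threshold_minutes duration threshold, default 15.
#' @return list with \code{kept} and \code{report}.
#' @export
filter_slow_trails <- function(logs, report = new_exclusion_report(),
                               threshold_minutes = 15) {
  if (nrow(logs) == 0L) return(list(kept = logs, report = report))
  trails <- logs$subtest_id %in% c(39L, 40L)
  dur <- logs$end_time - logs$start_time
  if (any(trails & is.na(dur))) {
    stop("filter_slow_trails requires timestamps on trail-making entries",
         call. = FALSE)
  }
  slow <- trails & dur > threshold_minutes * 60
  bad_users <- unique(logs$user_id[slow])
  report <- add_excluded(report, "slow_trails", bad_users)
  list(kept = logs[!logs$user_id %in% bad_users, , drop = FALSE],
       report = report)
}

#' Safe-Harbor age top-coding
#'
#' Ages over 89 are recoded to 90 for de-identification; ages 18-89 pass
#' through unchanged.
#'
#' @param age integer vector of ages in years (>= 18).
#' @return integer vector with ages above 89 coded as 90.
#' @export
topcode_age <- function(age) {
  if (any(!is.na(age) & age < 18)) {
    stop("age below 18 is outside the supported range", call. = FALSE)
  }
  as.integer(ifelse(!is.na(age) & age > 89, 90L, age))
}

#' Flag complete test runs
#'
#' A run is complete when it holds exactly one score for every subtest of
#' its battery. Duplicate (run, subtest) rows are a data-integrity error.
#'
#' @param records score-table data.frame (or session logs with
#'   \code{subtest_id}).
#' @return named logical vector indexed by test_run_id.
#' @export
completeness_flags <- function(records) {
  sub_col <- if ("specific_subtest_id" %in% names(records))
    "specific_subtest_id" else "subtest_id"
  if (nrow(records) == 0L) return(stats::setNames(logical(), character()))
  key <- paste(records$test_run_id, records[[sub_col]])
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate subtest row within a test run: ", d, call. = FALSE)
  }
  run <- factor(records$test_run_id)
  # rows within a run are distinct battery members, so a run is complete
  # iff its row count equals its battery size and no score is missing
  n_rows <- tabulate(run, nbins = nlevels(run))
  first <- !duplicated(run)
  expected <- lengths(battery_registry())[
    as.character(records$battery_id[first])]
  expected <- expected[match(levels(run), records$test_run_id[first])]
  has_na <- tabulate(run[is.na(records$raw_score)],
                     nbins = nlevels(run)) > 0L
  reg <- battery_registry()
  valid_pairs <- unlist(lapply(names(reg), function(b) paste(b, reg[[b]])))
  ok_member <- paste(records$battery_id, records[[sub_col]]) %in% valid_pairs
  bad <- tabulate(run[!ok_member], nbins = nlevels(run)) > 0L
  stats::setNames(as.logical(n_rows == expected & !has_na & !bad),
                  levels(run))
}

#' Run the full inclusion-filter chain on session logs
#'
#' Applies, in order: slow-trails exclusion, interleaved-test exclusion,
#' first-assessment selection, and the 24-hour pause rule; then top-codes
#' ages. Participants missing age are flagged (the released data exclude
#' them upstream).
#'
#' @param logs session-log data.frame.
#' @return list with \code{kept} (filtered logs, ages top-coded) and
#'   \code{report} (exclusion report).
#' @export
preprocess_logs <- function(logs) {
  report <- new_exclusion_report()
  missing_demo <- unique(logs$user_id[is.na(logs$age)])
  report <- add_excluded(report, "missing_required_demographics", missing_demo)
  logs <- logs[!logs$user_id %in% missing_demo, , drop = FALSE]
  st <- filter_slow_trails(logs, report)
  st <- filter_interleaved(st$kept, st$report)
  st <- select_first_assessment(st$kept, st$report)
  st <- filter_pauses(st$kept, st$report)
  kept <- st$kept
  kept$age <- topcode_age(kept$age)
  list(kept = kept, report = st$report)
}
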