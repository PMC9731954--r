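# Session logs carry what the released score schema cannot: per-subtest
# start/end timestamps and the pre-test gameplay count. They are represented
# as a flat data.frame with one row per (test run, subtest) entry; times are
# numeric seconds since an arbitrary epoch.

session_log_columns <- function() {
  c("user_id", "test_run_id", "battery_id", "subtest_id", "start_time",
    "end_time", "raw_score", "age", "gender", "education_level", "country",
    "pre_test_gameplays")
}

#' Assemble and validate a session-log table
#'
#' @param entries data.frame with columns \code{user_id}, \code{test_run_id},
#'   \code{battery_id}, \code{subtest_id}, \code{start_time},
#'   \code{end_time}, \code{raw_score}, \code{age}, \code{gender},
#'   \code{education_level}, \code{country}, \code{pre_test_gameplays}.
#'   Times are numeric seconds. One row per administered subtest.
#' @return The validated data.frame, rows ordered by (test_run_id,
#'   start_time).
#' @export
session_log <- function(entries) {
  missing_cols <- setdiff(session_log_columns(), names(entries))
  if (length(missing_cols)) {
    stop("session log is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  entries <- entries[order(entries$test_run_id, entries$start_time), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  bad <- !is.na(entries$end_time) & !is.na(entries$start_time) &
    entries$end_time < entries$start_time
  if (any(bad)) {
    stop("session log entry with end_time < start_time (run '",
         entries$test_run_id[bad][1L], "', subtest ",
         entries$subtest_id[bad][1L], ")", call. = FALSE)
  }
  entries
}

# Convert session logs to the released 11-column score schema.
# time_of_day is the floor hour of the run's first subtest start. Entries
# without a valid raw score (e.g. a failed go/no-go session) are dropped,
# leaving the run incomplete.
logs_to_score_table <- function(logs, epoch_hour = 0) {
  logs <- logs[!is.na(logs$raw_score), , drop = FALSE]
  if (nrow(logs) == 0L) {
    return(load_score_table(textConnection(
      paste(score_table_columns(), collapse = ","))))
  }
  first_start <- stats::ave(logs$start_time, logs$test_run_id, FUN = min)
  data.frame(
    user_id = logs$user_id,
    age = as.integer(logs$age),
    gender = logs$gender,
    education_level = as.integer(logs$education_level),
    country = logs$country,
    test_run_id = logs$test_run_id,
    battery_id = as.integer(logs$battery_id),
    specific_subtest_id = as.integer(logs$subtest_id),
    time_of_day = as.integer(floor((epoch_hour + first_start / 3600)) %% 24),
    raw_score = logs$raw_score,
    grand_index = NA_real_,
    stringsAsFactors = FALSE
  )
}
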