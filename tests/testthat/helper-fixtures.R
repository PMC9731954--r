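# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# A minimal session-log table: one row per subtest, times in seconds.
make_log <- function(user, run, battery = 60L, subtests = NULL,
                     start0 = 0, dur = 120, gap = 60, age = 35L,
                     gender = "f", education = 4L, gameplays = 3L,
                     scores = NULL) {
  if (is.null(subtests)) subtests <- battery_subtests(battery)
  n <- length(subtests)
  starts <- start0 + (seq_len(n) - 1L) * (dur + gap)
  if (is.null(scores)) scores <- seq_len(n) + 10
  data.frame(user_id = user, test_run_id = run, battery_id = battery,
             subtest_id = subtests, start_time = starts,
             end_time = starts + dur, raw_score = scores, age = age,
             gender = gender, education_level = education, country = "US",
             pre_test_gameplays = gameplays, stringsAsFactors = FALSE)
}

# A released-schema score table with explicit demographics, one row per
# (user, subtest).
make_scores <- function(users, battery = 60L, age = 35L, gender = "f",
                        education = 4L, score_fun = NULL) {
  subtests <- battery_subtests(battery)
  rows <- lapply(seq_along(users), function(i) {
    raw <- if (is.null(score_fun)) stats::rnorm(length(subtests), 20, 5) else
      score_fun(i, subtests)
    data.frame(user_id = users[i],
               age = if (length(age) > 1) age[i] else age,
               gender = if (length(gender) > 1) gender[i] else gender,
               education_level = if (length(education) > 1) education[i] else
                 education,
               country = "US",
               test_run_id = paste0("run-", users[i]),
               battery_id = battery, specific_subtest_id = subtests,
               time_of_day = 12L, raw_score = raw, grand_index = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Score table covering all 36 gendered demographic bins with exactly
# `per_cell` participants per cell (used by norm-table tests).
make_binned_scores <- function(battery = 60L, per_cell = 20L,
                               score_fun = NULL, seed = 42L) {
  set.seed(seed)
  ages <- c(25L, 35L, 45L, 55L, 65L, 75L)          # one per age bin
  edus <- c(2L, 4L, 6L)                            # one per education group
  cells <- expand.grid(age = ages, edu = edus, gender = c("m", "f"),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    users <- sprintf("c%02d_p%03d", i, seq_len(per_cell))
    make_scores(users, battery = battery, age = cells$age[i],
                gender = cells$gender[i], education = cells$edu[i],
                score_fun = score_fun)
  })
  do.call(rbind, rows)
}
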