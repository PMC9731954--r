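test_that("cohort sampling respects n, composition and the seed contract", {
  cfg1 <- cohort_config(n = 1, battery_id = 60L)
  expect_equal(nrow(sample_cohort(cfg1, seed = 2)), 1L)
  # composition concentrated on one cell lands every profile there
  conc <- cohort_config(n = 50, battery_id = 60L,
                        age_probs = c(0, 0, 1, 0, 0, 0),
                        edu_probs = c(0, 0, 0, 1, rep(0, 6)),
                        gender_probs = c(m = 1, f = 0, 0))
  prof <- sample_cohort(conc, seed = 3)
  expect_true(all(prof$age >= 40 & prof$age <= 49))
  expect_true(all(prof$education_level == 4L))
  expect_true(all(prof$gender == "m"))
  # same seed, same cohort; different seed, different cohort
  cfg <- cohort_config(n = 100, battery_id = 60L)
  expect_identical(sample_cohort(cfg, seed = 4), sample_cohort(cfg, seed = 4))
  expect_false(identical(sample_cohort(cfg, seed = 4),
                         sample_cohort(cfg, seed = 5)))
  # positive loadings give positively correlated subtest abilities
  big <- sample_cohort(cohort_config(n = 5000, battery_id = 60L), seed = 6)
  ab <- as.matrix(big[, grep("^ability_", names(big))])
  cc <- cor(ab)
  expect_true(all(cc[upper.tri(cc)] > 0))
})

test_that("forced agents hit the published stopping and scoring rules", {
  best <- list(ability = Inf, speed = 0)
  worst <- list(ability = -Inf, speed = 0)
  # progressive matrices: 17 trials, all correct
  expect_equal(simulate_subtest(best, 31, seed = 1)$raw_score, 17)
  # an always-wrong agent stops after three consecutive misses
  m_bad <- simulate_subtest(worst, 31, seed = 1)
  expect_equal(m_bad$raw_score, 0)
  expect_equal(nrow(m_bad$events), 3L)
  # grammar floors at zero
  expect_equal(simulate_subtest(worst, 30, seed = 2)$raw_score, 0)
  # go/no-go v2 ends at exactly 10 correct go trials
  gng <- simulate_subtest(best, 32, seed = 3)
  expect_equal(sum(gng$events$stimulus == "go" & gng$events$correct), 10L)
  last <- nrow(gng$events)
  expect_true(gng$events$stimulus[last] == "go" && gng$events$correct[last])
  # v1 stops at five correct go trials
  gng1 <- simulate_subtest(best, 26, seed = 4)
  expect_equal(sum(gng1$events$stimulus == "go" & gng1$events$correct), 5L)
  # a hopeless agent fails three attempts and scores NA
  expect_true(is.na(simulate_subtest(worst, 32, seed = 5)$raw_score))
  # DVA is bounded by its 12 trials
  expect_equal(simulate_subtest(best, 27, seed = 6)$raw_score, 12)
  # spans: error-free agents climb to the 10-circle ceiling
  expect_equal(simulate_subtest(best, 28, seed = 7)$raw_score, 10)
  expect_equal(simulate_subtest(best, 43, seed = 8)$raw_score, 24)
})

test_that("scores stay inside the published ranges across random agents", {
  set.seed(81)
  for (i in 1:40) {
    prof <- list(ability = rnorm(1), speed = rnorm(1, 0, 0.15))
    expect_true(simulate_subtest(prof, 27)$raw_score %in% 0:12)
    expect_true(simulate_subtest(prof, 31)$raw_score %in% 0:17)
    expect_true(simulate_subtest(prof, 52)$raw_score %in% 0:100)
    expect_true(simulate_subtest(prof, 54)$raw_score %in% 0:40)
    expect_true(simulate_subtest(prof, 55)$raw_score %in% 0:50)
    expect_true(simulate_subtest(prof, 51)$raw_score %in% 0:25)
    expect_gte(simulate_subtest(prof, 30)$raw_score, 0)
    gng <- simulate_subtest(prof, 32)
    expect_lte(sum(gng$events$stimulus == "go" & gng$events$correct), 10L)
    ev <- simulate_subtest(prof, 36)$events
    expect_true(all(ev$rt > 0))
    expect_equal(ev$trial, seq_len(nrow(ev)))
  }
})

test_that("the Posner simulator shows the 60% cue-validity structure", {
  set.seed(82)
  cued <- vapply(1:300, function(i) {
    ev <- simulate_subtest(list(ability = 0.2, speed = 0), 52)$events
    c(mean(ev$stimulus == "cued"), nrow(ev))
  }, numeric(2))
  expect_equal(unique(cued[2, ]), 100)
  frac <- mean(cued[1, ])
  se <- sqrt(0.6 * 0.4 / (300 * 100))
  expect_lt(abs(frac - 0.6), 3 * se)
})

test_that("higher ability raises count scores and lowers trail times", {
  set.seed(83)
  mean_score <- function(sid, ability, n = 2000) {
    mean(vapply(seq_len(n), function(i) {
      simulate_subtest(list(ability = ability, speed = 0), sid)$raw_score
    }, numeric(1)), na.rm = TRUE)
  }
  for (sid in c(29L, 31L, 52L)) {
    expect_gt(mean_score(sid, 1), mean_score(sid, -1))
  }
  expect_lt(mean_score(39L, 1, n = 1000), mean_score(39L, -1, n = 1000))
  expect_lt(mean_score(32L, 1, n = 1000), mean_score(32L, -1, n = 1000))
})

test_that("cohort simulation emits the released schema in administration order", {
  cfg <- cohort_config(n = 40, battery_id = 60L, trial_level = TRUE)
  sim <- simulate_cohort(cfg, seed = 12)
  # ages run to 99 before Safe-Harbor top-coding; otherwise released schema
  sc <- sim$scores
  sc$age <- topcode_age(sc$age)
  expect_silent(validate_score_table(sc))
  per_run <- table(sim$scores$test_run_id)
  expect_true(all(per_run == 5L))   # battery 60 has five subtests
  # rows within a run appear in battery order
  first_run <- sim$scores[sim$scores$test_run_id ==
                            sim$scores$test_run_id[1], ]
  expect_equal(first_run$specific_subtest_id, battery_subtests(60))
  # determinism: identical outputs under the same master seed
  sim2 <- simulate_cohort(cfg, seed = 12)
  expect_identical(sim$scores, sim2$scores)
  expect_identical(sim$logs, sim2$logs)
  # zero contamination: the filter chain excludes nobody
  pp <- preprocess_logs(sim$logs)
  expect_true(all(exclusion_counts(pp$report) == 0))
  expect_equal(nrow(pp$kept), nrow(sim$logs))
})

test_that("injected contamination is recovered exactly from the truth table", {
  cfg <- cohort_config(n = 1000, battery_id = 39L, trial_level = FALSE,
                       contamination = list(pause = 0.1, interleave = 0.04,
                                            slow_trails = 0.04,
                                            dropout = 0.05))
  sim <- simulate_cohort(cfg, seed = 13)
  pp <- preprocess_logs(sim$logs)
  tr <- sim$truth
  expect_identical(pp$report$users$pause_gt_24h,
                   sort(tr$user_id[tr$pause]))
  expect_identical(pp$report$users$interleaved_tests,
                   sort(tr$user_id[tr$interleave]))
  expect_identical(pp$report$users$slow_trails,
                   sort(tr$user_id[tr$slow_trails]))
  expect_equal(unname(exclusion_counts(pp$report)[
    c("pause_gt_24h", "interleaved_tests", "slow_trails")]),
    c(sum(tr$pause), sum(tr$interleave), sum(tr$slow_trails)))
  # dropout users survive the filters but have incomplete runs (no GI)
  comp <- completeness_flags(logs_to_scores <- ncpt:::logs_to_score_table(pp$kept))
  dropped <- tr$user_id[tr$dropout & !tr$pause & !tr$interleave &
                          !tr$slow_trails]
  runs <- logs_to_scores$test_run_id[match(dropped, logs_to_scores$user_id)]
  expect_true(all(!comp[stats::na.omit(runs)]))
})

test_that("reference builders cover uniform, match and explicit modes", {
  expect_equal(as.numeric(make_reference(mode = "uniform")), rep(1 / 18, 18))
  cfg <- cohort_config(n = 600, battery_id = 60L, trial_level = FALSE)
  sim <- simulate_cohort(cfg, seed = 14)
  ref <- make_reference(sim)
  bins <- assign_bin(sim$profiles$age, sim$profiles$education_level)
  k <- bins$k[!is.na(bins$k)]
  expect_equal(as.numeric(ref), tabulate(k + 1L, 18L) / length(k),
               tolerance = 1e-12)
  # explicit vectors must sum to one unless strictness is relaxed
  bad <- rep(0.05, 18)   # sums to 0.9
  expect_error(make_reference(mode = "explicit", proportions = bad),
               "sum to")
  expect_warning(ref2 <- make_reference(mode = "explicit", proportions = bad,
                                        strict = FALSE), "renormalizing")
  expect_equal(sum(ref2), 1, tolerance = 1e-12)
  expect_error(make_reference(mode = "explicit",
                              proportions = c(-0.1, rep(1.1 / 17, 17))),
               "non-negative")
})
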