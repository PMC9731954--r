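# Independent oracle for the reweighted ranks: literal prefix summation of
# the two defining equations, one observation at a time.
oracle_ranks <- function(x, k, fstar) {
  n <- length(x)
  f <- tabulate(k + 1L, nbins = 18L) / n
  w <- fstar[k + 1L] / (n * f[k + 1L])
  ord <- order(x)
  r <- numeric(n)
  for (pos in seq_len(n)) {
    i <- ord[pos]
    below <- if (pos > 1) sum(w[ord[seq_len(pos - 1L)]]) else 0
    r[i] <- w[i] / 2 + below
  }
  list(w = w, r_tilde = r)
}

test_that("demographic bins follow the published boundaries", {
  expect_equal(assign_bin(29, 4), data.frame(age_bin = 0L, edu_bin = 1L,
                                             k = 1L))
  expect_equal(assign_bin(70, 7), data.frame(age_bin = 5L, edu_bin = 2L,
                                             k = 17L))
  expect_true(is.na(assign_bin(40, 99)$k))     # "Other" is unbinnable
  expect_true(is.na(assign_bin(40, NA)$k))
  expect_error(assign_bin(40, 12), "unknown education code")
  expect_error(assign_bin(101, 4), "outside")
  # k = 3 * age_bin + edu_bin over the full grid; boundaries inclusive
  grid <- expand.grid(age = c(18, 29, 30, 39, 40, 49, 50, 59, 60, 69, 70, 99),
                      edu = 1:8)
  b <- assign_bin(grid$age, grid$edu)
  expect_true(all(b$k == 3L * b$age_bin + b$edu_bin))
  expect_setequal(unique(b$k), 0:17)
})

test_that("score orientation negates only the time-scored subtests", {
  expect_equal(orient_score(39, 30.2), -30.2)
  expect_equal(orient_score(29, 12), 12)
  expect_equal(orient_score(26, 450), -450)
  expect_equal(orient_score(54, c(1, 2)), c(1, 2))
  expect_error(orient_score(999, 1), "unknown subtest_id")
})

test_that("reweighted ranks reproduce the 4-point worked example", {
  ref <- reference_composition(c(0.75, 0.25, rep(0, 16)))
  x <- c(1, 2, 3, 4)
  k <- c(0L, 1L, 0L, 1L)
  rr <- reweighted_ranks(x, k, ref)
  expect_equal(rr$w, c(0.375, 0.125, 0.375, 0.125), tolerance = 1e-12)
  expect_equal(rr$r_tilde, c(0.1875, 0.4375, 0.6875, 0.9375),
               tolerance = 1e-12)
  # literal prefix-summation oracle agrees
  or <- oracle_ranks(x, k, as.numeric(ref))
  expect_equal(rr$w, or$w, tolerance = 1e-15)
  expect_equal(rr$r_tilde, or$r_tilde, tolerance = 1e-15)
  # and the normalized scores are the normal quantiles at (100, 15)
  fit <- reweighted_int(x, k, ref)
  expect_equal(fit$y, qnorm(c(0.1875, 0.4375, 0.6875, 0.9375), 100, 15),
               tolerance = 1e-9)
})

test_that("with reference equal to sample composition the INT collapses to centered ranks", {
  set.seed(21)
  x <- rnorm(1000)
  k <- sample(0:17, 1000, replace = TRUE)
  ref <- ncpt:::empirical_composition(k)
  fit <- reweighted_int(x, k, ref)
  # textbook centered-rank INT, implemented independently
  y_text <- qnorm((rank(x, ties.method = "average") - 0.5) / length(x),
                  100, 15)
  expect_equal(fit$y, y_text, tolerance = 1e-12)
  # degenerate case: one bin with full reference mass
  one <- reference_composition(c(1, rep(0, 17)))
  fit1 <- reweighted_int(x[1:50], rep(0L, 50), one)
  expect_equal(sort(fit1$r_tilde), (1:50 - 0.5) / 50, tolerance = 1e-12)
  # median maps to the target mean
  xm <- c(-1, 0, 1)
  fm <- reweighted_int(xm, rep(0L, 3), one)
  expect_equal(fm$y[2], 100, tolerance = 1e-12)
})

test_that("weights conserve mass and ranks stay in (0,1) on random bin structures", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(5:400, 1)
    bins_present <- sort(sample(0:17, sample(1:18, 1)))
    k <- sample(bins_present, n, replace = TRUE)
    bins_present <- sort(unique(k))
    fstar <- rep(0, 18)
    mass <- rgamma(length(bins_present), 1)
    fstar[bins_present + 1L] <- mass / sum(mass)
    ref <- reference_composition(fstar)
    x <- rnorm(n)
    rr <- reweighted_ranks(x, k, ref)
    expect_equal(sum(rr$w), 1, tolerance = 1e-12)
    expect_true(all(rr$r_tilde > 0 & rr$r_tilde < 1))
    # r~ strictly increases along the sorted score order (ties absent)
    expect_true(all(diff(rr$r_tilde[order(x)]) > 0))
    # oracle agreement
    or <- oracle_ranks(x, k, fstar)
    expect_equal(rr$r_tilde, or$r_tilde, tolerance = 1e-12)
  }
  # reference bins absent from the sample leave sum(w) < 1, with a warning
  ref <- uniform_reference()
  expect_warning(rr <- reweighted_ranks(rnorm(20), rep(3L, 20), ref),
                 "absent from the sample")
  expect_equal(sum(rr$w), 1 / 18, tolerance = 1e-12)
})

test_that("normalization is a monotone, shift-invariant rank statistic with fair ties", {
  set.seed(41)
  x <- rnorm(200)
  k <- sample(0:5, 200, replace = TRUE)
  fstar <- rep(0, 18); fstar[1:6] <- c(0.1, 0.2, 0.3, 0.2, 0.1, 0.1)
  ref <- reference_composition(fstar)
  fit <- reweighted_int(x, k, ref)
  ord <- order(x)
  expect_true(all(diff(fit$y[ord]) > 0))
  # adding a constant changes nothing
  fit2 <- reweighted_int(x + 17.3, k, ref)
  expect_equal(fit2$y, fit$y, tolerance = 1e-12)
  # tied raw scores receive equal normalized scores
  xt <- c(1, 2, 2, 3)
  kt <- c(0L, 0L, 1L, 1L)
  rt <- reweighted_int(xt, kt, reference_composition(
    c(0.6, 0.4, rep(0, 16))))
  expect_equal(rt$y[2], rt$y[3], tolerance = 1e-12)
  expect_true(rt$y[1] < rt$y[2] && rt$y[3] < rt$y[4])
})

test_that("shifting reference mass toward a lower-scoring bin raises higher-bin scores", {
  # members of bin 0 hold the two lowest scores; raising bin 0's reference
  # share widens the mass below bin 1's members, so their r~ and y rise
  x <- c(1, 2, 3, 4)
  k <- c(0L, 0L, 1L, 1L)
  even <- reweighted_int(x, k, reference_composition(
    c(0.5, 0.5, rep(0, 16))))
  shifted <- reweighted_int(x, k, reference_composition(
    c(0.75, 0.25, rep(0, 16))))
  expect_true(all(shifted$y[3:4] > even$y[3:4]))
  # brute-force confirmation via the oracle
  or_even <- oracle_ranks(x, k, c(0.5, 0.5, rep(0, 16)))
  or_shift <- oracle_ranks(x, k, c(0.75, 0.25, rep(0, 16)))
  expect_true(all(or_shift$r_tilde[3:4] > or_even$r_tilde[3:4]))
})

test_that("the frozen INT curve interpolates outsiders monotonically within clamps", {
  set.seed(51)
  x <- sort(rnorm(60))
  k <- sample(0:2, 60, replace = TRUE)
  ref <- ncpt:::empirical_composition(k)
  curve <- int_curve(x, k, ref)
  # sample points reproduce their own fitted values
  expect_equal(predict(curve, x), curve$fit$y[order(x)], tolerance = 1e-9)
  probes <- seq(min(x) - 2, max(x) + 2, length.out = 101)
  yy <- predict(curve, probes)
  expect_true(all(diff(yy) >= 0))
  expect_true(all(is.finite(yy)))
  # clamped beyond the observed range
  expect_equal(predict(curve, min(x) - 10),
               qnorm(curve$lo, 100, 15), tolerance = 1e-12)
  expect_equal(predict(curve, max(x) + 10),
               qnorm(curve$hi, 100, 15), tolerance = 1e-12)
})

test_that("norm-sample construction enforces the published exclusions", {
  users <- sprintf("u%02d", 1:6)
  rec <- make_scores(users, battery = 60L,
                     education = c(4L, 4L, NA, 99L, 4L, 4L))
  # u5's run is incomplete, u6 has 26 gameplays, u2 has exactly 25
  rec <- rec[!(rec$user_id == "u05" & rec$specific_subtest_id == 51L), ]
  gp <- c(u01 = 0, u02 = 25, u03 = 1, u04 = 2, u05 = 3, u06 = 26)
  names(gp) <- users
  ns <- build_norm_sample(rec, gameplay_counts = gp)
  expect_setequal(unique(ns$user_id), c("u01", "u02"))
  expect_true(all(ns$k == assign_bin(35, 4)$k))
  # without gameplay counts the criterion is skipped, with a warning
  expect_warning(ns2 <- build_norm_sample(rec), "gameplay")
  expect_setequal(unique(ns2$user_id), c("u01", "u02", "u06"))
})

test_that("Grand Index is missing for incomplete runs and monotone in mean score", {
  set.seed(61)
  users <- sprintf("u%02d", 1:40)
  rec <- make_scores(users, battery = 60L)
  # u40 misses one subtest
  rec <- rec[!(rec$user_id == "u40" & rec$specific_subtest_id == 51L), ]
  ref <- make_reference(rec[!duplicated(rec$user_id), ])
  norm <- suppressWarnings(normalize_scores(rec, ref))
  gi <- compute_grand_index(norm, ref)
  expect_true(is.na(gi[["run-u40"]]))
  complete <- setdiff(names(gi), "run-u40")
  expect_true(all(!is.na(gi[complete])))
  means <- tapply(norm$normalized_score, norm$test_run_id, mean)[complete]
  expect_equal(order(gi[complete]), order(means))
  # single demographic cell: GI is the centered-rank INT of the means
  expect_equal(sort(as.numeric(gi[complete])),
               qnorm((seq_along(complete) - 0.5) / length(complete), 100, 15),
               tolerance = 1e-9)
})

test_that("norm tables honour the 20-per-cell rule, raw-score statistics and direction", {
  rec <- make_binned_scores(battery = 60L, per_cell = 21L)
  tabs <- compute_norm_tables(rec, min_n = 20)
  expect_named(tabs, "60")
  t60 <- tabs[["60"]]
  # 5 subtests x 36 cells (GI rows absent: grand_index all missing)
  expect_equal(nrow(t60), 5L * 36L)
  expect_equal(names(t60), ncpt:::norms_table_columns())
  expect_true(all(t60$N == 21L))
  # knocking two participants out of one cell drops the whole battery
  drop2 <- rec[!(rec$user_id %in% c("c01_p001", "c01_p002")), ]
  expect_length(compute_norm_tables(drop2, min_n = 20), 0L)
  # constant scores: SD 0 and all five percentiles equal the value
  const <- make_binned_scores(battery = 60L, per_cell = 20L,
                              score_fun = function(i, s) rep(7, length(s)))
  ct <- compute_norm_tables(const, min_n = 20)[["60"]]
  expect_true(all(ct$SD == 0))
  expect_true(all(ct$percentile_10 == 7 & ct$percentile_90 == 7))
})

test_that("percentiles for time-scored subtests report fast times at high percentiles", {
  rec <- make_binned_scores(battery = 39L, per_cell = 20L,
                            score_fun = function(i, s) {
                              out <- stats::rnorm(length(s), 20, 3)
                              out[s %in% c(39L, 40L)] <-
                                seq(10, 100, length.out = 2)[match(
                                  s[s %in% c(39L, 40L)], c(39L, 40L))] +
                                stats::runif(2, 0, 5)
                              out
                            })
  # give trails a spread inside one cell: replace with a known ladder
  sel <- rec$specific_subtest_id == 39L & rec$age == 25L &
    rec$education_level == 2L & rec$gender == "m"
  rec$raw_score[sel] <- seq(10, 100, length.out = sum(sel))
  tabs <- compute_norm_tables(rec, min_n = 20)
  expect_true("39" %in% names(tabs))
  t39 <- tabs[["39"]]
  row <- t39[t39$specific_subtest_id == 39L & t39$age == "18-29" &
               t39$education_level == "high_school_or_less" &
               t39$gender == "m", ]
  x <- seq(10, 100, length.out = 20)
  # brute-force direction oracle: the 90th performance percentile is the
  # time only 10% undercut (a fast time); quantile symmetry gives the value
  expect_equal(row$percentile_90, unname(quantile(x, 0.10, type = 7)),
               tolerance = 1e-9)
  expect_equal(row$percentile_10, unname(quantile(x, 0.90, type = 7)),
               tolerance = 1e-9)
  expect_true(row$percentile_90 < row$percentile_50)
  expect_true(row$percentile_50 < row$percentile_10)
  # mean and SD are plain raw-score statistics
  expect_equal(row$mean, mean(x), tolerance = 1e-9)
  expect_equal(row$SD, sd(x), tolerance = 1e-9)
})
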