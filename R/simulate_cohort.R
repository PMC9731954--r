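# Synthetic cohorts. Participants carry a latent general ability g on a
# standard-normal scale; subtest-specific ability is
#   a_s = lambda_s * g + sqrt(1 - lambda_s^2) * e_s + eta_s(demographics),
# which yields a positive manifold whenever all loadings lambda_s are
# positive. Demographic effects eta_s (age slope per decade, education-group
# offsets, gender offset, in ability SD units) are injected so that the
# validation stage has something real to remove. Cohorts can be rendered at
# trial level (full task simulation) or score level (scores drawn from a
# continuous map of ability; same latent structure, much faster).

derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 7919 + h * 104729) %% 2147483587)
}

#' Cohort configuration
#'
#' The stated world of the generator. Defaults emulate the released data's
#' structure: an adult web-sample age profile (more mass under 60 than a
#' census would have), education marginals dominated by some-college and
#' college-degree, a mostly-female gender split with ~10% non-report, a
#' single positive general-ability factor (loadings 0.6), a mild ability
#' decline of 0.15 SD per decade of age, increasing ability with education
#' group, and a long-tailed pre-test gameplay count (mean 8, so most
#' participants fall at or under the 25-gameplay norms cutoff).
#'
#' @param n number of participants.
#' @param battery_id which battery to administer (default 39).
#' @param age_probs probabilities over the six age bins (18-29 ... 70-99).
#' @param edu_probs probabilities over education codes 1-8, 99, and missing
#'   (length 10, order 1:8, 99, NA).
#' @param gender_probs probabilities over \code{c("m", "f", NA)}.
#' @param loadings named numeric vector of factor loadings per subtest id;
#'   a single unnamed value is recycled to the whole battery.
#' @param age_slope_per_decade ability change per decade of age (SD units).
#' @param edu_effects ability offsets for the three education groups.
#' @param gender_effect ability offset for gender "f" relative to "m".
#' @param speed_sd SD of the per-participant log response-time offset.
#' @param gameplay_mean mean of the negative-binomial gameplay count.
#' @param contamination list of rates in [0,1]: \code{pause},
#'   \code{interleave}, \code{slow_trails}, \code{dropout}.
#' @param trial_level simulate at trial level (TRUE) or score level.
#' @return a list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n,
                          battery_id = 39L,
                          age_probs = c(0.18, 0.17, 0.19, 0.20, 0.15, 0.11),
                          edu_probs = c(0.015, 0.085, 0.20, 0.31, 0.068,
                                        0.16, 0.025, 0.047, 0.018, 0.072),
                          gender_probs = c(m = 0.41, f = 0.49, 0.10),
                          loadings = 0.6,
                          age_slope_per_decade = -0.15,
                          edu_effects = c(-0.2, 0, 0.25),
                          gender_effect = 0,
                          speed_sd = 0.15,
                          gameplay_mean = 8,
                          contamination = list(pause = 0, interleave = 0,
                                               slow_trails = 0,
                                               dropout = 0),
                          trial_level = TRUE) {
  stopifnot(n >= 1)
  subtests <- battery_subtests(battery_id)
  lam <- if (is.null(names(loadings)) && length(loadings) == 1L) {
    stats::setNames(rep(loadings, length(subtests)), subtests)
  } else {
    stats::setNames(as.numeric(loadings[as.character(subtests)]), subtests)
  }
  if (anyNA(lam) || any(!is.finite(lam)) || any(abs(lam) > 1)) {
    stop("loadings must be finite, in [-1, 1], and cover every battery ",
         "subtest", call. = FALSE)
  }
  rates <- c(pause = 0, interleave = 0, slow_trails = 0, dropout = 0)
  rates[names(contamination)] <- unlist(contamination)
  if (any(rates < 0 | rates > 1)) {
    stop("contamination rates must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(age_probs) - 1) > 1e-6 || abs(sum(edu_probs) - 1) > 1e-6 ||
      abs(sum(gender_probs) - 1) > 1e-6) {
    stop("composition probabilities must each sum to 1", call. = FALSE)
  }
  structure(list(n = as.integer(n), battery_id = as.integer(battery_id),
                 subtests = subtests, age_probs = age_probs,
                 edu_probs = edu_probs, gender_probs = gender_probs,
                 loadings = lam,
                 age_slope_per_decade = age_slope_per_decade,
                 edu_effects = edu_effects, gender_effect = gender_effect,
                 speed_sd = speed_sd, gameplay_mean = gameplay_mean,
                 contamination = as.list(rates),
                 trial_level = isTRUE(trial_level)),
            class = "cohort_config")
}

#' Sample a cohort of agent profiles
#'
#' Draws demographics from the configured composition and latent abilities
#' from the one-factor model. Deterministic under a fixed seed.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed.
#' @return data.frame with one row per participant: demographics, latent
#'   \code{g}, \code{speed}, \code{gameplays}, and one \code{ability_<id>}
#'   column per battery subtest.
#' @export
sample_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(seed, "cohort"))
  n <- config$n
  age_bin <- sample.int(6L, n, replace = TRUE, prob = config$age_probs) - 1L
  lo <- c(18, 30, 40, 50, 60, 70)[age_bin + 1L]
  hi <- c(29, 39, 49, 59, 69, 99)[age_bin + 1L]
  age <- lo + floor(stats::runif(n) * (hi - lo + 1))
  edu_pool <- c(1:8, 99L, NA_integer_)
  education <- edu_pool[sample.int(10L, n, replace = TRUE,
                                   prob = config$edu_probs)]
  gender <- c("m", "f", NA_character_)[sample.int(3L, n, replace = TRUE,
                                                  prob = config$gender_probs)]
  g <- stats::rnorm(n)
  speed <- stats::rnorm(n, 0, config$speed_sd)
  gameplays <- stats::rnbinom(n, size = 1.2, mu = config$gameplay_mean)
  eg <- edu_group(education)
  eta_demo <- config$age_slope_per_decade * (age - 45) / 10 +
    ifelse(is.na(eg), 0, config$edu_effects[eg + 1L]) +
    ifelse(!is.na(gender) & gender == "f", config$gender_effect, 0)
  prof <- data.frame(user_id = sprintf("u%07d", seq_len(n)),
                     age = as.integer(age), gender = gender,
                     education_level = education, country = "US",
                     g = g, speed = speed,
                     gameplays = as.integer(gameplays),
                     stringsAsFactors = FALSE)
  for (sid in config$subtests) {
    lam <- config$loadings[as.character(sid)]
    prof[[paste0("ability_", sid)]] <-
      lam * g + sqrt(1 - lam^2) * stats::rnorm(n) + eta_demo
  }
  prof
}

# score-level map: continuous raw score as a function of ability (plus a
# whiff of measurement noise). Timed subtests are lognormal and decrease
# with ability; the rest are affine in ability.
fast_score_map <- list(
  "26" = function(a, z) exp(log(430) - 0.15 * a + 0.05 * z),
  "32" = function(a, z) exp(log(450) - 0.15 * a + 0.05 * z),
  "39" = function(a, z) exp(log(30) - 0.25 * a + 0.08 * z),
  "40" = function(a, z) exp(log(52) - 0.25 * a + 0.08 * z),
  "27" = function(a, z) 8 + 2 * a + 0.3 * z,
  "28" = function(a, z) 6 + 1.5 * a + 0.25 * z,
  "33" = function(a, z) 5.5 + 1.5 * a + 0.25 * z,
  "43" = function(a, z) 14 + 5 * a + 0.8 * z,
  "44" = function(a, z) 12 + 5 * a + 0.8 * z,
  "29" = function(a, z) 11 + 4 * a + 0.6 * z,
  "30" = function(a, z) 14 + 6 * a + 0.9 * z,
  "31" = function(a, z) 9 + 3.5 * a + 0.5 * z,
  "36" = function(a, z) 7 + 2.5 * a + 0.4 * z,
  "37" = function(a, z) 6 + 2.5 * a + 0.4 * z,
  "38" = function(a, z) 35 + 8 * a + 1.2 * z,
  "45" = function(a, z) 35 + 8 * a + 1.2 * z,
  "51" = function(a, z) 10 + 4 * a + 0.6 * z,
  "52" = function(a, z) 93 + 4 * a + 0.6 * z,
  "53" = function(a, z) 8 + 3 * a + 0.5 * z,
  "54" = function(a, z) 32 + 4 * a + 0.6 * z,
  "55" = function(a, z) 40 + 5 * a + 0.8 * z
)

# plausible per-subtest session durations (seconds) for score-level mode;
# trail-making durations are the raw score itself
fast_duration_base <- function(sid) {
  unname(c("26" = 40, "32" = 60, "27" = 90, "28" = 120, "33" = 120,
           "43" = 150, "44" = 150, "29" = 60, "30" = 60, "31" = 180,
           "36" = 240, "37" = 90, "38" = 105, "45" = 105, "39" = 35,
           "40" = 60, "51" = 240, "52" = 300, "53" = 180, "54" = 180,
           "55" = 240)[as.character(sid)])
}

#' Simulate a full cohort through a battery
#'
#' Administers the configured battery to a sampled cohort, in the battery's
#' administration order, producing (i) a score table in the released
#' 11-column schema (grand_index left missing; it is a derived field the
#' norming stage fills in), (ii) session logs with per-subtest timestamps
#' and pre-test gameplay counts, and (iii) a truth table recording which
#' users were contaminated with which filter violation, their latent g, and
#' their gameplay count. Contamination (at most one kind per user, so each
#' injected set is exactly recoverable by its filter):
#' \describe{
#'   \item{pause}{a 24-48 h gap injected between two successive subtests}
#'   \item{interleave}{a second test run started inside the first run's span}
#'   \item{slow_trails}{a trail-making subtest stretched past 15 minutes}
#'   \item{dropout}{the last subtest(s) of the battery never taken}
#' }
#'
#' @param config a [cohort_config()].
#' @param seed master seed; stage seeds are derived from it.
#' @return list with \code{scores}, \code{logs}, \code{truth},
#'   \code{profiles}, \code{config}.
#' @export
simulate_cohort <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  profiles <- sample_cohort(config, seed)
  set.seed(derive_seed(seed, "sessions"))
  n <- config$n
  subtests <- config$subtests
  rates <- config$contamination
  has_trails <- any(c(39L, 40L) %in% subtests)
  p <- c(pause = rates$pause, interleave = rates$interleave,
         slow_trails = if (has_trails) rates$slow_trails else 0,
         dropout = rates$dropout)
  if (sum(p) > 1) stop("contamination rates sum above 1", call. = FALSE)
  # at most one violation per user, so each injected set is exactly the set
  # a single filter should recover
  kind <- apply(stats::rmultinom(n, 1L, c(none = 1 - sum(p), p)) == 1L, 2,
                which)
  kind <- c("none", names(p))[kind]
  truth <- data.frame(
    user_id = profiles$user_id,
    pause = kind == "pause",
    interleave = kind == "interleave",
    slow_trails = kind == "slow_trails",
    dropout = kind == "dropout",
    gameplays = profiles$gameplays,
    g = profiles$g,
    stringsAsFactors = FALSE)
  m <- length(subtests)
  # raw scores and durations as n x m matrices
  raw <- matrix(NA_real_, n, m)
  dur <- matrix(NA_real_, n, m)
  if (config$trial_level) {
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        sid <- subtests[j]
        sim <- simulate_subtest(
          list(ability = profiles[[paste0("ability_", sid)]][i],
               speed = profiles$speed[i]), sid)
        raw[i, j] <- sim$raw_score
        dur[i, j] <- 30 + 2 * nrow(sim$events) +
          sum(sim$events$rt, na.rm = TRUE) / 1000
      }
    }
  } else {
    for (j in seq_len(m)) {
      sid <- subtests[j]
      a <- profiles[[paste0("ability_", sid)]]
      raw[, j] <- fast_score_map[[as.character(sid)]](a, stats::rnorm(n))
      base <- fast_duration_base(sid)
      dur[, j] <- if (sid %in% c(39L, 40L)) raw[, j] else
        base * stats::runif(n, 0.8, 1.3)
    }
  }
  if (any(truth$slow_trails)) {
    jt <- which(subtests %in% c(39L, 40L))[1L]
    idx <- which(truth$slow_trails)
    dur[idx, jt] <- 15 * 60 + stats::runif(length(idx), 1, 600)
    raw[idx, jt] <- dur[idx, jt]   # trails raw score IS the completion time
  }
  # timeline: per-user random day/hour, subtests sequential with short gaps
  gaps <- matrix(stats::rexp(n * m, rate = 1 / 45), n, m)
  gaps[, 1L] <- 0
  if (any(truth$pause) && m >= 2L) {
    idx <- which(truth$pause)
    gaps[cbind(idx, sample(2:m, length(idx), replace = TRUE))] <-
      24 * 3600 + stats::runif(length(idx), 60, 24 * 3600)
  }
  starts <- matrix(0, n, m)
  ends <- matrix(0, n, m)
  prev_end <- stats::runif(n, 0, 365) * 86400
  for (j in seq_len(m)) {
    starts[, j] <- prev_end + gaps[, j]
    ends[, j] <- starts[, j] + dur[, j]
    prev_end <- ends[, j]
  }
  keep <- matrix(TRUE, n, m)
  if (any(truth$dropout) && m >= 2L) {
    idx <- which(truth$dropout)
    n_drop <- sample.int(m - 1L, length(idx), replace = TRUE)
    keep[idx, ] <- outer(m - n_drop, seq_len(m), ">=")
  }
  long <- function(mat) as.vector(t(mat))
  keep_v <- long(keep)
  per_user <- function(x) rep(x, each = m)[keep_v]
  logs <- data.frame(
    user_id = per_user(profiles$user_id),
    test_run_id = per_user(sprintf("r%07d-1", seq_len(n))),
    battery_id = config$battery_id,
    subtest_id = rep(subtests, times = n)[keep_v],
    start_time = long(starts)[keep_v],
    end_time = long(ends)[keep_v],
    raw_score = long(raw)[keep_v],
    age = per_user(profiles$age),
    gender = per_user(profiles$gender),
    education_level = per_user(profiles$education_level),
    country = per_user(profiles$country),
    pre_test_gameplays = per_user(profiles$gameplays),
    stringsAsFactors = FALSE)
  if (any(truth$interleave)) {
    # a second run begins strictly inside the first run's span, so the
    # first run finishes after the second one starts
    idx <- which(truth$interleave)
    span_mid <- starts[idx, 1L] + 0.5 * (ends[idx, m] - starts[idx, 1L])
    starts2 <- matrix(0, length(idx), m)
    ends2 <- matrix(0, length(idx), m)
    prev_end <- span_mid
    for (j in seq_len(m)) {
      starts2[, j] <- prev_end + 30
      ends2[, j] <- starts2[, j] + dur[idx, j]
      prev_end <- ends2[, j]
    }
    per_user2 <- function(x) rep(x[idx], each = m)
    logs2 <- data.frame(
      user_id = per_user2(profiles$user_id),
      test_run_id = rep(sprintf("r%07d-2", idx), each = m),
      battery_id = config$battery_id,
      subtest_id = rep(subtests, times = length(idx)),
      start_time = as.vector(t(starts2)),
      end_time = as.vector(t(ends2)),
      raw_score = as.vector(t(raw[idx, , drop = FALSE])),
      age = per_user2(profiles$age),
      gender = per_user2(profiles$gender),
      education_level = per_user2(profiles$education_level),
      country = per_user2(profiles$country),
      pre_test_gameplays = per_user2(profiles$gameplays),
      stringsAsFactors = FALSE)
    logs <- rbind(logs, logs2)
  }
  logs <- session_log(logs)
  scores <- logs_to_score_table(logs)
  list(scores = scores, logs = logs, truth = truth, profiles = profiles,
       config = config)
}

#' Build a reference composition
#'
#' @param x for mode \code{"match"}, a cohort object, profile or score
#'   data.frame (anything with \code{age} and \code{education_level});
#'   ignored otherwise.
#' @param mode \code{"match"} (empirical composition of the binnable
#'   participants of \code{x}), \code{"uniform"}, or \code{"explicit"}.
#' @param proportions length-18 vector for mode \code{"explicit"}.
#' @param strict passed to [reference_composition()] for explicit vectors.
#' @return a [reference_composition()].
#' @export
make_reference <- function(x = NULL, mode = c("match", "uniform", "explicit"),
                           proportions = NULL, strict = TRUE) {
  mode <- match.arg(mode)
  if (mode == "uniform") return(uniform_reference())
  if (mode == "explicit") {
    if (is.null(proportions)) stop("explicit mode needs proportions",
                                   call. = FALSE)
    return(reference_composition(proportions, strict = strict))
  }
  df <- if (is.data.frame(x)) x else if (is.list(x) && !is.null(x$profiles))
    x$profiles else stop("cannot extract demographics from x", call. = FALSE)
  if ("user_id" %in% names(df)) df <- df[!duplicated(df$user_id), ]
  bins <- assign_bin(df$age, df$education_level)
  empirical_composition(bins$k)
}
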