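# Trial-level subtest simulators. Each simulator follows the published task
# rules (trial counts, adaptive schedules, stopping rules, scoring rules);
# the agent's behaviour is an artifact model: correctness is Bernoulli with
# probability logistic(1.7 * (ability - difficulty)) and response times are
# lognormal, scaled by the agent's speed parameter and (boundedly) by
# ability. Ability may be +/-Inf to force always-correct / always-wrong
# agents in tests.

p_correct <- function(ability, difficulty) {
  stats::plogis(1.7 * (ability - difficulty))
}

# ability effect on response speed is clamped so forced agents (+/-Inf)
# still produce finite times
draw_rt <- function(n, base, speed, ability, sdlog = 0.3) {
  a <- pmax(pmin(ability, 3), -3)
  stats::rlnorm(n, meanlog = log(base) + speed - 0.12 * a, sdlog = sdlog)
}

trial_events <- function(subtest_id, stimulus, response, correct, rt) {
  n <- length(correct)
  data.frame(subtest_id = subtest_id, trial = seq_len(n),
             stimulus = stimulus, response = response, correct = correct,
             rt = rt, stringsAsFactors = FALSE)
}

# --- go/no-go (IDs 26 and 32) ------------------------------------------
# Trials continue until `target` correct responses on go trials, or three
# incorrect responses of either type (which forces a retry; after three
# failed attempts the score is missing). Stimuli show for at most 1500 ms;
# a late go response is incorrect. Score: mean correct-go RT in ms.
sim_go_no_go <- function(ability, speed, target) {
  p_go <- 0.7
  attempt_once <- function() {
    stim <- character(); resp <- character(); corr <- logical()
    rts <- numeric()
    correct_go <- 0L; wrong <- 0L
    while (correct_go < target && wrong < 3L) {
      go <- stats::runif(1) < p_go
      ok <- stats::runif(1) < p_correct(ability, -1.5)
      rt <- if (go) min(draw_rt(1, 450, speed, ability), 1500) else NA_real_
      if (go && ok && rt >= 1500) ok <- FALSE   # timed out on a go trial
      if (go && ok) correct_go <- correct_go + 1L
      if (!ok) wrong <- wrong + 1L
      stim <- c(stim, if (go) "go" else "no-go")
      resp <- c(resp, if (ok) "correct" else "incorrect")
      corr <- c(corr, ok)
      rts <- c(rts, rt)
    }
    list(events = trial_events(NA_integer_, stim, resp, corr, rts),
         passed = correct_go >= target)
  }
  for (attempt in 1:3) {
    a <- attempt_once()
    if (a$passed) {
      go_rt <- a$events$rt[a$events$stimulus == "go" & a$events$correct]
      return(list(events = a$events, raw_score = mean(go_rt)))
    }
  }
  list(events = a$events, raw_score = NA_real_)
}

# --- divided visual attention (ID 27) ----------------------------------
# 12 trials; presentation time starts at 1 s and is stepped down after a
# correct response, up after an incorrect one (step 100 ms, floor 100 ms,
# cap 3000 ms -- the step size is an artifact default). Score: correct of 12.
sim_dva <- function(ability, speed, step = 100, floor_ms = 100,
                    cap_ms = 3000) {
  pres <- 1000
  corr <- logical(12); stim <- character(12); rts <- numeric(12)
  for (t in 1:12) {
    d <- -0.7 - 0.8 * log2(pres / 1000)
    corr[t] <- stats::runif(1) < p_correct(ability, d)
    stim[t] <- paste0("presentation_ms=", round(pres))
    rts[t] <- pres + draw_rt(1, 1200, speed, ability)
    pres <- if (corr[t]) max(pres - step, floor_ms) else min(pres + step,
                                                             cap_ms)
  }
  list(events = trial_events(27L, stim,
                             ifelse(corr, "correct", "incorrect"),
                             corr, rts),
       raw_score = sum(corr))
}

# --- memory spans (IDs 28/33 and 43/44) --------------------------------
# Span starts at 3 and increases by one after every `block` trials
# (block = 2 for IDs 28/33, 3 for IDs 43/44). Two incorrect responses at
# the same span level end the subtest; span is capped at 10 (ten circles).
# Score: IDs 28/33, maximum span with at least one correct trial (0 when
# none); IDs 43/44, total correct trials.
sim_span <- function(ability, speed, block, score_type,
                     start_span = 3L, max_span = 10L) {
  span <- start_span
  in_block <- 0L
  wrong_at <- stats::setNames(integer(max_span), seq_len(max_span))
  spans <- integer(); corr <- logical(); rts <- numeric()
  repeat {
    d <- 0.45 * (span - 5)
    ok <- stats::runif(1) < p_correct(ability, d)
    spans <- c(spans, span); corr <- c(corr, ok)
    rts <- c(rts, span * 700 + draw_rt(1, 1500, speed, ability))
    if (!ok) {
      wrong_at[span] <- wrong_at[span] + 1L
      if (wrong_at[span] >= 2L) break
    }
    in_block <- in_block + 1L
    if (in_block >= block) {
      if (span >= max_span) break
      span <- span + 1L
      in_block <- 0L
    }
  }
  score <- if (score_type == "max_span") {
    if (any(corr)) max(spans[corr]) else 0L
  } else {
    sum(corr)
  }
  list(events = trial_events(NA_integer_, paste0("span=", spans),
                             ifelse(corr, "correct", "incorrect"), corr,
                             rts),
       raw_score = as.numeric(score))
}

# --- timed item streams: arithmetic (29), grammar (30), digit symbol
# (38/45) ----------------------------------------------------------------
# Trials are answered until the time budget runs out; a trial begun but not
# finished inside the budget does not count. Grammar is scored
# correct - incorrect with a floor of zero.
sim_timed_stream <- function(ability, speed, budget_s, base_rt_ms, acc_d,
                             scoring = c("correct", "net")) {
  scoring <- match.arg(scoring)
  n_max <- ceiling(budget_s / (base_rt_ms / 1000) * 6) + 20
  rts <- draw_rt(n_max, base_rt_ms, speed, ability) / 1000
  done <- cumsum(rts) <= budget_s
  n <- sum(done)
  corr <- stats::runif(n) < p_correct(ability, acc_d)
  score <- if (scoring == "correct") sum(corr) else
    max(sum(corr) - sum(!corr), 0)
  list(events = trial_events(NA_integer_, "item",
                             ifelse(corr, "correct", "incorrect"), corr,
                             rts[seq_len(n)] * 1000),
       raw_score = as.numeric(score))
}

# --- progressive matrices (ID 31) --------------------------------------
# 17 trials of increasing difficulty; three consecutive incorrect answers
# end the subtest. Score: total correct.
sim_matrices <- function(ability, speed) {
  corr <- logical(0); rts <- numeric(0)
  streak <- 0L
  for (t in 1:17) {
    d <- -1.8 + 0.25 * (t - 1)
    ok <- stats::runif(1) < p_correct(ability, d)
    corr <- c(corr, ok)
    rts <- c(rts, draw_rt(1, 9000, speed, ability))
    streak <- if (ok) 0L else streak + 1L
    if (streak >= 3L) break
  }
  list(events = trial_events(31L, paste0("item=", seq_along(corr)),
                             ifelse(corr, "correct", "incorrect"), corr,
                             rts),
       raw_score = sum(corr))
}

# --- verbal list learning (IDs 36, 37) ---------------------------------
# 12 words, three presentation/recall rounds; score is the round-3 recall
# count. The delayed version (37) replays the learning phase and retains
# each round-3 word with a retention probability (artifact default).
sim_lists <- function(ability, speed, delayed = FALSE,
                      retention_d = -1.4) {
  d_round <- c(1.0, 0.4, -0.1)
  recalled <- matrix(FALSE, 12, 3)
  for (r in 1:3) {
    recalled[, r] <- stats::runif(12) < p_correct(ability, d_round[r])
  }
  final <- recalled[, 3]
  if (delayed) {
    final <- final & stats::runif(12) < p_correct(ability, retention_d)
  }
  sid <- if (delayed) 37L else 36L
  list(events = trial_events(sid, paste0("word=", 1:12),
                             ifelse(final, "recalled", "missed"), final,
                             draw_rt(12, 2500, speed, ability)),
       raw_score = sum(final))
}

# --- trail making (IDs 39, 40) -----------------------------------------
# 24 circles clicked in sequence; a wrong click shows an X and forces a
# return to the previous circle (modelled as two penalty clicks). Score:
# completion time in seconds.
sim_trails <- function(ability, speed, part = c("A", "B")) {
  part <- match.arg(part)
  base <- if (part == "A") 1100 else 1800
  err_d <- if (part == "A") 2.6 else 2.2
  clicks <- 24L
  errs <- stats::runif(clicks) > p_correct(ability, -err_d)
  click_rt <- draw_rt(clicks, base, speed, ability)
  penalty <- ifelse(errs, draw_rt(clicks, base, speed, ability) +
                      draw_rt(clicks, base, speed, ability), 0)
  per_circle <- click_rt + penalty
  sid <- if (part == "A") 39L else 40L
  list(events = trial_events(sid, paste0("circle=", seq_len(clicks)),
                             ifelse(errs, "error_then_correct", "correct"),
                             !errs, per_circle),
       raw_score = sum(per_circle) / 1000)
}

# --- scale balance (ID 51) ---------------------------------------------
# Up to 25 trials of increasing difficulty inside a ten-minute budget;
# three incorrect in a row ends the subtest. Score: correct responses.
sim_scale_balance <- function(ability, speed) {
  corr <- logical(0); rts <- numeric(0)
  streak <- 0L; elapsed <- 0
  for (t in 1:25) {
    d <- -1.5 + 0.18 * (t - 1)
    rt <- draw_rt(1, 12000, speed, ability) / 1000
    if (elapsed + rt > 600) break
    elapsed <- elapsed + rt
    ok <- stats::runif(1) < p_correct(ability, d)
    corr <- c(corr, ok); rts <- c(rts, rt * 1000)
    streak <- if (ok) 0L else streak + 1L
    if (streak >= 3L) break
  }
  list(events = trial_events(51L, paste0("item=", seq_along(corr)),
                             ifelse(corr, "correct", "incorrect"), corr,
                             rts),
       raw_score = sum(corr))
}

# --- Posner cueing (ID 52) ---------------------------------------------
# 100 trials; the stimulus appears at the cued location on 60% of trials.
# Score: correct responses out of 100.
sim_posner <- function(ability, speed, n_trials = 100L, p_cued = 0.6) {
  cued <- stats::runif(n_trials) < p_cued
  d <- ifelse(cued, -2.4, -2.0)
  corr <- stats::runif(n_trials) < p_correct(ability, d)
  rts <- pmin(draw_rt(n_trials, 420, speed, ability), 6000)
  list(events = trial_events(52L, ifelse(cued, "cued", "uncued"),
                             ifelse(corr, "correct", "incorrect"), corr,
                             rts),
       raw_score = sum(corr))
}

# --- complex span (ID 53) ----------------------------------------------
# Span starts at 4 and increases by one after each correct response; two
# incorrect responses at the same span end the subtest (trials capped at 30
# as a guard for forced agents). Score: total correct trials.
sim_complex_span <- function(ability, speed, max_trials = 30L) {
  span <- 4L
  wrong_at <- integer(64)
  spans <- integer(); corr <- logical(); rts <- numeric()
  for (t in seq_len(max_trials)) {
    d <- 0.5 * (span - 5)
    ok <- stats::runif(1) < p_correct(ability, d)
    spans <- c(spans, span); corr <- c(corr, ok)
    rts <- c(rts, span * 1200 + draw_rt(1, 2500, speed, ability))
    if (ok) {
      span <- span + 1L
    } else {
      wrong_at[span] <- wrong_at[span] + 1L
      if (wrong_at[span] >= 2L) break
    }
  }
  list(events = trial_events(53L, paste0("span=", spans),
                             ifelse(corr, "correct", "incorrect"), corr,
                             rts),
       raw_score = sum(corr))
}

# --- object recognition (ID 54) ----------------------------------------
# 20 studied shapes, then 40 yes/no probes (20 old, 20 new). Score: correct.
sim_object_recognition <- function(ability, speed) {
  old <- rep(c(TRUE, FALSE), each = 20L)
  corr <- stats::runif(40) < p_correct(ability, -0.9)
  list(events = trial_events(54L, ifelse(old, "old", "new"),
                             ifelse(corr, "correct", "incorrect"), corr,
                             draw_rt(40, 1600, speed, ability)),
       raw_score = sum(corr))
}

# --- dual search (ID 55) -----------------------------------------------
# 50 trials; each poses one of two randomly selected questions (were the
# five central letters the same / which red letter appeared). Unanswered
# trials (6 s limit) are incorrect. Score: correct of 50.
sim_dual_search <- function(ability, speed) {
  qtype <- ifelse(stats::runif(50) < 0.5, "center_same", "red_letter")
  d <- ifelse(qtype == "red_letter", -1.0, -0.8)
  corr <- stats::runif(50) < p_correct(ability, d)
  rts <- pmin(draw_rt(50, 1500, speed, ability), 6000)
  list(events = trial_events(55L, qtype,
                             ifelse(corr, "correct", "incorrect"), corr,
                             rts),
       raw_score = sum(corr))
}

#' Simulate one subtest session
#'
#' Runs the trial-level simulator for a subtest: trials are generated under
#' the task's published rules (trial counts, adaptive difficulty, stopping
#' rules) and scored by its published scoring rule; the agent responds
#' correctly with probability \code{logistic(1.7 * (ability - difficulty))}
#' and with lognormal response times.
#'
#' @param profile list (or one-row data.frame) with numeric \code{ability}
#'   (standard-normal scale; \code{Inf} forces an always-correct agent) and
#'   \code{speed} (log response-time offset, 0 = typical).
#' @param subtest_id integer subtest id from [subtest_registry()].
#' @param seed optional integer seed for a reproducible session.
#' @return list with \code{events} (one row per trial: stimulus descriptor,
#'   response, correct flag, response time in ms) and \code{raw_score} in
#'   the subtest's units (\code{NA} for a failed go/no-go session).
#' @examples
#' simulate_subtest(list(ability = 0, speed = 0), 31, seed = 1)$raw_score
#' @export
simulate_subtest <- function(profile, subtest_id, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- profile$ability
  s <- if (is.null(profile$speed)) 0 else profile$speed
  subtest_id <- as.integer(subtest_id)
  res <- switch(as.character(subtest_id),
    "26" = sim_go_no_go(a, s, target = 5L),
    "32" = sim_go_no_go(a, s, target = 10L),
    "27" = sim_dva(a, s),
    "28" = sim_span(a, s, block = 2L, score_type = "max_span"),
    "33" = sim_span(a, s, block = 2L, score_type = "max_span"),
    "43" = sim_span(a, s, block = 3L, score_type = "total_correct"),
    "44" = sim_span(a, s, block = 3L, score_type = "total_correct"),
    "29" = sim_timed_stream(a, s, budget_s = 45, base_rt_ms = 3500,
                            acc_d = -1.2, scoring = "correct"),
    "30" = sim_timed_stream(a, s, budget_s = 45, base_rt_ms = 3000,
                            acc_d = -0.9, scoring = "net"),
    "38" = sim_timed_stream(a, s, budget_s = 90, base_rt_ms = 1800,
                            acc_d = -2.0, scoring = "correct"),
    "45" = sim_timed_stream(a, s, budget_s = 90, base_rt_ms = 1800,
                            acc_d = -2.0, scoring = "correct"),
    "31" = sim_matrices(a, s),
    "36" = sim_lists(a, s, delayed = FALSE),
    "37" = sim_lists(a, s, delayed = TRUE),
    "39" = sim_trails(a, s, part = "A"),
    "40" = sim_trails(a, s, part = "B"),
    "51" = sim_scale_balance(a, s),
    "52" = sim_posner(a, s),
    "53" = sim_complex_span(a, s),
    "54" = sim_object_recognition(a, s),
    "55" = sim_dual_search(a, s),
    stop("unknown subtest_id: ", subtest_id, call. = FALSE)
  )
  res$events$subtest_id <- subtest_id
  res
}
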