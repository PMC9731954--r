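# Census-reweighted inverse normal transformation (INT).
#
# Given oriented scores x_1..x_N with demographic bins k_i, sample bin
# proportions f_k = N_k/N and reference proportions f*_k, each observation
# receives a reweighted percentile-bin width
#     w_i = f*_{k_i} / (N f_{k_i}),
# and, after rank-ordering the scores, a reweighted rank
#     r~_i = w_i / 2 + sum_{j < i} w_j
# (the 1/2 centers each percentile bin, as in the standard centered-rank
# INT). Normalized scores are y_i = Phi^{-1}(r~_i) at the target mean/SD.
# When f* = f the construction collapses to the textbook centered ranks
# (i - 1/2)/N.

#' Orient raw scores so that larger is better
#'
#' Subtests whose raw score grows as performance worsens (go/no-go mean RT,
#' IDs 26/32; trail-making completion time, IDs 39/40) are negated before
#' normalization. Raw scores in output files are never negated.
#'
#' @param subtest_id integer subtest id (scalar or vector).
#' @param raw_score numeric raw scores.
#' @return numeric oriented scores.
#' @export
orient_score <- function(subtest_id, raw_score) {
  subtest_id <- as.integer(subtest_id)
  known <- subtest_id %in% subtest_registry()$subtest_id
  if (any(!known)) {
    stop("unknown subtest_id: ", paste(unique(subtest_id[!known]),
                                       collapse = ", "), call. = FALSE)
  }
  neg <- rep_len(subtest_id %in% negated_subtests(), length(raw_score))
  ifelse(neg, -raw_score, raw_score)
}

#' Reweighted percentile widths and ranks
#'
#' Computes the per-observation reweighted width w and reweighted rank r~
#' of the census-reweighted INT. Sample proportions f are taken from the
#' observations themselves. Tied scores receive the weight-averaged r~ of
#' their tie group, so equal scores map to equal normalized values.
#'
#' @param x numeric oriented scores (any order).
#' @param k integer demographic bin indices (0-17), no \code{NA}.
#' @param reference a [reference_composition()] of target proportions f*.
#' @return list with \code{w} and \code{r_tilde}, aligned with the input
#'   order; \code{sum(w)} equals the total reference mass of the bins
#'   present in the sample.
#' @examples
#' ref <- reference_composition(c(0.75, 0.25, rep(0, 16)))
#' reweighted_ranks(c(1, 2, 3, 4), c(0L, 1L, 0L, 1L), ref)
#' @export
reweighted_ranks <- function(x, k, reference) {
  n <- length(x)
  stopifnot(length(k) == n)
  if (n == 0L) return(list(w = numeric(), r_tilde = numeric()))
  if (anyNA(x) || anyNA(k)) {
    stop("scores and bins must be complete for reweighting", call. = FALSE)
  }
  if (any(k < 0L | k > 17L)) stop("bin index outside 0..17", call. = FALSE)
  fstar <- as.numeric(reference)
  f <- tabulate(k + 1L, nbins = 18L) / n
  present <- which(f > 0) - 1L
  if (any(fstar[present + 1L] == 0 & f[present + 1L] > 0)) {
    # sample members of a bin with zero reference mass get zero width;
    # allowed, but they carry no weight
    absent <- present[fstar[present + 1L] == 0]
    warning("sample bin(s) with zero reference mass: ",
            paste(absent, collapse = ", "), call. = FALSE)
  }
  missing_mass <- sum(fstar[-(present + 1L)])
  if (missing_mass > 1e-12) {
    warning(sprintf(
      "reference bins absent from the sample carry mass %.4f; sum(w) < 1",
      missing_mass), call. = FALSE)
  }
  w <- fstar[k + 1L] / (n * f[k + 1L])
  ord <- order(x)              # stable
  ws <- w[ord]
  r <- cumsum(ws) - ws / 2
  # midrank analogue for ties: weight-averaged r~ within each tie group
  xs <- x[ord]
  ties <- cumsum(c(TRUE, xs[-1L] != xs[-n]))
  if (ties[n] < n) {
    grp_wr <- tapply(ws * r, ties, sum)
    grp_w <- tapply(ws, ties, sum)
    r <- as.numeric((grp_wr / grp_w)[ties])
  }
  r_tilde <- numeric(n)
  r_tilde[ord] <- r
  list(w = w, r_tilde = r_tilde)
}

#' Census-reweighted inverse normal transformation
#'
#' Maps oriented scores to a normal scale with the stated target mean and
#' SD, weighting each observation's percentile bin by the ratio of its
#' demographic bin's reference proportion to its sample proportion. With
#' the reference equal to the sample composition this is the standard
#' centered-rank INT.
#'
#' @inheritParams reweighted_ranks
#' @param target_mean,target_sd parameters of the target normal scale
#'   (defaults 100 and 15).
#' @return list with \code{w}, \code{r_tilde}, \code{y} (normalized scores,
#'   input order), \code{target_mean}, \code{target_sd}.
#' @export
reweighted_int <- function(x, k, reference, target_mean = 100,
                           target_sd = 15) {
  rr <- reweighted_ranks(x, k, reference)
  if (length(rr$r_tilde) &&
      (min(rr$r_tilde) <= 0 || max(rr$r_tilde) >= 1)) {
    stop("internal invariant violated: reweighted ranks outside (0, 1)",
         call. = FALSE)
  }
  y <- stats::qnorm(rr$r_tilde, mean = target_mean, sd = target_sd)
  list(w = rr$w, r_tilde = rr$r_tilde, y = y,
       target_mean = target_mean, target_sd = target_sd)
}

#' Normalization curve from a norm sample
#'
#' Freezes the (oriented score -> reweighted rank) mapping estimated on a
#' norm sample so that scores outside the sample can be normalized too.
#' Between adjacent sample points the rank is linearly interpolated;
#' outside the sample range it is clamped to [w_min/2, 1 - w_min/2], where
#' w_min is the smallest reweighted width in the sample.
#'
#' @inheritParams reweighted_int
#' @return an object of class \code{"int_curve"} with a
#'   \code{predict} method mapping oriented scores to normalized values.
#' @export
int_curve <- function(x, k, reference, target_mean = 100, target_sd = 15) {
  fit <- reweighted_int(x, k, reference, target_mean, target_sd)
  ord <- order(x)
  xs <- x[ord]
  rs <- fit$r_tilde[ord]
  keep <- !duplicated(xs)
  w_pos <- fit$w[fit$w > 0]
  w_min <- if (length(w_pos)) min(w_pos) else 1 / length(x)
  structure(list(x = xs[keep], r = rs[keep],
                 lo = w_min / 2, hi = 1 - w_min / 2,
                 target_mean = target_mean, target_sd = target_sd,
                 fit = fit),
            class = "int_curve")
}

#' @rdname int_curve
#' @param object an \code{int_curve}.
#' @param newdata numeric oriented scores to normalize.
#' @param ... unused.
#' @export
predict.int_curve <- function(object, newdata, ...) {
  if (length(object$x) == 1L) {
    r <- rep(object$r, length(newdata))
    r[newdata < object$x] <- object$lo
    r[newdata > object$x] <- object$hi
  } else {
    r <- stats::approx(object$x, object$r, xout = newdata, rule = 2)$y
  }
  r <- pmin(pmax(r, object$lo), object$hi)
  stats::qnorm(r, mean = object$target_mean, sd = object$target_sd)
}

#' Build the norm sample
#'
#' The norm sample excludes participants who did not report age or
#' education (including education "Other", which belongs to no demographic
#' bin), who logged more than 25 gameplays before testing, or who did not
#' complete their test battery.
#'
#' @param records score-table data.frame.
#' @param gameplay_counts named numeric vector of pre-test gameplay counts
#'   indexed by user_id, or \code{NULL} (criterion skipped with a warning).
#' @param completeness named logical vector from [completeness_flags()];
#'   computed from \code{records} when \code{NULL}.
#' @param max_gameplays inclusion threshold; strictly more are excluded.
#' @return the subset of \code{records} in the norm sample, with columns
#'   \code{k} (demographic bin) added.
#' @export
build_norm_sample <- function(records, gameplay_counts = NULL,
                              completeness = NULL, max_gameplays = 25) {
  if (is.null(completeness)) completeness <- completeness_flags(records)
  bins <- assign_bin(records$age, records$education_level)
  keep <- !is.na(bins$k) & completeness[records$test_run_id]
  if (is.null(gameplay_counts)) {
    warning("gameplay counts unavailable; the >", max_gameplays,
            "-gameplay exclusion is skipped", call. = FALSE)
  } else {
    gp <- gameplay_counts[records$user_id]
    keep <- keep & !is.na(gp) & gp <= max_gameplays
  }
  out <- records[which(keep), , drop = FALSE]
  out$k <- bins$k[which(keep)]
  rownames(out) <- NULL
  out
}

#' Normalize subtest scores against a reference composition
#'
#' Fits, per subtest version (versions of the same task are never pooled),
#' a census-reweighted INT curve on the norm sample and maps every record's
#' oriented score through it. Records outside the norm sample are
#' normalized by interpolation of the sample curve.
#'
#' @inheritParams build_norm_sample
#' @param reference a [reference_composition()].
#' @param target_mean,target_sd target normal scale.
#' @return \code{records} with columns \code{normalized_score} (NA when the
#'   subtest has no norm sample) and \code{in_norm_sample} added.
#' @export
normalize_scores <- function(records, reference, gameplay_counts = NULL,
                             completeness = NULL, target_mean = 100,
                             target_sd = 15) {
  if (is.null(completeness)) completeness <- completeness_flags(records)
  norm <- build_norm_sample(records, gameplay_counts, completeness)
  records$normalized_score <- NA_real_
  records$in_norm_sample <- FALSE
  nkey <- paste(norm$test_run_id, norm$specific_subtest_id)
  rkey <- paste(records$test_run_id, records$specific_subtest_id)
  records$in_norm_sample <- rkey %in% nkey
  for (sid in unique(records$specific_subtest_id)) {
    ns <- norm[norm$specific_subtest_id == sid, ]
    if (nrow(ns) == 0L) next
    curve <- int_curve(orient_score(sid, ns$raw_score), ns$k, reference,
                       target_mean, target_sd)
    rows <- which(records$specific_subtest_id == sid)
    records$normalized_score[rows] <-
      predict(curve, orient_score(sid, records$raw_score[rows]))
    # exact (non-interpolated) values for the norm sample itself
    in_ns <- rows[records$in_norm_sample[rows]]
    if (length(in_ns)) {
      m <- match(paste(records$test_run_id[in_ns], sid),
                 paste(ns$test_run_id, sid))
      records$normalized_score[in_ns] <- curve$fit$y[m]
    }
  }
  records
}

#' Grand Index
#'
#' The battery-level composite: the mean of a run's normalized subtest
#' scores, re-mapped through a second census-reweighted INT to a normal
#' scale with mean 100 and SD 15 (so GI = 100 is average performance
#' relative to the reference population). The GI exists only for runs that
#' completed every subtest of their battery; it is computed separately per
#' battery against the shared reference.
#'
#' @param normalized records as returned by [normalize_scores()].
#' @inheritParams normalize_scores
#' @return named numeric vector of GI values indexed by test_run_id
#'   (\code{NA} for incomplete runs).
#' @export
compute_grand_index <- function(normalized, reference, completeness = NULL,
                                target_mean = 100, target_sd = 15) {
  if (is.null(completeness)) completeness <- completeness_flags(normalized)
  runs <- unique(normalized[, c("user_id", "test_run_id", "battery_id",
                                "age", "education_level")])
  gi <- stats::setNames(rep(NA_real_, nrow(runs)), runs$test_run_id)
  complete <- completeness[runs$test_run_id]
  mean_y <- tapply(normalized$normalized_score, normalized$test_run_id,
                   mean)
  bins <- assign_bin(runs$age, runs$education_level)
  in_ns <- tapply(normalized$in_norm_sample, normalized$test_run_id, all)
  for (b in unique(runs$battery_id)) {
    sel <- runs$battery_id == b & complete &
      !is.na(mean_y[runs$test_run_id])
    if (!any(sel)) next
    ns_sel <- sel & in_ns[runs$test_run_id] & !is.na(bins$k)
    if (!any(ns_sel)) next
    curve <- int_curve(as.numeric(mean_y[runs$test_run_id[ns_sel]]),
                       bins$k[ns_sel], reference, target_mean, target_sd)
    gi[runs$test_run_id[ns_sel]] <- curve$fit$y
    outside <- sel & !ns_sel
    if (any(outside)) {
      gi[runs$test_run_id[outside]] <-
        predict(curve, as.numeric(mean_y[runs$test_run_id[outside]]))
    }
  }
  gi
}
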