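# Technical validation: regress each subtest's raw score on age (linear),
# education and gender (categorical), subtract the fit to obtain
# demographics-corrected residual scores, and inspect the subtest-subtest
# Pearson correlation matrix per battery. Across cognitive tasks these
# residual correlations are expected to be exclusively positive (the
# positive manifold).

#' Demographics-corrected residual scores
#'
#' Fits, per battery and subtest, an ordinary least squares model
#' \code{raw_score ~ age + factor(education_level) + factor(gender)} and
#' returns observed minus fitted. Only participants with a complete battery
#' and complete demographics (age, education, gender all reported; education
#' "Other" counts as a level here) are used — listwise inclusion.
#'
#' @param records score-table data.frame.
#' @param use_oriented if \code{TRUE}, time-scored subtests are negated
#'   before fitting; default \code{FALSE} (raw scores are the outcome).
#' @return data.frame of class \code{"residual_table"} with columns
#'   \code{user_id}, \code{test_run_id}, \code{battery_id},
#'   \code{specific_subtest_id}, \code{residual}; per-subtest OLS
#'   coefficients in \code{attr(, "models")}.
#' @export
residualize <- function(records, use_oriented = FALSE) {
  complete_demo <- !is.na(records$age) & !is.na(records$education_level) &
    !is.na(records$gender)
  completeness <- completeness_flags(records)
  keep <- complete_demo & completeness[records$test_run_id]
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no complete records to residualize",
                            call. = FALSE)
  out <- list()
  models <- list()
  for (b in unique(rec$battery_id)) {
    rb <- rec[rec$battery_id == b, ]
    for (sid in unique(rb$specific_subtest_id)) {
      rs <- rb[rb$specific_subtest_id == sid, ]
      y <- if (use_oriented) orient_score(sid, rs$raw_score) else
        rs$raw_score
      df <- data.frame(y = y, age = rs$age,
                       education_level = factor(rs$education_level),
                       gender = factor(rs$gender))
      singletons <- names(which(table(df$education_level) == 1L))
      if (length(singletons)) {
        warning("battery ", b, " subtest ", sid,
                ": education level(s) with a single observation: ",
                paste(singletons, collapse = ", "), call. = FALSE)
      }
      # constant predictors would make the design singular; drop them
      terms <- c(
        if (stats::var(df$age) > 0) "age",
        if (nlevels(droplevels(df$education_level)) > 1L) "education_level",
        if (nlevels(droplevels(df$gender)) > 1L) "gender")
      form <- stats::reformulate(if (length(terms)) terms else "1",
                                 response = "y")
      fit <- stats::lm(form, data = df)
      if (any(is.na(stats::coef(fit)))) {
        stop("singular design for battery ", b, " subtest ", sid,
             call. = FALSE)
      }
      models[[paste(b, sid, sep = ":")]] <- summary(fit)$coefficients
      out[[length(out) + 1L]] <- data.frame(
        user_id = rs$user_id, test_run_id = rs$test_run_id,
        battery_id = b, specific_subtest_id = sid,
        residual = as.numeric(stats::resid(fit)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "models") <- models
  class(res) <- c("residual_table", class(res))
  res
}

#' Subtest-subtest residual correlation matrices
#'
#' Pearson correlations between residual scores of each subtest pair,
#' per battery, over participants with both scores.
#'
#' @param residuals a \code{residual_table} from [residualize()].
#' @param min_pairs minimum participants required per pair (default 3).
#' @return list of class \code{"correlation_report"}: per battery a list
#'   with \code{matrix} (symmetric, unit diagonal), \code{n}, \code{min},
#'   \code{max} (off-diagonal extremes) and \code{all_positive}.
#' @export
correlation_matrix <- function(residuals, min_pairs = 3) {
  out <- list()
  for (b in unique(residuals$battery_id)) {
    rb <- residuals[residuals$battery_id == b, ]
    sids <- battery_subtests(b)
    sids <- sids[sids %in% rb$specific_subtest_id]
    wide <- stats::reshape(
      rb[, c("test_run_id", "specific_subtest_id", "residual")],
      idvar = "test_run_id", timevar = "specific_subtest_id",
      direction = "wide")
    m <- as.matrix(wide[, paste0("residual.", sids), drop = FALSE])
    colnames(m) <- as.character(sids)
    if (nrow(m) < min_pairs) {
      stop("fewer than ", min_pairs, " participants for battery ", b,
           call. = FALSE)
    }
    zero_var <- apply(m, 2, function(x) stats::sd(x, na.rm = TRUE) == 0)
    if (any(zero_var, na.rm = TRUE)) {
      stop("zero-variance residuals for subtest(s) ",
           paste(colnames(m)[which(zero_var)], collapse = ", "),
           " in battery ", b, "; correlation undefined", call. = FALSE)
    }
    cm <- stats::cor(m, use = "pairwise.complete.obs")
    off <- cm[upper.tri(cm)]
    out[[as.character(b)]] <- list(
      matrix = cm, n = nrow(m),
      min = if (length(off)) min(off) else NA_real_,
      max = if (length(off)) max(off) else NA_real_,
      all_positive = length(off) == 0L || all(off > 0))
  }
  class(out) <- "correlation_report"
  out
}

#' Positive-manifold check
#'
#' Confirms that every off-diagonal residual correlation is strictly
#' positive, battery by battery.
#'
#' @param report a \code{correlation_report} from [correlation_matrix()].
#' @return list with \code{positive} (TRUE iff all off-diagonals in all
#'   batteries are > 0), \code{min}, \code{max}, and \code{negative_pairs}
#'   (data.frame naming any offending entries).
#' @export
positive_manifold_check <- function(report) {
  neg <- list()
  mins <- maxs <- numeric()
  for (b in names(report)) {
    cm <- report[[b]]$matrix
    mins <- c(mins, report[[b]]$min)
    maxs <- c(maxs, report[[b]]$max)
    idx <- which(upper.tri(cm) & cm <= 0, arr.ind = TRUE)
    if (nrow(idx)) {
      neg[[b]] <- data.frame(battery_id = as.integer(b),
                             subtest_a = rownames(cm)[idx[, 1]],
                             subtest_b = colnames(cm)[idx[, 2]],
                             r = cm[idx], stringsAsFactors = FALSE)
    }
  }
  negative_pairs <- if (length(neg)) do.call(rbind, neg) else
    data.frame(battery_id = integer(), subtest_a = character(),
               subtest_b = character(), r = numeric())
  rownames(negative_pairs) <- NULL
  list(positive = nrow(negative_pairs) == 0L,
       min = if (length(mins)) min(mins, na.rm = TRUE) else NA_real_,
       max = if (length(maxs)) max(maxs, na.rm = TRUE) else NA_real_,
       negative_pairs = negative_pairs)
}
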