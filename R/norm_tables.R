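# Normative tables: per battery, summary statistics of raw scores within
# 36 demographic bins (6 age x 3 education x 2 gender). A battery is
# reported only when every (subtest x bin) cell holds at least 20
# participants. Statistics are computed on raw, unnegated scores; for
# subtests where lower raw scores mean better performance, the p-th
# performance percentile is the (100-p)-th raw-score quantile, so a higher
# reported percentile always means better performance.

norm_percentiles <- function() c(10, 25, 50, 75, 90)

# Linear interpolation between order statistics (quantile type 7).
score_percentiles <- function(x, negated) {
  p <- norm_percentiles() / 100
  if (negated) p <- 1 - p
  stats::setNames(stats::quantile(x, probs = p, type = 7, names = FALSE),
                  paste0("percentile_", norm_percentiles()))
}

#' Compute normative tables
#'
#' @param records preprocessed score-table data.frame; the
#'   \code{grand_index} column (when present and non-missing) supplies the
#'   Grand Index rows.
#' @param min_n minimum participants per (subtest x bin) cell for a battery
#'   to be reported (default 20).
#' @param genders the gender tokens admitted to the gendered bins
#'   (default \code{c("m", "f")}); participants outside the set (or with
#'   missing gender, age or binnable education) are excluded.
#' @return named list, one entry per reported battery id, each a data.frame
#'   in the 13-column norms schema (see [write_norms_table()]). Batteries
#'   failing the \code{min_n} rule are absent.
#' @export
compute_norm_tables <- function(records, min_n = 20, genders = c("m", "f")) {
  bins <- assign_bin(records$age, records$education_level)
  ok <- !is.na(bins$k) & !is.na(records$gender) &
    records$gender %in% genders
  rec <- records[ok, , drop = FALSE]
  rec$age_bin <- bins$age_bin[ok]
  rec$edu_bin <- bins$edu_bin[ok]
  reg <- subtest_registry()
  out <- list()
  for (b in sort(unique(rec$battery_id))) {
    rb <- rec[rec$battery_id == b, ]
    subtests <- battery_subtests(b)
    cells <- expand.grid(age_bin = 0:5, edu_bin = 0:2, gender = genders,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    cells <- cells[order(cells$age_bin, cells$edu_bin, cells$gender), ]
    # the >= min_n rule: every subtest must meet it in every cell
    meets <- TRUE
    for (sid in subtests) {
      rs <- rb[rb$specific_subtest_id == sid & !is.na(rb$raw_score), ]
      n_cell <- vapply(seq_len(nrow(cells)), function(i) {
        sum(rs$age_bin == cells$age_bin[i] &
              rs$edu_bin == cells$edu_bin[i] &
              rs$gender == cells$gender[i])
      }, integer(1))
      if (any(n_cell < min_n)) { meets <- FALSE; break }
    }
    if (!meets) next
    rows <- list()
    stat_row <- function(name, sid, x, negated, cell) {
      pc <- score_percentiles(x, negated)
      cbind(data.frame(subtest_name = name,
                       specific_subtest_id = sid,
                       age = age_bin_labels()[cell$age_bin + 1L],
                       education_level = edu_bin_labels()[cell$edu_bin + 1L],
                       gender = cell$gender,
                       N = length(x),
                       mean = mean(x), SD = stats::sd(x),
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(pc)))
    }
    for (sid in subtests) {
      negated <- sid %in% negated_subtests()
      name <- reg$short_name[reg$subtest_id == sid]
      rs <- rb[rb$specific_subtest_id == sid & !is.na(rb$raw_score), ]
      for (i in seq_len(nrow(cells))) {
        x <- rs$raw_score[rs$age_bin == cells$age_bin[i] &
                            rs$edu_bin == cells$edu_bin[i] &
                            rs$gender == cells$gender[i]]
        rows[[length(rows) + 1L]] <- stat_row(name, sid, x, negated,
                                              cells[i, ])
      }
    }
    # Grand Index rows: one value per completed run
    if ("grand_index" %in% names(rb)) {
      runs <- rb[!duplicated(rb$test_run_id) & !is.na(rb$grand_index), ]
      if (nrow(runs)) {
        for (i in seq_len(nrow(cells))) {
          x <- runs$grand_index[runs$age_bin == cells$age_bin[i] &
                                  runs$edu_bin == cells$edu_bin[i] &
                                  runs$gender == cells$gender[i]]
          if (length(x) == 0L) next
          rows[[length(rows) + 1L]] <-
            stat_row("grand_index", NA_integer_, x, FALSE, cells[i, ])
        }
      }
    }
    tbl <- do.call(rbind, rows)
    rownames(tbl) <- NULL
    out[[as.character(b)]] <- tbl
  }
  out
}
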