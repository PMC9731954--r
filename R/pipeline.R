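# End-to-end orchestration: (simulate) -> preprocess -> normalize -> Grand
# Index -> normative tables -> technical validation, with a run manifest
# summarizing record counts per stage. Counts are non-increasing across the
# filter stages. When only released-schema scores are available (no session
# logs), the time-based filters cannot run; they are skipped and the
# manifest records a warning.

#' Run the full processing pipeline
#'
#' @param input either a [cohort_config()] (a cohort is simulated first), a
#'   list with elements \code{logs} and/or \code{scores} (e.g. the result
#'   of [simulate_cohort()]), or a bare score-table data.frame.
#' @param reference a [reference_composition()], or the string
#'   \code{"match"} / \code{"uniform"} (built from the preprocessed data).
#' @param seed master seed; per-stage seeds are derived from it.
#' @param out_dir optional directory; when given, the cleaned scores (with
#'   grand_index filled), per-battery norms files
#'   (\code{batteryNN_norms.csv}) and the manifest JSON are written there.
#' @param min_norm_n per-cell participant minimum for norms (default 20).
#' @return list of class \code{"ncpt_pipeline"} with \code{scores}
#'   (grand_index filled), \code{report} (exclusions), \code{norms},
#'   \code{validation} (correlation report + manifold check), and
#'   \code{manifest}.
#' @export
run_pipeline <- function(input, reference = "match", seed = 1L,
                         out_dir = NULL, min_norm_n = 20) {
  manifest <- list(tool_version = as.character(utils::packageVersion("ncpt")),
                   seed = seed, stages = list(), warnings = character())
  note <- function(stage, n_records, n_users) {
    manifest$stages[[stage]] <<- list(records = n_records, users = n_users)
  }
  logs <- NULL
  scores <- NULL
  gameplay_counts <- NULL
  if (inherits(input, "cohort_config")) {
    sim <- simulate_cohort(input, seed)
    logs <- sim$logs
    note("simulate", nrow(logs), length(unique(logs$user_id)))
  } else if (is.data.frame(input)) {
    scores <- input
  } else if (is.list(input)) {
    logs <- input$logs
    scores <- input$scores
  } else {
    stop("unsupported input", call. = FALSE)
  }
  report <- new_exclusion_report()
  if (!is.null(logs)) {
    pp <- preprocess_logs(logs)
    report <- pp$report
    gameplay_counts <- stats::setNames(
      pp$kept$pre_test_gameplays[!duplicated(pp$kept$user_id)],
      pp$kept$user_id[!duplicated(pp$kept$user_id)])
    scores <- logs_to_score_table(pp$kept)
    note("preprocess", nrow(scores), length(unique(scores$user_id)))
  } else {
    w <- paste("no session logs supplied: time-based filters",
               "(pause, interleave, slow trails, first assessment)",
               "were skipped")
    warning(w, call. = FALSE)
    manifest$warnings <- c(manifest$warnings, w)
    scores$age <- topcode_age(scores$age)
    note("preprocess", nrow(scores), length(unique(scores$user_id)))
  }
  validate_score_table(scores)
  if (identical(reference, "match")) {
    reference <- make_reference(scores[!duplicated(scores$user_id), ],
                                mode = "match")
  } else if (identical(reference, "uniform")) {
    reference <- uniform_reference()
  }
  completeness <- completeness_flags(scores)
  normalized <- normalize_scores(scores, reference,
                                 gameplay_counts = gameplay_counts,
                                 completeness = completeness)
  note("normalize", sum(!is.na(normalized$normalized_score)),
       length(unique(normalized$user_id)))
  gi <- compute_grand_index(normalized, reference,
                            completeness = completeness)
  scores$grand_index <- as.numeric(gi[scores$test_run_id])
  note("grand_index", sum(!is.na(scores$grand_index)),
       length(unique(scores$user_id[!is.na(scores$grand_index)])))
  norms <- compute_norm_tables(scores, min_n = min_norm_n)
  note("norms", sum(vapply(norms, nrow, integer(1))), NA_integer_)
  # correlations are computed on oriented residuals, so "higher = better"
  # holds for every subtest and a positive manifold is interpretable even
  # in batteries with time-scored subtests
  res <- residualize(scores, use_oriented = TRUE)
  corr <- correlation_matrix(res)
  manifold <- positive_manifold_check(corr)
  note("validate", nrow(res), length(unique(res$user_id)))
  manifest$exclusions <- as.list(exclusion_counts(report))
  out <- list(scores = scores, normalized = normalized, report = report,
              reference = reference, norms = norms,
              validation = list(correlations = corr, manifold = manifold),
              manifest = manifest)
  class(out) <- "ncpt_pipeline"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    b <- unique(scores$battery_id)
    for (bb in b) {
      write_score_table(scores[scores$battery_id == bb, ],
                        file.path(out_dir, sprintf("battery%d_df.csv", bb)))
    }
    for (bb in names(norms)) {
      write_norms_table(norms[[bb]],
                        file.path(out_dir,
                                  sprintf("battery%s_norms.csv", bb)))
    }
    jsonlite::write_json(manifest,
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  out
}

#' @export
print.ncpt_pipeline <- function(x, ...) {
  cat("NCPT pipeline run\n")
  for (s in names(x$manifest$stages)) {
    st <- x$manifest$stages[[s]]
    cat(sprintf("  %-12s records=%s users=%s\n", s,
                format(st$records), format(st$users)))
  }
  cat("  positive manifold:", x$validation$manifold$positive, "\n")
  invisible(x)
}
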