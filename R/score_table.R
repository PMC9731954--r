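# Released score schema: 11 columns, fixed order. gender, education_level and
# grand_index may be empty; everything else is required.
score_table_columns <- function() {
  c("user_id", "age", "gender", "education_level", "country", "test_run_id",
    "battery_id", "specific_subtest_id", "time_of_day", "raw_score",
    "grand_index")
}

norms_table_columns <- function() {
  c("subtest_name", "specific_subtest_id", "age", "education_level", "gender",
    "N", "mean", "SD", "percentile_10", "percentile_25", "percentile_50",
    "percentile_75", "percentile_90")
}

# %.17g round-trips IEEE doubles through text exactly; integers print as
# integers. Period decimal separator, no grouping.
format_number <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- ""
  ok <- !is.na(x)
  out[ok] <- ifelse(x[ok] == trunc(x[ok]) & abs(x[ok]) < 1e15,
                    sprintf("%.0f", x[ok]), sprintf("%.17g", x[ok]))
  out
}

#' Read a released-schema score table
#'
#' Reads a CSV in the released 11-column score schema (one row per subtest
#' score, rows within a test run in administration order) and validates it
#' against the subtest/battery registries. Empty \code{gender},
#' \code{education_level} and \code{grand_index} fields become \code{NA};
#' the other fields must be present in every row.
#'
#' @param source path to a CSV file, or a connection.
#' @return A data.frame with the 11 schema columns; \code{gender} is
#'   lower-cased, ids are integers, scores are doubles. Row order (hence
#'   administration order within a run) is preserved.
#' @seealso [write_score_table()], [load_norms_table()]
#' @export
load_score_table <- function(source) {
  df <- utils::read.csv(source, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  if (!identical(names(df), score_table_columns())) {
    stop("score table header does not match the released 11-column schema; ",
         "got: ", paste(names(df), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    out <- data.frame(user_id = character(), age = integer(),
                      gender = character(), education_level = integer(),
                      country = character(), test_run_id = character(),
                      battery_id = integer(), specific_subtest_id = integer(),
                      time_of_day = integer(), raw_score = double(),
                      grand_index = double(), stringsAsFactors = FALSE)
    return(out)
  }
  num <- function(col, required) {
    raw <- df[[col]]
    empty <- !nzchar(raw)
    if (required && any(empty)) {
      stop("missing value in required column '", col, "' at row ",
           which(empty)[1L], call. = FALSE)
    }
    x <- suppressWarnings(as.numeric(raw))
    bad <- !empty & is.na(x)
    if (any(bad)) {
      stop("malformed number in column '", col, "' at row ", which(bad)[1L],
           ": '", raw[bad][1L], "'", call. = FALSE)
    }
    x
  }
  chr <- function(col, required) {
    raw <- df[[col]]
    empty <- !nzchar(raw)
    if (required && any(empty)) {
      stop("missing value in required column '", col, "' at row ",
           which(empty)[1L], call. = FALSE)
    }
    raw[empty] <- NA_character_
    raw
  }
  out <- data.frame(
    user_id = chr("user_id", TRUE),
    age = as.integer(num("age", TRUE)),
    gender = tolower(chr("gender", FALSE)),
    education_level = as.integer(num("education_level", FALSE)),
    country = chr("country", TRUE),
    test_run_id = chr("test_run_id", TRUE),
    battery_id = as.integer(num("battery_id", TRUE)),
    specific_subtest_id = as.integer(num("specific_subtest_id", TRUE)),
    time_of_day = as.integer(num("time_of_day", TRUE)),
    raw_score = num("raw_score", TRUE),
    grand_index = num("grand_index", FALSE),
    stringsAsFactors = FALSE
  )
  validate_score_table(out)
  out
}

#' Validate a score table against the registries and schema invariants
#'
#' Checks age range (18-90 after Safe-Harbor top-coding), time of day,
#' education codes, registry membership of every
#' (battery_id, specific_subtest_id) pair, and that \code{grand_index},
#' when present, is constant within a test run.
#'
#' @param records a score-table data.frame.
#' @return \code{records}, invisibly.
#' @export
validate_score_table <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(invisible(records))
  if (any(records$age < 18L | records$age > 90L)) {
    bad <- which(records$age < 18L | records$age > 90L)[1L]
    stop("age out of range [18, 90] at row ", bad, " (value ",
         records$age[bad], "); ages above 89 must be top-coded to 90",
         call. = FALSE)
  }
  if (any(records$time_of_day < 0L | records$time_of_day > 23L)) {
    bad <- which(records$time_of_day < 0L | records$time_of_day > 23L)[1L]
    stop("time_of_day out of range [0, 23] at row ", bad, call. = FALSE)
  }
  edu <- records$education_level
  bad_edu <- !is.na(edu) & !edu %in% education_levels()$code
  if (any(bad_edu)) {
    stop("unknown education code at row ", which(bad_edu)[1L], ": ",
         edu[bad_edu][1L], call. = FALSE)
  }
  reg <- battery_registry()
  for (b in unique(records$battery_id)) {
    key <- as.character(b)
    rows <- records$battery_id == b
    if (!key %in% names(reg)) {
      stop("unknown battery_id at row ", which(rows)[1L], ": ", b,
           call. = FALSE)
    }
    alien <- rows & !records$specific_subtest_id %in% reg[[key]]
    if (any(alien)) {
      stop("subtest ", records$specific_subtest_id[alien][1L],
           " at row ", which(alien)[1L], " is not part of battery ", b,
           call. = FALSE)
    }
  }
  gi_range <- tapply(records$grand_index, records$test_run_id, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0L) 0 else diff(range(g))
  })
  if (any(gi_range > 0)) {
    stop("grand_index differs across rows of test_run_id '",
         names(gi_range)[gi_range > 0][1L], "'", call. = FALSE)
  }
  invisible(records)
}

#' Write a score table in the released 11-column schema
#'
#' Numbers are written at full precision (they survive a write/read round
#' trip bit-exactly); missing gender, education and grand index become
#' empty fields.
#'
#' @param records a score-table data.frame as returned by
#'   [load_score_table()].
#' @param sink path or connection to write to.
#' @return \code{sink}, invisibly.
#' @export
write_score_table <- function(records, sink) {
  cols <- score_table_columns()
  stopifnot(all(cols %in% names(records)))
  out <- data.frame(
    user_id = as.character(records$user_id),
    age = format_number(as.numeric(records$age)),
    gender = ifelse(is.na(records$gender), "", records$gender),
    education_level = format_number(as.numeric(records$education_level)),
    country = as.character(records$country),
    test_run_id = as.character(records$test_run_id),
    battery_id = format_number(as.numeric(records$battery_id)),
    specific_subtest_id = format_number(as.numeric(records$specific_subtest_id)),
    time_of_day = format_number(as.numeric(records$time_of_day)),
    raw_score = format_number(records$raw_score),
    grand_index = format_number(records$grand_index),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, sink, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(sink)
}

#' Write and read normative tables (13-column schema)
#'
#' A norms file has 13 columns: subtest_name, specific_subtest_id, age
#' (age-bin label), education_level (education-group label), gender, N,
#' mean, SD and the 10th/25th/50th/75th/90th score percentiles. The Grand
#' Index rows carry subtest_name \code{"grand_index"} and an empty subtest
#' id. Writing then reading is lossless.
#'
#' @param rows a data.frame of norm rows (see [compute_norm_tables()]).
#' @param sink,source path or connection.
#' @return \code{write_norms_table}: \code{sink}, invisibly;
#'   \code{load_norms_table}: the norms data.frame.
#' @export
write_norms_table <- function(rows, sink) {
  cols <- norms_table_columns()
  stopifnot(all(cols %in% names(rows)))
  out <- data.frame(
    subtest_name = as.character(rows$subtest_name),
    specific_subtest_id = format_number(as.numeric(rows$specific_subtest_id)),
    age = as.character(rows$age),
    education_level = as.character(rows$education_level),
    gender = as.character(rows$gender),
    N = format_number(as.numeric(rows$N)),
    stringsAsFactors = FALSE
  )
  for (col in cols[7:13]) out[[col]] <- format_number(rows[[col]])
  utils::write.table(out, sink, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(sink)
}

#' @rdname write_norms_table
#' @export
load_norms_table <- function(source) {
  df <- utils::read.csv(source, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  if (!identical(names(df), norms_table_columns())) {
    stop("norms table header does not match the 13-column schema",
         call. = FALSE)
  }
  to_num <- function(x) suppressWarnings(as.numeric(ifelse(nzchar(x), x, NA)))
  out <- data.frame(
    subtest_name = df$subtest_name,
    specific_subtest_id = as.integer(to_num(df$specific_subtest_id)),
    age = df$age,
    education_level = df$education_level,
    gender = df$gender,
    N = as.integer(to_num(df$N)),
    stringsAsFactors = FALSE
  )
  for (col in norms_table_columns()[7:13]) out[[col]] <- to_num(df[[col]])
  out
}
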