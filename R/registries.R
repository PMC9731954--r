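#' Subtest registry
#'
#' The NCPT comprises 17 distinct cognitive tasks; four of them ship in two
#' scored versions, for 21 subtest identifiers in total. The registry records,
#' for each identifier, the task it instantiates, its version tag, the
#' identifier of the sibling version (if any), the raw-score units, and
#' whether the raw score must be negated before rank-based normalization
#' (true for the timed subtests, where a larger raw score means worse
#' performance: go/no-go mean reaction time, IDs 26 and 32, and trail-making
#' completion time, IDs 39 and 40).
#'
#' @return A data.frame with one row per subtest id and columns
#'   \code{subtest_id}, \code{task}, \code{short_name}, \code{version},
#'   \code{sibling_id} (\code{NA} when single-version),
#'   \code{negate_for_norms}, \code{score_units}.
#' @examples
#' reg <- subtest_registry()
#' reg[reg$subtest_id == 32, ]
#' @export
subtest_registry <- function() {
  reg <- data.frame(
    subtest_id = c(26L, 27L, 28L, 29L, 30L, 31L, 32L, 33L, 36L, 37L, 38L,
                   39L, 40L, 43L, 44L, 45L, 51L, 52L, 53L, 54L, 55L),
    task = c("Go/no-go", "Divided visual attention", "Forward memory span",
             "Arithmetic reasoning", "Grammatical reasoning",
             "Progressive matrices", "Go/no-go", "Reverse memory span",
             "Verbal list learning", "Delayed verbal list learning",
             "Digit symbol coding", "Trail making part A",
             "Trail making part B", "Forward memory span",
             "Reverse memory span", "Digit symbol coding", "Scale balance",
             "Posner cueing", "Complex memory span", "Object recognition",
             "Dual search"),
    short_name = c("Go/no-go", "DVA", "Forward mem.", "Arithmetic", "Grammar",
                   "Matrices", "Go/no-go", "Reverse mem.", "Lists",
                   "Delayed lists", "Digit symbol", "Trails A", "Trails B",
                   "Forward mem.", "Reverse mem.", "Digit symbol",
                   "Scale balance", "Posner", "Complex mem.", "Object recog.",
                   "Dual search"),
    version = c("v1", "v1", "v1", "v1", "v1", "v1", "v2", "v1", "v1", "v1",
                "v1", "v1", "v1", "v2", "v2", "v2", "v1", "v1", "v1", "v1",
                "v1"),
    sibling_id = c(32L, NA, 43L, NA, NA, NA, 26L, 44L, NA, NA, 45L,
                   NA, NA, 28L, 33L, 38L, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  reg$negate_for_norms <- reg$subtest_id %in% c(26L, 32L, 39L, 40L)
  reg$score_units <- c("milliseconds", "count", "span", "count", "net-count",
                       "count", "milliseconds", "span", "count", "count",
                       "count", "seconds", "seconds", "count", "count",
                       "count", "count", "count", "count", "count", "count")
  reg
}

#' Battery registry
#'
#' The eight released test batteries, each a fixed ordered set of subtests
#' (5 to 11 of them) administered together. Order is administration order.
#'
#' @return A named list mapping battery id (as character) to an integer
#'   vector of subtest ids in administration order.
#' @examples
#' battery_registry()[["14"]]
#' battery_subtests(60)
#' @export
battery_registry <- function() {
  list(
    "14" = c(29L, 28L, 30L, 27L, 26L),
    "17" = c(29L, 28L, 30L, 27L, 32L, 31L),
    "25" = c(29L, 28L, 33L, 30L, 27L, 32L, 31L),
    "26" = c(36L, 39L, 40L, 29L, 28L, 33L, 30L, 27L, 32L, 38L, 37L),
    "32" = c(29L, 38L, 28L, 33L, 39L, 40L, 30L, 27L, 31L),
    "39" = c(29L, 38L, 28L, 33L, 39L, 40L, 30L, 31L),
    "50" = c(29L, 45L, 43L, 44L, 39L, 40L, 30L, 31L),
    "60" = c(54L, 52L, 53L, 55L, 51L)
  )
}

#' @rdname battery_registry
#' @param battery_id integer battery identifier.
#' @export
battery_subtests <- function(battery_id) {
  reg <- battery_registry()
  key <- as.character(as.integer(battery_id))
  if (!key %in% names(reg)) {
    stop("unknown battery_id: ", battery_id, call. = FALSE)
  }
  reg[[key]]
}

#' Look up one subtest definition
#'
#' @param subtest_id integer subtest identifier.
#' @return A one-row data.frame from \code{\link{subtest_registry}}.
#' @export
subtest_definition <- function(subtest_id) {
  reg <- subtest_registry()
  row <- reg[reg$subtest_id == as.integer(subtest_id), , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown subtest_id: ", subtest_id, call. = FALSE)
  }
  row
}

#' Education coding
#'
#' Self-reported educational attainment is coded with integer levels 1-8
#' plus 99 = "Other".
#'
#' @return A data.frame with columns \code{code} and \code{description}.
#' @export
education_levels <- function() {
  data.frame(
    code = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 99L),
    description = c("Some high school", "High school diploma/GED",
                    "Some college", "College degree", "Professional degree",
                    "Master's degree", "Ph.D.", "Associate's degree",
                    "Other"),
    stringsAsFactors = FALSE
  )
}

#' @rdname education_levels
#' @param code integer education code.
#' @export
education_description <- function(code) {
  lev <- education_levels()
  i <- match(as.integer(code), lev$code)
  if (anyNA(i[!is.na(code)])) {
    bad <- unique(code[!is.na(code) & is.na(i)])
    stop("unknown education code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lev$description[i]
}

# Subtests negated before normalization (performance decreases as the raw
# score increases: reaction times and completion times).
negated_subtests <- function() c(26L, 32L, 39L, 40L)
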