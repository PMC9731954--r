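# Demographic binning for the census-reweighted INT: six age bins crossed
# with three educational-attainment groups, K = 18 bins. All bin boundaries
# are inclusive. Education code 99 ("Other") and missing codes belong to no
# bin; such participants cannot enter the norm sample.

age_bin_breaks <- function() c(18, 30, 40, 50, 60, 70, 100)

#' Age and education bin labels
#' @return character vectors of the six age-bin and three education-group
#'   labels used in normative tables.
#' @export
age_bin_labels <- function() {
  c("18-29", "30-39", "40-49", "50-59", "60-69", "70-99")
}

#' @rdname age_bin_labels
#' @export
edu_bin_labels <- function() {
  c("high_school_or_less", "college_or_associate", "graduate_degree")
}

# education code -> group index (0-2); NA for 99/missing
edu_group <- function(education_level) {
  grp <- rep(NA_integer_, length(education_level))
  grp[education_level %in% c(1L, 2L)] <- 0L
  grp[education_level %in% c(3L, 4L, 8L)] <- 1L
  grp[education_level %in% c(5L, 6L, 7L)] <- 2L
  known <- is.na(education_level) | education_level %in% education_levels()$code
  if (any(!known)) {
    stop("unknown education code(s): ",
         paste(unique(education_level[!known]), collapse = ", "),
         call. = FALSE)
  }
  grp
}

#' Assign demographic bins
#'
#' Maps (age, education code) to the flat demographic bin index
#' \code{k = 3 * age_bin + edu_bin} over the K = 18 bins. Age bins:
#' 18-29, 30-39, 40-49, 50-59, 60-69, 70-99, bounds inclusive. Education
#' groups: \{some high school, high school diploma/GED\},
#' \{some college, college degree, associate's degree\},
#' \{professional degree, master's degree, Ph.D.\}. Education 99 ("Other")
#' or missing yields \code{NA} (no bin).
#'
#' @param age integer ages in years, within [18, 99].
#' @param education_level integer education codes (1-8, 99) or \code{NA}.
#' @return data.frame with columns \code{age_bin} (0-5), \code{edu_bin}
#'   (0-2) and \code{k} (0-17), \code{NA} where unbinnable.
#' @examples
#' assign_bin(29, 4)   # k = 1: youngest age bin, middle education group
#' assign_bin(70, 7)   # k = 17
#' assign_bin(40, 99)  # unbinnable
#' @export
assign_bin <- function(age, education_level) {
  if (any(!is.na(age) & (age < 18 | age > 99))) {
    stop("age outside [18, 99]", call. = FALSE)
  }
  ab <- as.integer(cut(age, breaks = age_bin_breaks(), right = FALSE,
                       labels = FALSE)) - 1L
  eb <- edu_group(education_level)
  k <- ifelse(is.na(ab) | is.na(eb), NA_integer_, 3L * ab + eb)
  data.frame(age_bin = ifelse(is.na(k), NA_integer_, ab),
             edu_bin = ifelse(is.na(k), NA_integer_, eb),
             k = k)
}

#' Reference demographic composition
#'
#' The reweighting target: proportions f*_k over the 18 age-by-education
#' bins, summing to one. Stands in for a joint census (ACS-style) table.
#'
#' @param proportions numeric vector of length 18, non-negative.
#' @param strict if \code{TRUE}, a vector not summing to 1 (within 1e-8) is
#'   an error; otherwise it is renormalized with a warning.
#' @return numeric vector of length 18 summing to 1, class
#'   \code{"reference_composition"}, named \code{k0}..\code{k17}.
#' @export
reference_composition <- function(proportions, strict = TRUE) {
  p <- as.numeric(proportions)
  if (length(p) != 18L) {
    stop("a reference composition has exactly 18 proportions", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("reference proportions must be finite and non-negative",
         call. = FALSE)
  }
  s <- sum(p)
  if (abs(s - 1) > 1e-8) {
    if (strict) {
      stop("reference proportions sum to ", format(s), ", not 1",
           call. = FALSE)
    }
    warning("reference proportions sum to ", format(s),
            "; renormalizing", call. = FALSE)
  }
  p <- p / s
  structure(stats::setNames(p, paste0("k", 0:17)),
            class = "reference_composition")
}

#' @rdname reference_composition
#' @export
uniform_reference <- function() reference_composition(rep(1 / 18, 18))

# Empirical composition of a set of bin indices k (0-17); NA bins dropped.
empirical_composition <- function(k) {
  k <- k[!is.na(k)]
  if (length(k) == 0L) stop("no binnable observations", call. = FALSE)
  reference_composition(tabulate(k + 1L, nbins = 18L) / length(k))
}
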