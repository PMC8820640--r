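#' Assign a five-year age group
#'
#' Maps single-year ages to the 0-based index of the five-year groups
#' 15-19 ... 45-49: `floor((age - 15) / 5)`.
#'
#' @param age Integer vector of ages in completed years, all in \[15, 49\].
#' @return Integer vector of group indices 0-6.
#' @examples
#' assign_age_group(c(15, 27, 49))
#' @export
assign_age_group <- function(age) {
  if (any(is.na(age)) || any(age < 15) || any(age > 49))
    stop("age must lie in [15, 49]")
  as.integer(floor((age - 15) / 5))
}

#' Label for a 0-based age-group index
#' @param group Integer vector of indices 0-6.
#' @return Character labels ("15-19", ...).
#' @export
age_group_label <- function(group) {
  if (any(is.na(group)) || any(group < 0) || any(group > 6))
    stop("group index must lie in 0..6")
  age_group_labels()[group + 1L]
}

#' Collapse a five-year age schedule into three broad bands
#'
#' Aggregates the seven five-year values into the bands 15-24, 25-34 and
#' 35-49 used for subgroup analyses, as the population-weighted mean of the
#' constituent five-year values.
#'
#' @param schedule Numeric length-7 schedule (rates, proportions, ...).
#' @param weights Numeric length-7 population weights (e.g. weighted women
#'   counts per group); must be non-negative with a positive sum within each
#'   band.
#' @return Named numeric vector of length 3 (`15-24`, `25-34`, `35-49`).
#' @examples
#' collapse_age_groups(c(10, 20, 1, 1, 1, 1, 1), c(1, 1, 1, 1, 1, 1, 1))
#' @export
collapse_age_groups <- function(schedule, weights) {
  stopifnot(length(schedule) == n_age_groups)
  if (missing(weights) || is.null(weights))
    stop("population weights are required to collapse age groups")
  stopifnot(length(weights) == n_age_groups, all(weights >= 0))
  bands <- list(`15-24` = 1:2, `25-34` = 3:4, `35-49` = 5:7)
  out <- vapply(bands, function(idx) {
    w <- weights[idx]
    if (sum(w) <= 0) return(NA_real_)
    sum(schedule[idx] * w) / sum(w)
  }, numeric(1))
  out
}
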