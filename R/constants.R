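#' Five-year age group labels
#'
#' The seven reproductive-age groups 15-19 through 45-49 used throughout the
#' package. All age schedules are named numeric vectors of length 7 in this
#' order.
#'
#' @return Character vector of length 7.
#' @export
age_group_labels <- function() {
  c("15-19", "20-24", "25-29", "30-34", "35-39", "40-44", "45-49")
}

n_age_groups <- 7L

#' Model constants for the proximate-determinants model
#'
#' Bundles every fixed input of the decomposition: the age-specific fecundity
#' adjustment `r(a)` applied to contraceptive prevalence, the natural
#' age-specific fecundity schedule (births per woman-year) used both as the
#' contraception-index weights and to predict age-specific fertility, total
#' fecundity `TF` (births per woman), the method use-effectiveness table, the
#' constants of the infecundability and births-averted formulas, the
#' small-cell suppression thresholds, and the significance heuristic for
#' comparing percent contributions.
#'
#' Defaults are the published inputs of the India 2015-16 application:
#' `r = (0.62, 0.81, 0.99, 1.08, 1.14, 1.26, 1.62)`,
#' `f_star = (0.484, 0.540, 0.531, 0.448, 0.290, 0.167, 0.109)`, `TF = 10.9`.
#' The effectiveness table is configurable; the defaults are standard
#' order-of-magnitude use-effectiveness values (complement of use-failure
#' rates) and should be overridden to match any specific published table.
#'
#' @param r Fecundity adjustment by age group (length 7).
#' @param f_star Natural fecundity rates, births per woman-year (length 7).
#' @param TF Total fecundity, births per woman.
#' @param e_table Named numeric: use-effectiveness in (0, 1] per method.
#' @param b_numerator,b_offset Constants of the births-averted-per-abortion
#'   formula `b = b_numerator / (b_offset + i)` with `i` in months.
#' @param ci_numerator,ci_offset Constants of the infecundability index
#'   `Ci = ci_numerator / (ci_offset + i)`.
#' @param suppress_women,flag_women Unweighted-women thresholds: below
#'   `suppress_women` all results are suppressed; between `suppress_women`
#'   and `flag_women` results are bracket-flagged.
#' @param suppress_births,flag_births Unweighted recent-birth thresholds
#'   governing the infecundability chain (Ci, TFRe, residual).
#' @param sig_threshold Percentage-point difference beyond which two percent
#'   contributions are deemed significantly different (strict inequality).
#' @param index_floor Lower clip applied to indices before taking logs in the
#'   percent-contribution decomposition.
#' @param asfr_window Length in months of the retrospective birth-history
#'   window used for fertility rates.
#'
#' @return An object of class `pd_constants` (a list).
#' @examples
#' cst <- pd_constants()
#' cst$TF
#' @export
pd_constants <- function(r = c(0.62, 0.81, 0.99, 1.08, 1.14, 1.26, 1.62),
                         f_star = c(0.484, 0.540, 0.531, 0.448, 0.290,
                                    0.167, 0.109),
                         TF = 10.9,
                         e_table = c(sterilization = 0.995, IUD = 0.985,
                                     injectable = 0.97, pill = 0.92,
                                     condom = 0.87, traditional = 0.75,
                                     other = 0.80),
                         b_numerator = 14, b_offset = 18.5,
                         ci_numerator = 20, ci_offset = 18.5,
                         suppress_women = 50, flag_women = 100,
                         suppress_births = 25, flag_births = 50,
                         sig_threshold = 5,
                         index_floor = 1e-6,
                         asfr_window = 36L) {
  stopifnot(length(r) == n_age_groups, all(r > 0),
            length(f_star) == n_age_groups, all(f_star > 0),
            TF > 0, length(e_table) >= 1,
            all(e_table > 0), all(e_table <= 1),
            b_numerator > 0, b_offset > 0,
            ci_numerator > 0, ci_offset > 0,
            suppress_women >= 0, flag_women >= suppress_women,
            suppress_births >= 0, flag_births >= suppress_births,
            sig_threshold >= 0, index_floor > 0, index_floor < 1,
            asfr_window > 0)
  names(r) <- names(f_star) <- age_group_labels()
  structure(list(r = r, f_star = f_star, TF = TF, e_table = e_table,
                 b_numerator = b_numerator, b_offset = b_offset,
                 ci_numerator = ci_numerator, ci_offset = ci_offset,
                 suppress_women = suppress_women, flag_women = flag_women,
                 suppress_births = suppress_births, flag_births = flag_births,
                 sig_threshold = sig_threshold, index_floor = index_floor,
                 asfr_window = as.integer(asfr_window)),
            class = "pd_constants")
}

#' Read model constants from a YAML file
#'
#' Any field absent from the file keeps its [pd_constants()] default, so a
#' config need only override what it changes.
#'
#' @param path Path to a YAML file whose top-level keys are arguments of
#'   [pd_constants()].
#' @return A `pd_constants` object.
#' @export
read_constants <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$e_table)) cfg$e_table <- unlist(cfg$e_table)
  known <- names(formals(pd_constants))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0)
    stop("unknown constants field(s): ", paste(bad, collapse = ", "))
  do.call(pd_constants, cfg)
}

#' @export
print.pd_constants <- function(x, ...) {
  cat("Proximate-determinants model constants\n")
  cat("  TF:", x$TF, "births per woman\n")
  cat("  r(a):     ", paste(formatC(x$r, format = "g"), collapse = " "), "\n")
  cat("  f*(a):    ", paste(formatC(x$f_star, format = "g"), collapse = " "),
      "\n")
  cat("  methods:  ", paste(names(x$e_table), collapse = ", "), "\n")
  cat("  suppression: <", x$suppress_women, "women; <", x$suppress_births,
      "recent births\n")
  invisible(x)
}
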