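# The four fertility-inhibiting indices of the proximate-determinants
# model: TFR = Cm * Cc * Ca * Ci * TF.

#' Index of marriage
#'
#' Age-specific index `Cm(a) = m(a)`, aggregated with marital-fertility
#' weights: `Cm = sum(m(a) * w(a))`, `w(a) = f_m(a) / sum(f_m)`. The 15-19
#' element of `f_m` is expected to carry the three-quarters imputation
#' applied by [marital_fertility()].
#'
#' @param m Proportions currently married by age group (length 7).
#' @param f_m Marital fertility rates by age group (length 7), used only as
#'   weights (scale-free).
#' @return List: `Cm`, `Cm_by_age`, `w`.
#' @examples
#' index_marriage(rep(1, 7), c(0.24, 0.32, 0.2, 0.1, 0.04, 0.015, 0.005))$Cm
#' @export
index_marriage <- function(m, f_m) {
  stopifnot(length(m) == n_age_groups, length(f_m) == n_age_groups)
  # groups absent from the stratum (both schedule entries NA, as in
  # age-band subpopulations) drop out; weights renormalize over the rest
  sel <- !is.na(m) & !is.na(f_m)
  if (!any(sel) || sum(f_m[sel]) <= 0)
    stop("marriage-index weights undefined: marital fertility missing or ",
         "all zero")
  w <- rep(0, n_age_groups)
  w[sel] <- f_m[sel] / sum(f_m[sel])
  list(Cm = sum(m[sel] * w[sel]),
       Cm_by_age = stats::setNames(m, age_group_labels()),
       w = stats::setNames(w, age_group_labels()))
}

#' Mean contraceptive use-effectiveness by age group
#'
#' `e(a) = sum_m e(m) * u(m, a) / u(a)`: the use-weighted mean of the
#' method-specific effectiveness values. Where `u(a) = 0`, `e(a)` is
#' undefined (`NA`) and unused, since the contraception index is 1 there.
#'
#' @param mix 7 x methods matrix of method prevalences among married women
#'   (as from [contraceptive_prevalence()]).
#' @param e_table Named effectiveness values covering every method in `mix`.
#' @param u Contraceptive prevalence by age group (row sums of `mix`).
#' @return Named numeric vector of length 7.
#' @export
method_effectiveness <- function(mix, e_table, u = rowSums(mix)) {
  missing_m <- setdiff(colnames(mix), names(e_table))
  if (length(missing_m) > 0)
    stop("no effectiveness value for method(s): ",
         paste(missing_m, collapse = ", "))
  num <- as.vector(mix %*% e_table[colnames(mix)])
  e <- ifelse(!is.na(u) & u > 0, num / u, NA_real_)
  stats::setNames(e, age_group_labels())
}

#' Index of contraception
#'
#' Age-specific `Cc(a) = 1 - r(a) * (u(a) - o(a)) * e(a)` (1 where nobody
#' uses contraception), aggregated with natural-fertility weights
#' `w(a) = f_n(a) / sum(f_n)`. By default `f_n` is the natural fecundity
#' schedule `f_star` of the model constants. Age-specific values are
#' clipped to \[0, 1\] with a warning when clipping occurs.
#'
#' @param u Contraceptive prevalence by age group.
#' @param o Use-infecundability overlap by age group; `o(a) <= u(a)`.
#' @param e Mean use-effectiveness by age group ([method_effectiveness()]).
#' @param constants A `pd_constants` object (supplies `r` and the default
#'   weights).
#' @param f_n Optional user-supplied natural-fertility weight schedule.
#' @return List: `Cc`, `Cc_by_age`, `w`.
#' @export
index_contraception <- function(u, o, e, constants = pd_constants(),
                                f_n = NULL) {
  stopifnot(length(u) == n_age_groups, length(o) == n_age_groups,
            length(e) == n_age_groups)
  if (any(!is.na(u) & !is.na(o) & o > u + 1e-12))
    stop("overlap proportion exceeds contraceptive prevalence")
  # groups with no married women (u missing) drop out of the aggregate;
  # weights renormalize over the remaining groups
  sel <- !is.na(u)
  if (!any(sel)) stop("contraceptive prevalence missing in every group")
  o <- ifelse(is.na(o), 0, o)
  cc <- rep(NA_real_, n_age_groups)
  cc[sel] <- ifelse(u[sel] > 0,
                    1 - constants$r[sel] * (u[sel] - o[sel]) * e[sel], 1)
  if (any(is.na(cc[sel])))
    stop("effectiveness undefined in a group with non-zero prevalence")
  if (any(cc[sel] < 0 | cc[sel] > 1)) {
    warning("age-specific contraception index clipped to [0, 1]")
    cc[sel] <- pmin(pmax(cc[sel], 0), 1)
  }
  fn <- if (is.null(f_n)) constants$f_star else f_n
  stopifnot(length(fn) == n_age_groups, sum(fn[sel]) > 0)
  w <- rep(0, n_age_groups)
  w[sel] <- fn[sel] / sum(fn[sel])
  list(Cc = sum(cc[sel] * w[sel]),
       Cc_by_age = stats::setNames(cc, age_group_labels()),
       w = stats::setNames(w, age_group_labels()))
}

#' Index of postpartum infecundability
#'
#' `Ci = 20 / (18.5 + i)` with `i` the mean infecundability duration in
#' months, capped at 1 (durations at or below 1.5 months imply no
#' inhibition).
#'
#' @param i_bar Mean infecundability duration, months.
#' @param constants A `pd_constants` object.
#' @return Scalar index in (0, 1\], or `NA` if `i_bar` is missing.
#' @examples
#' index_infecundability(11.5)  # 20/30
#' @export
index_infecundability <- function(i_bar, constants = pd_constants()) {
  if (is.na(i_bar)) return(NA_real_)
  stopifnot(i_bar >= 0)
  min(1, constants$ci_numerator / (constants$ci_offset + i_bar))
}

#' Births averted per induced abortion
#'
#' `b = 14 / (18.5 + i)`: an abortion averts less than one birth because a
#' birth would have been followed by a period of postpartum
#' infecundability, and the effect is tied to contraceptive practice after
#' the abortion.
#'
#' @param i_bar Mean infecundability duration, months.
#' @param constants A `pd_constants` object.
#' @return Scalar in (0, 14/18.5\].
#' @examples
#' births_averted_per_abortion(9.5)  # 0.5
#' @export
births_averted_per_abortion <- function(i_bar, constants = pd_constants()) {
  if (is.na(i_bar)) return(NA_real_)
  stopifnot(i_bar >= 0)
  constants$b_numerator / (constants$b_offset + i_bar)
}

#' Allocate an aggregate abortion count to subgroups by unmet need
#'
#' Splits a total abortion count across categories in proportion to each
#' category's share of women with unmet need for contraception, then forms
#' per-category abortion rates. The allocation conserves the total exactly.
#'
#' @param total_abortions Total abortions in the reference population.
#' @param unmet_counts Named weighted counts of unmet-need women per
#'   category.
#' @param women Named weighted women counts per category (same names).
#' @return List: `abortions`, `rates` (abortions per woman; `NA` where a
#'   category has no women), `shares`.
#' @export
allocate_abortions <- function(total_abortions, unmet_counts, women) {
  stopifnot(total_abortions >= 0, all(unmet_counts >= 0),
            length(unmet_counts) == length(women))
  if (sum(unmet_counts) <= 0)
    stop("unmet-need counts are all zero: allocation impossible")
  shares <- unmet_counts / sum(unmet_counts)
  abortions <- total_abortions * shares
  rates <- ifelse(women > 0, abortions / women, NA_real_)
  if (any(women <= 0 & abortions > 0))
    warning("abortions allocated to a category with no women; rate ",
            "undefined there")
  list(abortions = abortions, rates = rates, shares = shares)
}

#' Rescale national age-specific abortion rates to a state
#'
#' The unmet-need allocation overstates abortion at the oldest ages, so
#' state age-specific rates are taken as the national age schedule rescaled
#' by the states overall rate. The default mode multiplies by
#' `R_state / R_national`, which preserves the state's overall rate; the
#' `"literal"` mode multiplies by `R_national / R_state` (the inverse
#' convention, retained for comparison).
#'
#' @param national_age_rates National abortion rates by age group.
#' @param R_state,R_national Overall abortion rates (same units) for the
#'   state and the nation; both must be positive.
#' @param mode `"preserve_state_total"` (default) or `"literal"`.
#' @return Named numeric vector of length 7.
#' @export
adjust_state_age_rates <- function(national_age_rates, R_state, R_national,
                                   mode = c("preserve_state_total",
                                            "literal")) {
  mode <- match.arg(mode)
  stopifnot(length(national_age_rates) == n_age_groups,
            all(national_age_rates >= 0))
  if (R_national <= 0) stop("national abortion rate must be positive")
  if (R_state <= 0) stop("state abortion rate must be positive")
  k <- if (mode == "preserve_state_total") R_state / R_national
       else R_national / R_state
  stats::setNames(national_age_rates * k, age_group_labels())
}

#' Total abortion rate
#'
#' `TAR = 5 * sum(ab(a))` with `ab` in abortions per woman-year: abortions
#' per woman over the reproductive span at current age-specific rates.
#'
#' @param ab Abortion rates by age group, abortions per woman-year.
#' @return Scalar TAR.
#' @examples
#' total_abortion_rate(rep(0.047, 7))  # 35 * 0.047
#' @export
total_abortion_rate <- function(ab) {
  stopifnot(length(ab) == n_age_groups, all(ab >= 0))
  5 * sum(ab)
}

#' Index of induced abortion (aggregate formula)
#'
#' `Ca = TFR / (TFR + b * TAR)`. The aggregate form is used throughout; the
#' age-specific aggregation path is deliberately not taken.
#'
#' @param TFRa Actual total fertility rate, births per woman; must be
#'   positive.
#' @param TAR Total abortion rate, abortions per woman.
#' @param b Births averted per abortion ([births_averted_per_abortion()]).
#' @return Scalar index in (0, 1\], or `NA` if any input is missing.
#' @export
index_abortion <- function(TFRa, TAR, b) {
  if (any(is.na(c(TFRa, TAR, b)))) return(NA_real_)
  if (TFRa <= 0) stop("index of abortion undefined for non-positive TFR")
  stopifnot(TAR >= 0, b >= 0)
  TFRa / (TFRa + b * TAR)
}

#' Compute the four indices for one stratum
#'
#' Assembles the marriage, contraception, abortion and infecundability
#' indices from a stratum's [rate_bundle()] and its total abortion rate.
#'
#' @param rates A `pd_rates` object.
#' @param TAR Total abortion rate for the stratum's reference population.
#' @param constants A `pd_constants` object.
#' @param f_n Optional natural-fertility weights for the contraception
#'   index.
#' @return An object of class `pd_indices`: `Cm`, `Cc`, `Ca`, `Ci`, `b`,
#'   `TAR`, with age-specific `Cm_by_age`, `Cc_by_age`.
#' @export
compute_indices <- function(rates, TAR, constants = pd_constants(),
                            f_n = NULL) {
  mar <- index_marriage(rates$m, rates$f_m)
  e <- method_effectiveness(rates$mix, constants$e_table, rates$u)
  con <- index_contraception(rates$u, rates$o, e, constants, f_n)
  Ci <- index_infecundability(rates$i_bar, constants)
  b <- births_averted_per_abortion(rates$i_bar, constants)
  Ca <- index_abortion(rates$TFRa, TAR, b)
  structure(list(Cm = mar$Cm, Cc = con$Cc, Ca = Ca, Ci = Ci,
                 b = b, TAR = TAR,
                 Cm_by_age = mar$Cm_by_age, Cc_by_age = con$Cc_by_age,
                 e = e), class = "pd_indices")
}
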