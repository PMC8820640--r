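# Survey-weighted rates consumed by the proximate-determinants indices.
# All estimates use sampling weights; all suppression decisions downstream
# use unweighted counts.

.wmean <- function(x, w) {
  if (length(x) == 0 || sum(w) <= 0) return(NA_real_)
  sum(x * w) / sum(w)
}

# weighted mean of `x` by age group over the supplied records
.by_group <- function(records, x, w = records$weight, subset = TRUE) {
  g <- assign_age_group(records$age) + 1L
  out <- rep(NA_real_, n_age_groups)
  for (a in seq_len(n_age_groups)) {
    sel <- subset & g == a
    out[a] <- .wmean(x[sel], w[sel])
  }
  names(out) <- age_group_labels()
  out
}

.group_counts <- function(records, subset = TRUE) {
  g <- assign_age_group(records$age) + 1L
  out <- integer(n_age_groups)
  for (a in seq_len(n_age_groups)) out[a] <- sum(subset & g == a)
  names(out) <- age_group_labels()
  out
}

#' Proportion currently married by age group
#'
#' Weighted share of currently married women among all women, per five-year
#' age group. Empty groups yield `NA`.
#'
#' @param records Microdata data frame.
#' @return Named numeric vector of length 7.
#' @export
proportion_married <- function(records) {
  .by_group(records, as.numeric(records$currently_married))
}

# Weighted exposure (woman-years) and births by age group over the
# retrospective window, classified by age at the time.
.exposure_births <- function(records, window = 36L) {
  n <- nrow(records)
  exposure <- stats::setNames(numeric(n_age_groups), age_group_labels())
  births_w <- exposure
  births_n <- stats::setNames(integer(n_age_groups), age_group_labels())
  if (n == 0) return(list(exposure = exposure, births_w = births_w,
                          births_n = births_n))
  g_at <- outer(records$age, seq_len(window), .group_at_month)
  wmat <- matrix(records$weight, n, window)
  ok <- !is.na(g_at)
  exp_tab <- tapply(wmat[ok] / 12, g_at[ok], sum)
  exposure[as.integer(names(exp_tab))] <- exp_tab
  bml <- .birth_month_list(records)
  nb <- lengths(bml)
  if (any(nb > 0)) {
    who <- rep(seq_len(n), nb)
    t_b <- unlist(bml, use.names = FALSE)
    keep <- t_b <= window
    who <- who[keep]; t_b <- t_b[keep]
    gb <- .group_at_month(records$age[who], t_b)
    valid <- !is.na(gb)
    bw <- tapply(records$weight[who][valid], gb[valid], sum)
    births_w[as.integer(names(bw))] <- bw
    bn <- table(gb[valid])
    births_n[as.integer(names(bn))] <- as.integer(bn)
  }
  list(exposure = exposure, births_w = births_w, births_n = births_n)
}

#' Age-specific and total fertility rates
#'
#' DHS-style retrospective estimator: births in the `window` months before
#' interview, classified by the mother's age group at the birth, divided by
#' weighted woman-years of exposure in that group within the window
#' (exposure below exact age 15 excluded). `TFRa = 5 * sum(f)`.
#'
#' @param records Microdata data frame.
#' @param window Window length in months (default 36).
#' @return List: `f` (births per woman-year, length 7), `TFRa`,
#'   `exposure` (woman-years), `births_n` (unweighted births per group).
#' @export
asfr <- function(records, window = 36L) {
  eb <- .exposure_births(records, window)
  f <- ifelse(eb$exposure > 0, eb$births_w / eb$exposure, NA_real_)
  names(f) <- age_group_labels()
  # groups without exposure (e.g. age-band subpopulations) drop out of the
  # total rather than voiding it
  list(f = f, TFRa = 5 * sum(f, na.rm = TRUE), exposure = eb$exposure,
       births_n = eb$births_n)
}

#' Marital age-specific fertility rates
#'
#' As [asfr()] but restricted to currently married women, with the standard
#' guard against sparse teenage marriage: the 15-19 rate is always replaced
#' by three-quarters of the 20-24 rate.
#'
#' @param records Microdata data frame.
#' @param window Window length in months.
#' @return Named numeric vector of length 7 (births per married woman-year).
#' @export
marital_fertility <- function(records, window = 36L) {
  eb <- .exposure_births(records[records$currently_married, , drop = FALSE],
                         window)
  f_m <- ifelse(eb$exposure > 0, eb$births_w / eb$exposure, NA_real_)
  names(f_m) <- age_group_labels()
  if (!is.na(f_m[2])) {
    f_m[1] <- 0.75 * f_m[2]
  } else if (!is.na(f_m[1])) {
    # cannot stabilize the sparse 15-19 rate: drop it rather than keep a
    # noisy observed value
    warning("no married women aged 20-24: cannot impute the 15-19 marital ",
            "fertility rate")
    f_m[1] <- NA_real_
  }
  f_m
}

#' Contraceptive prevalence and method mix by age group
#'
#' Weighted share of currently married women using any method (`u`), and
#' the per-age method prevalences `u(m, a)` with `sum_m u(m, a) = u(a)`.
#'
#' @param records Microdata data frame.
#' @param methods Method universe (columns of the mix matrix).
#' @return List: `u` (length 7), `mix` (7 x methods matrix of prevalences
#'   among married women).
#' @export
contraceptive_prevalence <- function(records,
                                     methods = setdiff(
                                       microdata_schema()$methods, "none")) {
  married <- records$currently_married
  u <- .by_group(records, as.numeric(records$method != "none"),
                 subset = married)
  mix <- sapply(methods, function(m)
    .by_group(records, as.numeric(records$method == m), subset = married))
  mix <- matrix(mix, nrow = n_age_groups,
                dimnames = list(age_group_labels(), methods))
  list(u = u, mix = mix)
}

#' Overlap of contraceptive use with infecundability
#'
#' Per-record overlap indicator: the woman is married, currently using a
#' method, and either had a non-contraceptive hysterectomy in the window or
#' has a recent birth with a still-ongoing postpartum factor (the longest of
#' full breastfeeding, amenorrhea and abstinence reaching the months elapsed
#' since the most recent birth). Returns the weighted share of married women
#' with the indicator set, per age group; `o(a) <= u(a)` by construction.
#'
#' @param records Microdata data frame.
#' @return Named numeric vector of length 7.
#' @export
overlap_proportion <- function(records) {
  last_birth <- months_since_last_birth(records)
  ongoing <- !is.na(last_birth) &
    pmax(records$bf_months, records$amen_months, records$abst_months) >=
      last_birth
  ov <- records$currently_married & records$method != "none" &
    (records$hysterectomy | ongoing)
  .by_group(records, as.numeric(ov), subset = records$currently_married)
}

#' Mean duration of postpartum infecundability
#'
#' For each eligible woman — a birth in the window, or a non-contraceptive
#' hysterectomy in the window — the duration is the longest of full
#' breastfeeding, amenorrhea, postpartum abstinence and (if flagged) months
#' since the hysterectomy. Returns the weighted mean over eligible women,
#' overall and by age group, with the unweighted eligible and recent-birth
#' counts used by the suppression rules.
#'
#' @param records Microdata data frame.
#' @return List: `i_bar` (months), `i_by_age` (length 7), `n_eligible`,
#'   `n_recent_births` (unweighted counts).
#' @export
infecundability_duration <- function(records) {
  last_birth <- months_since_last_birth(records)
  recent <- !is.na(last_birth)
  eligible <- recent | records$hysterectomy
  dur <- pmax(records$bf_months, records$amen_months, records$abst_months,
              ifelse(records$hysterectomy & !is.na(records$hyst_months_ago),
                     records$hyst_months_ago, 0))
  i_by_age <- .by_group(records, dur, subset = eligible)
  sel <- which(eligible)
  i_bar <- .wmean(dur[sel], records$weight[sel])
  list(i_bar = i_bar, i_by_age = i_by_age,
       n_eligible = sum(eligible), n_recent_births = sum(recent))
}

#' Distribution of unmet need across the categories of a stratifier
#'
#' Weighted count of women with unmet need per category and the resulting
#' shares (summing to 1), used to allocate aggregate abortion counts to
#' subgroups.
#'
#' @param records Microdata data frame.
#' @param stratifier Column name (e.g. `"education"`), or `"age_band"` for
#'   the three broad bands 15-24 / 25-34 / 35-49.
#' @return List: `counts` (weighted), `shares`, `women` (weighted women per
#'   category).
#' @export
unmet_need_distribution <- function(records, stratifier) {
  cat <- .stratum_categories(records, stratifier)
  counts <- tapply(records$weight * as.numeric(records$unmet_need), cat,
                   sum, default = 0)
  women <- tapply(records$weight, cat, sum, default = 0)
  total <- sum(counts)
  if (total <= 0)
    stop("no women with unmet need: abortion allocation impossible")
  list(counts = counts, shares = counts / total, women = women)
}

# category labels for a stratifier, with age_band derived from age
.stratum_categories <- function(records, stratifier) {
  if (stratifier == "age_band") {
    bands <- c("15-24", "25-34", "35-49")
    factor(bands[findInterval(records$age, c(15, 25, 35))], levels = bands)
  } else {
    if (!stratifier %in% names(records))
      stop("unknown stratifier: ", stratifier)
    factor(records[[stratifier]])
  }
}

#' All survey rates needed by the four indices
#'
#' Convenience wrapper computing every input of [compute_indices()] for one
#' stratum's records.
#'
#' @param records Microdata data frame.
#' @param window ASFR window in months.
#' @return An object of class `pd_rates`: proportions married `m`, fertility
#'   `f` and `TFRa`, marital fertility `f_m`, contraceptive prevalence `u`
#'   and method `mix`, overlap `o`, infecundability `i_bar` / `i_by_age`,
#'   and the unweighted counts `n_women`, `n_by_group`, `n_recent_births`,
#'   plus total weighted women `women_w`.
#' @export
rate_bundle <- function(records, window = 36L) {
  fert <- asfr(records, window)
  cp <- contraceptive_prevalence(records)
  inf <- infecundability_duration(records)
  structure(list(
    m = proportion_married(records),
    f = fert$f, TFRa = fert$TFRa,
    f_m = marital_fertility(records, window),
    u = cp$u, mix = cp$mix,
    o = overlap_proportion(records),
    i_bar = inf$i_bar, i_by_age = inf$i_by_age,
    n_women = nrow(records),
    n_by_group = .group_counts(records),
    n_recent_births = inf$n_recent_births,
    women_w = sum(records$weight)), class = "pd_rates")
}
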