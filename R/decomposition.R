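# Predicted fertility, residuals, percent contributions and model-fit
# diagnostics.

#' Predicted total fertility rate
#'
#' `TFRe = Cm * Cc * Ca * Ci * TF`.
#'
#' @param Cm,Cc,Ca,Ci The four indices, each in \[0, 1\]; alternatively
#'   pass a `pd_indices` object as `Cm`.
#' @param TF Total fecundity, births per woman.
#' @return Births per woman; `NA` if any index is missing.
#' @examples
#' predicted_tfr(0.59, 0.70, 0.71, 0.78, TF = 10.9)
#' @export
predicted_tfr <- function(Cm, Cc, Ca, Ci, TF = pd_constants()$TF) {
  if (inherits(Cm, "pd_indices")) {
    ix <- Cm; Cm <- ix$Cm; Cc <- ix$Cc; Ca <- ix$Ca; Ci <- ix$Ci
  }
  if (any(is.na(c(Cm, Cc, Ca, Ci)))) return(NA_real_)
  Cm * Cc * Ca * Ci * TF
}

#' Predicted age-specific fertility rates
#'
#' `ASFRe(a) = Cm(a) * Cc(a) * Ca * Ci * f_star(a)`: the age-specific
#' marriage and contraception indices combined with the aggregate abortion
#' and infecundability indices and the natural fecundity schedule.
#'
#' @param Cm_by_age,Cc_by_age Age-specific indices (length 7).
#' @param Ca,Ci Aggregate indices.
#' @param f_star Natural fecundity rates, births per woman-year (length 7).
#' @return Named numeric vector of length 7, births per woman-year.
#' @export
predicted_asfr <- function(Cm_by_age, Cc_by_age, Ca, Ci,
                           f_star = pd_constants()$f_star) {
  stopifnot(length(Cm_by_age) == n_age_groups,
            length(Cc_by_age) == n_age_groups,
            length(f_star) == n_age_groups)
  stats::setNames(Cm_by_age * Cc_by_age * Ca * Ci * f_star,
                  age_group_labels())
}

#' Percent contribution of each determinant to fertility reduction
#'
#' Decomposes the reduction from total fecundity to the TFR on the log
#' scale: `share_k = 100 * ln(C_k) / (ln(Cm)+ln(Cc)+ln(Ca)+ln(Ci))`. The
#' four shares sum to 100. Indices are clipped to `[index_floor, 1]` before
#' the logs (a zero index would make its log-share undefined); if all four
#' indices equal 1 there is no reduction to attribute and the shares are
#' `NA`.
#'
#' @param Cm,Cc,Ca,Ci The four indices; alternatively a `pd_indices` object
#'   as `Cm`.
#' @param index_floor Lower clip applied before taking logs.
#' @return Named numeric vector `c(marriage=, contraception=, abortion=,
#'   infecundability=)` in percent.
#' @examples
#' percent_contributions(0.8, 0.8, 0.8, 0.8)  # 25 each
#' @export
percent_contributions <- function(Cm, Cc, Ca, Ci,
                                  index_floor = pd_constants()$index_floor) {
  if (inherits(Cm, "pd_indices")) {
    ix <- Cm; Cm <- ix$Cm; Cc <- ix$Cc; Ca <- ix$Ca; Ci <- ix$Ci
  }
  out_names <- c("marriage", "contraception", "abortion", "infecundability")
  idx <- c(Cm, Cc, Ca, Ci)
  if (any(is.na(idx)))
    return(stats::setNames(rep(NA_real_, 4), out_names))
  stopifnot(all(idx <= 1 + 1e-12))
  clipped <- pmin(pmax(idx, index_floor), 1)
  if (any(clipped != idx))
    warning("index clipped to [", index_floor, ", 1] before log ",
            "decomposition")
  lg <- log(clipped)
  if (sum(lg) == 0) {
    warning("all indices equal 1: no fertility reduction to decompose")
    return(stats::setNames(rep(NA_real_, 4), out_names))
  }
  stats::setNames(100 * lg / sum(lg), out_names)
}

#' Residual between predicted and actual TFR
#'
#' `TFRe - TFRa` (signed): the fertility unexplained, or over-explained, by
#' the four modeled determinants.
#'
#' @param TFRe Predicted TFR.
#' @param TFRa Actual TFR.
#' @return Births per woman, or `NA` if either input is missing.
#' @export
tfr_residual <- function(TFRe, TFRa) {
  if (any(is.na(c(TFRe, TFRa)))) return(NA_real_)
  TFRe - TFRa
}

#' Fit of actual against predicted fertility
#'
#' Ordinary least squares of actual on predicted values across strata (or
#' age groups) and the resulting coefficient of determination, the
#' model-fit diagnostic of the decomposition.
#'
#' @param actual,predicted Numeric vectors of equal length (>= 3 pairs after
#'   removing missing values).
#' @return List: `r_squared`, `fit` (the `lm` object), `n`.
#' @export
fit_actual_vs_predicted <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  ok <- !is.na(actual) & !is.na(predicted)
  actual <- actual[ok]; predicted <- predicted[ok]
  if (length(actual) < 3)
    stop("at least 3 complete (actual, predicted) pairs are required")
  if (stats::var(predicted) == 0)
    stop("predicted values are constant: R-squared undefined")
  fit <- stats::lm(actual ~ predicted)
  list(r_squared = summary(fit)$r.squared, fit = fit, n = length(actual))
}

#' Flag a significant difference between two percent contributions
#'
#' Two shares are deemed significantly different when they differ by
#' strictly more than the threshold (default five percentage points, i.e. a
#' 20 percent change when determinants contribute 25 percent each).
#'
#' @param share_a,share_b Percent contributions.
#' @param threshold Percentage points; strict inequality.
#' @return Logical.
#' @examples
#' significance_flag(36.0, 30.9)  # TRUE (difference 5.1)
#' significance_flag(36.0, 31.0)  # FALSE (exactly 5)
#' @export
significance_flag <- function(share_a, share_b,
                              threshold = pd_constants()$sig_threshold) {
  if (any(is.na(c(share_a, share_b)))) return(NA)
  abs(share_a - share_b) > threshold
}
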