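# Stratified runs, abortion-rate resolution and small-cell suppression.

#' Small-cell suppression status
#'
#' Applies the reporting thresholds: below 50 unweighted women the whole
#' row is suppressed; 50-100 women the row is bracket-flagged; below 25
#' unweighted recent births the infecundability chain (Ci, TFRe, residual)
#' is suppressed; 25-50 recent births that chain is bracket-flagged.
#' Suppression is a pure function of the unweighted counts.
#'
#' @param n_women Unweighted women in the stratum.
#' @param n_recent_births Unweighted women with a birth in the window.
#' @param constants A `pd_constants` object (thresholds).
#' @return List of logicals: `suppress_all`, `flag_all`,
#'   `suppress_ci_chain`, `flag_ci_chain`.
#' @examples
#' apply_suppression(49, 40)$suppress_all   # TRUE
#' apply_suppression(500, 24)$suppress_ci_chain  # TRUE
#' @export
apply_suppression <- function(n_women, n_recent_births,
                              constants = pd_constants()) {
  stopifnot(n_women >= 0, n_recent_births >= 0)
  suppress_all <- n_women < constants$suppress_women
  flag_all <- !suppress_all & n_women <= constants$flag_women
  suppress_ci <- n_recent_births < constants$suppress_births
  flag_ci <- !suppress_ci & n_recent_births <= constants$flag_births
  list(suppress_all = suppress_all, flag_all = flag_all,
       suppress_ci_chain = suppress_all | suppress_ci,
       flag_ci_chain = flag_all | flag_ci)
}

#' Abortion-rate inputs
#'
#' Overall abortion rates per 1000 women 15-49 for the national reference
#' population and, optionally, for regions and individual states. For a
#' state stratum the resolution order is state rate, then its region's
#' rate, then the national rate.
#'
#' @param national_rate National abortions per 1000 women 15-49 per year.
#' @param state_rates Named vector of state rates (optional).
#' @param region_rates Named vector of region rates (optional).
#' @param national_age_rates Optional length-7 national age-specific
#'   schedule (per 1000 women per year) for [adjust_state_age_rates()].
#' @return An object of class `pd_abortion`.
#' @export
abortion_inputs <- function(national_rate, state_rates = NULL,
                            region_rates = NULL,
                            national_age_rates = NULL) {
  stopifnot(national_rate >= 0)
  if (!is.null(state_rates)) stopifnot(all(state_rates >= 0))
  if (!is.null(region_rates)) stopifnot(all(region_rates >= 0))
  if (!is.null(national_age_rates))
    stopifnot(length(national_age_rates) == n_age_groups,
              all(national_age_rates >= 0))
  structure(list(national_rate = national_rate, state_rates = state_rates,
                 region_rates = region_rates,
                 national_age_rates = national_age_rates),
            class = "pd_abortion")
}

#' Read abortion-rate inputs from delimited text
#'
#' Expects columns `level` (`national`, `region` or `state`), `name`, and
#' `rate_per_1000`.
#'
#' @param path CSV path.
#' @return A `pd_abortion` object.
#' @export
read_abortion_inputs <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("level", "name", "rate_per_1000") %in% names(d)))
  pick <- function(lv) {
    s <- d[d$level == lv, ]
    if (nrow(s) == 0) NULL else stats::setNames(s$rate_per_1000, s$name)
  }
  nat <- pick("national")
  if (is.null(nat)) stop("abortion inputs must include a national rate")
  abortion_inputs(unname(nat[1]), state_rates = pick("state"),
                  region_rates = pick("region"))
}

#' Resolve the abortion rate for a state
#'
#' @param abortion A `pd_abortion` object.
#' @param state,region State name and its region.
#' @return List: `rate` (per 1000 women 15-49), `source` (`"state"`,
#'   `"region"` or `"national"`).
#' @export
resolve_abortion_rate <- function(abortion, state, region = NA) {
  if (!is.null(abortion$state_rates) && state %in%
        names(abortion$state_rates))
    return(list(rate = unname(abortion$state_rates[state]),
                source = "state"))
  if (!is.null(abortion$region_rates) && !is.na(region) &&
        region %in% names(abortion$region_rates))
    return(list(rate = unname(abortion$region_rates[region]),
                source = "region"))
  list(rate = abortion$national_rate, source = "national")
}

#' Total abortion rate implied by a flat overall rate
#'
#' Converts an overall annual rate per 1000 women 15-49 to a total abortion
#' rate under a flat age schedule: `TAR = 35 * rate / 1000`.
#'
#' @param rate_per_1000 Abortions per 1000 women 15-49 per year.
#' @return Abortions per woman over the reproductive span.
#' @examples
#' tar_from_overall_rate(47)  # 1.645
#' @export
tar_from_overall_rate <- function(rate_per_1000) {
  stopifnot(rate_per_1000 >= 0)
  total_abortion_rate(rep(rate_per_1000 / 1000, n_age_groups))
}

# One stratum's full decomposition, with suppression applied. Returns a
# one-row data frame, or NULL when the computation is impossible.
.decompose_stratum <- function(records, TAR, constants, stratifier,
                               category, abortion_source, window = 36L) {
  if (nrow(records) == 0) return(NULL)
  rates <- rate_bundle(records, window)
  sup <- apply_suppression(rates$n_women, rates$n_recent_births, constants)
  row <- data.frame(stratifier = stratifier, category = category,
                    n_women = rates$n_women,
                    n_recent_births = rates$n_recent_births,
                    women_weighted = rates$women_w,
                    Cm = NA_real_, Cc = NA_real_, Ca = NA_real_,
                    Ci = NA_real_, TFRa = NA_real_, TFRe = NA_real_,
                    residual = NA_real_,
                    share_marriage = NA_real_,
                    share_contraception = NA_real_,
                    share_abortion = NA_real_,
                    share_infecundability = NA_real_,
                    flag_all = sup$flag_all,
                    flag_ci_chain = sup$flag_ci_chain,
                    suppressed = sup$suppress_all,
                    suppressed_ci_chain = sup$suppress_ci_chain,
                    abortion_source = abortion_source,
                    stringsAsFactors = FALSE)
  if (sup$suppress_all) return(row)
  ix <- tryCatch(compute_indices(rates, TAR, constants),
                 error = function(e) {
                   message("stratum ", stratifier, "=", category,
                           " skipped: ", conditionMessage(e))
                   NULL
                 })
  if (is.null(ix)) return(NULL)
  row$Cm <- ix$Cm; row$Cc <- ix$Cc; row$Ca <- ix$Ca
  row$TFRa <- rates$TFRa
  if (!sup$suppress_ci_chain) {
    row$Ci <- ix$Ci
    row$TFRe <- predicted_tfr(ix, TF = constants$TF)
    row$residual <- tfr_residual(row$TFRe, row$TFRa)
    sh <- percent_contributions(ix, index_floor = constants$index_floor)
    row$share_marriage <- sh[["marriage"]]
    row$share_contraception <- sh[["contraception"]]
    row$share_abortion <- sh[["abortion"]]
    row$share_infecundability <- sh[["infecundability"]]
  }
  row
}

#' Run the stratified proximate-determinants decomposition
#'
#' Computes the four indices, predicted fertility, residual and percent
#' contributions for the whole population and for each requested
#' stratification. State strata use the resolved overall abortion rate
#' (state, then region, then national); all other stratifiers receive
#' abortion counts allocated across categories in proportion to unmet need
#' for contraception within the reference population.
#'
#' @param records Microdata data frame (all strata pooled).
#' @param abortion A `pd_abortion` object, or a single national rate per
#'   1000 women 15-49.
#' @param constants A `pd_constants` object.
#' @param strata Character vector of stratifiers to run marginally, drawn
#'   from `state`, `region`, `residence`, `education`, `wealth`, `caste`,
#'   `age_band`.
#' @param omit_categories Named list: categories (per stratifier) to keep in
#'   the national aggregate but omit as output rows (e.g. territories too
#'   small to report).
#' @param window ASFR window in months.
#' @return Data frame with one row per stratum (the national row first);
#'   suppressed quantities are `NA` with their status in the `suppressed*`
#'   and `flag*` columns.
#' @export
run_decomposition <- function(records, abortion,
                              constants = pd_constants(),
                              strata = NULL,
                              omit_categories = list(),
                              window = 36L) {
  if (!inherits(abortion, "pd_abortion"))
    abortion <- abortion_inputs(abortion)
  known <- c("state", "region", "residence", "education", "wealth",
             "caste", "age_band")
  if (!all(strata %in% known))
    stop("unknown stratifier(s): ",
         paste(setdiff(strata, known), collapse = ", "))

  rows <- list()
  nat_tar <- tar_from_overall_rate(abortion$national_rate)
  rows[[1]] <- .decompose_stratum(records, nat_tar, constants,
                                  "national", "national", "national",
                                  window)
  if (is.null(rows[[1]])) stop("national decomposition failed")

  total_abortions <- abortion$national_rate / 1000 * sum(records$weight)

  for (st in strata) {
    cats <- .stratum_categories(records, st)
    drop <- omit_categories[[st]]
    if (st %in% c("state", "region")) {
      for (cat in setdiff(levels(cats), drop)) {
        sub <- records[cats == cat, , drop = FALSE]
        if (nrow(sub) == 0) { message("empty stratum ", st, "=", cat,
                                      " omitted"); next }
        if (st == "state") {
          reg <- names(sort(table(sub$region), decreasing = TRUE))[1]
          res <- resolve_abortion_rate(abortion, cat, reg)
        } else {
          res <- resolve_abortion_rate(abortion, NA_character_, cat)
        }
        rows[[length(rows) + 1]] <-
          .decompose_stratum(sub, tar_from_overall_rate(res$rate),
                             constants, st, cat, res$source, window)
      }
    } else {
      und <- unmet_need_distribution(records, st)
      alloc <- allocate_abortions(total_abortions, und$counts, und$women)
      for (cat in setdiff(levels(cats), drop)) {
        sub <- records[cats == cat, , drop = FALSE]
        if (nrow(sub) == 0) { message("empty stratum ", st, "=", cat,
                                      " omitted"); next }
        tar <- 35 * alloc$rates[[cat]]
        rows[[length(rows) + 1]] <-
          .decompose_stratum(sub, tar, constants, st, cat,
                             "unmet_need_allocated", window)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write decomposition results as delimited text
#'
#' Serializes [run_decomposition()] output with reporting precision
#' (indices 2 decimals, TFRs and residual 2 decimals, shares 1 decimal);
#' internal computation keeps full precision, rounding happens only here.
#'
#' @param results Data frame from [run_decomposition()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- results
  for (nm in c("Cm", "Cc", "Ca", "Ci", "TFRa", "TFRe", "residual"))
    out[[nm]] <- round(out[[nm]], 2)
  for (nm in grep("^share_", names(out), value = TRUE))
    out[[nm]] <- round(out[[nm]], 1)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
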