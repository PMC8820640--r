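#' Parameters of a synthetic survey cohort
#'
#' Defines the data-generating process for a DHS-style woman-level cohort
#' with fully known statistical structure, so that every downstream rate and
#' index has an exact closed-form true value (see [cohort_truth()]).
#'
#' The process, per woman: age uniform on 15-49; marriage Bernoulli with the
#' current age group's `prop_married`; for married women, one Bernoulli birth
#' trial per month over the 36 months before interview with probability
#' `fertility_rate(g)/12`, where `g` is the woman's five-year age group at
#' that month (months before exact age 15 carry no risk); postpartum
#' durations (full breastfeeding, amenorrhea, abstinence) drawn for recent
#' mothers from truncated exponentials on \[0, 36\] months, floored to whole
#' months and capped at the months elapsed since the most recent birth;
#' non-contraceptive hysterectomy drawn only for married women without a
#' recent birth, with its timing uniform on 1-36 months before interview;
#' contraceptive use Bernoulli with `contraceptive_prevalence(g)` among
#' married women, the method drawn from `method_mix`; unmet need Bernoulli
#' with `unmet_need_prob(g)` among married non-users; stratifiers drawn
#' independently from `strata_shares`, except region, which is a
#' deterministic function of state via `state_region`.
#'
#' Defaults emulate the broad structure of the India 2015-16 survey round:
#' marriage rising steeply then plateauing with age, sterilization-dominated
#' method mix, median postpartum insusceptibility near 7 months, and a small
#' recent non-contraceptive hysterectomy prevalence. The default marital
#' fertility schedule satisfies `fertility_rate(15-19) =
#' 0.75 * fertility_rate(20-24)`, matching the imputation rule applied by
#' [marital_fertility()], so closed-form truth and pipeline estimates use
#' identical marriage-index weights.
#'
#' @param n_women Number of records to generate.
#' @param seed Integer RNG seed; generation is fully reproducible.
#' @param prop_married Probability currently married, by age group (length 7).
#' @param fertility_rate Marital fertility, births per married woman-year,
#'   by age group (length 7).
#' @param contraceptive_prevalence Probability a married woman uses any
#'   method, by age group (length 7).
#' @param method_mix Named shares over methods, summing to 1.
#' @param postpartum_means Named numeric `c(bf=, amen=, abst=)`: means (in
#'   months) of the untruncated exponentials behind the three postpartum
#'   durations.
#' @param hysterectomy_prob Probability of a non-contraceptive hysterectomy
#'   in the past 3 years, among married women without a recent birth.
#' @param unmet_need_prob Probability of unmet need among married non-users,
#'   by age group (length 7).
#' @param strata_shares Named list of named share vectors for the
#'   stratifiers `state`, `residence`, `education`, `wealth`, `caste`.
#' @param state_region Named character vector mapping each state to a region.
#' @param weight_distribution `"constant"` (all weights 1) or `"lognormal"`
#'   (positive-skew weights with mean 1).
#'
#' @return An object of class `pd_cohort_params`.
#' @seealso [generate_cohort()], [cohort_truth()]
#' @export
cohort_params <- function(n_women = 10000L,
                          seed = 1L,
                          prop_married = c(0.16, 0.57, 0.83, 0.90, 0.91,
                                           0.89, 0.86),
                          fertility_rate = c(0.24, 0.32, 0.20, 0.10, 0.04,
                                             0.015, 0.005),
                          contraceptive_prevalence = c(0.10, 0.25, 0.45,
                                                       0.60, 0.65, 0.62,
                                                       0.55),
                          method_mix = c(sterilization = 0.65, IUD = 0.03,
                                         pill = 0.08, injectable = 0.01,
                                         condom = 0.10, traditional = 0.11,
                                         other = 0.02),
                          postpartum_means = c(bf = 5, amen = 7, abst = 3),
                          hysterectomy_prob = 0.01,
                          unmet_need_prob = c(0.27, 0.27, 0.22, 0.18, 0.12,
                                              0.08, 0.05),
                          strata_shares = list(
                            state = c(S1 = 0.5, S2 = 0.3, S3 = 0.2),
                            residence = c(urban = 0.35, rural = 0.65),
                            education = c("<5" = 0.35, "5-9" = 0.30,
                                          "10+" = 0.35),
                            wealth = c(poor = 1/3, middle = 1/3, rich = 1/3),
                            caste = c("SC/ST" = 0.30, OBC = 0.44,
                                      Other = 0.26)),
                          state_region = c(S1 = "R1", S2 = "R1", S3 = "R2"),
                          weight_distribution = c("constant", "lognormal")) {
  weight_distribution <- match.arg(weight_distribution)
  p <- list(n_women = as.integer(n_women), seed = as.integer(seed),
            prop_married = prop_married, fertility_rate = fertility_rate,
            contraceptive_prevalence = contraceptive_prevalence,
            method_mix = method_mix, postpartum_means = postpartum_means,
            hysterectomy_prob = hysterectomy_prob,
            unmet_need_prob = unmet_need_prob,
            strata_shares = strata_shares, state_region = state_region,
            weight_distribution = weight_distribution)
  class(p) <- "pd_cohort_params"
  validate_cohort_params(p)
  p
}

#' Validate cohort parameters
#'
#' Checks every probability lies in \[0, 1\], the method mix and each
#' stratifier's shares sum to 1 (tolerance 1e-9), schedules have length 7,
#' and duration means are positive.
#'
#' @param params A `pd_cohort_params` object.
#' @return `params`, invisibly, or an error describing the violation.
#' @export
validate_cohort_params <- function(params) {
  chk_prob <- function(x, nm) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1))
      stop(nm, " must lie in [0, 1]", call. = FALSE)
  }
  chk_len7 <- function(x, nm) {
    if (length(x) != n_age_groups)
      stop(nm, " must have length 7", call. = FALSE)
  }
  if (params$n_women < 0) stop("n_women must be non-negative")
  for (nm in c("prop_married", "contraceptive_prevalence",
               "unmet_need_prob")) {
    chk_len7(params[[nm]], nm); chk_prob(params[[nm]], nm)
  }
  chk_len7(params$fertility_rate, "fertility_rate")
  if (any(params$fertility_rate < 0)) stop("fertility_rate must be >= 0")
  chk_prob(params$hysterectomy_prob, "hysterectomy_prob")
  if (abs(sum(params$method_mix) - 1) > 1e-9)
    stop("method_mix shares must sum to 1")
  chk_prob(params$method_mix, "method_mix")
  if (!all(c("bf", "amen", "abst") %in% names(params$postpartum_means)) ||
      any(params$postpartum_means <= 0))
    stop("postpartum_means must name positive bf, amen and abst means")
  for (nm in names(params$strata_shares)) {
    s <- params$strata_shares[[nm]]
    chk_prob(s, paste0("strata_shares$", nm))
    if (abs(sum(s) - 1) > 1e-9)
      stop("strata_shares$", nm, " must sum to 1")
  }
  st <- names(params$strata_shares$state)
  if (!all(st %in% names(params$state_region)))
    stop("state_region must map every state to a region")
  invisible(params)
}

#' Write cohort parameters to a YAML file
#'
#' Named vectors are serialized as maps so that names survive the round
#' trip through [read_cohort_params()].
#'
#' @param params A `pd_cohort_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_params <- function(params, path) {
  to_tree <- function(x) {
    if (is.list(x)) lapply(x, to_tree)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(lapply(unclass(params), to_tree), path, precision = 15)
  invisible(path)
}

#' Read cohort parameters from a YAML file
#'
#' @param path YAML file whose top-level keys are arguments of
#'   [cohort_params()].
#' @return A `pd_cohort_params` object.
#' @export
read_cohort_params <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (nm in c("method_mix", "postpartum_means", "state_region"))
    if (!is.null(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  if (!is.null(cfg$strata_shares))
    cfg$strata_shares <- lapply(cfg$strata_shares, unlist)
  do.call(cohort_params, cfg)
}

# Age (exact, years) t months before interview for a woman aged A completed
# years now; exact current age is taken as A + 0.5.
.age_at_month <- function(A, t) A + 0.5 - t / 12

# 1-based five-year group at t months before interview; NA below exact
# age 15.
.group_at_month <- function(A, t) {
  age <- .age_at_month(A, t)
  ifelse(age >= 15, pmin(floor((age - 15) / 5), 6) + 1L, NA_integer_)
}

# Survival P(D >= j) of an exponential with the given mean truncated to
# [0, 36]; j may be any non-negative value.
.truncexp_surv <- function(j, mean) {
  lam <- 1 / mean
  z <- 1 - exp(-36 * lam)
  s <- (exp(-lam * j) - exp(-36 * lam)) / z
  pmax(pmin(s, 1), 0)
}

# Inverse-CDF draw from the truncated exponential on [0, 36].
.rtruncexp <- function(n, mean) {
  lam <- 1 / mean
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-36 * lam))) / lam
}

# P(max of the three floored postpartum durations >= j), integer j >= 1.
.surv_max_postpartum <- function(j, means) {
  s <- 1
  for (m in means) s <- s * (1 - .truncexp_surv(j, m))
  1 - s
}

#' Generate a synthetic woman-level cohort
#'
#' Draws `params$n_women` records from the process described in
#' [cohort_params()]. Identical `(params, seed)` give byte-identical output.
#'
#' @param params A `pd_cohort_params` object.
#' @return A data frame with one row per woman and the microdata columns
#'   documented in [microdata_schema()].
#' @examples
#' coh <- generate_cohort(cohort_params(n_women = 200, seed = 42))
#' table(coh$currently_married)
#' @export
generate_cohort <- function(params) {
  validate_cohort_params(params)
  n <- params$n_women
  set.seed(params$seed)
  labs <- age_group_labels()

  age <- sample(15:49, n, replace = TRUE)
  g <- assign_age_group(age) + 1L
  married <- stats::runif(n) < params$prop_married[g]

  # monthly birth trials over the 36-month window, by age group at the month
  g_at <- outer(age, 1:36, .group_at_month)          # n x 36, NA below 15
  p_mon <- matrix(0, n, 36)
  ok <- !is.na(g_at)
  p_mon[ok] <- params$fertility_rate[g_at[ok]] / 12
  p_mon <- p_mon * married
  birth <- matrix(stats::runif(n * 36), n, 36) < p_mon
  has_birth <- rowSums(birth) > 0
  # months since the most recent birth (smallest t with a birth)
  last_birth <- rep(NA_integer_, n)
  last_birth[has_birth] <-
    max.col(birth[has_birth, , drop = FALSE], ties.method = "first")
  birth_months <- character(n)
  if (any(has_birth)) {
    idx <- which(birth, arr.ind = TRUE)
    bm <- split(idx[, 2], idx[, 1])
    birth_months[as.integer(names(bm))] <-
      vapply(bm, function(v) paste(sort(v), collapse = ";"), character(1))
  }

  # postpartum durations: floored truncated exponentials, capped at months
  # since the most recent birth
  dur <- matrix(0L, n, 3, dimnames = list(NULL, c("bf", "amen", "abst")))
  nb <- sum(has_birth)
  if (nb > 0) {
    for (k in c("bf", "amen", "abst")) {
      d <- floor(.rtruncexp(nb, params$postpartum_means[[k]]))
      dur[has_birth, k] <- as.integer(pmin(d, last_birth[has_birth]))
    }
  }

  hyst <- married & !has_birth &
    stats::runif(n) < params$hysterectomy_prob
  hyst_months <- rep(NA_integer_, n)
  hyst_months[hyst] <- sample(1:36, sum(hyst), replace = TRUE)

  use <- married & stats::runif(n) < params$contraceptive_prevalence[g]
  method <- rep("none", n)
  if (any(use))
    method[use] <- sample(names(params$method_mix), sum(use),
                          replace = TRUE, prob = params$method_mix)

  unmet <- married & method == "none" &
    stats::runif(n) < params$unmet_need_prob[g]

  strat <- lapply(params$strata_shares, function(s)
    sample(names(s), n, replace = TRUE, prob = s))
  region <- unname(params$state_region[strat$state])

  weight <- if (params$weight_distribution == "constant") rep(1, n)
            else stats::rlnorm(n, meanlog = -0.125, sdlog = 0.5)

  data.frame(weight = weight, age = age,
             currently_married = married, method = method,
             birth_months = birth_months,
             bf_months = dur[, "bf"], amen_months = dur[, "amen"],
             abst_months = dur[, "abst"],
             hysterectomy = hyst, hyst_months_ago = hyst_months,
             unmet_need = unmet,
             state = strat$state, region = region,
             residence = strat$residence, education = strat$education,
             wealth = strat$wealth, caste = strat$caste,
             stringsAsFactors = FALSE)
}

#' Closed-form true values for a synthetic cohort
#'
#' Computes, by exact enumeration over the 35 single-year ages and the 36
#' monthly birth trials (no sampling), the population-level quantities the
#' pipeline estimates from a generated cohort: proportions married, marital
#' and all-women age-specific fertility, TFR, contraceptive prevalence and
#' mean effectiveness, contraception-infecundability overlap, mean
#' infecundability duration, and the implied marriage, contraception and
#' infecundability indices.
#'
#' The marriage-index weights apply the same imputation as the pipeline
#' (marital fertility at 15-19 replaced by three-quarters of the 20-24
#' rate), so truth and estimate are directly comparable.
#'
#' @param params A `pd_cohort_params` object.
#' @param constants A `pd_constants` object.
#' @return An object of class `pd_truth`: a list with age schedules `m`,
#'   `f_m`, `f`, `u`, `o`, `i_by_age`, `p_recent_birth`, scalars `TFR`,
#'   `e_bar`, `i_bar`, `Cm`, `Cc`, `Ci`, and the schedule `Cc_by_age`.
#' @export
cohort_truth <- function(params, constants = pd_constants()) {
  validate_cohort_params(params)
  labs <- age_group_labels()
  fr <- params$fertility_rate
  pm <- params$prop_married
  u <- params$contraceptive_prevalence
  h <- params$hysterectomy_prob
  means <- params$postpartum_means[c("bf", "amen", "abst")]

  ages <- 15:49
  nA <- length(ages)
  gA <- assign_age_group(ages) + 1L

  # per-age monthly birth probabilities and recent-birth pmf
  S_M <- vapply(1:36, .surv_max_postpartum, numeric(1), means = means)
  cumS <- cumsum(S_M)                       # E[min(maxdur, t)] = cumS[t]
  p_b <- numeric(nA)                        # P(recent birth | married)
  o_cond <- numeric(nA)                     # P(overlap factor | married)
  d_num <- numeric(nA)                      # E[dur; birth | married]
  exp_months <- matrix(0, nA, n_age_groups) # months of exposure by group
  birth_num <- matrix(0, nA, n_age_groups)  # expected births by group
  for (a in seq_len(nA)) {
    gt <- .group_at_month(ages[a], 1:36)
    rt <- ifelse(is.na(gt), 0, fr[ifelse(is.na(gt), 1L, gt)] / 12)
    surv <- cumprod(1 - rt)
    pmf <- rt * c(1, surv[-36])             # most recent birth t months ago
    p_b[a] <- 1 - surv[36]
    o_cond[a] <- sum(pmf * S_M) + (1 - p_b[a]) * h
    d_num[a] <- sum(pmf * cumS)
    for (t in 1:36) {
      if (!is.na(gt[t])) {
        exp_months[a, gt[t]] <- exp_months[a, gt[t]] + 1 / 12
        birth_num[a, gt[t]] <- birth_num[a, gt[t]] +
          pm[gA[a]] * fr[gt[t]] / 12
      }
    }
  }

  # all-women ASFR: expected births over expected exposure, by age at event
  f <- colSums(birth_num) / colSums(exp_months)
  TFR <- 5 * sum(f)

  by_group <- function(x) vapply(split(x, gA), mean, numeric(1))
  p_recent <- by_group(p_b)                 # per married woman
  o <- u * by_group(o_cond)                 # per married woman, with use

  # mean infecundability duration among eligible women (recent mothers plus
  # recent non-contraceptive hysterectomies; hysterectomy timing uniform on
  # 1..36 months, mean 18.5)
  elig_w <- pm[gA] * (p_b + (1 - p_b) * h)
  dur_w <- pm[gA] * (d_num + (1 - p_b) * h * 18.5)
  i_by_age <- vapply(split(seq_len(nA), gA), function(ii)
    sum(dur_w[ii]) / sum(elig_w[ii]), numeric(1))
  i_bar <- sum(dur_w) / sum(elig_w)

  e_bar <- sum(constants$e_table[names(params$method_mix)] *
                 params$method_mix)

  f_m <- fr
  f_m_w <- f_m
  f_m_w[1] <- 0.75 * f_m_w[2]               # same imputation as the pipeline
  w_m <- f_m_w / sum(f_m_w)
  Cm <- sum(pm * w_m)

  Cc_by_age <- pmin(pmax(1 - constants$r * (u - o) * e_bar, 0), 1)
  w_c <- constants$f_star / sum(constants$f_star)
  Cc <- sum(Cc_by_age * w_c)

  Ci <- min(1, constants$ci_numerator / (constants$ci_offset + i_bar))

  sched <- function(x) { names(x) <- labs; x }
  structure(list(m = sched(pm), f_m = sched(f_m), f = sched(f), TFR = TFR,
                 u = sched(u), e_bar = e_bar, o = sched(o),
                 p_recent_birth = sched(p_recent),
                 i_by_age = sched(i_by_age), i_bar = i_bar,
                 Cm = Cm, Cc = Cc, Cc_by_age = sched(Cc_by_age), Ci = Ci),
            class = "pd_truth")
}
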