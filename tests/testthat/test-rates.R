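test_that("proportion married is a weighted share per age group", {
  all_m <- make_women(20, age = rep(c(17, 22, 27, 32, 37, 42, 47), 3)[1:20])
  expect_equal(unname(proportion_married(all_m)), rep(1, 7))
  none_m <- all_m
  none_m$currently_married <- FALSE
  expect_equal(unname(proportion_married(none_m)), rep(0, 7))
  # weights (2, 1), married flags (1, 0) -> 2/3
  d <- make_women(2, age = 30, weight = c(2, 1),
                  currently_married = c(TRUE, FALSE))
  expect_equal(proportion_married(d)[["30-34"]], 2 / 3)
  # empty groups are NA
  expect_true(is.na(proportion_married(d)[["15-19"]]))
})

test_that("ASFR divides births by woman-years of exposure at that age", {
  # two women aged 23 (exact 23.5): the whole 36-month window lies in
  # 20-24, so exposure there is 6 woman-years; 3 births -> 0.5/woman-year
  d <- make_women(2, age = 23, birth_months = c("6;18", "30"))
  got <- asfr(d)
  expect_equal(got$f[["20-24"]], 0.5)
  expect_equal(got$exposure[["20-24"]], 6)
  expect_equal(sum(got$births_n), 3L)
  # no births in the window: zero rate and zero total
  d0 <- make_women(2, age = 23)
  expect_equal(asfr(d0)$f[["20-24"]], 0)
  expect_equal(asfr(d0)$TFRa, 0)
})

test_that("TFRa equals five times the ASFR sum to machine precision", {
  coh <- small_cohort(1500, seed = 12)
  got <- asfr(coh)
  expect_equal(got$TFRa, 5 * sum(got$f), tolerance = 1e-12)
})

test_that("marital fertility imputes 15-19 as three-quarters of 20-24", {
  # 4 married women aged 28 (window inside 25-29), 2 births -> 2/12
  d <- rbind(make_women(2, age = 28, birth_months = "10"),
             make_women(2, age = 28),
             make_women(2, age = 23, birth_months = c("8", "")))
  f_m <- marital_fertility(d)
  expect_equal(f_m[["25-29"]], 2 / 12)
  expect_equal(f_m[["15-19"]], 0.75 * f_m[["20-24"]])
  # childless cohort: all rates zero including the imputed one
  d0 <- make_women(5, age = c(23, 28, 33, 38, 43))
  f0 <- marital_fertility(d0)
  expect_equal(unname(f0[2:7][!is.na(f0[2:7])]),
               rep(0, sum(!is.na(f0[2:7]))))
  expect_equal(f0[["15-19"]], 0)
  # married teens but no married women 20-24: imputation impossible and
  # the unstable observed 15-19 rate is dropped
  d1 <- rbind(make_women(3, age = 30, birth_months = "9"),
              make_women(1, age = 17))
  expect_warning(f1 <- marital_fertility(d1), "20-24")
  expect_true(is.na(f1[["15-19"]]))
})

test_that("contraceptive prevalence and method mix are weighted tabulations", {
  d <- make_women(3, age = 30, weight = c(1, 1, 2),
                  method = c("sterilization", "none", "pill"))
  got <- contraceptive_prevalence(d)
  expect_equal(got$u[["30-34"]], 3 / 4)
  expect_equal(got$mix["30-34", "sterilization"], 1 / 4)
  expect_equal(got$mix["30-34", "pill"], 2 / 4)
  expect_equal(sum(got$mix["30-34", ]), got$u[["30-34"]])
  # no users / all sterilized
  expect_equal(contraceptive_prevalence(
    make_women(4, age = 30))$u[["30-34"]], 0)
  expect_equal(contraceptive_prevalence(
    make_women(4, age = 30, method = "sterilization"))$u[["30-34"]], 1)
})

test_that("overlap counts users who are postpartum-insusceptible or have had
           a non-contraceptive hysterectomy", {
  # 10 married women: 4 users, of whom 1 has an ongoing factor -> o = 0.1
  d <- rbind(
    make_women(1, age = 30, method = "pill", birth_months = "5",
               amen_months = 5),                    # ongoing: amen == elapsed
    make_women(1, age = 30, method = "pill", birth_months = "10",
               amen_months = 4),                    # lapsed
    make_women(2, age = 30, method = "condom"),
    make_women(6, age = 30))
  expect_equal(overlap_proportion(d)[["30-34"]], 0.1)
  # no users -> no overlap
  d$method <- "none"
  expect_equal(overlap_proportion(d)[["30-34"]], 0)
  # every user amenorrheic -> o = u
  d2 <- make_women(5, age = 30, method = "IUD", birth_months = "3",
                   amen_months = 3)
  expect_equal(overlap_proportion(d2)[["30-34"]],
               contraceptive_prevalence(d2)$u[["30-34"]])
  # hysterectomy alone creates overlap for a user
  d3 <- rbind(make_women(1, age = 40, method = "condom",
                         hysterectomy = TRUE, hyst_months_ago = 12),
              make_women(1, age = 40))
  expect_equal(overlap_proportion(d3)[["40-44"]], 0.5)
})

test_that("infecundability duration is the max of the four factors", {
  one <- make_women(1, age = 25, birth_months = "12", bf_months = 10,
                    amen_months = 6, abst_months = 2)
  got <- infecundability_duration(one)
  expect_equal(got$i_bar, 10)
  expect_equal(got$n_eligible, 1L)
  # recent mother (10) plus hysterectomy at 24 months, equal weights -> 17
  two <- rbind(one, make_women(1, age = 25, hysterectomy = TRUE,
                               hyst_months_ago = 24))
  got2 <- infecundability_duration(two)
  expect_equal(got2$i_bar, 17)
  expect_equal(got2$n_recent_births, 1L)
  # all durations zero
  zero <- make_women(3, age = 25, birth_months = "30")
  expect_equal(infecundability_duration(zero)$i_bar, 0)
  # nobody eligible
  expect_true(is.na(infecundability_duration(
    make_women(3, age = 25))$i_bar))
})

test_that("unmet-need distribution normalizes weighted counts", {
  d <- rbind(make_women(3, weight = 100, education = "<5",
                        unmet_need = TRUE),
             make_women(7, weight = 100, education = "10+",
                        unmet_need = TRUE),
             make_women(5, education = "5-9"))
  got <- unmet_need_distribution(d, "education")
  expect_equal(got$shares[["<5"]], 0.3)
  expect_equal(got$shares[["10+"]], 0.7)
  expect_equal(sum(got$shares), 1)
  # single receiving category
  d1 <- make_women(4, unmet_need = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(unname(unmet_need_distribution(d1, "wealth")$shares["middle"]),
               1)
  # no unmet need anywhere is an error
  expect_error(unmet_need_distribution(make_women(5), "education"),
               "unmet need")
})

test_that("weighted estimates with constant weights equal unweighted ones", {
  coh <- small_cohort(1200, seed = 31)
  coh2 <- coh
  coh2$weight <- 2.5          # any constant weight
  for (f in list(proportion_married, overlap_proportion)) {
    expect_equal(f(coh), f(coh2))
  }
  expect_equal(asfr(coh)$f, asfr(coh2)$f)
  expect_equal(infecundability_duration(coh)$i_bar,
               infecundability_duration(coh2)$i_bar)
})

test_that("rate bundle invariants hold on generated cohorts", {
  for (seed in c(8, 21)) {
    rb <- rate_bundle(small_cohort(2500, seed = seed))
    ok <- !is.na(rb$u) & !is.na(rb$o)
    expect_true(all(rb$o[ok] <= rb$u[ok] + 1e-12))
    expect_true(all(rb$m >= 0 & rb$m <= 1, na.rm = TRUE))
    expect_equal(rb$TFRa, 5 * sum(rb$f), tolerance = 1e-12)
    expect_equal(sum(rb$n_by_group), rb$n_women)
  }
})
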