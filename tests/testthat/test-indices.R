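test_that("marriage index is the marital-fertility-weighted mean of m(a)", {
  fm <- c(0.1, 0.3, 0.3, 0.2, 0.05, 0.03, 0.02)
  expect_equal(index_marriage(rep(1, 7), fm)$Cm, 1)
  expect_equal(index_marriage(rep(0, 7), fm)$Cm, 0)
  m <- c(0.2, 0.6, 0.9, 0.95, 0.95, 0.9, 0.9)
  expect_equal(index_marriage(m, fm)$Cm, sum(m * fm / sum(fm)))
  expect_equal(index_marriage(m, fm)$Cm, 0.7525)
  expect_error(index_marriage(m, rep(0, 7)), "weights")
})

test_that("mean effectiveness is the use-weighted mean over methods", {
  mix <- matrix(0, 7, 3,
                dimnames = list(age_group_labels(),
                                c("sterilization", "pill", "condom")))
  mix[4, ] <- c(0.3, 0.1, 0.1)
  e_tab <- c(sterilization = 1.00, pill = 0.94, condom = 0.89)
  e <- method_effectiveness(mix, e_tab)
  expect_equal(e[["30-34"]], (0.3 + 0.094 + 0.089) / 0.5)
  expect_equal(e[["30-34"]], 0.966)
  expect_true(all(is.na(e[-4])))        # undefined where u = 0
  # single method with effectiveness 1
  mix1 <- mix; mix1[, ] <- 0; mix1[2, "sterilization"] <- 0.4
  expect_equal(method_effectiveness(mix1, e_tab)[["20-24"]], 1)
  expect_error(method_effectiveness(
    matrix(0.1, 7, 1, dimnames = list(NULL, "withdrawal")), e_tab),
    "withdrawal")
})

test_that("contraception index follows 1 - r(u - o)e with f* weights", {
  cst <- pd_constants()
  u0 <- rep(0, 7)
  expect_equal(index_contraception(u0, u0, rep(NA_real_, 7), cst)$Cc, 1)
  # full effective use with r = 1 drives the index to 0
  cst1 <- pd_constants(r = rep(1, 7))
  got <- index_contraception(rep(1, 7), rep(0, 7), rep(1, 7), cst1)
  expect_equal(got$Cc, 0)
  # single-group evaluation
  u <- c(0, 0.50, rep(0, 5)); o <- c(0, 0.05, rep(0, 5))
  e <- c(NA, 0.95, rep(NA, 5))
  cstr <- pd_constants(r = rep(0.99, 7))
  got2 <- index_contraception(u, o, e, cstr)
  expect_equal(got2$Cc_by_age[["20-24"]], 1 - 0.99 * 0.45 * 0.95)
  expect_equal(got2$Cc_by_age[["20-24"]], 0.576775, tolerance = 1e-6)
  expect_error(index_contraception(u, u + 0.1, e, cst), "overlap")
})

test_that("infecundability index and births averted follow their formulas", {
  expect_equal(index_infecundability(1.5), 1.0)
  expect_equal(index_infecundability(21.5), 0.5)
  expect_equal(index_infecundability(11.5), 20 / 30)
  expect_equal(index_infecundability(0), 1)     # capped at 1
  expect_true(is.na(index_infecundability(NA)))
  expect_equal(births_averted_per_abortion(9.5), 0.5)
  expect_equal(births_averted_per_abortion(7.141), 14 / 25.641)
  expect_equal(births_averted_per_abortion(0), 14 / 18.5)
})

test_that("abortion allocation is proportional to unmet need and conserves
           the total", {
  got <- allocate_abortions(1000, c(A = 300, B = 700), c(A = 5000, B = 5000))
  expect_equal(unname(got$abortions), c(300, 700))
  expect_equal(sum(got$abortions), 1000)
  expect_equal(unname(got$rates), c(0.06, 0.14))
  # one category receives everything
  one <- allocate_abortions(50, c(X = 10), c(X = 200))
  expect_equal(unname(one$abortions), 50)
  # zero total -> zero rates
  z <- allocate_abortions(0, c(A = 1, B = 3), c(A = 10, B = 10))
  expect_equal(unname(z$rates), c(0, 0))
  expect_error(allocate_abortions(10, c(A = 0, B = 0), c(A = 1, B = 1)),
               "impossible")
  # conservation on random draws
  set.seed(4)
  for (k in 1:20) {
    cnt <- stats::setNames(stats::runif(4, 0, 100), letters[1:4])
    tot <- stats::runif(1, 0, 5000)
    expect_equal(sum(allocate_abortions(tot, cnt,
                                        cnt * 10)$abortions), tot)
  }
})

test_that("state age-rate rescaling preserves the state total by default", {
  nat <- c(10, 20, 30, 25, 15, 5, 2)
  expect_equal(unname(adjust_state_age_rates(nat, 47, 47)), nat)
  doubled <- adjust_state_age_rates(nat, 94, 47)
  expect_equal(unname(doubled), 2 * nat)
  # the implied state overall rate is preserved exactly under a flat
  # population: mean of rates scales by the same factor
  expect_equal(mean(doubled) / mean(nat), 2)
  lit <- adjust_state_age_rates(nat, 94, 47, mode = "literal")
  expect_equal(unname(lit), nat / 2)
  expect_error(adjust_state_age_rates(nat, 0, 47), "positive")
  expect_error(adjust_state_age_rates(nat, 47, 0), "positive")
})

test_that("total abortion rate is five times the schedule sum", {
  expect_equal(total_abortion_rate(rep(0, 7)), 0)
  expect_equal(total_abortion_rate(rep(0.047, 7)), 1.645)
  expect_equal(total_abortion_rate(c(0.02, rep(0, 6))), 0.1)
})

test_that("abortion index uses the aggregate formula", {
  expect_equal(index_abortion(2.18, 0, 0.5), 1)
  b <- births_averted_per_abortion(20 / 0.78 - 18.5)
  expect_equal(index_abortion(2.18, 1.645, b), 2.18 / (2.18 + b * 1.645))
  expect_error(index_abortion(0, 1, 0.5), "non-positive")
  # Bihar-level TFR stays inside (0, 1)
  ca <- index_abortion(3.41, 1.8, 0.5)
  expect_true(ca > 0 && ca < 1)
})

test_that("indices are monotone in their drivers", {
  cst <- pd_constants()
  e <- rep(0.95, 7)
  o <- rep(0.02, 7)
  u1 <- rep(0.4, 7); u2 <- u1; u2[3] <- 0.5
  cc1 <- index_contraception(u1, o, e, cst)$Cc
  cc2 <- index_contraception(u2, o, e, cst)$Cc
  expect_lt(cc2, cc1)
  expect_gt(index_infecundability(5), index_infecundability(6))
  expect_gt(index_abortion(2, 1.0, 0.5), index_abortion(2, 1.2, 0.5))
  expect_gt(index_abortion(2, 1.0, 0.5), index_abortion(2, 1.0, 0.6))
})

test_that("aggregate indices match brute-force sums on random schedules", {
  set.seed(99)
  cst <- pd_constants()
  for (k in 1:25) {
    m <- stats::runif(7)
    fm <- stats::runif(7, 0.01, 0.4)
    expect_equal(index_marriage(m, fm)$Cm,
                 sum(vapply(1:7, function(a) m[a] * fm[a] / sum(fm),
                            numeric(1))),
                 tolerance = 1e-12)
    u <- stats::runif(7, 0.05, 0.9)
    o <- u * stats::runif(7, 0, 0.5)
    e <- stats::runif(7, 0.7, 1)
    got <- suppressWarnings(index_contraception(u, o, e, cst)$Cc)
    brute <- 0
    for (a in 1:7) {
      cca <- min(max(1 - cst$r[[a]] * (u[a] - o[a]) * e[a], 0), 1)
      brute <- brute + cca * cst$f_star[[a]] / sum(cst$f_star)
    }
    expect_equal(got, unname(brute), tolerance = 1e-12)
  }
})
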