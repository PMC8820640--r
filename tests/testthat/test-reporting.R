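test_that("suppression thresholds act on unweighted counts at the stated
           boundaries", {
  # women thresholds: <50 suppress, 50-100 flag, >100 clean
  expect_true(apply_suppression(49, 100)$suppress_all)
  s50 <- apply_suppression(50, 100)
  expect_false(s50$suppress_all); expect_true(s50$flag_all)
  s100 <- apply_suppression(100, 100)
  expect_false(s100$suppress_all); expect_true(s100$flag_all)
  s101 <- apply_suppression(101, 100)
  expect_false(s101$flag_all)
  # recent-birth thresholds: <25 suppress Ci chain, 25-50 flag it
  expect_true(apply_suppression(500, 24)$suppress_ci_chain)
  b25 <- apply_suppression(500, 25)
  expect_false(b25$suppress_ci_chain); expect_true(b25$flag_ci_chain)
  b50 <- apply_suppression(500, 50)
  expect_false(b50$suppress_ci_chain); expect_true(b50$flag_ci_chain)
  expect_false(apply_suppression(500, 51)$flag_ci_chain)
  # full-row suppression implies chain suppression
  expect_true(apply_suppression(49, 500)$suppress_ci_chain)
})

test_that("abortion-rate resolution falls back state -> region -> national", {
  ab <- abortion_inputs(47, state_rates = c(Assam = 70),
                        region_rates = c(R1 = 55))
  expect_equal(resolve_abortion_rate(ab, "Assam", "R1"),
               list(rate = 70, source = "state"))
  expect_equal(resolve_abortion_rate(ab, "Bihar", "R1"),
               list(rate = 55, source = "region"))
  expect_equal(resolve_abortion_rate(ab, "Bihar", "R9"),
               list(rate = 47, source = "national"))
  expect_equal(tar_from_overall_rate(47), 1.645)
})

test_that("suppressed strata carry NA values and status columns", {
  coh <- small_cohort(n = 5000, seed = 55)
  # a tiny state: relabel 30 records
  coh$state[1:30] <- "tiny"
  res <- run_decomposition(coh, abortion_inputs(47), strata = "state")
  tiny <- res[res$category == "tiny", ]
  expect_true(tiny$suppressed)
  expect_true(all(is.na(tiny[c("Cm", "Cc", "Ca", "Ci", "TFRa", "TFRe",
                               "residual", "share_marriage")])))
  big <- res[res$category == "national", ]
  expect_false(big$suppressed)
  expect_false(anyNA(big[c("Cm", "Cc", "Ca", "Ci", "TFRe")]))
})

test_that("a single-category stratifier reproduces the national stratum", {
  p <- cohort_params(n_women = 4000, seed = 19,
                     strata_shares = list(
                       state = c(S1 = 1),
                       residence = c(rural = 1),
                       education = c("<5" = 0.4, "5-9" = 0.3, "10+" = 0.3),
                       wealth = c(poor = 1/3, middle = 1/3, rich = 1/3),
                       caste = c("SC/ST" = 0.3, OBC = 0.44, Other = 0.26)),
                     state_region = c(S1 = "R1"))
  coh <- generate_cohort(p)
  res <- run_decomposition(coh, abortion_inputs(47), strata = "residence")
  expect_false("urban" %in% res$category)
  rural <- res[res$category == "rural", ]
  nat <- res[res$category == "national", ]
  for (nm in c("Cm", "Cc", "Ca", "Ci", "TFRa", "TFRe", "share_marriage"))
    expect_equal(rural[[nm]], nat[[nm]], tolerance = 1e-9)
})

test_that("runs are deterministic and marginal strata partition the
           population", {
  coh <- small_cohort(n = 4000, seed = 23)
  ab <- abortion_inputs(47, state_rates = c(S1 = 60),
                        region_rates = c(R2 = 40))
  r1 <- run_decomposition(coh, ab, strata = c("state", "education"))
  r2 <- run_decomposition(coh, ab, strata = c("state", "education"))
  expect_identical(r1, r2)
  nat <- r1[r1$stratifier == "national", ]
  for (st in c("state", "education")) {
    sub <- r1[r1$stratifier == st, ]
    expect_equal(sum(sub$women_weighted), nat$women_weighted)
    expect_equal(sum(sub$n_women), nat$n_women)
  }
  # abortion-rate sources recorded per stratum
  st <- r1[r1$stratifier == "state", ]
  expect_equal(st$abortion_source[st$category == "S1"], "state")
  expect_equal(st$abortion_source[st$category == "S3"], "region")
  expect_setequal(
    r1$abortion_source[r1$stratifier == "education"],
    "unmet_need_allocated")
})

test_that("age-band strata use the unmet-need abortion allocation", {
  coh <- small_cohort(n = 6000, seed = 29)
  res <- run_decomposition(coh, abortion_inputs(47), strata = "age_band")
  bands <- res[res$stratifier == "age_band", ]
  expect_setequal(bands$category, c("15-24", "25-34", "35-49"))
  # allocation conserves the national abortion total
  und <- unmet_need_distribution(coh, "age_band")
  tot <- 47 / 1000 * sum(coh$weight)
  alloc <- allocate_abortions(tot, und$counts, und$women)
  expect_equal(sum(alloc$abortions), tot)
})

test_that("omitted categories stay in the national aggregate only", {
  coh <- small_cohort(n = 3000, seed = 37)
  res <- run_decomposition(coh, abortion_inputs(47), strata = "state",
                           omit_categories = list(state = "S3"))
  expect_false("S3" %in% res$category)
  nat <- res[res$category == "national", ]
  expect_equal(nat$n_women, nrow(coh))   # S3 women still counted nationally
})

test_that("results serialize with reporting precision", {
  coh <- small_cohort(n = 3000, seed = 41)
  res <- run_decomposition(coh, abortion_inputs(47))
  path <- tempfile(fileext = ".csv")
  write_results(res, path)
  got <- utils::read.csv(path)
  expect_equal(got$Cm, round(res$Cm, 2))
  expect_equal(got$share_marriage, round(res$share_marriage, 1))
})
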