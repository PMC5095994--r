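test_that("growth ratios reproduce the reported two-decimal arithmetic", {
  expect_equal(growth_ratio(340000, 674000), 1.98)
  expect_equal(growth_ratio(142000, 291000), 2.05)
  expect_equal(growth_ratio(5, 5), 1.00)
  expect_error(growth_ratio(0, 10), "undefined ratio")
})

test_that("point prevalence follows the mid-year definition", {
  # no incidence: prevalence 0 everywhere
  p0 <- const_bundle(incidence = 0)
  r0 <- run_population(p0, n_actors = 1000L, seed = 12)
  pv <- point_prevalence(r0, 2015)
  expect_true(all(pv$cases == 0))
  expect_error(point_prevalence(r0, 1999), "outside the simulation horizon")

  # deterministic-ish world: everyone onsets at birth, no deaths, so cases
  # equal the stratum population and rates are 1000 per 1000
  p1 <- const_bundle(m0 = 1e-12, hr = 1, years = 1950:2040,
                     cohort_year = 1950L, births = 2000)
  r1 <- run_population(p1, n_actors = 500L, seed = 13, onset_mode = "at_birth")
  pv1 <- point_prevalence(r1, 2031)   # cohort aged 80-81 at mid-year
  tot <- pv1[pv1$sex == "total", ]
  expect_equal(tot$cases, 2000)
  expect_equal(tot$rate40, 1000)
  expect_equal(tot$rate80, 1000)
  expect_equal(pv1$cases[pv1$sex == "male"] + pv1$cases[pv1$sex == "female"],
               tot$cases)
})

test_that("mortality summary ties deaths, prevalence and YLL together", {
  p <- const_bundle(m0 = 0.05, hr = 2.5, years = 2000:2060)
  r <- run_population(p, n_actors = 20000L, seed = 14, onset_mode = "at_birth")
  ms <- mortality_summary(r, 2010)
  pv <- point_prevalence(r, 2010)
  expect_equal(ms$rate_per_1000,
               ms$deaths / pv$cases[pv$sex == "total"] * 1000)
  expect_false(ms$rate_undefined)
  expect_gt(ms$deaths, 0)
  # with effective HR = 1 every decedent has YLL exactly 0
  rnull <- run_population(p, scenario("null-hr", hr_multiplier = 1 / 2.5),
                          n_actors = 5000L, seed = 14, onset_mode = "at_birth")
  msn <- mortality_summary(rnull, 2010)
  expect_identical(msn$mean_yll, 0)
})

test_that("caregiving summaries respect degenerate models and partition", {
  # receipt probability zero: nobody receives care
  p0 <- const_bundle(m0 = 0.02, hr = 1, incidence = 0.2, min_age = 0L,
                     receipt = c(none = 0, dementia = 0))
  r0 <- run_population(p0, n_actors = 3000L, seed = 15)
  cs0 <- caregiving_summary(r0, 2015)
  expect_equal(cs0$recipients, 0)
  expect_equal(cs0$hours_per_year, 0)
  expect_equal(cs0$pct_none, 100)

  # receipt 1 with the hours distribution degenerate at the >= 71 bin
  p1 <- const_bundle(m0 = 0.02, hr = 1, incidence = 0.2, min_age = 0L,
                     receipt = c(none = 1, dementia = 1))
  p1$caregiving <- caregiving_model(
    array(1, c(3L, 2L, 3L)),
    hours_probs = c(none = 0, lt7 = 0, h7_14 = 0, h15_70 = 0, ge71 = 1),
    rep_hours = c(none = 0, lt7 = 3.5, h7_14 = 10.5, h15_70 = 40, ge71 = 80))
  r1 <- run_population(p1, n_actors = 3000L, seed = 15)
  cs1 <- caregiving_summary(r1, 2015)
  yr <- r1$years[r1$years$year == 2015 & r1$years$dementia, ]
  # every prevalent (not incident-that-year) person is in the top bin
  expect_true(all(yr$care_bin[!yr$onset_this_year] == 4L))
  expect_equal(cs1$hours_per_year, cs1$recipients * 80 * 52)
  # bin percentages partition all persons with dementia
  expect_equal(cs1$pct_none + cs1$pct_lt7 + cs1$pct_7_14 + cs1$pct_15_70 +
                 cs1$pct_ge71, 100, tolerance = 1e-9)
})

test_that("receipt probability is recovered at the reported 77% level", {
  p <- small_bundle()   # dementia receipt probability 0.77
  r <- cached("receipt_run", run_population(p, n_actors = 30000L, seed = 16))
  yr <- r$years[r$years$dementia & !r$years$onset_this_year, ]
  n <- nrow(yr)
  expect_gt(n, 5000)
  # conditional on the actor-year set, receipt draws are iid Bernoulli(0.77)
  frac <- mean(yr$care_bin > 0)
  se <- sqrt(0.77 * 0.23 / n)
  expect_lt(abs(frac - 0.77), 3 * se)
})

test_that("sector costs prorate the incident year and sum exactly", {
  p <- const_bundle(m0 = 1e-12, hr = 1, incidence = 50, min_age = 0L,
                    years = 2000:2030)
  # incident cost 1500/yr, prevalent 1000/yr in every sector
  r <- run_population(p, n_actors = 400L, seed = 17)
  w <- r$meta$weight
  # all actors onset January-uniform in 2001; the incident window straddles
  # 2001 and 2002
  co1 <- cost_summary(r, 2001)
  co2 <- cost_summary(r, 2002)
  co3 <- cost_summary(r, 2003)
  yr1 <- r$years[r$years$year == 2001, ]
  f1 <- sum(yr1$frac_incident); d1 <- sum(yr1$frac_dementia)
  expect_equal(co1$physician * 1e6, w * (f1 * 1500 + (d1 - f1) * 1000),
               tolerance = 1e-9)
  # steady prevalent year: exactly 1000 per weighted person
  expect_equal(co3$physician * 1e6, w * nrow(r$years[r$years$year == 2003, ]) *
                 1000, tolerance = 1e-9)
  for (co in list(co1, co2, co3)) {
    sectors <- unlist(co[c("physician", "hospitalization", "drug", "rehab",
                           "assistive_devices", "home_care", "long_term_care")])
    expect_identical(co$total, sum(sectors))
  }
})

test_that("report writing is deterministic", {
  p <- const_bundle(m0 = 0.02, hr = 2, incidence = 0.1, min_age = 0L,
                    years = 2000:2010)
  r <- run_population(p, n_actors = 1000L, seed = 18)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_report(r, d1, years = 2005:2008)
  write_report(r, d2, years = 2005:2008)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  expect_true(all(c("prev.csv", "burden.csv", "cost.csv",
                    "run_summary.json") %in% list.files(d1)))
})
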