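test_that("scenario application is pure, composable and matches the footnotes", {
  p <- small_bundle()
  snap <- p$incidence$values
  s5 <- scenario("delayed", incidence_age_shift = 5)
  p5 <- apply_scenario(p, s5)
  # input untouched; shifted table: i'(70) = i(65)
  expect_identical(p$incidence$values, snap)
  expect_equal(rate_lookup(p5$incidence, 70, "male", 2011),
               rate_lookup(p$incidence, 65, "male", 2011))
  expect_equal(rate_lookup(p5$incidence, 44, "female", 2020), 0)

  # HR multiplier scales every effective cell by 0.9
  p9 <- apply_scenario(p, scenario("lower-hr", hr_multiplier = 0.9))
  expect_equal(p9$hazard_ratio$scenario_multiplier,
               0.9 * p$hazard_ratio$scenario_multiplier)

  # baseline is the identity and idempotent
  pb <- apply_scenario(apply_scenario(p, scenario("baseline")),
                       scenario("baseline"))
  expect_equal(pb, p)

  # growth variant switches the mortality improvement multiplier
  ph <- apply_scenario(p, scenario("hg", growth_variant = "high"))
  expect_identical(ph$mortality$growth_variant, "high")
  expect_lt(baseline_mortality(ph$mortality, 80, 1, 2035),
            baseline_mortality(p$mortality, 80, 1, 2035))

  expect_warning(apply_scenario(p, scenario("x", incidence_age_shift = 120)),
                 "zeroed")
})

test_that("delayed incidence never advances an onset and lowers prevalence", {
  p <- small_bundle()
  seeds <- build_actor_seeds(p$demography$cohorts, p$demography$migration,
                             15000L, seed = 21)
  rb <- run_population(p, actor_seeds = seeds, seed = 21)
  rd <- run_population(p, scenario("delayed", incidence_age_shift = 5),
                       actor_seeds = seeds, seed = 21)
  ob <- rb$actors$onset_time; od <- rd$actors$onset_time
  both <- which(!is.na(ob) & !is.na(od))
  expect_gt(length(both), 100)
  expect_true(all(od[both] >= ob[both]))        # exact, per actor
  expect_true(all(is.na(od) | !is.na(ob)))      # no onset unique to the delay
  # aggregate prevalence never exceeds baseline in any year
  evb <- rb$events; evd <- rd$events
  expect_true(all(evd$prevalent_jan1 <= evb$prevalent_jan1))
})

test_that("a lower dementia hazard never shortens a life", {
  p <- small_bundle()
  seeds <- build_actor_seeds(p$demography$cohorts, p$demography$migration,
                             15000L, seed = 22)
  rb <- run_population(p, actor_seeds = seeds, seed = 22)
  r9 <- run_population(p, scenario("lower-hr", hr_multiplier = 0.9),
                       actor_seeds = seeds, seed = 22)
  db <- rb$actors$death_time; d9 <- r9$actors$death_time
  e9 <- r9$actors$emigration_time
  has_b <- which(!is.na(db))
  # under the lower hazard the same actor either dies no earlier or is
  # censored by an emigration no earlier than the baseline death
  later <- ifelse(!is.na(d9[has_b]), d9[has_b], e9[has_b])
  expect_true(all(later >= db[has_b]))
})

test_that("the scenario suite shares streams and reports ratio directions", {
  p <- small_bundle()
  suite <- run_suite(p, list(scenario("baseline"),
                             scenario("lower-hr", hr_multiplier = 0.9)),
                     n_actors = 15000L, seed = 23, horizon = 2011:2031)
  base <- suite$aggregates$baseline
  low <- suite$aggregates$`lower-hr`
  # suite of {baseline} equals a direct run
  direct <- run_population(p, n_actors = 15000L, seed = 23,
                           horizon = 2011:2031)
  expect_identical(annual_aggregates(direct), base)
  # prevalent cases never drop under the lower hazard (exact per actor)
  expect_true(all(low$cases >= base$cases))
  expect_true(all(c("baseline", "lower-hr") %in% suite$ratios$scenario))
  expect_true(all(c("cases", "deaths") %in% suite$ratios$measure))
})
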