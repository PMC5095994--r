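test_that("rate lookup returns exact cells and clamps age and year", {
  v <- array(0.01, c(111L, 2L, 3L))
  v[76L, 2L, 1L] <- 0.02   # (age 75, female, first year)
  v[111L, 1L, ] <- 0.5
  tab <- age_sex_year_table(v, 2011:2013)
  expect_equal(rate_lookup(tab, 75, "female", 2011), 0.02)
  expect_equal(rate_lookup(tab, 115, "male", 2012), 0.5)      # age clamp
  expect_equal(rate_lookup(tab, 75, "female", 1990), 0.02)    # year clamp down
  expect_equal(rate_lookup(tab, 75, "female", 2050),
               rate_lookup(tab, 75, "female", 2013))          # year clamp up
  expect_error(rate_lookup(tab, -1, "male", 2011), "nonnegative")
})

test_that("hazard-to-probability conversion is exact, monotone and bounded", {
  expect_identical(rate_to_annual_prob(0), 0)
  expect_equal(rate_to_annual_prob(0.02), 1 - exp(-0.02), tolerance = 1e-13)
  expect_equal(rate_to_annual_prob(50), 1, tolerance = 1e-14)
  expect_error(rate_to_annual_prob(-0.1), "nonnegative")
  r <- seq(0, 10, by = 0.05)
  p <- rate_to_annual_prob(r)
  expect_true(all(diff(p) > 0))
  expect_true(all(p >= 0 & p < 1))
})

test_that("table validation names the offending cell and rule", {
  v <- array(0.01, c(111L, 2L, 1L))
  v[71L, 1L, 1L] <- -0.01
  expect_error(age_sex_year_table(v, 2011),
               "age 70, male, 2011.*nonnegative")
  v[71L, 1L, 1L] <- 1.5
  expect_error(age_sex_year_table(v, 2011, kind = "probability"),
               "\\[0, 1\\]")
})

test_that("synthesized bundles are deterministic and match closed forms", {
  cfg <- synth_config(birth_years = 1990:2000, years = 2011:2015,
                      incidence_at_65 = 0.01, incidence_doubling_years = 6)
  p1 <- synthesize_parameter_set(3, cfg)
  p2 <- synthesize_parameter_set(3, cfg)
  expect_identical(p1, p2)
  # doubling time: i(71) = 2 x i(65)
  expect_equal(rate_lookup(p1$incidence, 71, "male", 2011), 0.02,
               tolerance = 1e-12)
  expect_equal(rate_lookup(p1$incidence, 65, "female", 2011), 0.01)
  # Gompertz mortality strictly increasing in age until the cap
  m <- p1$mortality$reference[, 1L]
  uncapped <- m < 1
  expect_true(all(diff(m[uncapped]) > 0))
  # incidence zero below minimum age, non-decreasing above
  inc <- p1$incidence$values[, 1L, 1L]
  expect_true(all(inc[1:40] == 0))
  expect_true(all(diff(inc[41:111]) >= 0))
  expect_error(synthesize_parameter_set(1, synth_config(gompertz_beta = -1)),
               "config error")
})

test_that("a saved bundle loads back identically (bit-exact round trip)", {
  p <- synthesize_parameter_set(2, synth_config(birth_years = 1990:2000,
                                                years = 2011:2015))
  d <- withr::local_tempdir()
  save_parameter_set(p, d)
  p2 <- load_parameter_set(d)
  expect_identical(p$incidence$values, p2$incidence$values)
  expect_identical(p$mortality$reference, p2$mortality$reference)
  expect_identical(p$hui3$mean, p2$hui3$mean)
  expect_identical(p$costs$annual_cost, p2$costs$annual_cost)
  expect_identical(p$demography$cohorts$births, p2$demography$cohorts$births)
  expect_equal(p, p2)
})

test_that("bundle loading reports missing inputs and invalid cells", {
  p <- synthesize_parameter_set(2, synth_config(birth_years = 1990:2000,
                                                years = 2011:2015))
  d <- withr::local_tempdir()
  save_parameter_set(p, d)

  # invalid incidence cell named in the error
  inc <- read.csv(file.path(d, "incidence.csv"))
  inc$value[inc$age == 70 & inc$sex == "male" & inc$year == 2011] <- -0.01
  write.csv(inc, file.path(d, "incidence.csv"), row.names = FALSE, quote = FALSE)
  expect_error(load_parameter_set(d), "age 70, male, 2011")

  # missing sector
  save_parameter_set(p, d)
  co <- read.csv(file.path(d, "costs.csv"))
  write.csv(co[co$sector != "long_term_care", ], file.path(d, "costs.csv"),
            row.names = FALSE, quote = FALSE)
  expect_error(load_parameter_set(d), "missing input: long_term_care")

  # missing table file
  save_parameter_set(p, d)
  unlink(file.path(d, "hui3.csv"))
  expect_error(load_parameter_set(d), "missing input: hui3")
})
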