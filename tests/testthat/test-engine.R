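test_that("piecewise cumulative-hazard inversion is exact", {
  # constant hazard: t* = E / h
  expect_equal(sample_death_age(rep(0.0693, 120), 0.693), 10.0,
               tolerance = 1e-12)
  # doubling all hazards halves the death age
  expect_equal(sample_death_age(rep(2 * 0.0693, 120), 0.693), 5.0,
               tolerance = 1e-12)
  # threshold beyond the total cumulative hazard: death at the cap
  expect_equal(sample_death_age(rep(0.001, 111), 5), 111)
  expect_equal(sample_death_age(rep(0, 111), 1), 111)
  # two-segment path, hand inversion: H(3) = 0.3, then h = 0.2
  # E = 0.5 -> t* = 3 + 0.2 / 0.2 = 4
  expect_equal(sample_death_age(c(rep(0.1, 3), rep(0.2, 100)), 0.5), 4.0,
               tolerance = 1e-12)
  expect_error(sample_death_age(c(-0.1, 0.2), 1), "nonnegative")
  expect_error(sample_death_age(0.1, 0), "positive")
})

test_that("HYLL path arithmetic matches hand sums", {
  expect_identical(hyll_from_paths(c(0.5, 0.5), c(1, 1), c(0.5, 0.5), c(1, 1)), 0)
  # factual 3 years at 0.4; counterfactual those 3 at 0.8 plus 2 more at 0.8
  expect_equal(hyll_from_paths(rep(0.4, 3), rep(1, 3),
                               rep(0.8, 5), rep(1, 5)), 2.8)
  # utility 1 in both states: HYLL equals the difference in years lived
  expect_equal(hyll_from_paths(rep(1, 4), c(1, 1, 1, 0.25),
                               rep(1, 6), c(1, 1, 1, 1, 1, 0.25)), 2)
})

test_that("onset draws honour zero, saturating and geometric regimes", {
  # zero incidence: no onsets ever
  p0 <- const_bundle(incidence = 0)
  r0 <- run_population(p0, n_actors = 2000L, seed = 5)
  expect_true(all(is.na(r0$actors$onset_time)))

  # saturating incidence: every actor alive at an eligible January 1 onsets
  pbig <- const_bundle(m0 = 1e-12, hr = 1, incidence = 50, min_age = 0L)
  rbig <- run_population(pbig, n_actors = 2000L, seed = 5)
  expect_true(all(!is.na(rbig$actors$onset_time)))
  # first eligible January 1 is the year after birth (age 0 at that Jan 1)
  expect_true(all(floor(rbig$actors$onset_time) == 2001))

  # constant incidence, no mortality: onset-year counts are geometric
  pg <- const_bundle(m0 = 1e-12, hr = 1, incidence = 0.05, min_age = 0L,
                     births = 1e5, years = 2000:2060)
  n <- 50000L
  rg <- run_population(pg, n_actors = n, seed = 6)
  yr_onset <- floor(rg$actors$onset_time) - 2001
  p <- 1 - exp(-0.05)
  for (k in 0:9) {
    expected <- n * p * (1 - p)^k
    se <- sqrt(n * p * (1 - p)^k * (1 - p * (1 - p)^k))
    expect_lt(abs(sum(yr_onset == k, na.rm = TRUE) - expected), 3 * se)
  }
})

test_that("constant-hazard lifecourses recover the YLL closed form", {
  # m0 = 0.1, HR = 2, onset at birth: factual death ~ Exp at rate 0.2, the
  # counterfactual at rate 0.1, and YLL = E/0.1 - E/0.2 equals the factual
  # death age actor by actor
  p <- const_bundle(m0 = 0.1, hr = 2, max_age = 110L, years = 2000:2030)
  r <- run_population(p, n_actors = 5000L, seed = 7, onset_mode = "at_birth")
  ac <- r$actors
  uncapped <- ac$death_time_cf - ac$birth_time < 109
  expect_gt(mean(uncapped), 0.99)
  age_f <- (ac$death_time - ac$birth_time)[uncapped]
  expect_equal(ac$yll[uncapped], age_f, tolerance = 1e-8)
  # counterfactual never dies first while HR >= 1
  expect_true(all(ac$death_time_cf >= ac$death_time))
})

test_that("same seed gives identical runs regardless of actor order", {
  p <- small_bundle()
  seeds <- build_actor_seeds(p$demography$cohorts, p$demography$migration,
                             3000L, seed = 8)
  r1 <- run_population(p, actor_seeds = seeds, seed = 8)
  r2 <- run_population(p, actor_seeds = seeds, seed = 8)
  expect_identical(r1$actors, r2$actors)
  expect_identical(r1$years, r2$years)
  expect_identical(r1$events, r2$events)
  # permuted actor order: identical outputs (draws are keyed, not sequential)
  perm <- seeds[sample.int(nrow(seeds)), ]
  r3 <- run_population(p, actor_seeds = perm, seed = 8)
  expect_identical(r1$actors, r3$actors)
  expect_identical(r1$years, r3$years)
  expect_identical(r1$events, r3$events)
})

test_that("the event log balances prevalence flows exactly", {
  p <- small_bundle()
  r <- run_population(p, n_actors = 5000L, seed = 9)
  ev <- r$events
  for (t in seq_len(nrow(ev) - 1L)) {
    expect_identical(ev$prevalent_jan1[t + 1L],
                     ev$prevalent_jan1[t] + ev$onsets[t] -
                       ev$deaths_dementia[t] - ev$emigrants_dementia[t])
  }
})

test_that("annual HUI3 values stay on the HUI3 scale", {
  p <- small_bundle()
  r <- run_population(p, n_actors = 3000L, seed = 10)
  expect_true(all(r$years$hui3 >= -0.36 & r$years$hui3 <= 1))
  expect_true(all(r$years$frac_incident <= r$years$frac_dementia + 1e-12))
  expect_true(all(r$years$frac_dementia <= r$years$frac_present + 1e-12))
  # the 12 incident months split across calendar years sum to one year
  yr <- r$years
  ac <- r$actors
  end_t <- pmin(ac$death_time, ac$emigration_time, na.rm = TRUE)
  end_t[is.na(end_t)] <- Inf
  full <- ac$id[which(!is.na(ac$onset_time) & end_t > ac$onset_time + 1 &
                        ac$onset_time >= min(r$meta$horizon) &
                        ac$onset_time + 1 <= max(r$meta$horizon))]
  inc_sum <- tapply(yr$frac_incident[yr$id %in% full], yr$id[yr$id %in% full], sum)
  expect_equal(as.numeric(inc_sum), rep(1, length(inc_sum)), tolerance = 1e-9)
})

test_that("emigration censors the factual lifecourse", {
  p <- const_bundle(m0 = 0.02, hr = 2, incidence = 0.05, min_age = 0L,
                    emigration = 0.05, years = 2000:2050)
  r <- run_population(p, n_actors = 4000L, seed = 11)
  ac <- r$actors
  em <- !is.na(ac$emigration_time)
  expect_gt(sum(em), 0)
  expect_true(all(is.na(ac$death_time[em])))
  # YLL censored for emigrants with onset, zero without onset
  expect_true(all(is.na(ac$yll[em & !is.na(ac$onset_time)])))
  expect_true(all(ac$yll[is.na(ac$onset_time)] == 0))
})
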