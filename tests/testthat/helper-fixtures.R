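# Fixtures are built in code; heavier shared runs are cached per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# desk-scale synthetic world: short cohort span, 30-year reporting horizon
small_bundle <- function() {
  cached("small_bundle",
         synthesize_parameter_set(1, synth_config(birth_years = 1900:2040,
                                                  years = 2011:2040)))
}

# single closed cohort with constant rates everywhere: the closed-form world.
# mortality m0 at every age/year (no improvement), hazard ratio hr, optional
# constant incidence from min_age, status-specific constant HUI3, no
# migration unless an emigration rate is given.
const_bundle <- function(m0 = 0.1, hr = 2, incidence = 0, min_age = 0L,
                         hui3_none = 0.8, hui3_dem = 0.8, hui3_sd = 0,
                         emigration = 0, cohort_year = 2000L, births = 1000,
                         years = 2000:2030, max_age = 110L,
                         receipt = c(none = 0, dementia = 0)) {
  inc <- array(0, c(111L, 2L, length(years)))
  if (incidence > 0) inc[(min_age + 1L):111L, , ] <- incidence
  hmean <- array(c(rep(hui3_none, 222L), rep(hui3_dem, 222L)), c(111L, 2L, 2L))
  parameter_set(
    incidence = age_sex_year_table(inc, years),
    mortality = mortality_model(m0, reference_year = min(years), improvement = 0),
    hazard_ratio = hazard_ratio_spec(hr, years),
    hui3 = hui3_table(hmean, hui3_sd),
    caregiving = caregiving_model(
      array(rep(c(receipt[["none"]], receipt[["dementia"]]), each = 3L),
            c(3L, 2L, 3L))),
    costs = cost_schedule(array(rep(c(1500, 1000), each = 7L),
                                c(7L, 2L, 1L, 1L))[, , c(1L, 1L, 1L),
                                                   c(1L, 1L), drop = FALSE],
                          out_of_pocket = matrix(c(0, 500), 3L, 2L,
                                                 byrow = TRUE)),
    demography = list(
      cohorts = cohort_schedule(matrix(c(births / 2, births / 2), 1L, 2L),
                                cohort_year),
      migration = migration_schedule(0, years, emigration_rate = emigration)),
    years = years, min_incidence_age = min_age, max_age = max_age)
}

# shared 200k-actor baseline run on the synthetic world plus its oracle;
# reused by the oracle-equivalence and calibration checks
big_run <- function() {
  cached("big_run", {
    p <- small_bundle()
    list(params = p,
         result = run_population(p, n_actors = 200000L, seed = 101L),
         oracle = run_oracle(p))
  })
}
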