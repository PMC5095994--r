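#' Configuration for the synthetic-parameter generator
#'
#' Shape parameters for [synthesize_parameter_set()]. Defaults describe a
#' Canada-like open population and dementia process at desk scale: Gompertz
#' baseline mortality (`m(a) = alpha * exp(beta * a)`, capped at 1/yr) with
#' 1%/yr improvement; dementia incidence zero below the minimum age, then
#' exponentially increasing from the age-65 anchor with a fixed doubling
#' time and a plateau cap at the oldest ages; HUI3 declining linearly in age
#' with a constant dementia decrement; caregiving receipt at the reported
#' 77% level among people with dementia; sector cost levels proportioned to
#' the published 2011 sector totals per prevalent person.
#'
#' @param ... overrides of any default listed below.
#' @return named list of generator settings.
#' @export
synth_config <- function(...) {
  cfg <- list(
    years = 2001:2041,            # reporting horizon of the bundle
    birth_years = 1872:2041,      # historic cohorts through projected births
    births_base = 130000,         # births in the first cohort year
    births_growth = 0.0077,       # exponential growth of annual births
    male_fraction = 0.512,
    immigration_start = 20000,    # annual immigrants, ramping linearly ...
    immigration_2011 = 250000,    # ... to this level by 2011, flat after
    immigration_age_probs = c(0.20, 0.60, 0.15, 0.05),
    arrival_age_breaks = c(0, 18, 45, 65, 111),
    emigration_rate = 0.002,      # per person-year, flat
    gompertz_alpha = 2e-5,        # mortality at age 0 scale
    gompertz_beta = 0.1,          # log-slope per year of age
    mortality_cap = 1.0,          # hazard cap, per person-year
    improvement = 0.01,           # annual log-decline of mortality
    reference_year = 2006,
    variant_multipliers = c(low = 0.5, mid = 1, high = 1.5),
    min_incidence_age = 40,
    incidence_at_65 = 0.004,      # per person-year
    incidence_doubling_years = 6,
    incidence_cap = 0.25,         # plateau at the oldest ages
    hazard_ratio = 2.5,           # dementia excess mortality
    hui3_at_40 = 0.95,
    hui3_slope = 0.0025,          # decline per year of age above 40
    hui3_dementia_decrement = 0.30,
    hui3_sd = 0.05,               # truncated-normal noise; 0 = deterministic
    receipt_prob_dementia = 0.77, # 2011 informal-care receipt level
    receipt_prob_none = 0.02,
    cost_per_prevalent = c(physician = 2141, hospitalization = 7529,
                           drug = 2941, rehab = 250, assistive_devices = 235,
                           home_care = 1706, long_term_care = 12235),
    incident_cost_multiplier = 1.5,
    oop_dementia = 1500,
    oop_none = 100,
    max_age = 110
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown synth_config fields: ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Synthesize a complete parameter bundle
#'
#' Builds a [parameter_set()] from closed-form curves controlled by
#' [synth_config()]; a stand-in for national rate tables with the same shape
#' (Gompertz-like mortality, late-life-rising incidence, age-declining HUI3
#' with a dementia decrement). Deterministic: identical `(seed, config)` give
#' identical bundles, including after a save/load round trip.
#'
#' @param seed integer recorded in the bundle name and used for any future
#'   stochastic generator features (the current curves are deterministic).
#' @param config a [synth_config()].
#' @return a validated [parameter_set()].
#' @examples
#' p <- synthesize_parameter_set(1, synth_config(birth_years = 1950:2040))
#' rate_lookup(p$incidence, 71, "male", 2011) # 2 x the age-65 anchor
#' @export
synthesize_parameter_set <- function(seed = 1L, config = synth_config()) {
  cfg <- config
  if (cfg$gompertz_beta <= 0)
    stop("config error: Gompertz beta must be positive")
  years <- as.integer(cfg$years)
  ages <- 0:110

  # mortality: Gompertz, capped, equal across sexes at reference year
  m_ref <- pmin(cfg$mortality_cap, cfg$gompertz_alpha * exp(cfg$gompertz_beta * ages))
  mort <- mortality_model(matrix(m_ref, 111L, 2L), cfg$reference_year,
                          cfg$improvement, cfg$variant_multipliers, "mid")

  # incidence: 0 below the minimum age, exponential doubling above, capped
  inc_a <- ifelse(ages < cfg$min_incidence_age, 0,
                  pmin(cfg$incidence_cap,
                       cfg$incidence_at_65 *
                         2 ^ ((ages - 65) / cfg$incidence_doubling_years)))
  inc <- age_sex_year_table(array(inc_a, c(111L, 2L, length(years))), years)

  hr <- hazard_ratio_spec(cfg$hazard_ratio, years)

  h_none <- hui3_clip(cfg$hui3_at_40 - cfg$hui3_slope * pmax(0, ages - 40))
  h_dem <- hui3_clip(h_none - cfg$hui3_dementia_decrement)
  hui <- hui3_table(array(c(rep(h_none, 2L), rep(h_dem, 2L)), c(111L, 2L, 2L)),
                    cfg$hui3_sd)

  care <- caregiving_model(
    array(rep(c(cfg$receipt_prob_none, cfg$receipt_prob_dementia), each = 3L),
          c(3L, 2L, 3L)))

  costs <- cost_schedule(
    array(c(cfg$cost_per_prevalent[cost_sectors] * cfg$incident_cost_multiplier,
            cfg$cost_per_prevalent[cost_sectors]),
          c(7L, 2L, 1L, 1L))[, , rep(1L, 3L), c(1L, 1L), drop = FALSE],
    out_of_pocket = matrix(c(cfg$oop_none, cfg$oop_dementia), 3L, 2L,
                           byrow = TRUE))

  by <- as.integer(cfg$birth_years)
  births <- cfg$births_base * exp(cfg$births_growth * (by - by[1L]))
  cohorts <- cohort_schedule(
    cbind(births * cfg$male_fraction, births * (1 - cfg$male_fraction)), by)

  ramp <- pmin(1, pmax(0, (by - by[1L]) / max(1, 2011 - by[1L])))
  imm_tot <- cfg$immigration_start + ramp * (cfg$immigration_2011 - cfg$immigration_start)
  n_grp <- length(cfg$arrival_age_breaks) - 1L
  imm <- array(0, c(length(by), 2L, n_grp))
  for (g in seq_len(n_grp)) {
    imm[, 1L, g] <- imm_tot * cfg$immigration_age_probs[g] * cfg$male_fraction
    imm[, 2L, g] <- imm_tot * cfg$immigration_age_probs[g] * (1 - cfg$male_fraction)
  }
  emi <- age_sex_year_table(cfg$emigration_rate, by)
  migration <- migration_schedule(imm, by, cfg$arrival_age_breaks, emi)

  parameter_set(inc, mort, hr, hui, care, costs,
                list(cohorts = cohorts, migration = migration),
                name = sprintf("synthetic-%d", as.integer(seed)),
                years = years, min_incidence_age = cfg$min_incidence_age,
                max_age = cfg$max_age)
}
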