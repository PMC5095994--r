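#' Baseline mortality with secular improvement
#'
#' Baseline (dementia-free) mortality is a reference age/sex schedule at a
#' reference year, declining exponentially in calendar time at a per-age-sex
#' improvement rate `rho` (a reduced form of the Lee-Carter projection that
#' national statistical agencies feed into population projections):
#' `m0(a,s,t) = ref(a,s) * exp(-rho(a,s) * mult * (t - reference_year))`,
#' where `mult` is the growth-variant multiplier (low/mid/high life-expectancy
#' scenarios act through it).
#'
#' @param reference 111 x 2 matrix (age 0--110 x sex) of strictly positive
#'   hazards (per person-year) at `reference_year`, or a single number.
#' @param reference_year calendar year the reference schedule refers to.
#' @param improvement 111 x 2 matrix of annual log-decline rates `rho >= 0`,
#'   or a single number.
#' @param variant_multipliers named multipliers for the low/mid/high
#'   life-expectancy growth variants.
#' @param growth_variant which variant is in force.
#' @return an object of class `mortality_model`.
#' @export
mortality_model <- function(reference, reference_year = 2006L,
                            improvement = 0.01,
                            variant_multipliers = c(low = 0.5, mid = 1, high = 1.5),
                            growth_variant = c("mid", "low", "high")) {
  growth_variant <- match.arg(growth_variant)
  if (length(reference) == 1L) reference <- matrix(reference, 111L, 2L)
  if (length(improvement) == 1L) improvement <- matrix(improvement, 111L, 2L)
  reference <- unname(as.matrix(reference)); improvement <- unname(as.matrix(improvement))
  stopifnot(identical(dim(reference), c(111L, 2L)),
            identical(dim(improvement), c(111L, 2L)))
  if (any(reference <= 0))
    stop("mortality reference rates must be strictly positive")
  if (any(improvement < 0))
    stop("mortality improvement rates must be nonnegative")
  if (!all(c("low", "mid", "high") %in% names(variant_multipliers)))
    stop("variant_multipliers must name low, mid and high")
  structure(list(reference = reference,
                 reference_year = as.integer(reference_year),
                 improvement = improvement,
                 variant_multipliers = variant_multipliers[c("low", "mid", "high")],
                 growth_variant = growth_variant),
            class = "mortality_model")
}

#' Excess-mortality hazard ratio for dementia
#'
#' Mortality for a person with dementia is the product of the baseline rate
#' and a hazard ratio; the ratio may vary by age, sex and year (default
#' constant) and carries a scenario multiplier (1 = baseline).
#'
#' @param hr an [age_sex_year_table()] of nonnegative multipliers, or a single
#'   number with `years` giving the span.
#' @param years year span when `hr` is scalar.
#' @param scenario_multiplier positive scaling applied on top of the table.
#' @return an object of class `hazard_ratio_spec`.
#' @export
hazard_ratio_spec <- function(hr, years = NULL, scenario_multiplier = 1) {
  if (!inherits(hr, "asy_table")) {
    if (is.null(years)) stop("years required when hr is scalar")
    hr <- age_sex_year_table(hr, years, units = "ratio", kind = "hazard")
  }
  if (scenario_multiplier <= 0) stop("scenario_multiplier must be positive")
  structure(list(hr = hr, scenario_multiplier = scenario_multiplier),
            class = "hazard_ratio_spec")
}

effective_hr <- function(spec, age, sex, year) {
  rate_lookup(spec$hr, age, sex, year) * spec$scenario_multiplier
}

#' Health Utilities Index (HUI3) schedule
#'
#' Mean HUI3 per (age, sex, dementia status), plus a per-cell standard
#' deviation for truncated-normal sampling; draws are clipped to the HUI3
#' scale `[-0.36, 1]` (states worse than death through perfect health).
#' `sd = 0` makes the assignment deterministic at the cell mean.
#'
#' @param mean 111 x 2 x 2 array (age x sex x status none/dementia) of means
#'   in `[-0.36, 1]`, or a single number.
#' @param sd matching array of nonnegative standard deviations, or a number.
#' @return an object of class `hui3_table`.
#' @export
hui3_table <- function(mean, sd = 0) {
  if (length(mean) == 1L) mean <- array(mean, c(111L, 2L, 2L))
  if (length(sd) == 1L) sd <- array(sd, c(111L, 2L, 2L))
  mean <- unname(mean); sd <- unname(sd)
  stopifnot(identical(dim(mean), c(111L, 2L, 2L)),
            identical(dim(sd), c(111L, 2L, 2L)))
  if (any(mean < -0.36 | mean > 1))
    stop("HUI3 means must lie in [-0.36, 1]")
  if (any(sd < 0)) stop("HUI3 sd must be nonnegative")
  structure(list(mean = mean, sd = sd), class = "hui3_table")
}

hui3_clip <- function(x) pmin(1, pmax(-0.36, x))

#' Informal-caregiving model
#'
#' Receipt of informal care is a Bernoulli draw whose probability depends on
#' age group, dementia status and HUI3 band; recipients draw a weekly-hours
#' category and are assigned a caregiver HUI3 and caregiver out-of-pocket
#' cost. Hour bins partition the line with half-open integer edges
#' (none, <7, 7-14, 15-70, >= 71 hours/week).
#'
#' @param receipt_prob array `n_age_groups x 2 x n_hui3_bands` of receipt
#'   probabilities (dimension 2 is none/dementia), or a single number.
#' @param age_breaks increasing break points defining age groups
#'   (`c(0, 65, 80, Inf)` gives 0-64, 65-79, 80+).
#' @param hui3_breaks increasing break points over `[-0.36, 1]` defining HUI3
#'   bands (last band closed above).
#' @param hours_probs named probabilities over the weekly-hour bins
#'   `none, lt7, h7_14, h15_70, ge71`; must sum to 1.
#' @param rep_hours representative weekly hours per bin.
#' @param caregiver_hui3_mean mean HUI3 assigned to caregivers.
#' @param caregiver_oop caregiver out-of-pocket cost, currency/year.
#' @return an object of class `caregiving_model`.
#' @export
caregiving_model <- function(receipt_prob,
                             age_breaks = c(0, 65, 80, Inf),
                             hui3_breaks = c(-0.36, 0.5, 0.8, 1),
                             hours_probs = c(none = 0, lt7 = 0.001, h7_14 = 0.002,
                                             h15_70 = 0.345, ge71 = 0.652),
                             rep_hours = c(none = 0, lt7 = 3.5, h7_14 = 10.5,
                                           h15_70 = 40, ge71 = 80),
                             caregiver_hui3_mean = 0.85,
                             caregiver_oop = 1000) {
  bins <- c("none", "lt7", "h7_14", "h15_70", "ge71")
  n_age <- length(age_breaks) - 1L
  n_band <- length(hui3_breaks) - 1L
  if (length(receipt_prob) == 1L)
    receipt_prob <- array(receipt_prob, c(n_age, 2L, n_band))
  receipt_prob <- unname(receipt_prob)
  stopifnot(identical(dim(receipt_prob), c(n_age, 2L, n_band)))
  if (any(receipt_prob < 0 | receipt_prob > 1))
    stop("receipt_prob must lie in [0, 1]")
  hours_probs <- hours_probs[bins]; rep_hours <- rep_hours[bins]
  if (anyNA(hours_probs) || anyNA(rep_hours))
    stop("hours_probs and rep_hours must name bins ", paste(bins, collapse = ", "))
  if (abs(sum(hours_probs) - 1) > 1e-9)
    stop("hours_probs must sum to 1 (within 1e-9)")
  if (caregiver_hui3_mean < -0.36 || caregiver_hui3_mean > 1)
    stop("caregiver_hui3_mean must lie in [-0.36, 1]")
  if (caregiver_oop < 0) stop("caregiver_oop must be nonnegative")
  structure(list(receipt_prob = receipt_prob, age_breaks = age_breaks,
                 hui3_breaks = hui3_breaks, hours_probs = hours_probs,
                 rep_hours = rep_hours, caregiver_hui3_mean = caregiver_hui3_mean,
                 caregiver_oop = caregiver_oop),
            class = "caregiving_model")
}

care_bins <- c("none", "lt7", "h7_14", "h15_70", "ge71")

age_group_labels <- function(breaks) {
  lo <- breaks[-length(breaks)]; hi <- breaks[-1]
  ifelse(is.finite(hi), paste0(lo, "-", hi - 1), paste0(lo, "+"))
}

age_group_index <- function(breaks, age) {
  pmin(findInterval(age, breaks), length(breaks) - 1L)
}

hui3_band_index <- function(breaks, hui3) {
  pmin(pmax(findInterval(hui3, breaks), 1L), length(breaks) - 1L)
}

#' Sectoral health-care cost schedule
#'
#' Annual direct costs among people with dementia for the seven health
#' sectors, split into an incident phase (the 12 months following onset) and
#' a prevalent phase (thereafter), by age group and sex; plus out-of-pocket
#' costs by age group and dementia status.
#'
#' @param annual_cost array `7 x 2 x n_age_groups x 2`
#'   (sector x phase incident/prevalent x age group x sex) of nonnegative
#'   currency/year values, or a single number.
#' @param age_breaks increasing break points defining the age groups.
#' @param out_of_pocket `n_age_groups x 2` matrix (age group x none/dementia),
#'   or a single number.
#' @return an object of class `cost_schedule`.
#' @export
cost_schedule <- function(annual_cost, age_breaks = c(0, 65, 80, Inf),
                          out_of_pocket = 0) {
  n_age <- length(age_breaks) - 1L
  if (length(annual_cost) == 1L)
    annual_cost <- array(annual_cost, c(7L, 2L, n_age, 2L))
  annual_cost <- unname(annual_cost)
  stopifnot(identical(dim(annual_cost), c(7L, 2L, n_age, 2L)))
  if (length(out_of_pocket) == 1L)
    out_of_pocket <- matrix(out_of_pocket, n_age, 2L)
  out_of_pocket <- unname(as.matrix(out_of_pocket))
  stopifnot(identical(dim(out_of_pocket), c(n_age, 2L)))
  if (any(annual_cost < 0) || any(out_of_pocket < 0))
    stop("costs must be nonnegative")
  structure(list(annual_cost = annual_cost, age_breaks = age_breaks,
                 out_of_pocket = out_of_pocket),
            class = "cost_schedule")
}

cost_sectors <- c("physician", "hospitalization", "drug", "rehab",
                  "assistive_devices", "home_care", "long_term_care")

#' Bundle every model input into one parameter set
#'
#' A `parameter_set` is the complete collection of rate tables and schedules
#' that drives one simulation: dementia incidence, baseline mortality with
#' improvement, the dementia mortality hazard ratio, HUI3, caregiving, costs
#' and the demographic schedules, plus metadata (year span of the reporting
#' horizon, minimum incidence age, age cap, currency year).
#'
#' @param incidence [age_sex_year_table()] of dementia incidence
#'   (per person-year among the dementia-free).
#' @param mortality a [mortality_model()].
#' @param hazard_ratio a [hazard_ratio_spec()].
#' @param hui3 a [hui3_table()].
#' @param caregiving a [caregiving_model()].
#' @param costs a [cost_schedule()].
#' @param demography list with a [cohort_schedule()] (`cohorts`) and a
#'   [migration_schedule()] (`migration`).
#' @param name bundle name.
#' @param years reporting horizon (contiguous calendar years).
#' @param currency_year year costs are expressed in.
#' @param min_incidence_age youngest age with nonzero dementia incidence.
#' @param max_age age cap: no survival beyond the calendar year in which the
#'   January-1 age reaches this value.
#' @return an object of class `demsim_params`.
#' @export
parameter_set <- function(incidence, mortality, hazard_ratio, hui3, caregiving,
                          costs, demography, name = "bundle",
                          years = NULL, currency_year = 2011L,
                          min_incidence_age = 40L, max_age = 110L) {
  years <- as.integer(years %||% incidence$years)
  p <- structure(list(
    incidence = incidence, mortality = mortality, hazard_ratio = hazard_ratio,
    hui3 = hui3, caregiving = caregiving, costs = costs, demography = demography,
    metadata = list(name = name, years = years,
                    currency_year = as.integer(currency_year),
                    min_incidence_age = as.integer(min_incidence_age),
                    max_age = as.integer(max_age))),
    class = "demsim_params")
  validate_parameter_set(p)
  p
}

validate_parameter_set <- function(p) {
  stopifnot(inherits(p$incidence, "asy_table"),
            inherits(p$mortality, "mortality_model"),
            inherits(p$hazard_ratio, "hazard_ratio_spec"),
            inherits(p$hui3, "hui3_table"),
            inherits(p$caregiving, "caregiving_model"),
            inherits(p$costs, "cost_schedule"))
  validate_asy_table(p$incidence, "incidence")
  yrs <- p$metadata$years
  for (nm in c("incidence")) {
    tb <- p[[nm]]
    if (min(tb$years) > min(yrs) || max(tb$years) < max(yrs))
      stop(sprintf("%s year span (%d-%d) does not cover the horizon (%d-%d)",
                   nm, min(tb$years), max(tb$years), min(yrs), max(yrs)))
  }
  ma <- p$metadata$min_incidence_age
  if (ma > 0 && any(p$incidence$values[seq_len(min(ma, 111L)), , ] != 0))
    stop(sprintf("incidence must be 0 below the minimum incidence age (%d)", ma))
  invisible(p)
}

#' @export
print.demsim_params <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("<demsim_params> '%s': horizon %d-%d, incidence from age %d, age cap %d\n",
              m$name, min(m$years), max(m$years), m$min_incidence_age, m$max_age))
  cat(sprintf("  growth variant: %s; HR multiplier: %g; currency year: %d\n",
              x$mortality$growth_variant, x$hazard_ratio$scenario_multiplier,
              m$currency_year))
  invisible(x)
}
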