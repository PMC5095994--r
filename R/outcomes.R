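# Aggregation of lifecourses into annual population-level measures:
# prevalence counts and rates, deaths and mortality rate, mean YLL/HYLL among
# decedents, caregiving volumes and hour-bin distributions, sectoral costs.

present_at <- function(actors, t) {
  actors$entry_time <= t &
    (is.na(actors$death_time) | actors$death_time > t) &
    (is.na(actors$emigration_time) | actors$emigration_time > t)
}

check_year <- function(result, year) {
  if (!(year %in% result$meta$horizon))
    stop(sprintf("year %d outside the simulation horizon (%d-%d)", year,
                 min(result$meta$horizon), max(result$meta$horizon)))
}

#' Point prevalence of dementia
#'
#' Weighted persons living with dementia at the July 1 (mid-year) reference
#' date of `year`, with rates per 1000 population for the "age 40 and older"
#' and "age 80 and older" strata, by sex and in total.
#'
#' @param result a [run_population()] result.
#' @param year calendar year inside the simulation horizon.
#' @return data.frame with rows male/female/total: weighted `cases` (all
#'   ages), stratum populations and `rate40`/`rate80` per 1000.
#' @export
point_prevalence <- function(result, year) {
  check_year(result, year)
  ac <- result$actors
  t <- year + 0.5
  pres <- present_at(ac, t)
  case <- pres & !is.na(ac$onset_time) & ac$onset_time <= t
  age <- floor(t - ac$birth_time)
  out <- lapply(c(male = 1, female = 2, total = 0), function(s) {
    sel <- if (s == 0) pres else pres & ac$sex == s
    csel <- if (s == 0) case else case & ac$sex == s
    w <- ac$weight
    p40 <- sum(w[sel & age >= 40]); c40 <- sum(w[csel & age >= 40])
    p80 <- sum(w[sel & age >= 80]); c80 <- sum(w[csel & age >= 80])
    data.frame(cases = sum(w[csel]),
               pop40 = p40, rate40 = ifelse(p40 > 0, c40 / p40 * 1000, NA_real_),
               pop80 = p80, rate80 = ifelse(p80 > 0, c80 / p80 * 1000, NA_real_))
  })
  cbind(data.frame(year = year, sex = names(out)),
        do.call(rbind, out), row.names = NULL)
}

#' Ratio of a measure between two years
#'
#' Horizon-to-base growth ratio, reported to 2 decimals.
#'
#' @param base value at the base year (> 0).
#' @param horizon value at the horizon year.
#' @return `round(horizon / base, 2)`.
#' @examples
#' growth_ratio(340000, 674000) # 1.98
#' @export
growth_ratio <- function(base, horizon) {
  if (any(base <= 0)) stop("undefined ratio: base value must be positive")
  round(horizon / base, 2)
}

#' Deaths, mortality rate and YLL/HYLL among dementia decedents
#'
#' Deaths are weighted persons with dementia dying in `year`; the mortality
#' rate divides them by the July 1 point prevalence (per 1000); mean YLL and
#' HYLL are weighted means over that year's dementia decedents.
#'
#' @inheritParams point_prevalence
#' @return one-row data.frame: `deaths`, `rate_per_1000` (NA with
#'   `rate_undefined = TRUE` when prevalence is zero), `mean_yll`,
#'   `mean_hyll`.
#' @export
mortality_summary <- function(result, year) {
  check_year(result, year)
  ac <- result$actors
  dec <- !is.na(ac$death_time) & ac$death_time > year & ac$death_time <= year + 1 &
    !is.na(ac$onset_time) & ac$onset_time <= ac$death_time
  deaths <- sum(ac$weight[dec])
  prev <- point_prevalence(result, year)
  cases <- prev$cases[prev$sex == "total"]
  undef <- cases == 0 && deaths > 0
  data.frame(
    year = year, deaths = deaths,
    rate_per_1000 = if (cases > 0) deaths / cases * 1000 else NA_real_,
    rate_undefined = undef,
    mean_yll = if (any(dec)) sum((ac$weight * ac$yll)[dec]) / sum(ac$weight[dec])
               else NA_real_,
    mean_hyll = if (any(dec)) sum((ac$weight * ac$hyll)[dec]) / sum(ac$weight[dec])
                else NA_real_)
}

#' Informal-caregiving volumes and hour-bin distribution
#'
#' Recipients are weighted persons with dementia assigned care for the year;
#' total hours multiply representative weekly hours by 52; hours per
#' working-age person divide by the weighted mid-year population aged 25-65
#' inclusive; bin percentages (including "receiving no care") are over all
#' persons with dementia that year and sum to 100.
#'
#' @inheritParams point_prevalence
#' @return one-row data.frame: `recipients`, `hours_per_year`,
#'   `hours_per_working_age`, percentage columns `pct_none`, `pct_lt7`,
#'   `pct_7_14`, `pct_15_70`, `pct_ge71`, and caregiver-side totals
#'   (`caregiver_hours`, `caregiver_oop`, `caregiver_mean_hui3`).
#' @export
caregiving_summary <- function(result, year) {
  check_year(result, year)
  yr <- result$years[result$years$year == year & result$years$dementia, ]
  ac <- result$actors
  w <- result$meta$weight
  cgm <- result$schedules$caregiving
  rep_hours <- cgm$rep_hours
  n_dem <- nrow(yr)
  rec <- yr$care_bin > 0
  hours <- sum(w * rep_hours[yr$care_bin[rec] + 1L] * 52)
  age_mid <- floor(year + 0.5 - ac$birth_time)
  working <- sum(ac$weight[present_at(ac, year + 0.5) &
                             age_mid >= 25 & age_mid <= 65])
  pct <- function(k) if (n_dem > 0) 100 * sum(yr$care_bin == k) / n_dem else
    if (k == 0) 100 else 0
  data.frame(
    year = year, recipients = w * sum(rec), hours_per_year = hours,
    hours_per_working_age = ifelse(working > 0, hours / working, NA_real_),
    pct_none = pct(0), pct_lt7 = pct(1), pct_7_14 = pct(2),
    pct_15_70 = pct(3), pct_ge71 = pct(4),
    caregiver_hours = hours,
    caregiver_oop = w * sum(rec) * cgm$caregiver_oop,
    caregiver_mean_hui3 = cgm$caregiver_hui3_mean)
}

#' Sectoral health-care costs among people with dementia
#'
#' For each of the seven sectors, weighted annual costs with
#' incident/prevalent phase proration: the incident rate applies to the
#' fraction of the year within 12 months of onset, the prevalent rate to the
#' remaining dementia person-time; out-of-pocket costs are reported
#' separately. Values in millions.
#'
#' @inheritParams point_prevalence
#' @param costs a [cost_schedule()]; defaults to the one used in the run.
#' @return one-row data.frame with one column per sector, `total` (the exact
#'   sector sum) and `out_of_pocket`, in millions.
#' @export
cost_summary <- function(result, year, costs = NULL) {
  check_year(result, year)
  costs <- costs %||% result$schedules$costs
  yr <- result$years[result$years$year == year & result$years$frac_dementia > 0, ]
  w <- result$meta$weight
  gi <- age_group_index(costs$age_breaks, yr$age)
  vals <- vapply(seq_along(cost_sectors), function(k) {
    inc <- costs$annual_cost[cbind(k, 1L, gi, yr$sex)]
    prv <- costs$annual_cost[cbind(k, 2L, gi, yr$sex)]
    sum(w * (yr$frac_incident * inc + (yr$frac_dementia - yr$frac_incident) * prv)) / 1e6
  }, numeric(1L))
  names(vals) <- cost_sectors
  oop <- sum(w * yr$frac_dementia * costs$out_of_pocket[cbind(gi, 2L)]) / 1e6
  out <- as.data.frame(as.list(vals))
  out$total <- sum(vals)
  out$out_of_pocket <- oop
  cbind(data.frame(year = year), out)
}

#' Annual aggregate series
#'
#' One row per horizon year combining prevalence, mortality, caregiving and
#' cost summaries -- the machine analogue of the published report tables.
#'
#' @param result a [run_population()] result.
#' @param years years to aggregate (default: the full horizon).
#' @param costs optional [cost_schedule()]; defaults to the one stored with
#'   the run.
#' @return data.frame, one row per year.
#' @export
annual_aggregates <- function(result, years = NULL, costs = NULL) {
  years <- years %||% result$meta$horizon
  costs <- costs %||% result$schedules$costs
  do.call(rbind, lapply(years, function(y) {
    pv <- point_prevalence(result, y)
    ms <- mortality_summary(result, y)
    cs <- caregiving_summary(result, y)
    co <- cost_summary(result, y, costs)
    data.frame(
      year = y,
      cases = pv$cases[pv$sex == "total"],
      cases_male = pv$cases[pv$sex == "male"],
      cases_female = pv$cases[pv$sex == "female"],
      rate40 = pv$rate40[pv$sex == "total"],
      rate80 = pv$rate80[pv$sex == "total"],
      deaths = ms$deaths, mortality_rate = ms$rate_per_1000,
      mean_yll = ms$mean_yll, mean_hyll = ms$mean_hyll,
      care_recipients = cs$recipients,
      care_hours_millions = cs$hours_per_year / 1e6,
      care_hours_per_working_age = cs$hours_per_working_age,
      pct_none = cs$pct_none, pct_lt7 = cs$pct_lt7, pct_7_14 = cs$pct_7_14,
      pct_15_70 = cs$pct_15_70, pct_ge71 = cs$pct_ge71,
      cost_total_millions = co$total,
      cost_oop_millions = co$out_of_pocket)
  }))
}

#' Write the report tables for a run
#'
#' Emits the three delimited report tables (prevalence, burden/caregiving,
#' costs), aligned-text versions, and a machine-readable JSON run summary.
#' Output is deterministic: identical seeds and bundles give byte-identical
#' files.
#'
#' @param result a [run_population()] result.
#' @param path output directory.
#' @param costs the [cost_schedule()] used in the run.
#' @param years years to report (default: full horizon).
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, costs = NULL, years = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  years <- years %||% result$meta$horizon
  costs <- costs %||% result$schedules$costs
  prev <- do.call(rbind, lapply(years, point_prevalence, result = result))
  burden <- do.call(rbind, lapply(years, function(y)
    cbind(mortality_summary(result, y),
          caregiving_summary(result, y)[-1L])))
  cost <- do.call(rbind, lapply(years, cost_summary, result = result,
                                costs = costs))
  for (nm in c("prev", "burden", "cost")) {
    df <- get(nm)
    num <- vapply(df, is.double, TRUE)
    df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
    write.csv(df, file.path(path, paste0(nm, ".csv")),
              row.names = FALSE, quote = FALSE)
    writeLines(utils::capture.output(print(df, row.names = FALSE)),
               file.path(path, paste0(nm, ".txt")))
  }
  meta <- result$meta
  jsonlite::write_json(
    list(seed = meta$seed, n_actors = meta$n_actors, weight = meta$weight,
         scenario = meta$scenario, horizon = range(meta$horizon),
         bundle = meta$params_name),
    file.path(path, "run_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
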