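# Deterministic cohort-component twin of the microsimulation. The same event
# ordering as the engine -- onset resolved at the year start with the onset
# date uniform in the year, excess mortality prorated from the onset date,
# emigration as a competing constant hazard, forced death at the year-end
# boundary once the January-1 age reaches the cap -- is propagated as exact
# expected flows, so the microsimulation matches it in expectation cell by
# cell, not just asymptotically.

#' Run the cohort-component oracle
#'
#' Evolves expected occupancy `N(age, sex, dementia status)` at January 1 of
#' each year by deterministic difference equations whose within-year
#' integrals (onset-time-averaged survival, competing death/emigration
#' splits) reproduce the engine's continuous-time mechanics exactly in
#' expectation. No randomness.
#'
#' @param params a [parameter_set()].
#' @param scenario optional [scenario()].
#' @param horizon last calendar year to evolve to (default: end of the
#'   bundle's span).
#' @return object of class `demsim_oracle`: `years`, occupancy array `N`
#'   (age x sex x status x year, at January 1), and per-year expected flow
#'   series (`onsets`, `deaths_dementia`, `deaths_total`, `emigrants`,
#'   `prevalence`, `population`).
#' @export
run_oracle <- function(params, scenario = NULL, horizon = NULL) {
  if (!is.null(scenario)) params <- apply_scenario(params, scenario)
  md <- params$metadata
  y_last <- max(horizon %||% md$years)
  max_age <- md$max_age
  min_ia <- md$min_incidence_age
  coh <- params$demography$cohorts
  mig <- params$demography$migration
  emig_tab <- mig$emigration_rate
  y0 <- min(coh$years)
  years <- y0:y_last
  ny <- length(years)
  ages <- 0:max_age

  N <- array(0, c(max_age + 1L, 2L, 2L, ny))
  onsets <- deaths_dem <- deaths_tot <- emigr <- numeric(ny)
  cur <- array(0, c(max_age + 1L, 2L, 2L))

  # expected immigrant counts per integer age at arrival
  imm_by_age <- function(y, s) {
    out <- numeric(max_age + 1L)
    iy <- match(y, mig$years)
    if (is.na(iy)) return(out)
    br <- pmin(mig$arrival_age_breaks, 111)
    for (g in seq_len(length(br) - 1L)) {
      lo <- br[g]; hi <- br[g + 1L] - 1L
      k <- lo:hi
      kk <- k[k <= max_age]
      out[kk + 1L] <- out[kk + 1L] + mig$immigration[iy, s, g] / length(k)
    }
    out
  }

  for (t in seq_len(ny)) {
    y <- years[t]
    for (s in 1:2) # immigrants enter dementia-free on January 1
      cur[, s, 1L] <- cur[, s, 1L] + imm_by_age(y, s)
    N[, , , t] <- cur

    nxt <- array(0, c(max_age + 1L, 2L, 2L))
    for (s in 1:2) {
      m0 <- baseline_mortality(params$mortality, ages, s, y)
      em <- rate_lookup(emig_tab, ages, s, y)
      hr <- effective_hr(params$hazard_ratio, ages, s, y)
      iv <- rate_lookup(params$incidence, ages, s, y)
      p_on <- ifelse(ages >= min_ia, -expm1(-iv), 0)
      A <- m0 + em
      B <- m0 * hr + em
      fA <- exprel(A)
      q_no <- exp(-A)
      post_surv <- exp(-B) * exprel(A - B)
      bracket <- fA - post_surv
      free <- cur[, s, 1L]; demv <- cur[, s, 2L]

      surv_free <- free * (1 - p_on) * q_no
      surv_dem <- free * p_on * post_surv + demv * exp(-B)
      on_y <- free * p_on * fA
      d_dem <- free * p_on * safe_div(m0 * hr, B) * bracket +
        demv * safe_div(m0 * hr, B) * (1 - exp(-B))
      d_free <- free * (1 - p_on) * safe_div(m0, A) * (1 - q_no) +
        free * p_on * safe_div(m0, A) * (1 - fA)
      e_dem <- free * p_on * safe_div(em, B) * bracket +
        demv * safe_div(em, B) * (1 - exp(-B))
      e_free <- free * (1 - p_on) * safe_div(em, A) * (1 - q_no) +
        free * p_on * safe_div(em, A) * (1 - fA)

      # age cap: survivors of the last row die at the year-end boundary
      capped <- ages >= max_age
      d_free <- d_free + ifelse(capped, surv_free, 0)
      d_dem <- d_dem + ifelse(capped, surv_dem, 0)
      surv_free[capped] <- 0; surv_dem[capped] <- 0

      nxt[2:(max_age + 1L), s, 1L] <- surv_free[1:max_age]
      nxt[2:(max_age + 1L), s, 2L] <- surv_dem[1:max_age]

      # births during year y: uniform birth dates, age-0 rates, no onset
      bi <- match(y, coh$years)
      if (!is.na(bi) && coh$births[bi, s] > 0) {
        Bn <- coh$births[bi, s]
        A0 <- m0[1L] + em[1L]
        f0 <- exprel(A0)
        nxt[1L, s, 1L] <- nxt[1L, s, 1L] + Bn * f0
        d_free_b <- Bn * safe_div(m0[1L], A0) * (1 - f0)
        e_free_b <- Bn * safe_div(em[1L], A0) * (1 - f0)
        d_free[1L] <- d_free[1L] + d_free_b
        e_free[1L] <- e_free[1L] + e_free_b
      }

      onsets[t] <- onsets[t] + sum(on_y)
      deaths_dem[t] <- deaths_dem[t] + sum(d_dem)
      deaths_tot[t] <- deaths_tot[t] + sum(d_dem) + sum(d_free)
      emigr[t] <- emigr[t] + sum(e_dem) + sum(e_free)
    }
    cur <- nxt
  }

  structure(list(
    years = years, N = N,
    prevalence = apply(N[, , 2L, , drop = FALSE], 4L, sum),
    population = apply(N, 4L, sum),
    onsets = onsets, deaths_dementia = deaths_dem,
    deaths_total = deaths_tot, emigrants = emigr,
    meta = list(max_age = max_age, params_name = md$name,
                scenario = if (is.null(scenario)) "baseline" else scenario$name)),
    class = "demsim_oracle")
}

#' @export
print.demsim_oracle <- function(x, ...) {
  cat(sprintf("<demsim_oracle> '%s' (%s): years %d-%d\n", x$meta$params_name,
              x$meta$scenario, min(x$years), max(x$years)))
  cat(sprintf("  final population %.0f, dementia prevalence %.0f\n",
              x$population[length(x$years)], x$prevalence[length(x$years)]))
  invisible(x)
}

#' Compare a microsimulation run to the oracle
#'
#' For each horizon year and measure (January-1 dementia prevalence, onsets,
#' dementia deaths) computes the standardised discrepancy
#' `z = (microsim - expected) / SE`, with the sampling SE implied by the
#' actor count and weight (`SE = sqrt(w * mu * (1 - mu / total))`), and
#' flags `|z| > 3`.
#'
#' @param result a [run_population()] result.
#' @param oracle a [run_oracle()] on the same bundle and scenario.
#' @return data.frame `(year, measure, microsim, expected, z, flag)` with
#'   attribute `"fraction_within_3"`.
#' @export
compare_to_oracle <- function(result, oracle) {
  hz <- result$meta$horizon
  if (!all(hz %in% oracle$years))
    stop("oracle series does not cover the simulation horizon")
  ev <- result$events
  w <- result$meta$weight
  total <- result$meta$total_persons
  ti <- match(hz, oracle$years)
  tab <- rbind(
    data.frame(year = hz, measure = "prevalence",
               microsim = w * ev$prevalent_jan1[match(hz, ev$year)],
               expected = oracle$prevalence[ti]),
    data.frame(year = hz, measure = "onsets",
               microsim = w * ev$onsets[match(hz, ev$year)],
               expected = oracle$onsets[ti]),
    data.frame(year = hz, measure = "deaths",
               microsim = w * ev$deaths_dementia[match(hz, ev$year)],
               expected = oracle$deaths_dementia[ti]))
  se <- sqrt(pmax(0, w * tab$expected * (1 - tab$expected / total)))
  tab$z <- ifelse(se > 0, (tab$microsim - tab$expected) / se,
                  ifelse(tab$microsim == tab$expected, 0, Inf))
  tab$flag <- abs(tab$z) > 3
  attr(tab, "fraction_within_3") <- mean(!tab$flag)
  tab
}

#' Dementia prevalence by age stratum and sex
#'
#' January-1 weighted dementia counts in coarse age strata, from either a
#' microsimulation result or an oracle series; the common input of
#' [calibration_check()].
#'
#' @param x a `demsim_result` or `demsim_oracle`.
#' @param year calendar year.
#' @param age_breaks increasing stratum breaks (last stratum open-ended).
#' @return data.frame `(age_group, sex, value)`.
#' @export
prevalence_by_strata <- function(x, year, age_breaks = c(65, 80, Inf)) {
  labs <- age_group_labels(age_breaks)
  grid <- expand.grid(age_group = labs, sex = c("male", "female"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (inherits(x, "demsim_oracle")) {
    t <- match(year, x$years)
    if (is.na(t)) stop("year outside the oracle series")
    ages <- seq_len(dim(x$N)[1L]) - 1L
    gi <- findInterval(ages, age_breaks)
    grid$value <- mapply(function(g, s)
      sum(x$N[gi == match(g, labs), match(s, c("male", "female")), 2L, t]),
      grid$age_group, grid$sex)
  } else {
    ac <- x$actors
    a <- year - floor(ac$birth_time) - 1
    prev <- ac$entry_time <= year &
      (is.na(ac$death_time) | ac$death_time > year) &
      (is.na(ac$emigration_time) | ac$emigration_time > year) &
      !is.na(ac$onset_time) & ac$onset_time < year
    gi <- findInterval(a, age_breaks)
    grid$value <- mapply(function(g, s)
      sum(ac$weight[prev & gi == match(g, labs) &
                      ac$sex == match(s, c("male", "female"))]),
      grid$age_group, grid$sex)
  }
  grid
}

#' Compare projected to reference prevalence
#'
#' The calibration harness: joins projected and reference prevalence by
#' (age group, sex), computes projected/reference ratios, and reports
#' whether all ratios fall inside the acceptance band -- in which case
#' calibration of the baseline model is deemed unnecessary.
#'
#' @param projected data.frame `(age_group, sex, value)` of model output.
#' @param reference data.frame of the same shape with observed values.
#' @param band lower/upper ratio bounds (default 0.9-1.1).
#' @return object of class `calibration_report`: the merged table with
#'   `ratio` and `in_band`, and attribute `"calibration_unnecessary"`.
#' @export
calibration_check <- function(projected, reference, band = c(0.9, 1.1)) {
  m <- merge(projected, reference, by = c("age_group", "sex"),
             suffixes = c("_projected", "_reference"))
  if (!nrow(m)) stop("no overlapping strata between projected and reference")
  m$ratio <- ifelse(m$value_reference > 0,
                    m$value_projected / m$value_reference, NA_real_)
  m$in_band <- !is.na(m$ratio) & m$ratio >= band[1L] & m$ratio <= band[2L]
  attr(m, "calibration_unnecessary") <- all(m$in_band)
  class(m) <- c("calibration_report", "data.frame")
  m
}

#' @export
print.calibration_report <- function(x, ...) {
  print.data.frame(x, row.names = FALSE)
  cat(if (attr(x, "calibration_unnecessary"))
    "All strata within band: calibration unnecessary\n"
    else "Strata outside band: calibration flagged\n")
  invisible(x)
}
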