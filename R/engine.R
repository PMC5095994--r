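#' Invert a piecewise-constant cumulative hazard
#'
#' Death-age sampling primitive: given a hazard path `h` (per person-year,
#' constant within each year of age starting at age 0) and an Exponential(1)
#' threshold `E`, the death age `t*` solves `integral_0^t* h(u) du = E` by
#' exact piecewise inversion. If the cumulative hazard never reaches `E`
#' before the age cap, death occurs at the cap.
#'
#' @param hazard_path nonnegative hazards per year of age
#'   (ages `[0,1), [1,2), ...`).
#' @param threshold positive Exponential(1) draw(s); vectorised.
#' @param cap age cap (default: end of the path).
#' @return continuous death age(s).
#' @examples
#' sample_death_age(rep(0.0693, 120), 0.693) # 10.0
#' @export
sample_death_age <- function(hazard_path, threshold, cap = length(hazard_path)) {
  if (any(hazard_path < 0)) stop("hazards must be nonnegative")
  if (any(threshold <= 0)) stop("threshold must be positive")
  H <- cumsum(hazard_path)
  vapply(threshold, function(E) {
    k <- which(H >= E)
    if (!length(k)) return(as.numeric(cap))
    k <- k[1L]
    prev <- if (k == 1L) 0 else H[k - 1L]
    min(cap, (k - 1L) + (E - prev) / hazard_path[k])
  }, numeric(1L))
}

#' Health-adjusted years of life lost from two annual HUI3 paths
#'
#' `HYLL = sum(counterfactual HUI3 x fraction of year lived) -
#'         sum(factual HUI3 x fraction of year lived)`,
#' with partial death years prorated through the fraction-lived weights.
#'
#' @param hui3_factual,frac_factual factual annual HUI3 values and fractions
#'   of each year lived.
#' @param hui3_counterfactual,frac_counterfactual the counterfactual path.
#' @return HYLL in health-adjusted years.
#' @export
hyll_from_paths <- function(hui3_factual, frac_factual,
                            hui3_counterfactual, frac_counterfactual) {
  sum(hui3_counterfactual * frac_counterfactual) -
    sum(hui3_factual * frac_factual)
}

#' Simulate the population one actor-year at a time
#'
#' Ages every actor from entry to death in continuous time with annual state
#' updates. Within each calendar year, in order: dementia-onset draw at the
#' year start (eligible: alive, dementia-free, at or above the minimum
#' incidence age), with the onset date uniform within the year; mortality via
#' a single per-actor Exponential(1) threshold tested against the cumulative
#' hazard, where the dementia hazard ratio applies from the onset date
#' (prorated within the onset year); emigration via an independent threshold
#' against the emigration hazard; annual HUI3 assignment (truncated normal,
#' shared noise across statuses); caregiving assigned at the year end for the
#' following year. A counterfactual twin is evolved with the same random
#' draws and hazard ratio 1 -- by default also with the dementia-free HUI3
#' path ("did not develop dementia"); `counterfactual = "hr_only"` keeps the
#' dementia HUI3 decrement and removes only the excess mortality. YLL is the
#' counterfactual minus factual death age (0 without onset, NA when
#' emigration censors the factual lifecourse); HYLL is the difference in
#' HUI3-weighted lifetimes.
#'
#' All randomness comes from counter-based streams keyed by (master seed,
#' actor id, stream, calendar year), so two runs with the same seed --
#' whatever the actor processing order, and across scenarios -- reuse
#' identical draws (common random numbers).
#'
#' @param params a [parameter_set()].
#' @param scenario optional [scenario()]; applied via [apply_scenario()].
#' @param n_actors number of actors when `actor_seeds` is not supplied.
#' @param seed master seed (integer).
#' @param horizon calendar years for which actor-year records and the event
#'   log are kept (default: the bundle's year span). Lifecourses themselves
#'   always run to death or the age cap.
#' @param counterfactual `"full"` (no dementia at all) or `"hr_only"`.
#' @param onset_mode `"stochastic"` (the model), `"at_birth"` (forced onset
#'   at entry; closed-form validation runs) or `"never"`.
#' @param actor_seeds optional pre-built [build_actor_seeds()] table, shared
#'   across scenario runs.
#' @return an object of class `demsim_result`: list with `actors` (one row
#'   per actor: onset/death/emigration dates, YLL, HYLL), `years` (one row
#'   per actor-year in the horizon: dementia exposure fractions, HUI3,
#'   caregiving bin), `events` (per-year event log) and `meta`.
#' @export
run_population <- function(params, scenario = NULL, n_actors = 1000L,
                           seed = 1L, horizon = NULL,
                           counterfactual = c("full", "hr_only"),
                           onset_mode = c("stochastic", "at_birth", "never"),
                           actor_seeds = NULL) {
  counterfactual <- match.arg(counterfactual)
  onset_mode <- match.arg(onset_mode)
  scen_name <- if (is.null(scenario)) "baseline" else scenario$name
  if (!is.null(scenario)) params <- apply_scenario(params, scenario)
  md <- params$metadata
  horizon <- as.integer(horizon %||% md$years)
  max_age <- md$max_age
  min_ia <- md$min_incidence_age
  emig_tab <- params$demography$migration$emigration_rate
  cg <- params$caregiving
  stoch <- onset_mode == "stochastic"

  if (is.null(actor_seeds))
    actor_seeds <- build_actor_seeds(params$demography$cohorts,
                                     params$demography$migration,
                                     n_actors, seed)
  A <- actor_seeds[order(actor_seeds$id), , drop = FALSE]
  n <- nrow(A)
  id <- A$id; sexv <- A$sex
  bt <- A$birth_time; et <- A$entry_time
  born <- A$entry_mode == "born"
  w <- A$weight[1L]
  by <- as.integer(floor(bt))

  Ed <- -log(crn_u(seed, id, .streams$death, 0))
  Ee <- -log(crn_u(seed, id, .streams$emigration, 0))
  Hd <- He <- Hcf <- numeric(n)
  dem <- logical(n)
  onset_t <- death_f <- death_cf <- emig_t <- rep(NA_real_, n)
  hyll_acc <- numeric(n)
  care_next <- integer(n)
  f_open <- cf_open <- rep(TRUE, n)
  if (onset_mode == "at_birth") { dem[] <- TRUE; onset_t <- et }

  y0 <- min(by)
  y_end <- max(by) + max_age + 1L
  rec <- vector("list", length(horizon))
  names(rec) <- as.character(horizon)
  ev <- list()

  for (y in y0:y_end) {
    open <- f_open | cf_open
    if (!any(open)) break
    act <- which(open & et < y + 1)
    care_now <- care_next
    care_next <- integer(n)
    if (!length(act)) next

    a <- y - by[act] - 1L
    ar <- pmax(a, 0L)
    s0 <- pmax(0, et[act] - y)
    sx <- sexv[act]
    m0 <- baseline_mortality(params$mortality, ar, sx, y)
    em <- rate_lookup(emig_tab, ar, sx, y)
    hrv <- effective_hr(params$hazard_ratio, ar, sx, y)
    fi <- f_open[act]
    ci <- cf_open[act]
    dem_start <- dem[act]

    # event log: population state at January 1 of year y
    if (y >= y0 && y <= max(horizon)) {
      at_jan1 <- fi & et[act] <= y
      ev[[length(ev) + 1L]] <- list(
        year = y,
        pop_jan1 = sum(at_jan1),
        prevalent_jan1 = sum(at_jan1 & dem_start),
        entries = sum(et[act] >= y & et[act] < y + 1))
    }

    # (1) onset draw at year start
    if (stoch) {
      iv <- rate_lookup(params$incidence, ar, sx, y)
      elig <- fi & !dem_start & s0 == 0 & a >= min_ia
      uo <- crn_u(seed, id[act], .streams$onset, y)
      cand <- elig & uo < -expm1(-iv)
      cfrac <- crn_u(seed, id[act], .streams$onset_date, y)
    } else {
      cand <- rep(FALSE, length(act))
      cfrac <- rep(1, length(act))
    }

    # (2)-(3) factual hazard path and threshold test; segments collapse when
    # the post-onset hazard equals the pre-onset one so that an effective
    # HR of 1 reproduces the counterfactual arithmetic bit-for-bit
    h2 <- m0 * hrv
    h1 <- ifelse(dem_start, h2, m0)
    two_seg <- cand & h2 != h1
    e1 <- ifelse(two_seg, cfrac, 1)
    Rd <- Ed[act] - Hd[act]
    L1 <- e1 - s0
    H1 <- h1 * L1
    td <- rep(Inf, length(act))
    in1 <- H1 >= Rd & h1 > 0
    td[in1] <- s0[in1] + Rd[in1] / h1[in1]
    R2 <- Rd - H1
    L2 <- 1 - e1
    in2 <- !in1 & two_seg & h2 * L2 >= R2 & h2 > 0
    td[in2] <- e1[in2] + R2[in2] / h2[in2]
    te <- ifelse(em > 0, s0 + (Ee[act] - He[act]) / em, Inf)

    ev_d <- fi & td <= 1 & td <= te
    ev_e <- fi & te <= 1 & te < td
    surv <- fi & !ev_d & !ev_e
    end_f <- ifelse(ev_d, td, ifelse(ev_e, te, 1))
    on_ok <- fi & cand & cfrac < end_f

    # age cap: forced death at the year-end boundary
    capped <- surv & a >= max_age
    surv <- surv & !capped

    dem_now <- dem_start | on_ok
    i_act <- id[act]
    dem[act[on_ok]] <- TRUE
    onset_t[act[on_ok]] <- y + cfrac[on_ok]
    death_f[act[ev_d]] <- y + td[ev_d]
    death_f[act[capped]] <- y + 1
    emig_t[act[ev_e]] <- y + te[ev_e]
    f_open[act[ev_d | ev_e | capped]] <- FALSE
    s_i <- act[surv]
    Hd[s_i] <- Hd[s_i] + (h1 * L1 + h2 * L2 * two_seg)[surv]
    He[s_i] <- He[s_i] + (em * (1 - s0))[surv]

    # counterfactual twin: baseline hazard only, same threshold
    Rc <- Ed[act] - Hcf[act]
    tdc <- ifelse(m0 > 0, s0 + Rc / m0, Inf)
    evc <- ci & tdc <= 1
    cap_c <- ci & !evc & a >= max_age
    end_cf <- ifelse(evc, tdc, 1)
    death_cf[act[evc]] <- y + tdc[evc]
    death_cf[act[cap_c]] <- y + 1
    cf_open[act[evc | cap_c]] <- FALSE
    c_i <- act[ci & !evc & !cap_c]
    Hcf[c_i] <- Hcf[c_i] + (m0 * (1 - s0))[ci & !evc & !cap_c]

    # (4) HUI3 for the year, shared noise across statuses and twins
    z <- qnorm(crn_u(seed, i_act, .streams$hui3, y))
    ii <- cbind(pmin(ar, 110L) + 1L, sx)
    u_n <- hui3_clip(params$hui3$mean[cbind(ii, 1L)] +
                     params$hui3$sd[cbind(ii, 1L)] * z)
    u_d <- hui3_clip(params$hui3$mean[cbind(ii, 2L)] +
                     params$hui3$sd[cbind(ii, 2L)] * z)
    lf <- ifelse(fi, end_f - s0, 0)
    post <- ifelse(fi & dem_start, lf,
                   ifelse(on_ok, pmax(0, end_f - cfrac), 0))
    pre <- lf - post
    uf_sum <- ifelse(u_d == u_n, u_n * lf, pre * u_n + post * u_d)
    lc <- ifelse(ci, end_cf - s0, 0)
    if (counterfactual == "full") {
      uc_sum <- u_n * lc
    } else {
      # exact onset fraction in the onset year; (y + cfrac) - y would not
      # round-trip and the null-HR twin must cancel bit-for-bit
      of <- ifelse(on_ok, cfrac, onset_t[act] - y)
      post_c <- ifelse(ci & !is.na(of), pmax(0, end_cf - pmax(s0, of)), 0)
      uc_sum <- ifelse(u_d == u_n, u_n * lc,
                       (lc - post_c) * u_n + post_c * u_d)
    }
    hyll_acc[act] <- hyll_acc[act] + (uc_sum - uf_sum)

    # event log: flows of year y
    if (y <= max(horizon)) {
      k <- length(ev)
      ev[[k]]$onsets <- sum(on_ok)
      ev[[k]]$deaths_dementia <- sum((ev_d | capped) & dem_now)
      ev[[k]]$deaths_none <- sum((ev_d | capped) & !dem_now)
      ev[[k]]$emigrants_dementia <- sum(ev_e & dem_now)
      ev[[k]]$emigrants_none <- sum(ev_e & !dem_now)
    }

    # actor-year record within the reporting horizon
    if (y %in% horizon) {
      keep <- fi & lf > 0
      if (any(keep)) {
        oi <- onset_t[act]
        inc_frac <- ifelse(is.na(oi), 0,
                           pmax(0, pmin(y + end_f, oi + 1) - pmax(y + s0, oi)))
        rec[[as.character(y)]] <- data.table::data.table(
          id = i_act[keep], year = y, age = ar[keep], sex = sx[keep],
          dementia = dem_now[keep], onset_this_year = on_ok[keep],
          frac_present = lf[keep], frac_dementia = post[keep],
          frac_incident = inc_frac[keep],
          hui3 = ifelse(lf[keep] > 0, uf_sum[keep] / lf[keep], u_n[keep]),
          care_bin = care_now[act][keep])
      }
    }

    # (5) caregiving assignment at year end for the following year
    if (any(surv)) {
      gi <- age_group_index(cg$age_breaks, pmax(0L, a[surv] + 1L))
      band <- hui3_band_index(cg$hui3_breaks,
                              ifelse(lf[surv] > 0, uf_sum[surv] / lf[surv],
                                     u_n[surv]))
      p <- cg$receipt_prob[cbind(gi, dem_now[surv] + 1L, band)]
      ur <- crn_u(seed, i_act[surv], .streams$care_receipt, y)
      uh <- crn_u(seed, i_act[surv], .streams$care_hours, y)
      kbin <- findInterval(uh, cumsum(cg$hours_probs)[-5L]) + 1L
      care_next[act[surv]] <- ifelse(ur < p, kbin - 1L, 0L)
    }
  }

  actors <- data.table::data.table(
    id = id, sex = sexv, weight = A$weight, birth_time = bt, entry_time = et,
    entry_mode = A$entry_mode, onset_time = onset_t, death_time = death_f,
    death_time_cf = death_cf, emigration_time = emig_t)
  no_onset <- is.na(onset_t)
  emigrated <- !is.na(emig_t)
  actors$yll <- ifelse(no_onset, 0,
                       ifelse(emigrated, NA_real_, death_cf - death_f))
  actors$hyll <- ifelse(no_onset, 0, ifelse(emigrated, NA_real_, hyll_acc))

  years_dt <- data.table::rbindlist(rec[!vapply(rec, is.null, TRUE)])
  if (nrow(years_dt)) data.table::setkeyv(years_dt, c("year", "id"))
  events <- data.table::rbindlist(lapply(ev, data.table::as.data.table))
  structure(list(
    actors = actors, years = years_dt, events = events,
    schedules = list(costs = params$costs, caregiving = params$caregiving),
    meta = list(seed = as.integer(seed), n_actors = n, weight = w,
                total_persons = attr(actor_seeds, "total_persons") %||% (n * w),
                horizon = horizon, scenario = scen_name,
                counterfactual = counterfactual, onset_mode = onset_mode,
                params_name = md$name, max_age = max_age)),
    class = "demsim_result")
}

#' @export
print.demsim_result <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<demsim_result> scenario '%s': %d actors (weight %.1f), seed %d\n",
              m$scenario, m$n_actors, m$weight, m$seed))
  cat(sprintf("  horizon %d-%d; %d actor-year records; onsets: %d actors\n",
              min(m$horizon), max(m$horizon), nrow(x$years),
              sum(!is.na(x$actors$onset_time))))
  invisible(x)
}
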