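#' Birth-cohort schedule
#'
#' Counts of births per (birth year, sex) over a contiguous historical plus
#' projected span; the open population is initialised from these cohorts.
#'
#' @param births `n_years x 2` matrix (year x sex male/female) of nonnegative
#'   counts, or a single number.
#' @param years contiguous birth years covered.
#' @param projection_variant population-projection variant label.
#' @return an object of class `cohort_schedule`.
#' @export
cohort_schedule <- function(births, years,
                            projection_variant = c("mid", "low", "high")) {
  projection_variant <- match.arg(projection_variant)
  years <- as.integer(years)
  if (any(diff(years) != 1L)) stop("birth years must be contiguous")
  if (length(births) == 1L) births <- matrix(births, length(years), 2L)
  births <- unname(as.matrix(births))
  stopifnot(identical(dim(births), c(length(years), 2L)))
  if (any(births < 0)) stop("birth counts must be nonnegative")
  structure(list(births = births, years = years,
                 projection_variant = projection_variant),
            class = "cohort_schedule")
}

#' Immigration and emigration schedules
#'
#' Immigration as counts per (calendar year, sex, age-at-arrival group);
#' emigration as a hazard (per person-year) by age, sex and year. Immigrants
#' enter the population dementia-free on January 1 of the arrival year;
#' emigration censors a lifecourse (no return).
#'
#' @param immigration array `n_years x 2 x n_age_groups` of nonnegative
#'   counts, or a single number (0 disables immigration).
#' @param years calendar years covered by `immigration`.
#' @param arrival_age_breaks increasing breaks defining age-at-arrival groups.
#' @param emigration_rate an [age_sex_year_table()] of emigration hazards, or
#'   a single number (with the same `years`).
#' @return an object of class `migration_schedule`.
#' @export
migration_schedule <- function(immigration = 0, years,
                               arrival_age_breaks = c(0, 18, 45, 65, 111),
                               emigration_rate = 0) {
  years <- as.integer(years)
  n_grp <- length(arrival_age_breaks) - 1L
  if (length(immigration) == 1L)
    immigration <- array(immigration, c(length(years), 2L, n_grp))
  immigration <- unname(immigration)
  stopifnot(identical(dim(immigration), c(length(years), 2L, n_grp)))
  if (any(immigration < 0)) stop("immigration counts must be nonnegative")
  if (!inherits(emigration_rate, "asy_table"))
    emigration_rate <- age_sex_year_table(emigration_rate, years,
                                          units = "per person-year")
  structure(list(immigration = immigration, years = years,
                 arrival_age_breaks = arrival_age_breaks,
                 emigration_rate = emigration_rate),
            class = "migration_schedule")
}

#' Sample the actor population from the demographic schedules
#'
#' Draws `n_actors` actors multinomially across every (birth year, sex) cohort
#' cell and (arrival year, sex, arrival age) immigration cell, proportionally
#' to the scheduled counts. Each actor carries the common sampling weight
#' `total represented persons / n_actors`. Birth dates are uniform within the
#' birth year; immigrants enter on January 1 of the arrival year with an
#' integer age-at-arrival uniform within their arrival group.
#'
#' @param cohorts a [cohort_schedule()].
#' @param migration a [migration_schedule()].
#' @param n_actors number of actors to create (> 0).
#' @param seed integer seed; the draw is deterministic given
#'   (schedules, n_actors, seed).
#' @return `data.frame` of class `actor_seeds` with columns
#'   `id, sex, birth_time, entry_time, entry_mode, weight`.
#' @export
build_actor_seeds <- function(cohorts, migration, n_actors, seed = 1L) {
  if (n_actors <= 0) stop("n_actors must be positive")
  bc <- data.frame(
    year = rep(cohorts$years, 2L),
    sex = rep(1:2, each = length(cohorts$years)),
    count = as.vector(cohorts$births),
    mode = "born", age_at_entry = 0L
  )
  ni <- length(migration$years); ng <- length(migration$arrival_age_breaks) - 1L
  im <- data.frame(
    year = rep(migration$years, 2L * ng),
    sex = rep(rep(1:2, each = ni), ng),
    count = as.vector(migration$immigration),
    mode = "immigrant",
    age_at_entry = rep(seq_len(ng), each = 2L * ni)
  )
  cells <- rbind(bc, im)
  total <- sum(cells$count)
  if (total <= 0) stop("empty population: all cohort and immigration counts are zero")

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  draw <- as.vector(rmultinom(1L, n_actors, cells$count / total))
  idx <- rep.int(seq_len(nrow(cells)), draw)
  cells <- cells[idx, , drop = FALSE]
  n <- nrow(cells)

  born <- cells$mode == "born"
  # immigrants: integer age-at-arrival uniform within the group
  age_arr <- integer(n)
  if (any(!born)) {
    br <- migration$arrival_age_breaks
    g <- cells$age_at_entry[!born]
    lo <- br[g]; hi <- pmin(br[g + 1L], 111) - 1L
    age_arr[!born] <- lo + floor(runif(sum(!born)) * (hi - lo + 1L))
    age_arr[!born] <- pmin(age_arr[!born], hi)
  }
  entry_year <- cells$year
  # January-1 age a corresponds to birth year entry_year - a - 1
  birth_year <- ifelse(born, cells$year, entry_year - age_arr - 1L)
  birth_time <- birth_year + runif(n)
  entry_time <- ifelse(born, birth_time, as.numeric(entry_year))

  seeds <- data.frame(
    id = seq_len(n), sex = cells$sex, birth_time = birth_time,
    entry_time = entry_time, entry_mode = cells$mode,
    weight = total / n_actors
  )
  attr(seeds, "total_persons") <- total
  class(seeds) <- c("actor_seeds", "data.frame")
  seeds
}

#' Baseline mortality hazard
#'
#' Evaluates the improving baseline schedule
#' `m0(a,s,t) = ref(a,s) * exp(-rho(a,s) * mult * (t - reference_year))`
#' of a [mortality_model()]; vectorised over age, sex and year. Ages above
#' 110 clamp to the last row.
#'
#' @param model a [mortality_model()].
#' @param age age in whole years (>= 0).
#' @param sex `"male"`/`"female"` (or 1/2).
#' @param year calendar year.
#' @param growth_variant optional override of the model's variant.
#' @return hazard per person-year (strictly positive).
#' @export
baseline_mortality <- function(model, age, sex, year, growth_variant = NULL) {
  if (any(age < 0)) stop("age must be nonnegative")
  a <- pmin(as.integer(age), 110L) + 1L
  s <- sex_index(sex)
  n <- max(length(a), length(s), length(year))
  i <- cbind(rep_len(a, n), rep_len(s, n))
  mult <- model$variant_multipliers[[growth_variant %||% model$growth_variant]]
  model$reference[i] *
    exp(-model$improvement[i] * mult * (rep_len(year, n) - model$reference_year))
}
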