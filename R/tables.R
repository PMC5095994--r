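#' Age x sex x calendar-year rate table
#'
#' The basic container for every age-, sex- and year-indexed quantity the
#' simulator consumes: dementia incidence (per person-year), emigration rates,
#' hazard-ratio multipliers, and so on. The age grid is whole years 0--110 with
#' the last row open-ended; lookups clamp ages above 110 to the 110 row and
#' years outside the declared span to the nearest endpoint. Values are step
#' functions in age and year: no interpolation.
#'
#' @param values numeric array of dimension `c(111, 2, length(years))`
#'   (age 0--110 x sex male/female x year), or a single number recycled.
#' @param years integer vector of contiguous calendar years covered.
#' @param units unit label, e.g. `"per person-year"` or `"probability"`.
#' @param kind `"hazard"` (values >= 0) or `"probability"` (values in 0..1);
#'   controls validation.
#' @return an object of class `asy_table`.
#' @examples
#' tab <- age_sex_year_table(0.02, 2011:2031, units = "per person-year")
#' rate_lookup(tab, age = 75, sex = "female", year = 2011)
#' @export
age_sex_year_table <- function(values, years, units = "per person-year",
                               kind = c("hazard", "probability")) {
  kind <- match.arg(kind)
  years <- as.integer(years)
  if (length(years) == 0L || any(diff(years) != 1L))
    stop("years must be a contiguous span")
  if (length(values) == 1L)
    values <- array(values, dim = c(111L, 2L, length(years)))
  values <- unname(values)
  if (!identical(dim(values), c(111L, 2L, length(years))))
    stop("values must be a 111 x 2 x ", length(years), " array (age 0-110, sex, year)")
  x <- structure(list(values = values, years = years, units = units, kind = kind),
                 class = "asy_table")
  validate_asy_table(x)
  x
}

validate_asy_table <- function(x, name = "table") {
  v <- x$values
  if (anyNA(v)) {
    i <- which(is.na(v), arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: missing value at (age %d, %s, %d)", name,
                 i[1] - 1L, c("male", "female")[i[2]], x$years[i[3]]))
  }
  bad <- if (x$kind == "probability") v < 0 | v > 1 else v < 0
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "%s: invalid value %g at (age %d, %s, %d): %s", name,
      v[matrix(i, 1L)], i[1] - 1L, c("male", "female")[i[2]], x$years[i[3]],
      if (x$kind == "probability") "probabilities must lie in [0, 1]"
      else "hazards must be nonnegative"))
  }
  invisible(x)
}

#' @export
print.asy_table <- function(x, ...) {
  cat(sprintf("<asy_table> ages 0-110, years %d-%d, units: %s (%s)\n",
              min(x$years), max(x$years), x$units, x$kind))
  cat(sprintf("  value range: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

sex_index <- function(sex) {
  if (is.numeric(sex)) return(as.integer(sex))
  i <- match(tolower(as.character(sex)), c("male", "female"))
  if (anyNA(i)) stop("sex must be 'male' or 'female'")
  i
}

#' Look up a cell of an age/sex/year table
#'
#' Exact cell value with the clamping contract: ages above 110 use the 110
#' row, years outside the span use the nearest endpoint. Vectorised over
#' `age`, `sex`, `year`.
#'
#' @param table an [age_sex_year_table()].
#' @param age age in whole years (>= 0).
#' @param sex `"male"`/`"female"` (or 1/2).
#' @param year calendar year.
#' @return numeric vector of cell values.
#' @export
rate_lookup <- function(table, age, sex, year) {
  if (any(age < 0)) stop("age must be nonnegative")
  a <- pmin(as.integer(age), 110L) + 1L
  s <- sex_index(sex)
  y <- pmin(pmax(as.integer(year), table$years[1L]),
            table$years[length(table$years)]) - table$years[1L] + 1L
  n <- max(length(a), length(s), length(y))
  table$values[cbind(rep_len(a, n), rep_len(s, n), rep_len(y, n))]
}

#' Convert a constant hazard to an annual event probability
#'
#' `p = 1 - exp(-rate)` for a rate in events per person-year, the probability
#' that at least one event occurs within one year of exposure.
#'
#' @param rate nonnegative hazard (per person-year); vectorised.
#' @return probability in `[0, 1)`.
#' @examples
#' rate_to_annual_prob(0.02) # 0.0198...
#' @export
rate_to_annual_prob <- function(rate) {
  if (any(rate < 0)) stop("rate must be nonnegative")
  -expm1(-rate)
}

# table <-> long data.frame (age, sex, year, value), used by bundle IO
asy_to_df <- function(x) {
  data.frame(
    age = rep(0:110, times = 2L * length(x$years)),
    sex = rep(rep(c("male", "female"), each = 111L), times = length(x$years)),
    year = rep(x$years, each = 222L),
    value = as.vector(x$values)
  )
}

asy_from_df <- function(df, units, kind, name = "table") {
  need <- c("age", "sex", "year", "value")
  if (!all(need %in% names(df)))
    stop(name, ": expected columns age, sex, year, value")
  years <- sort(unique(as.integer(df$year)))
  if (any(diff(years) != 1L)) stop(name, ": years must be contiguous")
  v <- array(NA_real_, dim = c(111L, 2L, length(years)))
  v[cbind(as.integer(df$age) + 1L, sex_index(df$sex),
          match(as.integer(df$year), years))] <- df$value
  x <- structure(list(values = v, years = years, units = units, kind = kind),
                 class = "asy_table")
  validate_asy_table(x, name)
  x
}
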