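# Parameter-bundle IO: one directory with a YAML manifest plus one delimited
# table per model input. Numeric cells are written as %.17g so a save/load
# round trip reproduces every double bit-exactly.

fmt17 <- function(x) sprintf("%.17g", x)

write_table17 <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], fmt17)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

bundle_files <- c(
  incidence = "incidence.csv",
  mortality_reference = "mortality_reference.csv",
  mortality_improvement = "mortality_improvement.csv",
  hazard_ratio = "hazard_ratio.csv",
  hui3 = "hui3.csv",
  caregiving_receipt = "caregiving_receipt.csv",
  costs = "costs.csv",
  out_of_pocket = "out_of_pocket.csv",
  cohorts = "cohorts.csv",
  immigration = "immigration.csv",
  emigration = "emigration.csv"
)

#' Write a parameter bundle to a directory
#'
#' Writes one CSV per rate table plus a `manifest.yaml` with the metadata and
#' structural configuration (breaks, hour-bin distribution, variant
#' multipliers). [load_parameter_set()] of the result reproduces every table
#' cell bit-exactly.
#'
#' @param params a [parameter_set()].
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
save_parameter_set <- function(params, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  p <- params
  cg <- p$caregiving; cs <- p$costs; dem <- p$demography
  f <- function(nm) file.path(path, bundle_files[[nm]])

  write_table17(asy_to_df(p$incidence), f("incidence"))
  write_table17(data.frame(age = rep(0:110, 2L),
                           sex = rep(c("male", "female"), each = 111L),
                           value = as.vector(p$mortality$reference)),
                f("mortality_reference"))
  write_table17(data.frame(age = rep(0:110, 2L),
                           sex = rep(c("male", "female"), each = 111L),
                           value = as.vector(p$mortality$improvement)),
                f("mortality_improvement"))
  write_table17(asy_to_df(p$hazard_ratio$hr), f("hazard_ratio"))

  grid <- expand.grid(age = 0:110, sex = c("male", "female"),
                      dementia = c("no", "yes"), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  write_table17(cbind(grid, mean = as.vector(p$hui3$mean),
                      sd = as.vector(p$hui3$sd)), f("hui3"))

  ag <- age_group_labels(cg$age_breaks)
  bd <- paste0("band", seq_len(length(cg$hui3_breaks) - 1L))
  gr <- expand.grid(age_group = ag, dementia = c("no", "yes"), hui3_band = bd,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  write_table17(cbind(gr, value = as.vector(cg$receipt_prob)),
                f("caregiving_receipt"))

  agc <- age_group_labels(cs$age_breaks)
  gr <- expand.grid(sector = cost_sectors, phase = c("incident", "prevalent"),
                    age_group = agc, sex = c("male", "female"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  write_table17(cbind(gr, value = as.vector(cs$annual_cost)), f("costs"))
  gr <- expand.grid(age_group = agc, dementia = c("no", "yes"),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  write_table17(cbind(gr, value = as.vector(cs$out_of_pocket)),
                f("out_of_pocket"))

  write_table17(data.frame(year = rep(dem$cohorts$years, 2L),
                           sex = rep(c("male", "female"),
                                     each = length(dem$cohorts$years)),
                           births = as.vector(dem$cohorts$births)),
                f("cohorts"))
  mig <- dem$migration
  agm <- age_group_labels(pmin(mig$arrival_age_breaks, 111))
  ni <- length(mig$years)
  gr <- expand.grid(year = mig$years, sex = c("male", "female"),
                    age_group = agm, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  write_table17(cbind(gr, count = as.vector(mig$immigration)), f("immigration"))
  write_table17(asy_to_df(mig$emigration_rate), f("emigration"))

  manifest <- list(
    name = p$metadata$name,
    years = range(p$metadata$years),
    currency_year = p$metadata$currency_year,
    min_incidence_age = p$metadata$min_incidence_age,
    max_age = p$metadata$max_age,
    mortality = list(reference_year = p$mortality$reference_year,
                     variant_multipliers = as.list(p$mortality$variant_multipliers),
                     growth_variant = p$mortality$growth_variant),
    hazard_ratio = list(scenario_multiplier = p$hazard_ratio$scenario_multiplier),
    caregiving = list(age_breaks = cg$age_breaks, hui3_breaks = cg$hui3_breaks,
                      hours_probs = as.list(cg$hours_probs),
                      rep_hours = as.list(cg$rep_hours),
                      caregiver_hui3_mean = cg$caregiver_hui3_mean,
                      caregiver_oop = cg$caregiver_oop),
    costs = list(age_breaks = cs$age_breaks),
    demography = list(projection_variant = dem$cohorts$projection_variant,
                      arrival_age_breaks = mig$arrival_age_breaks),
    tables = as.list(bundle_files)
  )
  yaml::write_yaml(manifest, file.path(path, "manifest.yaml"), precision = 17L)
  invisible(path)
}

read_bundle_table <- function(path, manifest, nm) {
  file <- manifest$tables[[nm]]
  if (is.null(file) || !file.exists(file.path(path, file)))
    stop("missing input: ", nm)
  read.csv(file.path(path, file), stringsAsFactors = FALSE)
}

#' Read and validate a parameter bundle
#'
#' Reads the directory written by [save_parameter_set()] (or assembled by
#' hand in the same layout), reconstructs every table and checks all
#' invariants. A missing table raises a "missing input" error naming the
#' table; an invalid cell raises a validation error naming the cell and rule.
#'
#' @param path bundle directory containing `manifest.yaml`.
#' @return a validated [parameter_set()].
#' @export
load_parameter_set <- function(path) {
  mf <- file.path(path, "manifest.yaml")
  if (!file.exists(mf)) stop("missing input: manifest.yaml")
  m <- yaml::read_yaml(mf)
  num <- function(x) as.numeric(unlist(x))

  inc <- asy_from_df(read_bundle_table(path, m, "incidence"),
                     "per person-year", "hazard", "incidence")
  ref <- read_bundle_table(path, m, "mortality_reference")
  imp <- read_bundle_table(path, m, "mortality_improvement")
  to_mat <- function(df, col) {
    v <- matrix(NA_real_, 111L, 2L)
    v[cbind(df$age + 1L, sex_index(df$sex))] <- df[[col]]
    v
  }
  mort <- mortality_model(
    to_mat(ref, "value"), m$mortality$reference_year, to_mat(imp, "value"),
    unlist(m$mortality$variant_multipliers), m$mortality$growth_variant)
  hr <- hazard_ratio_spec(
    asy_from_df(read_bundle_table(path, m, "hazard_ratio"),
                "ratio", "hazard", "hazard_ratio"),
    scenario_multiplier = m$hazard_ratio$scenario_multiplier)

  h <- read_bundle_table(path, m, "hui3")
  arr <- function(col) {
    v <- array(NA_real_, c(111L, 2L, 2L))
    v[cbind(h$age + 1L, sex_index(h$sex), match(h$dementia, c("no", "yes")))] <- h[[col]]
    v
  }
  hui <- hui3_table(arr("mean"), arr("sd"))

  cgm <- m$caregiving
  cr <- read_bundle_table(path, m, "caregiving_receipt")
  ag <- age_group_labels(num(cgm$age_breaks))
  bd <- paste0("band", seq_len(length(num(cgm$hui3_breaks)) - 1L))
  rp <- array(NA_real_, c(length(ag), 2L, length(bd)))
  rp[cbind(match(cr$age_group, ag), match(cr$dementia, c("no", "yes")),
           match(cr$hui3_band, bd))] <- cr$value
  if (anyNA(rp)) stop("caregiving_receipt: incomplete cell coverage")
  care <- caregiving_model(rp, num(cgm$age_breaks), num(cgm$hui3_breaks),
                           unlist(cgm$hours_probs), unlist(cgm$rep_hours),
                           cgm$caregiver_hui3_mean, cgm$caregiver_oop)

  co <- read_bundle_table(path, m, "costs")
  missing_sector <- setdiff(cost_sectors, unique(co$sector))
  if (length(missing_sector))
    stop("missing input: ", paste(missing_sector, collapse = ", "))
  agc <- age_group_labels(num(m$costs$age_breaks))
  ac <- array(NA_real_, c(7L, 2L, length(agc), 2L))
  ac[cbind(match(co$sector, cost_sectors),
           match(co$phase, c("incident", "prevalent")),
           match(co$age_group, agc), sex_index(co$sex))] <- co$value
  if (anyNA(ac)) stop("costs: incomplete cell coverage")
  oo <- read_bundle_table(path, m, "out_of_pocket")
  op <- matrix(NA_real_, length(agc), 2L)
  op[cbind(match(oo$age_group, agc), match(oo$dementia, c("no", "yes")))] <- oo$value
  costs <- cost_schedule(ac, num(m$costs$age_breaks), op)

  ch <- read_bundle_table(path, m, "cohorts")
  cy <- sort(unique(ch$year))
  bm <- matrix(NA_real_, length(cy), 2L)
  bm[cbind(match(ch$year, cy), sex_index(ch$sex))] <- ch$births
  cohorts <- cohort_schedule(bm, cy, m$demography$projection_variant)

  im <- read_bundle_table(path, m, "immigration")
  br <- num(m$demography$arrival_age_breaks)
  agm <- age_group_labels(pmin(br, 111))
  iy <- sort(unique(im$year))
  ia <- array(NA_real_, c(length(iy), 2L, length(agm)))
  ia[cbind(match(im$year, iy), sex_index(im$sex),
           match(im$age_group, agm))] <- im$count
  emi <- asy_from_df(read_bundle_table(path, m, "emigration"),
                     "per person-year", "hazard", "emigration")
  migration <- migration_schedule(ia, iy, br, emi)

  parameter_set(inc, mort, hr, hui, care, costs,
                list(cohorts = cohorts, migration = migration),
                name = m$name, years = seq(m$years[[1]], m$years[[2]]),
                currency_year = m$currency_year,
                min_incidence_age = m$min_incidence_age,
                max_age = m$max_age)
}
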