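# Plain-CSV interfaces for every model input and output. Formats:
#   life_table.csv: age, sex, q          fertility.csv: age, f
#   population.csv: age, sex, n, year    migration.csv: age, sex, m
#   prevalence.csv: age_lo, age_hi, sex, state, p
#   rates.csv:      chain, rate_name, sex, value
#   projection.csv: year, age, sex, state, count

#' Read a life table from CSV
#' @param path CSV with columns `age`, `sex`, `q`.
#' @return A `life_table`.
#' @export
read_life_table <- function(path) {
  life_table(utils::read.csv(path))
}

#' Read a fertility schedule from CSV
#' @param path CSV with columns `age`, `f` (ages 15..49).
#' @param male_fraction Male fraction at birth.
#' @return A `fertility_schedule`.
#' @export
read_fertility <- function(path, male_fraction = 0.512) {
  fertility_schedule(utils::read.csv(path), male_fraction = male_fraction)
}

#' Read a population snapshot from CSV
#' @param path CSV with columns `age`, `sex`, `n`, `year`.
#' @return A `population_vector`.
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path)
  if (!"year" %in% names(df) || length(unique(df$year)) != 1L) {
    stopf("population CSV must carry a single 'year'")
  }
  population_vector(df, df$year[1L])
}

#' Read a net-migration schedule from CSV
#' @param path CSV with columns `age`, `sex`, `m`.
#' @param scaler Global multiplier.
#' @return A `migration_schedule`.
#' @export
read_migration <- function(path, scaler = 1) {
  migration_schedule(utils::read.csv(path), scaler = scaler)
}

#' Read a prevalence table from CSV
#' @param path CSV with columns `age_lo`, `age_hi`, `sex`, `state`, `p`.
#' @param spec The `chain_spec` the table describes.
#' @param reference_year Survey year.
#' @return A `prevalence_table`.
#' @export
read_prevalence <- function(path, spec, reference_year) {
  prevalence_table(utils::read.csv(path), spec, reference_year)
}

#' Write / read calibrated rates
#' @param rates A `rate_set`.
#' @param path Target CSV path (columns `chain`, `rate_name`, `sex`, `value`).
#' @return `write_rates`: the path, invisibly. `read_rates`: a `rate_set`.
#' @export
write_rates <- function(rates, path) {
  v <- rates$values
  df <- data.frame(chain = rates$chain,
                   rate_name = rep(rownames(v), times = ncol(v)),
                   sex = rep(colnames(v), each = nrow(v)),
                   value = c(v))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rates
#' @param spec The `chain_spec` the rates belong to.
#' @export
read_rates <- function(path, spec) {
  df <- utils::read.csv(path)
  rn <- rate_names(spec)
  m <- matrix(NA_real_, length(rn), 2L, dimnames = list(rn, .sexes))
  m[cbind(match(df$rate_name, rn), match(df$sex, .sexes))] <- df$value
  rate_set(spec, m)
}

#' Write a projected chain as a long CSV
#' @param tensors List of `state_tensor`s.
#' @param path Target CSV path (columns `year`, `age`, `sex`, `state`,
#'   `count`).
#' @return The path, invisibly.
#' @export
write_projection <- function(tensors, path) {
  rows <- lapply(tensors, function(t) {
    K <- length(t$spec$states)
    data.frame(year = t$year,
               age = rep(.ages, times = 2L * K),
               sex = rep(rep(.sexes, each = .n_ages), times = K),
               state = rep(t$spec$states, each = 2L * .n_ages),
               count = c(t$counts))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Reference UK projection point estimates
#'
#' Published point estimates (millions) of the UK adult population in each
#' oral-health state for 2020, 2035 and 2050, by reporting age band and
#' severity, together with the printed relative-change column. Ships with the
#' package as the reference input for exercising the reporting arithmetic
#' ([relative_change()], [state_share()]); reproducing the underlying
#' projection itself requires the original survey and national-statistics
#' inputs, which are not redistributable.
#'
#' @return Data frame with columns `table`, `section`, `row`, `y2020`,
#'   `y2035`, `y2050`, `printed_change_pct`.
#' @export
uk_projection_reference <- function() {
  utils::read.csv(system.file("extdata", "uk_projection_reference.csv",
                              package = "oralproj"),
                  check.names = FALSE)
}
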