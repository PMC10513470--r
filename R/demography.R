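# Cohort-component demographic engine: the annual aging chain (single-year
# cohorts 0..99 plus an open 100+ accumulator), life-table mortality, births
# from the fecund female population, and net migration. All disease chains
# ride on this engine, so its within-year ordering (mortality -> migration ->
# aging with births) is the single source of truth for both.

#' Life table of annual death probabilities
#'
#' @param q Either a 101 x 2 matrix of annual death probabilities (rows ages
#'   0..100 where 100 is the open 100+ cohort, columns `male`/`female`), or a
#'   long data frame with columns `age`, `sex`, `q`.
#' @return An object of class `life_table`.
#' @examples
#' lt <- life_table(matrix(0.01, 101, 2))
#' @export
life_table <- function(q) {
  if (is.data.frame(q)) q <- .df_to_age_sex_matrix(q, "q")
  q <- .check_age_sex_matrix(q, "q")
  if (any(q < 0 | q > 1)) stopf("death probabilities q must lie in [0, 1]")
  structure(list(q = q), class = "life_table")
}

#' Age-specific fertility schedule
#'
#' Births per woman per year for ages 15--49; fertility is zero outside that
#' range. The sex ratio at birth is a configurable male fraction (default
#' 0.512, the conventional ~105:100 ratio).
#'
#' @param f Numeric vector of length 35 named (or ordered) by ages 15..49,
#'   or a data frame with columns `age`, `f`.
#' @param male_fraction Fraction of births that are male, in (0, 1).
#' @return An object of class `fertility_schedule` whose `f` element spans
#'   the full 0..100 age grid (zero outside 15--49).
#' @examples
#' fert <- fertility_schedule(rep(0.05, 35))
#' @export
fertility_schedule <- function(f, male_fraction = 0.512) {
  if (is.data.frame(f)) {
    if (!all(c("age", "f") %in% names(f))) stopf("expected columns age, f")
    v <- numeric(35)
    i <- match(f$age, 15:49)
    if (anyNA(i)) stopf("fertility ages must lie in 15..49")
    v[i] <- f$f
    f <- v
  }
  if (length(f) != 35L) stopf("'f' must cover ages 15..49 (length 35)")
  if (any(!is.finite(f)) || any(f < 0)) stopf("fertility rates must be finite and >= 0")
  if (!is.finite(male_fraction) || male_fraction <= 0 || male_fraction >= 1) {
    stopf("male_fraction must lie strictly in (0, 1)")
  }
  full <- numeric(.n_ages)
  names(full) <- .ages
  full[as.character(15:49)] <- f
  structure(list(f = full, male_fraction = male_fraction),
            class = "fertility_schedule")
}

#' Population by single year of age and sex
#'
#' @param n 101 x 2 matrix of headcounts (ages 0..100+, `male`/`female`) or a
#'   long data frame with columns `age`, `sex`, `n`.
#' @param year Calendar year of the snapshot.
#' @return An object of class `population_vector`.
#' @export
population_vector <- function(n, year) {
  if (is.data.frame(n)) n <- .df_to_age_sex_matrix(n, "n")
  n <- .check_age_sex_matrix(n, "n")
  if (any(n < 0)) stopf("population counts must be >= 0")
  structure(list(n = n, year = as.integer(year)), class = "population_vector")
}

#' @export
print.population_vector <- function(x, ...) {
  cat(sprintf("<population_vector> year %d, total %.1f persons\n",
              x$year, sum(x$n)))
  invisible(x)
}

#' Total headcount of a population snapshot
#' @param pop A `population_vector`.
#' @return Total persons.
#' @export
total_population <- function(pop) sum(pop$n)

#' Net migration schedule
#'
#' Net migrants per cohort per year (immigrants minus emigrants; may be
#' negative). An optional global scaler multiplies the whole profile, which
#' is the single free migration parameter exposed to calibration.
#'
#' @param m 101 x 2 matrix or long data frame with columns `age`, `sex`, `m`.
#' @param scaler Dimensionless multiplier applied to the profile.
#' @return An object of class `migration_schedule`.
#' @export
migration_schedule <- function(m, scaler = 1) {
  if (is.data.frame(m)) m <- .df_to_age_sex_matrix(m, "m")
  m <- .check_age_sex_matrix(m, "m")
  if (!is.finite(scaler) || scaler < 0) stopf("migration scaler must be >= 0")
  structure(list(m = m, scaler = scaler), class = "migration_schedule")
}

# Effective migration flows (profile times scaler).
migration_flows <- function(mig) mig$m * mig$scaler

#' Births over one year
#'
#' Births are the fecund female population (ages 15--49) times the
#' age-specific fertility rate, split by the male fraction at birth.
#'
#' @param pop A `population_vector` (start-of-year stocks).
#' @param fert A `fertility_schedule`.
#' @return Named numeric `c(male =, female =)`, persons per year.
#' @examples
#' pop <- population_vector(matrix(100, 101, 2), 2020)
#' fert <- fertility_schedule(rep(0.05, 35))
#' compute_births(pop, fert)
#' @export
compute_births <- function(pop, fert) {
  if (!inherits(fert, "fertility_schedule")) stopf("'fert' must be a fertility_schedule")
  total <- sum(fert$f * pop$n[, "female"])
  c(male = total * fert$male_fraction,
    female = total * (1 - fert$male_fraction))
}

#' Apply one year of life-table mortality
#'
#' Survivors are `n * (1 - q)` and deaths `n * q`, cell by cell, so
#' survivors + deaths reconstitute the input exactly.
#'
#' @param pop A `population_vector`.
#' @param lt A `life_table`.
#' @return List with `survivors` (a `population_vector`, same year) and
#'   `deaths` (101 x 2 matrix).
#' @export
apply_mortality <- function(pop, lt) {
  if (!inherits(lt, "life_table")) stopf("'lt' must be a life_table")
  surv <- pop$n * (1 - lt$q)
  deaths <- pop$n * lt$q
  list(survivors = population_vector(surv, pop$year), deaths = deaths)
}

#' Advance every cohort one year of age
#'
#' Survivors in each single-year cohort flow to the next; the final cohort
#' (100+) is an open accumulator that retains its own survivors and receives
#' those aging out of 99. Newborns enter age 0.
#'
#' @param pop A `population_vector` of survivors.
#' @param newborns Named numeric `c(male =, female =)`.
#' @return A `population_vector` (year unchanged; [step_year()] increments it).
#' @export
shift_ages <- function(pop, newborns = c(male = 0, female = 0)) {
  if (any(newborns < 0)) stopf("newborns must be >= 0")
  n <- pop$n
  out <- matrix(0, .n_ages, 2L, dimnames = dimnames(n))
  out[1L, ] <- newborns[.sexes]
  out[2:.n_ages, ] <- n[1:(.n_ages - 1L), ]
  out[.n_ages, ] <- out[.n_ages, ] + n[.n_ages, ]  # open 100+ cohort persists
  population_vector(out, pop$year)
}

#' One calendar-year demographic update
#'
#' Applies, in fixed order: (1) mortality on start-of-year stocks,
#' (2) net migration, flow-limited so no cell goes negative, (3) the aging
#' shift with births (computed from start-of-year stocks) entering age 0.
#' The balance identity
#' `total(t+1) = total(t) - deaths + births + realized_migration`
#' holds exactly under this ordering.
#'
#' @param pop A `population_vector`.
#' @param lt A `life_table`.
#' @param fert A `fertility_schedule`.
#' @param mig A `migration_schedule`.
#' @return A `population_vector` for `year + 1`, with an attribute `flows`
#'   (list of `deaths`, `births`, `migration_realized`) for accounting.
#' @export
step_year <- function(pop, lt, fert, mig) {
  births <- compute_births(pop, fert)
  mort <- apply_mortality(pop, lt)
  surv <- mort$survivors$n
  m <- migration_flows(mig)
  realized <- pmax(m, -surv)  # flow-limited: out-migration cannot exceed the stock
  if (any(realized > m + 1e-12)) {
    warnf("net migration flow-limited in %d cell(s) to keep cohorts non-negative",
          sum(realized > m + 1e-12))
  }
  after <- population_vector(surv + realized, pop$year)
  out <- shift_ages(after, births)
  out$year <- pop$year + 1L
  attr(out, "flows") <- list(deaths = sum(mort$deaths),
                             births = sum(births),
                             migration_realized = sum(realized))
  out
}

#' Project the population forward
#'
#' Iterates [step_year()] with rates held constant over time. Returns
#' `n_years + 1` snapshots including the initial state.
#'
#' @inheritParams step_year
#' @param n_years Number of annual steps (>= 0).
#' @return List of `population_vector`s named by calendar year.
#' @export
project_population <- function(pop, lt, fert, mig, n_years) {
  if (n_years < 0) stopf("n_years must be >= 0")
  out <- vector("list", n_years + 1L)
  out[[1L]] <- pop
  if (n_years > 0) {
    for (i in seq_len(n_years)) out[[i + 1L]] <- step_year(out[[i]], lt, fert, mig)
  }
  names(out) <- vapply(out, function(p) as.character(p$year), character(1))
  out
}
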