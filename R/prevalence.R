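# Prevalence tables and calibration targets. Cross-sectional surveys report
# state prevalence by age band; the model needs per-single-age state counts
# (initialization) and a yearly target series (calibration). Prevalence is
# treated as a step function: constant within a band.

#' Age-band prevalence table for one chain
#'
#' Proportions of each age band and sex in every health state, from a
#' cross-sectional survey at `reference_year`. Bands are half-open integer
#' intervals `[age_lo, age_hi)` that must tile the chain's adult range
#' (entry age .. 100+) without gap or overlap, and each (band, sex) row set
#' must sum to 1 over states.
#'
#' @param df Data frame with columns `age_lo`, `age_hi`, `sex`, `state`, `p`.
#' @param spec A `chain_spec`.
#' @param reference_year Calendar year the proportions refer to.
#' @return An object of class `prevalence_table` holding the long table plus
#'   a `p` array (band x sex x state) and band bounds.
#' @export
prevalence_table <- function(df, spec, reference_year) {
  need <- c("age_lo", "age_hi", "sex", "state", "p")
  if (!all(need %in% names(df))) {
    stopf("expected columns %s", paste(need, collapse = ", "))
  }
  bands <- unique(df[order(df$age_lo), c("age_lo", "age_hi")])
  if (bands$age_lo[1L] != spec$entry_age || bands$age_hi[nrow(bands)] != 101L ||
      (nrow(bands) > 1L && any(bands$age_hi[-nrow(bands)] != bands$age_lo[-1L]))) {
    stopf("bands must tile [%d, 101) without gap or overlap", spec$entry_age)
  }
  K <- length(spec$states)
  B <- nrow(bands)
  p <- array(NA_real_, c(B, 2L, K),
             dimnames = list(band = paste0(bands$age_lo, "-", bands$age_hi - 1L),
                             sex = .sexes, state = spec$states))
  bi <- match(df$age_lo, bands$age_lo)
  si <- match(df$sex, .sexes)
  ki <- match(df$state, spec$states)
  if (anyNA(bi) || anyNA(si) || anyNA(ki)) stopf("unknown sex or state label in table")
  p[cbind(bi, si, ki)] <- df$p
  if (anyNA(p)) stopf("every (band, sex, state) cell must be present")
  if (any(p < 0 | p > 1)) stopf("proportions must lie in [0, 1]")
  sums <- apply(p, c(1, 2), sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stopf("state proportions must sum to 1 for every (band, sex); worst deviation %.3g",
          max(abs(sums - 1)))
  }
  structure(list(table = df, p = p, bands = bands, spec_name = spec$name,
                 reference_year = as.integer(reference_year)),
            class = "prevalence_table")
}

# Band index for each single age >= entry_age (vector over matrix rows).
.band_of_age <- function(ages, bands) findInterval(ages, bands$age_lo)

#' Initialize a state tensor from a prevalence table
#'
#' Distributes each adult cohort across health states by the band's
#' prevalence proportions: `c(age, sex, state) = p(band(age), sex, state) *
#' n(age, sex)`. Pre-entry cohorts are copied from the population into the
#' disease-free state, so state sums reconstitute the population everywhere.
#'
#' @param prev A `prevalence_table`.
#' @param pop A `population_vector`.
#' @param spec The matching `chain_spec`.
#' @return A `state_tensor` at the population's year.
#' @export
initialize_states <- function(prev, pop, spec) {
  if (prev$spec_name != spec$name) stopf("prevalence table is for chain '%s'", prev$spec_name)
  K <- length(spec$states)
  a <- array(0, c(.n_ages, 2L, K))
  pre <- seq_len(spec$entry_age)              # rows for ages < entry_age
  adult <- (spec$entry_age + 1L):.n_ages
  a[pre, , 1L] <- pop$n[pre, ]
  b <- .band_of_age(.ages[adult], prev$bands)
  for (s in seq_len(K)) {
    a[adult, , s] <- prev$p[b, , s] * pop$n[adult, ]
  }
  state_tensor(a, spec, pop$year)
}

#' Aggregate a state tensor to age bands
#'
#' @param tensor A `state_tensor`.
#' @param bands Data frame with columns `age_lo`, `age_hi` (half-open).
#' @param by_sex Keep the sex split (default) or sum over sexes.
#' @return Long data frame: `year`, `age_lo`, `age_hi`, (`sex`,) `state`,
#'   `count`.
#' @export
aggregate_to_bands <- function(tensor, bands, by_sex = TRUE) {
  spec <- tensor$spec
  rows <- lapply(seq_len(nrow(bands)), function(b) {
    idx <- which(.ages >= bands$age_lo[b] & .ages < bands$age_hi[b])
    sub <- tensor$counts[idx, , , drop = FALSE]
    if (by_sex) {
      cnt <- colSums(sub)  # sums over ages -> sex x state
      data.frame(year = tensor$year, age_lo = bands$age_lo[b], age_hi = bands$age_hi[b],
                 sex = rep(.sexes, times = length(spec$states)),
                 state = rep(spec$states, each = 2L),
                 count = c(cnt))
    } else {
      cnt <- colSums(sub, dims = 2L)  # sums over ages and sexes -> state
      data.frame(year = tensor$year, age_lo = bands$age_lo[b], age_hi = bands$age_hi[b],
                 state = spec$states, count = unname(cnt))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Prevalence-times-population calibration target series
#'
#' Builds the yearly target counts by applying the (fixed, reference-year)
#' band prevalence proportions to each population snapshot and aggregating to
#' the table's own bands — the standard construction when only one
#' cross-sectional survey is available: prevalence held constant, the
#' population carrying the demographic trend.
#'
#' @param prev A `prevalence_table`.
#' @param pop_traj Non-empty list of `population_vector`s (e.g. from
#'   [project_population()]).
#' @param spec The matching `chain_spec`.
#' @return Long data frame: `year`, `age_lo`, `age_hi`, `sex`, `state`,
#'   `count`.
#' @export
build_target_series <- function(prev, pop_traj, spec) {
  if (length(pop_traj) == 0L) stopf("pop_traj must be non-empty")
  out <- do.call(rbind, lapply(pop_traj, function(pop) {
    aggregate_to_bands(initialize_states(prev, pop, spec), prev$bands, by_sex = TRUE)
  }))
  rownames(out) <- NULL
  out
}
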