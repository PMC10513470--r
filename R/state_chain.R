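# Generic age/sex-structured multi-state disease layer over the demographic
# engine. A chain is described declaratively (states, entry age, rate-named
# edges) and instantiated three times: dental caries (3 states, with a
# treated -> untreated backward edge), periodontal pocketing (4 states,
# forward-only) and periodontal loss of attachment (4 states, forward-only,
# entry at age 55).
#
# Representation: a StateTensor is a 101 x 2 x K array (age x sex x state).
# Everyone younger than the chain's entry age sits in state 1 (the
# disease-free state), which is also where new entrants land when the aging
# shift carries them across the entry age — so the pooled pre-entry aging
# chain and the "direct entry into the disease-free state" assumption fall
# out of the array layout with no special cases.

#' Declarative description of one disease chain
#'
#' @param name Chain label.
#' @param states Ordered character vector of state labels; state 1 is the
#'   disease-free entry state.
#' @param entry_age Age at which individuals enter the chain's adult states
#'   (16 for caries and pocketing, 55 for loss of attachment).
#' @param edges Data frame with columns `from`, `to` (state labels or
#'   indices) and `rate` (the rate name governing that flow).
#' @return An object of class `chain_spec`.
#' @seealso [make_caries_spec()], [make_pocketing_spec()], [make_loa_spec()]
#' @export
chain_spec <- function(name, states, entry_age, edges) {
  if (length(states) < 2L) stopf("a chain needs at least two states")
  if (anyDuplicated(states)) stopf("state labels must be unique")
  if (entry_age < 1 || entry_age > 100) stopf("entry_age must lie in 1..100")
  if (!all(c("from", "to", "rate") %in% names(edges))) {
    stopf("edges must have columns from, to, rate")
  }
  to_idx <- function(x) {
    i <- if (is.numeric(x)) as.integer(x) else match(x, states)
    if (anyNA(i) || any(i < 1L | i > length(states))) stopf("edge references unknown state")
    i
  }
  edges <- data.frame(from = to_idx(edges$from), to = to_idx(edges$to),
                      rate = as.character(edges$rate), stringsAsFactors = FALSE)
  if (any(edges$from == edges$to)) stopf("self-loop edges are not allowed")
  if (anyDuplicated(edges$rate)) stopf("rate names must be unique")
  structure(list(name = name, states = states, entry_age = as.integer(entry_age),
                 entry_state = 1L, edges = edges),
            class = "chain_spec")
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf("<chain_spec> %s: %d states, entry at age %d\n",
              x$name, length(x$states), x$entry_age))
  for (i in seq_len(nrow(x$edges))) {
    cat(sprintf("  %s -> %s  [%s]\n", x$states[x$edges$from[i]],
                x$states[x$edges$to[i]], x$edges$rate[i]))
  }
  invisible(x)
}

#' Rate names of a chain
#' @param spec A `chain_spec`.
#' @return Character vector of rate names in edge order.
#' @export
rate_names <- function(spec) spec$edges$rate

#' Dental caries chain: no caries, untreated caries, treated caries
#'
#' Entry at age 16 into the no-caries state. Flows: caries incidence
#' (no caries -> untreated), treatment uptake (untreated -> treated) and
#' treatment cessation (treated -> untreated, the single backward edge).
#' @return A `chain_spec`.
#' @export
make_caries_spec <- function() {
  chain_spec(
    name = "caries",
    states = c("no_caries", "untreated_caries", "treated_caries"),
    entry_age = 16L,
    edges = data.frame(
      from = c("no_caries", "untreated_caries", "treated_caries"),
      to = c("untreated_caries", "treated_caries", "untreated_caries"),
      rate = c("caries_incidence", "treatment_uptake", "treatment_cessation")
    )
  )
}

#' Periodontal pocketing chain: none, 4--<6 mm, 6--<9 mm, 9+ mm
#'
#' Entry at age 16; strictly forward progression through the pocketing
#' severity thresholds (no recovery edge).
#' @return A `chain_spec`.
#' @export
make_pocketing_spec <- function() {
  chain_spec(
    name = "pocketing",
    states = c("no_pocketing", "pocketing_4_6mm", "pocketing_6_9mm", "pocketing_9mm_plus"),
    entry_age = 16L,
    edges = data.frame(
      from = c("no_pocketing", "pocketing_4_6mm", "pocketing_6_9mm"),
      to = c("pocketing_4_6mm", "pocketing_6_9mm", "pocketing_9mm_plus"),
      rate = c("incidence_4mm", "trans_4_to_6", "trans_6_to_9")
    )
  )
}

#' Loss-of-attachment chain: none, 4--<6 mm, 6--<9 mm, 9+ mm
#'
#' Loss of attachment is assessed only from age 55, so entry is at 55:
#' individuals aged 54 transition into the no-LOA state. Strictly forward
#' progression.
#' @return A `chain_spec`.
#' @export
make_loa_spec <- function() {
  chain_spec(
    name = "loa",
    states = c("no_loa", "loa_4_6mm", "loa_6_9mm", "loa_9mm_plus"),
    entry_age = 55L,
    edges = data.frame(
      from = c("no_loa", "loa_4_6mm", "loa_6_9mm"),
      to = c("loa_4_6mm", "loa_6_9mm", "loa_9mm_plus"),
      rate = c("incidence_4mm_loa", "trans_4_to_6_loa", "trans_6_to_9_loa")
    )
  )
}

#' Calibrated transition rates for a chain
#'
#' One scalar per rate name and sex, in fraction of the source stock per
#' year. Rates are age-constant. A plain named numeric ties the sexes; a
#' two-column matrix (or list of two named vectors) sets them separately.
#'
#' @param spec A `chain_spec`.
#' @param values Named numeric (applied to both sexes) or a matrix with
#'   rownames = rate names and columns `male`, `female`.
#' @return An object of class `rate_set` with a `values` matrix (rate x sex).
#' @examples
#' rs <- rate_set(make_caries_spec(),
#'                c(caries_incidence = 0.04, treatment_uptake = 0.30,
#'                  treatment_cessation = 0.05))
#' @export
rate_set <- function(spec, values) {
  rn <- rate_names(spec)
  if (is.matrix(values)) {
    v <- values[rn, .sexes, drop = FALSE]
  } else {
    if (is.null(names(values))) stopf("rate values must be named")
    if (!all(rn %in% names(values))) {
      stopf("missing rate(s): %s", paste(setdiff(rn, names(values)), collapse = ", "))
    }
    v <- cbind(male = values[rn], female = values[rn])
  }
  if (anyNA(v) || any(v < 0 | v > 1)) stopf("all rates must lie in [0, 1]")
  rownames(v) <- rn
  structure(list(chain = spec$name, values = v), class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("<rate_set> chain %s\n", x$chain))
  print(round(x$values, 6))
  invisible(x)
}

#' Age x sex x health-state headcounts for one chain
#'
#' @param counts 101 x 2 x K array (age 0..100+, sex, state). Ages below the
#'   chain's entry age must hold their whole cohort in state 1.
#' @param spec A `chain_spec`.
#' @param year Calendar year.
#' @return An object of class `state_tensor`.
#' @export
state_tensor <- function(counts, spec, year) {
  K <- length(spec$states)
  if (!is.array(counts) || !identical(dim(counts), c(.n_ages, 2L, K))) {
    stopf("counts must be a %d x 2 x %d array", .n_ages, K)
  }
  dimnames(counts) <- list(age = .ages, sex = .sexes, state = spec$states)
  if (any(counts < 0)) stopf("state counts must be >= 0")
  if (spec$entry_age > 0 && K > 1) {
    pre <- seq_len(spec$entry_age)  # rows for ages 0..entry_age-1
    if (any(counts[pre, , -1L] != 0)) {
      stopf("ages below entry age %d must be entirely in state '%s'",
            spec$entry_age, spec$states[1L])
    }
  }
  structure(list(counts = counts, spec = spec, year = as.integer(year)),
            class = "state_tensor")
}

#' @export
print.state_tensor <- function(x, ...) {
  tot <- apply(x$counts, 3, sum)
  cat(sprintf("<state_tensor> chain %s, year %d\n", x$spec$name, x$year))
  print(round(tot, 1))
  invisible(x)
}

#' All-disease-free state tensor from a population snapshot
#'
#' Places every cohort in state 1 (pre-entry ages pooled there by
#' construction). The usual starting point for burn-in simulations.
#'
#' @param pop A `population_vector`.
#' @param spec A `chain_spec`.
#' @return A `state_tensor`.
#' @export
disease_free_tensor <- function(pop, spec) {
  K <- length(spec$states)
  a <- array(0, c(.n_ages, 2L, K))
  a[, , 1L] <- pop$n
  state_tensor(a, spec, pop$year)
}

#' Marginal population of a state tensor
#'
#' Sums over states (including the pre-entry pool), recovering the
#' whole-population snapshot the chain is riding on.
#'
#' @param tensor A `state_tensor`.
#' @return A `population_vector`.
#' @export
chain_population <- function(tensor) {
  population_vector(.state_sum(tensor$counts), tensor$year)
}

# Sum an age x sex x state array over states (faster than apply()).
.state_sum <- function(a) {
  tot <- a[, , 1L]
  for (s in seq_len(dim(a)[3L])[-1L]) tot <- tot + a[, , s]
  tot
}

#' One-year update of a disease chain
#'
#' Applies, in fixed order: (1) state-transition flows computed
#' simultaneously from start-of-year stocks as `rate x stock` for every edge
#' (ages at or above the entry age only); (2) life-table mortality, identical
#' across states within an age/sex cell; (3) net migration allocated across
#' states within each cohort (proportionally to current occupancy by
#' default), flow-limited so no cell goes negative; (4) the aging shift with
#' births entering age 0 — survivors crossing the entry age land in the
#' disease-free state. If the combined outflow fraction from a state exceeds
#' 1, that state's rates are proportionally rescaled for the year and a
#' warning is issued.
#'
#' @param tensor A `state_tensor` (start-of-year stocks).
#' @param rates A `rate_set` for the tensor's chain.
#' @param lt A `life_table`.
#' @param fert A `fertility_schedule`.
#' @param mig A `migration_schedule`.
#' @param migration_strategy How net migration is split across states within
#'   an age/sex cohort: `"proportional"` to current occupancy (default) or
#'   `"disease_free_only"`.
#' @return A `state_tensor` for `year + 1`.
#' @export
step_chain <- function(tensor, rates, lt, fert, mig,
                       migration_strategy = c("proportional", "disease_free_only")) {
  migration_strategy <- match.arg(migration_strategy)
  spec <- tensor$spec
  if (!inherits(rates, "rate_set") || rates$chain != spec$name) {
    stopf("rates must be a rate_set for chain '%s'", spec$name)
  }
  K <- length(spec$states)
  c0 <- tensor$counts
  adult <- (spec$entry_age + 1L):.n_ages  # matrix rows for ages >= entry_age

  # births from start-of-year stocks
  births <- compute_births(chain_population(tensor), fert)

  # (1) simultaneous transition flows from start-of-year stocks
  out_frac <- sapply(1:2, function(sx) {
    vapply(seq_len(K), function(s)
      sum(rates$values[spec$edges$rate[spec$edges$from == s], sx]), numeric(1))
  })
  if (any(out_frac > 1)) {
    warnf("chain '%s': combined outflow fraction > 1 for state(s) %s; rates rescaled",
          spec$name,
          paste(spec$states[apply(out_frac > 1, 1, any)], collapse = ", "))
  }
  ct <- c0
  for (sx in 1:2) {
    r <- rates$values[, sx]
    rescale <- ifelse(out_frac[, sx] > 1, 1 / out_frac[, sx], 1)
    delta <- matrix(0, length(adult), K)
    for (e in seq_len(nrow(spec$edges))) {
      from <- spec$edges$from[e]; to <- spec$edges$to[e]
      fl <- r[spec$edges$rate[e]] * rescale[from] * c0[adult, sx, from]
      delta[, from] <- delta[, from] - fl
      delta[, to] <- delta[, to] + fl
    }
    ct[adult, sx, ] <- ct[adult, sx, ] + delta
  }

  # (2) mortality, state-independent within age/sex
  surv <- ct * rep(c(1 - lt$q), K)

  # (3) net migration, flow-limited at the cohort level then split by state
  m <- migration_flows(mig)
  tot <- .state_sum(surv)
  realized <- pmax(m, -tot)
  if (any(realized > m + 1e-12)) {
    warnf("chain '%s': net migration flow-limited in %d cell(s)",
          spec$name, sum(realized > m + 1e-12))
  }
  if (migration_strategy == "proportional") {
    share <- array(0, dim(surv))
    pos <- tot > 0
    for (s in seq_len(K)) {
      sl <- matrix(0, .n_ages, 2L)
      sl[pos] <- surv[, , s][pos] / tot[pos]
      share[, , s] <- sl
    }
    # empty cohorts receiving migrants: put them in the disease-free state
    share[, , 1L][!pos] <- 1
    surv <- surv + array(rep(c(realized), K), dim(surv)) * share
  } else {
    free <- surv[, , 1L]
    short <- realized < -free
    if (any(short)) {
      warnf("chain '%s': out-migration capped at the disease-free stock in %d cell(s)",
            spec$name, sum(short))
      realized <- pmax(realized, -free)
    }
    surv[, , 1L] <- free + realized
  }
  surv[surv < 0 & surv > -1e-9] <- 0  # clip tiny negative round-off

  # (4) aging shift; newborns enter age 0, disease-free
  out <- array(0, dim(surv))
  out[2:.n_ages, , ] <- surv[1:(.n_ages - 1L), , ]
  out[.n_ages, , ] <- out[.n_ages, , ] + surv[.n_ages, , ]
  out[1L, , 1L] <- births[.sexes]

  res <- state_tensor(out, spec, tensor$year + 1L)
  attr(res, "flows") <- list(births = sum(births),
                             migration_realized = sum(realized))
  res
}

#' Project a disease chain forward
#'
#' Iterates [step_chain()] with constant rates. The state-marginal totals of
#' the result equal the demography-only projection with identical inputs (to
#' floating-point accuracy), since transitions move people between states,
#' never in or out of the population.
#'
#' @inheritParams step_chain
#' @param n_years Number of annual steps (>= 0).
#' @return List of `state_tensor`s named by calendar year.
#' @export
project_chain <- function(tensor, rates, lt, fert, mig, n_years,
                          migration_strategy = "proportional") {
  if (n_years < 0) stopf("n_years must be >= 0")
  out <- vector("list", n_years + 1L)
  out[[1L]] <- tensor
  if (n_years > 0) {
    for (i in seq_len(n_years)) {
      out[[i + 1L]] <- step_chain(out[[i]], rates, lt, fert, mig,
                                  migration_strategy = migration_strategy)
    }
  }
  names(out) <- vapply(out, function(t) as.character(t$year), character(1))
  out
}
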