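# Shared fixtures. Heavy artefacts (the synthetic study, calibrations) are
# memoised so every test file reuses one computation.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

cached_study <- function() memo("study", generate_study(synthetic_scenario()))

cached_calibration <- function(chain, noisy = FALSE) {
  memo(paste0("cal_", chain, if (noisy) "_noisy"), {
    study <- cached_study()
    d <- study$demography
    ch <- study$chains[[chain]]
    targets <- if (noisy) add_target_noise(ch$targets, sd = 0.05, seed = 7L) else ch$targets
    problem <- calibration_problem(ch$spec, ch$tensor0, targets,
                                   d$lt, d$fert, d$mig)
    calibrate(problem)
  })
}

# Simple deterministic demography for unit tests: flat mortality, single-age
# fertility, no migration.
toy_demography <- function(q = 0.01, f30 = 0, n_per_age = 100, year = 2000L) {
  lt <- life_table(matrix(q, 101, 2))
  f <- numeric(35)
  f[30 - 15 + 1] <- f30
  fert <- fertility_schedule(f, male_fraction = 0.5)
  mig <- migration_schedule(matrix(0, 101, 2))
  pop <- population_vector(matrix(n_per_age, 101, 2), year)
  list(lt = lt, fert = fert, mig = mig, pop = pop)
}

zero_migration <- function() migration_schedule(matrix(0, 101, 2))

# Place `counts` (vector over states) at a single age for both sexes,
# everything else zero.
single_cohort_tensor <- function(spec, age, counts, year = 2000L) {
  K <- length(spec$states)
  a <- array(0, c(101, 2, K))
  a[age + 1, 1, ] <- counts
  a[age + 1, 2, ] <- counts
  state_tensor(a, spec, year)
}

# Independent reference implementation of the one-year chain update:
# explicit per-cell, per-edge loops, same ordering contract (simultaneous
# transitions from start-of-year stocks -> mortality -> proportional
# migration -> aging with births). Deliberately written without reusing any
# package internals beyond the input accessors.
reference_step_chain <- function(tensor, rates, lt, fert, mig) {
  spec <- tensor$spec
  K <- length(spec$states)
  c0 <- tensor$counts
  sexes <- c("male", "female")

  # births from start-of-year stocks
  total_births <- 0
  for (age in 15:49) {
    nf <- 0
    for (s in seq_len(K)) nf <- nf + c0[age + 1, "female", s]
    total_births <- total_births + fert$f[[as.character(age)]] * nf
  }
  births <- c(male = total_births * fert$male_fraction,
              female = total_births * (1 - fert$male_fraction))

  # simultaneous transitions for ages >= entry_age
  ct <- c0
  for (age in spec$entry_age:100) {
    for (sx in 1:2) {
      outflow <- numeric(K); inflow <- numeric(K)
      for (e in seq_len(nrow(spec$edges))) {
        from <- spec$edges$from[e]; to <- spec$edges$to[e]
        r <- rates$values[spec$edges$rate[e], sx]
        fl <- r * c0[age + 1, sx, from]
        outflow[from] <- outflow[from] + fl
        inflow[to] <- inflow[to] + fl
      }
      for (s in seq_len(K)) {
        # proportional rescale if a state's combined outflow exceeds stock
        if (outflow[s] > c0[age + 1, sx, s]) stop("outflow cap hit in reference")
        ct[age + 1, sx, s] <- c0[age + 1, sx, s] - outflow[s] + inflow[s]
      }
    }
  }

  # mortality, then proportional migration, per cell
  m <- mig$m * mig$scaler
  surv <- ct
  for (age in 0:100) for (sx in 1:2) {
    tot <- 0
    for (s in seq_len(K)) {
      surv[age + 1, sx, s] <- ct[age + 1, sx, s] * (1 - lt$q[age + 1, sx])
      tot <- tot + surv[age + 1, sx, s]
    }
    realized <- max(m[age + 1, sx], -tot)
    for (s in seq_len(K)) {
      share <- if (tot > 0) surv[age + 1, sx, s] / tot else (s == 1)
      surv[age + 1, sx, s] <- surv[age + 1, sx, s] + realized * share
    }
  }

  # aging with the open 100+ cohort and newborns
  out <- array(0, dim(surv), dimnames = dimnames(surv))
  for (age in 0:99) out[age + 2, , ] <- surv[age + 1, , ]
  out[101, , ] <- out[101, , ] + surv[101, , ]
  out[1, "male", 1] <- births[["male"]]
  out[1, "female", 1] <- births[["female"]]
  state_tensor(out, spec, tensor$year + 1L)
}
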