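# Monte-Carlo sensitivity analysis: all model parameters (fertility, net
# migration and mortality as scalar multipliers on their age-specific
# schedules, plus the nine chain transition rates) varied simultaneously and
# uniformly by +/- a fraction of their base value; the model is re-run per
# draw and per-output uncertainty envelopes are summarized as the ensemble
# mean with empirical 2.5/97.5 percentile bounds (min/max also reported).

#' Monte-Carlo sensitivity design
#'
#' @param variation Fraction by which each parameter is varied around its
#'   base value (0.5 = +/-50%), in `[0, 1)`.
#' @param n_runs Number of ensemble runs (>= 1).
#' @param seed Integer seed; the whole ensemble is reproducible from it.
#' @return An object of class `sensitivity_design`.
#' @export
sensitivity_design <- function(variation = 0.5, n_runs = 500L, seed = 42L) {
  if (!is.finite(variation) || variation < 0 || variation >= 1) {
    stopf("variation must lie in [0, 1)")
  }
  if (n_runs < 1L) stopf("n_runs must be >= 1")
  structure(list(variation = variation, n_runs = as.integer(n_runs),
                 seed = as.integer(seed)),
            class = "sensitivity_design")
}

#' Model inputs bundle for ensemble runs
#'
#' @param lt,fert,mig Baseline demographic inputs.
#' @param chains Named list; each element a list with `spec` (`chain_spec`),
#'   `rates` (`rate_set`) and `tensor0` (initial `state_tensor`).
#' @param n_years Projection horizon in years.
#' @param bands Data frame (`age_lo`, `age_hi`) used to aggregate outputs.
#' @return An object of class `model_inputs`.
#' @export
model_inputs <- function(lt, fert, mig, chains, n_years, bands) {
  if (length(chains) == 0L) stopf("at least one chain is required")
  structure(list(lt = lt, fert = fert, mig = mig, chains = chains,
                 n_years = as.integer(n_years), bands = bands),
            class = "model_inputs")
}

# Base parameter vector: unit multipliers for the age-specific schedules and
# the (sex-averaged) transition rates of every chain.
.base_parameters <- function(inputs) {
  base <- c(fertility = 1, migration = 1, mortality = 1)
  for (nm in names(inputs$chains)) {
    v <- rowMeans(inputs$chains[[nm]]$rates$values)
    base <- c(base, v)
  }
  base
}

#' Draw parameter sets for a sensitivity ensemble
#'
#' Each parameter is drawn independently, uniformly on
#' `[base * (1 - v), base * (1 + v)]`. Schedule parameters (fertility,
#' migration, mortality) are multipliers with base 1; rate parameters are the
#' rates themselves, clipped to `[0, 1]` after the draw.
#'
#' @param design A `sensitivity_design`.
#' @param base Named numeric of base parameter values (see
#'   [model_inputs()]; computed automatically by [run_ensemble()]).
#' @return Data frame of `n_runs` rows, one column per parameter, plus a
#'   `run` id column.
#' @export
sample_parameters <- function(design, base) {
  v <- design$variation
  set.seed(design$seed)
  draws <- matrix(stats::runif(design$n_runs * length(base)),
                  nrow = design$n_runs)
  colnames(draws) <- names(base)
  for (j in seq_along(base)) {
    lo <- base[j] * (1 - v); hi <- base[j] * (1 + v)
    draws[, j] <- lo + (hi - lo) * draws[, j]
  }
  rates <- setdiff(names(base), c("fertility", "migration", "mortality"))
  draws[, rates] <- pmin(pmax(draws[, rates, drop = FALSE], 0), 1)
  data.frame(run = seq_len(design$n_runs), draws, check.names = FALSE)
}

# One full model run under a drawn parameter set; returns the banded output
# table (summed over sexes) for every chain and year.
.run_once <- function(params, inputs) {
  lt <- life_table(pmin(inputs$lt$q * params[["mortality"]], 1))
  f <- inputs$fert$f[as.character(15:49)] * params[["fertility"]]
  fert <- fertility_schedule(f, inputs$fert$male_fraction)
  mig <- inputs$mig
  mig$m <- mig$m * params[["migration"]]
  out <- lapply(names(inputs$chains), function(nm) {
    ch <- inputs$chains[[nm]]
    rs <- rate_set(ch$spec, stats::setNames(
      params[rate_names(ch$spec)], rate_names(ch$spec)))
    traj <- project_chain(ch$tensor0, rs, lt, fert, mig, inputs$n_years)
    res <- do.call(rbind, lapply(traj, aggregate_to_bands,
                                 bands = inputs$bands, by_sex = FALSE))
    res$chain <- nm
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Run a Monte-Carlo sensitivity ensemble
#'
#' One full projection per parameter draw; runs are independent and the whole
#' ensemble is deterministic given the design seed. A failing run is
#' recorded, excluded, and counted in the `failed` attribute.
#'
#' @param design A `sensitivity_design`.
#' @param inputs A `model_inputs` bundle.
#' @return Long data frame (`run`, `chain`, `year`, `age_lo`, `age_hi`,
#'   `state`, `count`) with attributes `draws` (the parameter table) and
#'   `failed` (number of excluded runs).
#' @export
run_ensemble <- function(design, inputs) {
  base <- .base_parameters(inputs)
  draws <- sample_parameters(design, base)
  failed <- 0L
  out <- vector("list", design$n_runs)
  for (i in seq_len(design$n_runs)) {
    p <- unlist(draws[i, -1L])
    res <- tryCatch(.run_once(p, inputs), error = function(e) {
      warnf("ensemble run %d failed and was excluded: %s", i, conditionMessage(e))
      NULL
    })
    if (is.null(res)) { failed <- failed + 1L; next }
    res$run <- i
    out[[i]] <- res
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "draws") <- draws
  attr(out, "failed") <- failed
  out
}

#' Baseline (unperturbed) model run
#'
#' The same output table as one ensemble run, at the base parameter values.
#'
#' @param inputs A `model_inputs` bundle.
#' @return Long data frame (`chain`, `year`, `age_lo`, `age_hi`, `state`,
#'   `count`).
#' @export
run_baseline <- function(inputs) {
  .run_once(.base_parameters(inputs), inputs)
}

#' Uncertainty envelope of an ensemble
#'
#' Per output cell (chain x year x band x state): ensemble mean, empirical
#' percentile bounds at the requested level (2.5th/97.5th for `level = 0.95`,
#' linear-interpolation percentile definition), and the ensemble min/max.
#'
#' @param runs Ensemble output from [run_ensemble()].
#' @param level Central coverage level (default 0.95).
#' @return Data frame with columns `chain`, `year`, `age_lo`, `age_hi`,
#'   `state`, `mean`, `lower`, `upper`, `min`, `max`.
#' @export
envelope <- function(runs, level = 0.95) {
  if (is.null(runs) || nrow(runs) == 0L) stopf("ensemble output is empty")
  if (level <= 0 || level >= 1) stopf("level must lie in (0, 1)")
  a <- (1 - level) / 2
  key <- interaction(runs$chain, runs$year, runs$age_lo, runs$state, drop = TRUE)
  agg <- function(f) tapply(runs$count, key, f)
  first <- !duplicated(key)
  out <- data.frame(chain = runs$chain[first], year = runs$year[first],
                    age_lo = runs$age_lo[first], age_hi = runs$age_hi[first],
                    state = runs$state[first])
  k <- key[first]
  out$mean <- as.numeric(agg(mean)[k])
  out$lower <- as.numeric(tapply(runs$count, key, stats::quantile,
                                 probs = a, type = 7)[k])
  out$upper <- as.numeric(tapply(runs$count, key, stats::quantile,
                                 probs = 1 - a, type = 7)[k])
  out$min <- as.numeric(agg(min)[k])
  out$max <- as.numeric(agg(max)[k])
  out <- out[order(out$chain, out$year, out$age_lo, out$state), ]
  rownames(out) <- NULL
  out
}

#' Classical two-way sensitivity grid
#'
#' Varies exactly two parameters over a grid of multipliers of their base
#' values (all other parameters held at base) and runs the full model at
#' every grid point — the classical two-way design, complementing the
#' simultaneous Monte-Carlo ensemble.
#'
#' @param inputs A `model_inputs` bundle.
#' @param params Character vector of two parameter names (any of
#'   `"fertility"`, `"migration"`, `"mortality"` or a chain rate name).
#' @param multipliers Numeric vector of multipliers applied to each
#'   parameter's base value (default `c(0.5, 1, 1.5)`).
#' @return Long data frame: the ensemble output columns plus `mult_1`,
#'   `mult_2` identifying the grid point.
#' @export
two_way_grid <- function(inputs, params, multipliers = c(0.5, 1, 1.5)) {
  base <- .base_parameters(inputs)
  if (length(params) != 2L || !all(params %in% names(base))) {
    stopf("params must name exactly two of: %s",
          paste(names(base), collapse = ", "))
  }
  grid <- expand.grid(mult_1 = multipliers, mult_2 = multipliers)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    p <- base
    p[params[1L]] <- min(max(base[params[1L]] * grid$mult_1[i], 0),
                         if (params[1L] %in% c("fertility", "migration", "mortality")) Inf else 1)
    p[params[2L]] <- min(max(base[params[2L]] * grid$mult_2[i], 0),
                         if (params[2L] %in% c("fertility", "migration", "mortality")) Inf else 1)
    res <- .run_once(p, inputs)
    res$mult_1 <- grid$mult_1[i]
    res$mult_2 <- grid$mult_2[i]
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
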