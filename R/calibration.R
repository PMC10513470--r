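# Calibration of the age-constant transition rates (and optionally the net
# migration scaler) for one chain, by minimizing the weighted sum of squared
# relative errors between the projected banded state counts and a
# prevalence-derived target series. The optimizer is derivative-free
# (Nelder--Mead) run in a logit-transformed space so box bounds are respected
# exactly, with a fixed-seed multi-start for robustness.

#' Define a calibration problem for one chain
#'
#' @param spec A `chain_spec`.
#' @param tensor0 Initial `state_tensor`; its year must equal the first
#'   target year.
#' @param targets Long data frame (`year`, `age_lo`, `age_hi`, `sex`,
#'   `state`, `count`) covering at least two distinct years, e.g. from
#'   [build_target_series()] or [generate_study()].
#' @param lt,fert,mig Demographic inputs held fixed during calibration.
#' @param free Character vector of free parameter names: any subset of the
#'   chain's rate names, plus `"migration_scaler"` to calibrate the global
#'   migration multiplier.
#' @param bounds Named list of `c(lo, hi)` per free parameter. Defaults to
#'   `[0, 1]` for rates and `[0, 5]` for the migration scaler. Degenerate
#'   bounds (`lo == hi`) pin a parameter.
#' @param base_rates Optional `rate_set` supplying values for rates not in
#'   `free` (defaults to 0) and the starting structure.
#' @param weights Optional data frame (`age_lo`, `sex`, `state`, `w`) of
#'   non-negative target weights; default all 1. The objective is invariant
#'   to uniform rescaling of the weights.
#' @param migration_strategy Passed to [step_chain()].
#' @return An object of class `calibration_problem`.
#' @export
calibration_problem <- function(spec, tensor0, targets, lt, fert, mig,
                                free = rate_names(spec), bounds = NULL,
                                base_rates = NULL, weights = NULL,
                                migration_strategy = "proportional") {
  ok <- c(rate_names(spec), "migration_scaler")
  if (length(free) == 0L) stopf("at least one free parameter is required")
  if (!all(free %in% ok)) {
    stopf("unknown free parameter(s): %s", paste(setdiff(free, ok), collapse = ", "))
  }
  years <- sort(unique(targets$year))
  if (length(years) < 2L) stopf("targets must cover at least two years")
  if (any(diff(years) != 1L)) stopf("target years must be consecutive")
  if (tensor0$year != years[1L]) {
    stopf("tensor0 year (%d) must equal the first target year (%d)",
          tensor0$year, years[1L])
  }
  b <- lapply(free, function(p) if (p == "migration_scaler") c(0, 5) else c(0, 1))
  names(b) <- free
  if (!is.null(bounds)) {
    for (p in names(bounds)) {
      if (!p %in% free) stopf("bounds given for non-free parameter '%s'", p)
      if (bounds[[p]][1L] > bounds[[p]][2L]) stopf("lo > hi for '%s'", p)
      b[[p]] <- bounds[[p]]
    }
  }
  key <- paste(targets$year, targets$age_lo, targets$sex, targets$state)
  if (anyDuplicated(key)) stopf("duplicate target rows")
  targets <- targets[order(targets$year, targets$age_lo, targets$sex, targets$state), ]

  # precomputed banded-aggregation machinery so misfit evaluations stay cheap:
  # A maps ages to bands; perm maps the (band x sex x state) block of one year
  # onto the sorted target rows of that year.
  bands <- unique(targets[, c("age_lo", "age_hi")])
  bands <- bands[order(bands$age_lo), ]
  B <- nrow(bands)
  A <- matrix(0, B, .n_ages)
  for (bb in seq_len(B)) {
    A[bb, which(.ages >= bands$age_lo[bb] & .ages < bands$age_hi[bb])] <- 1
  }
  sub <- targets[targets$year == years[1L], ]
  if (nrow(sub) * length(years) != nrow(targets)) {
    stopf("targets must cover the same cells in every year")
  }
  bi <- match(sub$age_lo, bands$age_lo)
  si <- match(sub$sex, .sexes)
  ki <- match(sub$state, spec$states)
  if (anyNA(bi) || anyNA(si) || anyNA(ki)) stopf("unknown band, sex or state in targets")
  perm <- bi + B * ((ki - 1L) * 2L + si - 1L)
  slot <- split(seq_len(nrow(targets)), targets$year)
  w <- rep(1, nrow(targets))
  if (!is.null(weights)) {
    wk <- paste(weights$age_lo, weights$sex, weights$state)
    tk <- paste(targets$age_lo, targets$sex, targets$state)
    i <- match(tk, wk)
    w[!is.na(i)] <- weights$w[i[!is.na(i)]]
    if (any(w < 0)) stopf("weights must be >= 0")
  }
  if (all(w == 0)) stopf("at least one weight must be positive")
  w <- w / mean(w)  # objective invariant to uniform weight rescaling
  structure(list(spec = spec, tensor0 = tensor0, targets = targets,
                 lt = lt, fert = fert, mig = mig, free = free, bounds = b,
                 base_rates = base_rates, w = w, years = years,
                 migration_strategy = migration_strategy,
                 precomp = list(A = A, perm = perm, slot = slot)),
            class = "calibration_problem")
}

# Assemble a rate_set (and migration) from a free-parameter vector.
.problem_inputs <- function(params, problem) {
  spec <- problem$spec
  rn <- rate_names(spec)
  vals <- if (!is.null(problem$base_rates)) {
    problem$base_rates$values
  } else {
    matrix(0, length(rn), 2L, dimnames = list(rn, .sexes))
  }
  for (p in intersect(problem$free, rn)) vals[p, ] <- params[[p]]
  mig <- problem$mig
  if ("migration_scaler" %in% problem$free) mig$scaler <- params[["migration_scaler"]]
  list(rates = rate_set(spec, vals), mig = mig)
}

# Project the chain over the target window and return counts aligned
# row-for-row with problem$targets (fast path: no data-frame churn).
.projected_counts <- function(params, problem) {
  inp <- .problem_inputs(params, problem)
  pc <- problem$precomp
  vals <- numeric(nrow(problem$targets))
  tensor <- problem$tensor0
  n_years <- length(problem$years)
  for (yi in seq_len(n_years)) {
    banded <- pc$A %*% matrix(tensor$counts, nrow = .n_ages)  # B x (2K)
    vals[pc$slot[[yi]]] <- banded[pc$perm]
    if (yi < n_years) {
      tensor <- step_chain(tensor, inp$rates, problem$lt, problem$fert,
                           inp$mig, migration_strategy = problem$migration_strategy)
    }
  }
  vals
}

#' Calibration misfit
#'
#' Weighted sum of squared relative errors between projected and target
#' banded state counts over all years, bands, sexes and states:
#' `sum(w * ((proj - target) / max(target, 1))^2)` with weights normalized to
#' mean 1 (so the objective is invariant to uniform weight rescaling). The
#' 1-person floor on the denominator keeps (near-)empty target cells finite;
#' the misfit is zero iff the projection matches every weighted target.
#'
#' @param params Named numeric vector of free-parameter values (within
#'   bounds).
#' @param problem A `calibration_problem`.
#' @return Scalar misfit (>= 0); `Inf` if the projection is non-finite.
#' @export
misfit <- function(params, problem) {
  params <- as.list(params)
  proj <- tryCatch(.projected_counts(params, problem), error = function(e) NULL)
  if (is.null(proj) || any(!is.finite(proj))) return(Inf)
  tgt <- problem$targets$count
  sum(problem$w * ((proj - tgt) / pmax(tgt, 1))^2)
}

#' Optimizer settings for [calibrate()]
#'
#' @param n_starts Number of multi-start points (first is the box midpoint,
#'   the rest drawn from fixed seeds).
#' @param seed Base seed for the start draws; results are deterministic
#'   given the settings.
#' @param maxit Maximum Nelder--Mead iterations per start.
#' @param reltol Nelder--Mead relative convergence tolerance.
#' @param stop_value Stop launching further starts once a start achieves a
#'   misfit at or below this value (noise-free self-consistent targets reach
#'   ~0).
#' @return List of settings.
#' @export
calibration_settings <- function(n_starts = 5L, seed = 1409L, maxit = 1000L,
                                 reltol = 1e-12, stop_value = 1e-12) {
  list(n_starts = as.integer(n_starts), seed = as.integer(seed),
       maxit = as.integer(maxit), reltol = reltol, stop_value = stop_value)
}

#' Calibrate the free parameters of a chain
#'
#' Bounded derivative-free minimization of [misfit()]: Nelder--Mead in a
#' logit-transformed coordinate system (so iterates respect the box bounds
#' exactly), restarted from `n_starts` fixed-seed initial points; the best
#' start wins. Parameters with degenerate bounds are pinned.
#'
#' @param problem A `calibration_problem`.
#' @param settings See [calibration_settings()].
#' @return An object of class `calibration_result`: `par` (named fitted
#'   values), `rates` (fitted `rate_set`), `migration_scaler` (or `NA`),
#'   `value` (misfit at the optimum), `converged` (logical), `evaluations`,
#'   `residuals` (per-target data frame), `starts` (per-start summary).
#' @export
calibrate <- function(problem, settings = calibration_settings()) {
  lo <- vapply(problem$bounds, `[`, numeric(1), 1L)
  hi <- vapply(problem$bounds, `[`, numeric(1), 2L)
  free <- problem$free
  movable <- hi > lo
  pinned <- stats::setNames(lo, free)  # values for pinned params

  full_par <- function(z) {
    x <- pinned
    x[movable] <- lo[movable] + (hi[movable] - lo[movable]) * stats::plogis(z)
    x
  }
  to_z <- function(x) {
    u <- (x[movable] - lo[movable]) / (hi[movable] - lo[movable])
    stats::qlogis(pmin(pmax(u, 1e-6), 1 - 1e-6))
  }
  obj <- function(z) misfit(full_par(z), problem)

  # fixed-seed multi-start points in the interior of the box
  starts <- list(lo + 0.5 * (hi - lo))
  if (settings$n_starts > 1L) {
    for (k in seq_len(settings$n_starts - 1L)) {
      set.seed(settings$seed + k)
      starts[[k + 1L]] <- lo + (0.1 + 0.8 * stats::runif(length(free))) * (hi - lo)
    }
  }

  best <- NULL
  start_log <- data.frame(start = integer(), value = numeric(),
                          convergence = integer(), evaluations = integer())
  for (k in seq_along(starts)) {
    if (!any(movable)) {  # everything pinned: nothing to optimize
      best <- list(par = pinned, value = misfit(pinned, problem),
                   convergence = 0L, counts = 0L)
      start_log <- rbind(start_log, data.frame(start = k, value = best$value,
                                               convergence = 0L, evaluations = 0L))
      break
    }
    z0 <- to_z(starts[[k]])
    fit <- if (sum(movable) == 1L) {
      # one-dimensional: golden-section/Brent on the transformed axis
      stats::optim(z0, obj, method = "Brent", lower = -15, upper = 15,
                   control = list(maxit = settings$maxit))
    } else {
      stats::optim(z0, obj, method = "Nelder-Mead",
                   control = list(maxit = settings$maxit,
                                  reltol = settings$reltol))
    }
    ev <- unname(fit$counts[1L])
    if (is.na(ev)) ev <- 0L  # Brent does not report evaluation counts
    cand <- list(par = full_par(fit$par), value = fit$value,
                 convergence = fit$convergence, counts = ev)
    start_log <- rbind(start_log, data.frame(start = k, value = fit$value,
                                             convergence = fit$convergence,
                                             evaluations = ev))
    if (is.null(best) || cand$value < best$value) best <- cand
    if (best$value <= settings$stop_value) break
  }

  inp <- .problem_inputs(as.list(best$par), problem)
  res <- problem$targets
  res$projected <- .projected_counts(as.list(best$par), problem)
  res$residual <- res$projected - res$count

  structure(list(par = best$par,
                 rates = inp$rates,
                 migration_scaler = if ("migration_scaler" %in% free)
                   best$par[["migration_scaler"]] else NA_real_,
                 value = best$value,
                 converged = best$convergence == 0L,
                 evaluations = sum(start_log$evaluations),
                 residuals = res,
                 starts = start_log),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> misfit %.4g, %s after %d evaluations\n",
              x$value, if (x$converged) "converged" else "NOT converged",
              x$evaluations))
  print(round(x$par, 6))
  invisible(x)
}

#' Visual-fit summary of a calibration
#'
#' Per year/band/sex/state: target count, projected count and percentage
#' deviation — the table behind a visual fit check. Optionally written as
#' CSV.
#'
#' @param result A `calibration_result`.
#' @param file Optional path to write the table as CSV.
#' @return Data frame with columns of `residuals` plus `pct_deviation`.
#' @export
fit_report <- function(result, file = NULL) {
  res <- result$residuals
  if (is.null(res) || nrow(res) == 0L) stopf("calibration result carries no targets")
  res$pct_deviation <- 100 * res$residual / pmax(res$count, 1)
  if (!is.null(file)) utils::write.csv(res, file, row.names = FALSE)
  res
}
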