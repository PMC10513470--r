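# Synthetic study generator. Produces every input the pipeline needs with a
# known ground truth: a UK-like demography (Gompertz mortality, sub-
# replacement flat-with-peak fertility, a piecewise-linear age pyramid, net
# immigration concentrated in young adulthood) and survey-like banded
# prevalence tables obtained by forward-simulating each disease chain with
# known rates from a disease-free ancient start — so calibration can be
# validated by parameter recovery rather than against unavailable survey
# microdata.

#' Synthetic study scenario
#'
#' All generator knobs in one place. Defaults describe a UK-like population:
#' Gompertz mortality with female advantage (period life expectancy near 80),
#' a flat-with-peak fertility schedule with a total fertility rate of about
#' 1.6 (sub-replacement), net immigration of about 0.3% of the population per
#' year concentrated at ages 18--45, and plausible disease-chain rates.
#'
#' @param seed Integer seed; every random element of the scenario flows from
#'   it.
#' @param scale Approximate total population size in persons.
#' @param gompertz Per-sex mortality parameters `c(a, b, floor)`:
#'   `q(age) = min(1, floor + a * exp(b * age))`.
#' @param fertility_peak,fertility_peak_rate,fertility_base Flat-with-peak
#'   schedule: rates rise linearly from `fertility_base` at 15 to
#'   `fertility_peak_rate` at `fertility_peak`, then fall back by 49.
#' @param male_fraction Male fraction at birth.
#' @param migration_fraction Annual net migration as a fraction of `scale`.
#' @param true_rates Named list of ground-truth rate vectors for chains
#'   `caries`, `pocketing`, `loa`.
#' @param reference_year Calendar year the synthetic survey refers to.
#' @param burn_in Years of forward simulation before the reference year, long
#'   enough that state occupancy is near its emergent equilibrium.
#' @param target_years Length of the calibration target window (snapshots
#'   after the reference year; default 11, i.e. reference year + 11 years).
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(seed = 42L,
                               scale = 1e6,
                               gompertz = list(
                                 male = c(a = 2.6e-5, b = 0.095, floor = 4e-4),
                                 female = c(a = 1.6e-5, b = 0.097, floor = 3e-4)),
                               fertility_peak = 31L,
                               fertility_peak_rate = 0.085,
                               fertility_base = 0.005,
                               male_fraction = 0.512,
                               migration_fraction = 0.003,
                               true_rates = list(
                                 caries = c(caries_incidence = 0.04,
                                            treatment_uptake = 0.30,
                                            treatment_cessation = 0.05),
                                 pocketing = c(incidence_4mm = 0.07,
                                               trans_4_to_6 = 0.02,
                                               trans_6_to_9 = 0.01),
                                 loa = c(incidence_4mm_loa = 0.08,
                                         trans_4_to_6_loa = 0.03,
                                         trans_6_to_9_loa = 0.01)),
                               reference_year = 2009L,
                               burn_in = 60L,
                               target_years = 11L) {
  structure(list(seed = as.integer(seed), scale = scale, gompertz = gompertz,
                 fertility_peak = fertility_peak,
                 fertility_peak_rate = fertility_peak_rate,
                 fertility_base = fertility_base,
                 male_fraction = male_fraction,
                 migration_fraction = migration_fraction,
                 true_rates = true_rates,
                 reference_year = as.integer(reference_year),
                 burn_in = as.integer(burn_in),
                 target_years = as.integer(target_years)),
            class = "synthetic_scenario")
}

#' Survey-like prevalence age bands
#'
#' Decade-style bands (16--24, 25--34, ..., 75+) from the chain's entry age;
#' for a chain entering at 55 this reduces to 55--64, 65--74, 75+.
#'
#' @param entry_age First adult age of the chain.
#' @return Data frame with columns `age_lo`, `age_hi`.
#' @export
survey_bands <- function(entry_age = 16L) {
  cuts <- c(16L, 25L, 35L, 45L, 55L, 65L, 75L, 101L)
  cuts <- sort(unique(c(entry_age, cuts[cuts > entry_age])))
  data.frame(age_lo = cuts[-length(cuts)], age_hi = cuts[-1L])
}

#' Generate the synthetic demography
#'
#' @param scenario A `synthetic_scenario`.
#' @return List with `lt` (`life_table`), `fert` (`fertility_schedule`),
#'   `pop0` (`population_vector` at the start of the burn-in, i.e.
#'   `reference_year - burn_in`) and `mig` (`migration_schedule`).
#' @export
make_demography <- function(scenario) {
  ages <- .ages
  q <- sapply(.sexes, function(sx) {
    g <- scenario$gompertz[[sx]]
    qs <- g[["floor"]] + g[["a"]] * exp(g[["b"]] * ages)
    if (any(qs > 1 & ages < 100)) {
      warnf("Gompertz parameters reach q > 1 before age 100; clipped")
    }
    pmin(qs, 1)
  })
  dimnames(q) <- list(age = ages, sex = .sexes)
  lt <- life_table(q)

  fa <- 15:49
  up <- scenario$fertility_base +
    (scenario$fertility_peak_rate - scenario$fertility_base) *
    (fa - 15) / (scenario$fertility_peak - 15)
  down <- scenario$fertility_base +
    (scenario$fertility_peak_rate - scenario$fertility_base) *
    (49 - fa) / (49 - scenario$fertility_peak)
  fert <- fertility_schedule(pmin(up, down), scenario$male_fraction)

  # piecewise-linear age pyramid with a working-age bulge, a seeded smooth
  # ripple, and a female survival advantage at old ages
  knots_age <- c(0, 20, 40, 60, 80, 100)
  knots_w <- c(1.00, 1.05, 1.20, 1.00, 0.55, 0.02)
  w <- stats::approx(knots_age, knots_w, xout = ages)$y
  set.seed(scenario$seed)
  ripple <- exp(stats::rnorm(.n_ages, 0, 0.02))
  w <- w * ripple
  female_share <- 0.5 + 0.1 * pmax(ages - 60, 0) / 40
  n <- cbind(male = w * (1 - female_share), female = w * female_share)
  n <- n * scenario$scale / sum(n)
  dimnames(n) <- list(age = ages, sex = .sexes)
  pop0 <- population_vector(n, scenario$reference_year - scenario$burn_in)

  # net immigration concentrated at ages 18-45, split evenly by sex
  mw <- pmax(0, 1 - abs(ages - 25) / 20) * (ages >= 16 & ages <= 45)
  m_total <- scenario$migration_fraction * scenario$scale
  m <- cbind(male = mw, female = mw)
  m <- m * m_total / sum(m)
  dimnames(m) <- list(age = ages, sex = .sexes)
  mig <- migration_schedule(m)

  list(lt = lt, fert = fert, pop0 = pop0, mig = mig)
}

#' Generate a full synthetic study with known ground truth
#'
#' For each chain: forward-simulates from an all-disease-free population at
#' `reference_year - burn_in` under the true rates, so state occupancy at the
#' reference year is an emergent equilibrium; tabulates survey-like banded
#' prevalence from that snapshot; re-initializes from the banded prevalence
#' (exactly as the real pipeline would from survey tables); and emits the
#' calibration target series by projecting that initialization forward under
#' the true rates. By construction the true rates attain zero misfit on these
#' targets, which is what makes parameter recovery a sharp test.
#'
#' @param scenario A `synthetic_scenario`.
#' @return List with `scenario`, `demography` (list `lt`, `fert`, `mig`,
#'   `pop0`, `pop_ref` — the population at the reference year), `truth`
#'   (data frame chain/rate/value) and `chains`: per chain a list of `spec`,
#'   `prevalence` (`prevalence_table`), `tensor0` (initial `state_tensor` at
#'   the reference year), `targets` (long data frame) and `rates` (the true
#'   `rate_set`).
#' @export
generate_study <- function(scenario = synthetic_scenario()) {
  dem <- make_demography(scenario)
  specs <- list(caries = make_caries_spec(),
                pocketing = make_pocketing_spec(),
                loa = make_loa_spec())
  pop_ref <- NULL
  chains <- list()
  truth <- NULL
  for (nm in names(specs)) {
    spec <- specs[[nm]]
    rates <- rate_set(spec, scenario$true_rates[[nm]])
    start <- disease_free_tensor(dem$pop0, spec)
    burn <- project_chain(start, rates, dem$lt, dem$fert, dem$mig,
                          n_years = scenario$burn_in)
    ref <- burn[[length(burn)]]
    if (is.null(pop_ref)) pop_ref <- chain_population(ref)

    bands <- survey_bands(spec$entry_age)
    tab <- aggregate_to_bands(ref, bands, by_sex = TRUE)
    tot <- stats::ave(tab$count, tab$age_lo, tab$sex, FUN = sum)
    tab$p <- ifelse(tot > 0, tab$count / tot, ifelse(tab$state == spec$states[1L], 1, 0))
    prev <- prevalence_table(tab[, c("age_lo", "age_hi", "sex", "state", "p")],
                             spec, scenario$reference_year)

    tensor0 <- initialize_states(prev, pop_ref, spec)
    traj <- project_chain(tensor0, rates, dem$lt, dem$fert, dem$mig,
                          n_years = scenario$target_years)
    targets <- do.call(rbind, lapply(traj, aggregate_to_bands,
                                     bands = bands, by_sex = TRUE))
    rownames(targets) <- NULL

    chains[[nm]] <- list(spec = spec, prevalence = prev, tensor0 = tensor0,
                         targets = targets, rates = rates)
    truth <- rbind(truth, data.frame(chain = nm,
                                     rate = names(scenario$true_rates[[nm]]),
                                     value = unname(scenario$true_rates[[nm]])))
  }
  list(scenario = scenario,
       demography = list(lt = dem$lt, fert = dem$fert, mig = dem$mig,
                         pop0 = dem$pop0, pop_ref = pop_ref),
       truth = truth,
       chains = chains)
}

#' Add multiplicative noise to a target series
#'
#' Each target count is multiplied by an independent lognormal factor
#' `exp(N(0, sd))` — the noisy-recovery condition for calibration tests.
#'
#' @param targets Long target data frame with a `count` column.
#' @param sd Standard deviation of the log factor (0.05 = ~5% noise).
#' @param seed Seed for the noise draws.
#' @return The targets with perturbed counts.
#' @export
add_target_noise <- function(targets, sd = 0.05, seed = 1L) {
  set.seed(seed)
  targets$count <- targets$count * exp(stats::rnorm(nrow(targets), 0, sd))
  targets
}
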