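test_that("the synthetic demography is deterministic and demographically sane", {
  s <- synthetic_scenario(seed = 5)
  d1 <- make_demography(s)
  d2 <- make_demography(synthetic_scenario(seed = 5))
  expect_identical(d1, d2)
  d3 <- make_demography(synthetic_scenario(seed = 6))
  expect_false(identical(d1$pop0$n, d3$pop0$n))

  # Gompertz mortality: q in [0,1], non-decreasing in age for each sex
  expect_true(all(d1$lt$q >= 0 & d1$lt$q <= 1))
  expect_true(all(diff(d1$lt$q[, "male"]) >= 0))
  expect_true(all(diff(d1$lt$q[, "female"]) >= 0))
  # female advantage at old age
  expect_lt(d1$lt$q[81, "female"], d1$lt$q[81, "male"])

  # fertility confined to 15..49 and sub-replacement
  f <- d1$fert$f
  expect_true(all(f[c(1:15, 51:101)] == 0))
  expect_lt(sum(f), 2.1)
  expect_gt(sum(f), 1.2)
})

test_that("an immortal childless closed population is constant", {
  s <- synthetic_scenario(
    gompertz = list(male = c(a = 0, b = 0.1, floor = 0),
                    female = c(a = 0, b = 0.1, floor = 0)),
    fertility_peak_rate = 0, fertility_base = 0,
    migration_fraction = 0)
  d <- make_demography(s)
  traj <- project_population(d$pop0, d$lt, d$fert, d$mig, 20)
  expect_equal(total_population(traj[[21]]), total_population(d$pop0),
               tolerance = 1e-12)
})

test_that("generated prevalence is a proper table emerging from the true rates", {
  study <- cached_study()
  for (nm in names(study$chains)) {
    p <- study$chains[[nm]]$prevalence$p
    sums <- apply(p, c(1, 2), sum)
    expect_true(all(abs(sums - 1) < 1e-9))
    expect_true(all(p >= 0 & p <= 1))
  }
  # disease occupancy increases with age band for forward-only chains
  p_poc <- study$chains$pocketing$prevalence$p
  diseased <- 1 - p_poc[, , 1]
  expect_true(all(diff(diseased[, "male"]) > -1e-9))

  # zero true rates -> everyone disease-free in every band
  s0 <- synthetic_scenario(true_rates = list(
    caries = c(caries_incidence = 0, treatment_uptake = 0, treatment_cessation = 0),
    pocketing = c(incidence_4mm = 0, trans_4_to_6 = 0, trans_6_to_9 = 0),
    loa = c(incidence_4mm_loa = 0, trans_4_to_6_loa = 0, trans_6_to_9_loa = 0)),
    burn_in = 15L, target_years = 3L)
  st0 <- generate_study(s0)
  expect_true(all(st0$chains$caries$prevalence$p[, , 1] == 1))
  expect_true(all(st0$chains$caries$prevalence$p[, , -1] == 0))
})

test_that("the whole study generation is reproducible from the scenario seed", {
  s <- synthetic_scenario(seed = 8, burn_in = 10L, target_years = 2L)
  st1 <- generate_study(s)
  st2 <- generate_study(synthetic_scenario(seed = 8, burn_in = 10L, target_years = 2L))
  expect_identical(st1$chains$caries$targets, st2$chains$caries$targets)
  expect_identical(st1$truth, st2$truth)
})

test_that("calibrated rates re-project the generated target series", {
  # round trip: generate -> calibrate -> re-project; within 0.5% everywhere
  study <- cached_study()
  res <- cached_calibration("caries")
  rel <- abs(res$residuals$projected - res$residuals$count) /
    pmax(res$residuals$count, 1)
  expect_lt(max(rel), 0.005)
})

test_that("scenario inputs round-trip through the CSV interfaces", {
  study <- cached_study()
  d <- study$demography
  td <- tempfile(); dir.create(td)

  ages <- 0:100
  utils::write.csv(data.frame(age = rep(ages, 2),
                              sex = rep(c("male", "female"), each = 101),
                              q = c(d$lt$q)),
                   file.path(td, "life_table.csv"), row.names = FALSE)
  expect_equal(read_life_table(file.path(td, "life_table.csv"))$q, d$lt$q,
               tolerance = 1e-12, ignore_attr = TRUE)

  utils::write.csv(data.frame(age = 15:49, f = d$fert$f[16:50]),
                   file.path(td, "fertility.csv"), row.names = FALSE)
  expect_equal(read_fertility(file.path(td, "fertility.csv"))$f, d$fert$f,
               tolerance = 1e-12)

  rs <- study$chains$caries$rates
  write_rates(rs, file.path(td, "rates.csv"))
  rs2 <- read_rates(file.path(td, "rates.csv"), study$chains$caries$spec)
  expect_equal(rs2$values, rs$values, tolerance = 1e-12)

  prev <- study$chains$caries$prevalence
  utils::write.csv(prev$table[, c("age_lo", "age_hi", "sex", "state", "p")],
                   file.path(td, "prevalence.csv"), row.names = FALSE)
  prev2 <- read_prevalence(file.path(td, "prevalence.csv"),
                           study$chains$caries$spec, 2009)
  expect_equal(prev2$p, prev$p, tolerance = 1e-12)

  write_projection(list(study$chains$caries$tensor0), file.path(td, "proj.csv"))
  pj <- utils::read.csv(file.path(td, "proj.csv"))
  expect_equal(sum(pj$count), sum(study$chains$caries$tensor0$counts),
               tolerance = 1e-6)
})
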