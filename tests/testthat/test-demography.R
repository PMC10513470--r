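test_that("births follow fecund females times fertility, split by sex ratio", {
  # single-term sum
  n <- matrix(0, 101, 2)
  n[31, 2] <- 1000  # 1000 females aged 30
  pop <- population_vector(n, 2020)
  fert <- fertility_schedule({f <- numeric(35); f[16] <- 0.1; f},
                             male_fraction = 0.5)
  b <- compute_births(pop, fert)
  expect_equal(unname(sum(b)), 100)
  expect_equal(unname(b["male"]), 50)
  expect_equal(unname(b["female"]), 50)

  # zero schedule
  expect_equal(sum(compute_births(pop, fertility_schedule(rep(0, 35)))), 0)

  # uniform schedule, hand sum 35 ages x 100 females x 0.05 = 175
  n2 <- matrix(0, 101, 2)
  n2[16:50, 2] <- 100
  pop2 <- population_vector(n2, 2020)
  fert2 <- fertility_schedule(rep(0.05, 35), male_fraction = 0.512)
  b2 <- compute_births(pop2, fert2)
  expect_equal(unname(sum(b2)), 175)
  expect_equal(unname(b2["male"]), 89.6)
})

test_that("fertility and life-table validation rejects malformed schedules", {
  expect_error(fertility_schedule(rep(-0.01, 35)), ">= 0")
  expect_error(fertility_schedule(rep(0.05, 35), male_fraction = 1), "male_fraction")
  expect_error(life_table(matrix(1.2, 101, 2)), "\\[0, 1\\]")
})

test_that("mortality splits the population exactly into survivors and deaths", {
  d <- toy_demography(n_per_age = 100)

  out0 <- apply_mortality(d$pop, life_table(matrix(0, 101, 2)))
  expect_identical(out0$survivors$n, d$pop$n)
  expect_true(all(out0$deaths == 0))

  out1 <- apply_mortality(d$pop, life_table(matrix(1, 101, 2)))
  expect_true(all(out1$survivors$n == 0))
  expect_identical(out1$deaths, d$pop$n)

  n <- matrix(0, 101, 2); n[71, 1] <- 200
  q <- matrix(0, 101, 2); q[71, 1] <- 0.03
  out <- apply_mortality(population_vector(n, 2020), life_table(q))
  expect_equal(out$survivors$n[71, 1], 194)
  expect_equal(out$deaths[71, 1], 6)
  expect_equal(out$survivors$n + out$deaths, n, ignore_attr = TRUE)
})

test_that("aging shift moves cohorts up one year with an open 100+ accumulator", {
  mk <- function(fill) population_vector(matrix(fill, 101, 2), 2020)

  n99 <- matrix(0, 101, 2); n99[100, ] <- 5  # age 99
  out <- shift_ages(population_vector(n99, 2020))
  expect_equal(unname(out$n[101, ]), c(5, 5))
  expect_equal(sum(out$n), 10)

  n100 <- matrix(0, 101, 2); n100[101, ] <- 7
  out2 <- shift_ages(population_vector(n100, 2020))
  expect_equal(unname(out2$n[101, ]), c(7, 7))  # open cohort persists

  out3 <- shift_ages(mk(10), newborns = c(male = 7, female = 7))
  expect_equal(sum(out3$n), sum(mk(10)$n) + 14)
  expect_equal(unname(out3$n[1, ]), c(7, 7))
  expect_equal(unname(out3$n[101, ]), c(20, 20))
})

test_that("a yearly step conserves persons exactly", {
  study <- cached_study()
  d <- study$demography
  pop <- d$pop0
  for (i in 1:5) {
    nxt <- step_year(pop, d$lt, d$fert, d$mig)
    fl <- attr(nxt, "flows")
    expect_equal(total_population(nxt),
                 total_population(pop) - fl$deaths + fl$births + fl$migration_realized,
                 tolerance = 1e-12)
    expect_true(all(nxt$n >= 0))
    expect_equal(nxt$year, pop$year + 1L)
    pop <- nxt
  }
})

test_that("with no vital events a step is a pure age shift and cohorts track", {
  d <- toy_demography(q = 0, f30 = 0)
  set.seed(11)
  n <- matrix(runif(202, 10, 100), 101, 2)
  pop <- population_vector(n, 2000)
  traj <- project_population(pop, d$lt, d$fert, d$mig, 25)
  for (t in c(5, 25)) {
    for (a in c(0, 10, 60)) {
      if (a + t < 100) {
        expect_equal(traj[[t + 1]]$n[a + t + 1, ], n[a + 1, ], ignore_attr = TRUE)
      }
    }
  }
})

test_that("a stationary population stays constant over 30 years", {
  # stationary construction: survivorship age structure, fertility tuned so
  # births equal deaths, no migration
  q <- 0.01
  lt <- life_table(matrix(q, 101, 2))
  l <- cumprod(c(1, rep(1 - q, 99)))      # survivorship to ages 0..99
  n100 <- l[100] * (1 - q) / q            # stationary open cohort
  n <- cbind(c(l, n100), c(l, n100)) * 1000
  deaths <- sum(n * q)
  f <- numeric(35); f[16] <- deaths / n[31, 2]
  fert <- fertility_schedule(f, male_fraction = 0.5)
  pop <- population_vector(n, 2000)
  traj <- project_population(pop, lt, fert, zero_migration(), 30)
  totals <- vapply(traj, total_population, numeric(1))
  expect_equal(max(abs(totals / totals[1] - 1)), 0, tolerance = 1e-9)
})

test_that("projection is deterministic and returns n_years + 1 snapshots", {
  study <- cached_study()
  d <- study$demography
  expect_length(project_population(d$pop0, d$lt, d$fert, d$mig, 0), 1L)
  t1 <- project_population(d$pop0, d$lt, d$fert, d$mig, 10)
  t2 <- project_population(d$pop0, d$lt, d$fert, d$mig, 10)
  expect_length(t1, 11L)
  expect_identical(t1, t2)
  expect_true(all(vapply(t1, total_population, numeric(1)) > 0))
})

test_that("out-migration is flow-limited so no cohort goes negative", {
  d <- toy_demography(q = 0, n_per_age = 10)
  m <- matrix(0, 101, 2); m[41, ] <- -50  # more than the stock of 10
  mig <- migration_schedule(m)
  expect_warning(out <- step_year(d$pop, d$lt, d$fert, mig), "flow-limited")
  expect_true(all(out$n >= 0))
  expect_equal(attr(out, "flows")$migration_realized, -20)  # 10 per sex
})
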