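test_that("chain blueprints match the disease structure", {
  cs <- make_caries_spec()
  expect_length(cs$states, 3L)
  expect_equal(cs$entry_age, 16L)
  expect_equal(nrow(cs$edges), 3L)
  expect_equal(sum(cs$edges$to < cs$edges$from), 1L)  # one backward (cessation) edge

  ps <- make_pocketing_spec()
  expect_length(ps$states, 4L)
  expect_equal(nrow(ps$edges), 3L)
  expect_true(all(ps$edges$to == ps$edges$from + 1L))  # forward-only

  ls <- make_loa_spec()
  expect_equal(ls$entry_age, 55L)
  expect_true(all(ls$edges$to == ls$edges$from + 1L))
})

test_that("state tensors reject disease occupancy below the entry age", {
  spec <- make_loa_spec()
  a <- array(0, c(101, 2, 4))
  a[41, 1, 2] <- 5  # age 40 in a disease state of a chain entering at 55
  expect_error(state_tensor(a, spec, 2020), "entry age")
})

test_that("single-edge and two-edge flows match hand balances", {
  d <- toy_demography(q = 0)
  spec <- make_caries_spec()

  t0 <- single_cohort_tensor(spec, 40, c(100, 0, 0))
  rs <- rate_set(spec, c(caries_incidence = 0.2, treatment_uptake = 0,
                         treatment_cessation = 0))
  t1 <- step_chain(t0, rs, d$lt, d$fert, d$mig)
  expect_equal(unname(t1$counts[42, 1, ]), c(80, 20, 0))  # cohort now aged 41

  t0b <- single_cohort_tensor(spec, 40, c(0, 100, 100))
  rsb <- rate_set(spec, c(caries_incidence = 0, treatment_uptake = 0.3,
                          treatment_cessation = 0.1))
  t1b <- step_chain(t0b, rsb, d$lt, d$fert, d$mig)
  expect_equal(unname(t1b$counts[42, 1, ]), c(0, 100 - 30 + 10, 100 + 30 - 10))
})

test_that("zero rates leave within-cohort state proportions invariant", {
  spec <- make_pocketing_spec()
  t0 <- single_cohort_tensor(spec, 50, c(40, 30, 20, 10))
  d <- toy_demography(q = 0.02)
  rs <- rate_set(spec, c(incidence_4mm = 0, trans_4_to_6 = 0, trans_6_to_9 = 0))
  t1 <- step_chain(t0, rs, d$lt, d$fert, d$mig)
  p0 <- t0$counts[51, 1, ] / sum(t0$counts[51, 1, ])
  p1 <- t1$counts[52, 1, ] / sum(t1$counts[52, 1, ])
  expect_equal(p1, p0, tolerance = 1e-12)
})

test_that("step_chain matches the independent per-edge reference on a 3-cohort toy", {
  for (spec in list(make_caries_spec(), make_pocketing_spec(), make_loa_spec())) {
    K <- length(spec$states)
    a <- array(0, c(101, 2, K))
    # three cohorts: one pre-entry, two adult with mixed occupancy
    a[spec$entry_age - 3, , 1] <- 50
    a[spec$entry_age + 11, , ] <- matrix(c(60, 30, 8, 2)[seq_len(K)], 2, K, byrow = TRUE)
    a[81, , ] <- matrix(c(20, 40, 25, 15)[seq_len(K)], 2, K, byrow = TRUE)
    t0 <- state_tensor(a, spec, 2000L)

    q <- matrix(0.01, 101, 2); q[, 2] <- 0.008
    lt <- life_table(q)
    fert <- fertility_schedule(rep(0.05, 35))
    m <- matrix(0.5, 101, 2)
    m[81, ] <- -3
    mig <- migration_schedule(m)
    vals <- stats::setNames(c(0.05, 0.25, 0.04)[seq_len(nrow(spec$edges))],
                            rate_names(spec))
    rs <- rate_set(spec, vals)

    got <- step_chain(t0, rs, lt, fert, mig)
    want <- reference_step_chain(t0, rs, lt, fert, mig)
    expect_equal(got$counts, want$counts, tolerance = 1e-12)
    expect_equal(got$year, want$year)
  }
})

test_that("chain marginals equal the demography-only projection every year", {
  study <- cached_study()
  d <- study$demography
  pop_traj <- project_population(study$demography$pop_ref, d$lt, d$fert, d$mig, 30)
  for (nm in names(study$chains)) {
    ch <- study$chains[[nm]]
    traj <- project_chain(ch$tensor0, ch$rates, d$lt, d$fert, d$mig, 30)
    for (t in c(1, 15, 31)) {
      marg <- chain_population(traj[[t]])
      expect_equal(marg$n, pop_traj[[t]]$n, tolerance = 1e-9)
      expect_true(all(traj[[t]]$counts >= 0))
    }
  }
})

test_that("raising caries incidence never lowers the diseased count", {
  study <- cached_study()
  d <- study$demography
  ch <- study$chains$caries
  r2 <- ch$rates
  r2$values["caries_incidence", ] <- 2 * r2$values["caries_incidence", ]
  base <- project_chain(ch$tensor0, ch$rates, d$lt, d$fert, d$mig, 15)
  high <- project_chain(ch$tensor0, r2, d$lt, d$fert, d$mig, 15)
  for (t in seq_along(base)) {
    diseased <- function(x) sum(x$counts[, , c("untreated_caries", "treated_caries")])
    expect_gte(diseased(high[[t]]), diseased(base[[t]]) - 1e-9)
  }
})

test_that("excess combined outflow is rescaled proportionally with a warning", {
  d <- toy_demography(q = 0)
  # a state with two outgoing edges whose rates sum above 1
  custom <- chain_spec("toy", c("a", "b", "c"), 16L,
                       data.frame(from = c("a", "a"), to = c("b", "c"),
                                  rate = c("r_ab", "r_ac")))
  tc <- single_cohort_tensor(custom, 40, c(100, 0, 0))
  rc <- rate_set(custom, c(r_ab = 0.8, r_ac = 0.6))  # combined 1.4 > 1
  expect_warning(t1 <- step_chain(tc, rc, d$lt, d$fert, d$mig), "rescaled")
  # proportional rescale drains the state fully: 100 * (0.8, 0.6) / 1.4
  expect_equal(unname(t1$counts[42, 1, ]), c(0, 100 * 0.8 / 1.4, 100 * 0.6 / 1.4),
               tolerance = 1e-12)
})

test_that("disease-free-only migration puts all net migrants in state 1", {
  spec <- make_caries_spec()
  t0 <- single_cohort_tensor(spec, 40, c(50, 25, 25))
  d <- toy_demography(q = 0)
  m <- matrix(0, 101, 2); m[41, ] <- 8
  mig <- migration_schedule(m)
  rs <- rate_set(spec, c(caries_incidence = 0, treatment_uptake = 0,
                         treatment_cessation = 0))
  t1 <- step_chain(t0, rs, d$lt, d$fert, mig,
                   migration_strategy = "disease_free_only")
  expect_equal(unname(t1$counts[42, 1, ]), c(58, 25, 25))
})
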