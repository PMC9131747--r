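# Cohort engine: discounting, trace validity, oracle equivalence, and
# aggregation linearity.

test_that("discount factors follow (1+r)^-t", {
  expect_identical(discount_factor(0, 0.05), 1)
  expect_equal(discount_factor(1, 0.05), 1 / 1.05)
  expect_equal(discount_factor(10, 0.05), 1.05^-10)
  expect_error(discount_factor(1, -1.5), "> -1")
})

test_that("geometric toy chain reproduces its closed forms", {
  ch <- geometric_chain(0.5)
  tr <- chain_trace(ch$P, n_cycles = 200)
  pay <- list(cost = ch$cost, utility = ch$utility)

  out0 <- accumulate_outcomes(tr, pay, discount_rate = 0,
                              dead_states = NULL)
  # LY: alive defaults to all states without dead_states; use utility
  expect_equal(out0[["qaly"]], 2, tolerance = 1e-10)

  r <- 0.05
  outr <- accumulate_outcomes(tr, pay, discount_rate = r)
  expect_equal(outr[["qaly"]], 1 / (1 - 0.5 / (1 + r)), tolerance = 1e-10)
})

test_that("trace payoffs equal the fundamental-matrix closed form", {
  for (seed in 1:5) {
    ch <- make_toy_chain(sample(2:6, 1), seed = seed)
    tr <- chain_trace(ch$P, n_cycles = 1000)
    pay <- list(cost = ch$cost, utility = ch$utility)
    for (r in c(0, 0.05)) {
      beta <- 1 / (1 + r)
      cf <- closed_form_expected_payoff(ch, beta = beta)
      got <- accumulate_outcomes(tr, pay, discount_rate = r,
                                 dead_states = character())
      expect_equal(got[["cost"]], cf$cost[1], tolerance = 1e-10)
      expect_equal(got[["qaly"]], cf$qaly[1], tolerance = 1e-10)
    }
  }
})

test_that("cohort specs enforce the entry-age window and year arithmetic", {
  cs <- cohort_spec(60)
  expect_identical(cs$birth_year, 1961L)
  expect_error(cohort_spec(45), "within 50-74")
  expect_error(cohort_spec(60, birth_year = 1950), "entry_year - birth_year")
  expect_identical(sum(default_cohorts()$size), 80000L)
  expect_identical(sort(unique(default_cohorts()$entry_age)),
                   c(50L, 53L, 57L, 60L, 64L, 67L, 71L, 74L))
})

test_that("cohort traces conserve mass with monotone death occupancy", {
  p <- base_params()
  for (id in c(0L, 5L)) {
    for (age in c(50, 65, 74)) {
      res <- run_cohort(cohort_spec(age), id, p)
      tr <- res$trace
      expect_lt(max(abs(rowSums(tr) - 1)), 1e-10)
      expect_true(all(diff(tr[, "Death"]) >= -1e-15))
      expect_true(all(diff(tr[, "Normal"]) <= 1e-15))
      expect_identical(unname(tr[1, ]), c(1, rep(0, 11)))
      o <- res$outcome
      expect_lte(o$per_person[["qaly"]], o$per_person[["ly"]])
      expect_true(all(o$per_person >= 0))
    }
  }
})

test_that("strategy aggregation is linear in cohort size", {
  p <- base_params()
  cohorts <- rbind(cohort_spec(60, size = 10000),
                   cohort_spec(70, size = 10000))
  o1 <- run_strategy(2, cohorts, p)
  doubled <- cohorts
  doubled$size <- doubled$size * 2L
  o2 <- run_strategy(2, doubled, p)
  expect_equal(o2$population, 2 * o1$population)
  expect_equal(o2$per_person, o1$per_person)

  single <- run_cohort(cohort_spec(60), 2, p)$outcome
  agg <- run_strategy(2, cohort_spec(60), p)
  expect_equal(agg$per_person, single$per_person)
})

test_that("zero-sensitivity, zero-cost screening equals the no-screen arm", {
  p <- base_params()
  p$sens_ldct <- 0
  p$spec_ldct <- 1
  p$cost_ldct <- 0
  o_scr <- run_strategy(0, one_cohort(), p)
  o_non <- run_strategy("none", one_cohort(), p)
  expect_equal(o_scr$per_person, o_non$per_person, tolerance = 1e-14)
})

test_that("totals are non-increasing in the discount rate", {
  p <- base_params()
  rates <- c(0, 0.03, 0.05, 0.08)
  outs <- lapply(rates, function(r) {
    pr <- p
    pr$discount_rate <- r
    run_strategy(0, one_cohort(), pr)$per_person
  })
  for (k in c("cost", "ly", "qaly")) {
    vals <- vapply(outs, `[[`, numeric(1), k)
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("trace matches a count-based microsimulation within 3 SE", {
  p <- base_params()
  res <- run_cohort(cohort_spec(60), "none", p)
  # single unscreened female subcohort for a like-for-like comparison
  pf <- p
  pf$male_fraction <- 0
  pf$eligible_fraction_20py <- 0
  pf$eligible_fraction_30py <- 0
  det <- run_cohort(cohort_spec(60), "none", pf)$trace
  P60 <- build_transition_matrix(60, "female", no_screening_context(), pf)
  # age-dependent matrices: simulate cycle by cycle with the right matrix
  n <- 20000L
  set.seed(202)
  counts <- matrix(0L, nrow(det), 12L)
  cur <- c(n, integer(11L))
  counts[1, ] <- cur
  for (t in seq_len(nrow(det) - 1L)) {
    P <- build_transition_matrix(60 + t - 1L, "female",
                                 no_screening_context(), pf)
    nxt <- integer(12L)
    for (s in which(cur > 0L)) {
      nxt <- nxt + as.integer(stats::rmultinom(1L, cur[s], P[s, ]))
    }
    cur <- nxt
    counts[t + 1L, ] <- cur
  }
  emp <- counts / n
  se <- sqrt(det * (1 - det) / n)
  expect_true(all(abs(emp - det) <= 3 * se + 1e-9))
})

test_that("table units divide population totals as published", {
  p <- base_params()
  o <- run_strategy(0, one_cohort(), p)
  u <- as_table_units(o)
  expect_equal(u[["cost_millions"]], o$population[["cost"]] / 1e6)
  expect_equal(u[["qaly_10k"]], o$population[["qaly"]] / 1e4)
})

test_that("half-cycle correction halves first and last accruals", {
  p <- base_params()
  ph <- p
  ph$options$half_cycle_correction <- TRUE
  o <- run_strategy("none", one_cohort(), p)
  oh <- run_strategy("none", one_cohort(), ph)
  expect_lt(oh$per_person[["ly"]], o$per_person[["ly"]])
  expect_gt(oh$per_person[["ly"]], o$per_person[["ly"]] - 1)
})
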