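# Sensitivity machinery: sweeps, tornado ranking, PSA determinism,
# threshold search.

test_that("degenerate sweep returns the base-case ICER at both ends", {
  p <- base_params()
  sw <- sweep_spec("cost_ldct", 245.86 - 1e-9, 245.86 + 1e-9, n_points = 2)
  tab <- one_way_sweep(sw, c(2L, 0L), one_cohort(), p)
  base <- attr(tab, "base_icer")
  expect_equal(tab$icer, rep(base, 2), tolerance = 1e-6)
})

test_that("sweeps never mutate the shared base parameter set", {
  p <- base_params()
  d0 <- parameter_digest(p)
  sw <- sweep_spec("sens_ldct", 0.63, 0.95, n_points = 3)
  one_way_sweep(sw, c(2L, 0L), one_cohort(), p)
  expect_identical(parameter_digest(p), d0)
})

test_that("screening-cost sweep moves the ICER linearly", {
  # only the screening unit cost changes between grid points, so the ICER
  # as a function of cost_ldct must be affine: second differences vanish
  p <- base_params()
  sw <- sweep_spec("cost_ldct", -0.3, 0.3, n_points = 5, mode = "fraction")
  tab <- one_way_sweep(sw, c(2L, 0L), one_cohort(), p)
  expect_equal(tab$value, 245.86 * seq(0.7, 1.3, length.out = 5))
  expect_lt(max(abs(diff(diff(tab$icer)))), 1e-6 * abs(mean(tab$icer)))
  # delta QALY is untouched by a pure cost change
  expect_equal(diff(range(tab$delta_qaly)), 0, tolerance = 1e-12)
})

test_that("invalid substitution is reported with the grid value", {
  p <- base_params()
  sw <- sweep_spec("spec_ldct", 0.9, 1.2, n_points = 3)
  expect_error(one_way_sweep(sw, c(2L, 0L), one_cohort(), p),
               "invalidates 'spec_ldct'")
})

test_that("tornado ranks parameters by ICER bar width", {
  p <- base_params()
  sweeps <- list(
    spec_ldct = sweep_spec("spec_ldct", 0.65, 0.97, n_points = 2),
    cost_ldct = sweep_spec("cost_ldct", -0.05, 0.05, n_points = 2,
                           mode = "fraction")
  )
  tor <- tornado_table(sweeps, c(2L, 0L), one_cohort(), p)
  expect_identical(nrow(tor), 2L)
  expect_identical(tor$rank, 1:2)
  expect_true(all(diff(tor$width) <= 0))
  # the wide specificity range must dominate a 5% cost wiggle
  expect_identical(tor$parameter[1], "spec_ldct")
  expect_error(tornado_table(list(), c(2L, 0L), one_cohort(), p),
               "at least one sweep")
})

test_that("default sweep set covers the published parameter list", {
  sw <- default_sweeps()
  expect_identical(length(sw), 8L)
  expect_setequal(names(sw),
                  c("screening_cost", "maintenance_cost", "discount_rate",
                    "cpi_rate", "sens_ldct", "spec_ldct", "sens_msc_conj",
                    "spec_msc_conj"))
})

test_that("point-mass PSA reproduces the base case on every iteration", {
  p <- base_params()
  dt <- list(cost_ldct = make_distribution("point", p$cost_ldct),
             sens_ldct = make_distribution("point", p$sens_ldct))
  psa <- run_psa(5, seed = 1, dist_table = dt, strategies = c(0L, 2L),
                 cohorts = one_cohort(), params = p)
  cache <- new.env(parent = emptyenv())
  base0 <- run_strategy(0L, one_cohort(), p, .cache = cache)
  base2 <- run_strategy(2L, one_cohort(), p, .cache = cache)
  s <- psa$samples
  expect_equal(unique(s$cost[s$strategy_id == 0L]),
               base0$population[["cost"]])
  expect_equal(unique(s$qaly[s$strategy_id == 2L]),
               base2$population[["qaly"]])
})

test_that("PSA is bit-identical under a repeated seed", {
  p <- base_params()
  a <- run_psa(8, seed = 42, strategies = c(0L, 2L),
               cohorts = one_cohort(), params = p)
  b <- run_psa(8, seed = 42, strategies = c(0L, 2L),
               cohorts = one_cohort(), params = p)
  expect_identical(a$samples, b$samples)
  c2 <- run_psa(8, seed = 43, strategies = c(0L, 2L),
                cohorts = one_cohort(), params = p)
  expect_false(identical(a$samples$cost, c2$samples$cost))
})

test_that("threshold search matches closed forms and a grid oracle", {
  # toy: ICER falls linearly from 200,000 at spec 0.8 to 0 at spec 1.0
  icer_fn <- function(x) 200000 * (1 - (x - 0.8) / 0.2)
  res <- threshold_search("spec", target = 70892, bounds = c(0.8, 1.0),
                          icer_fn = icer_fn, tol_icer = 0.01)
  expect_equal(res$value, 1.0 - 0.2 * 70892 / 200000, tolerance = 1e-6)

  # grid oracle: dense argmin of |ICER - target|
  grid <- seq(0.8, 1.0, length.out = 1000)
  oracle <- grid[which.min(abs(vapply(grid, icer_fn, numeric(1)) - 70892))]
  expect_lt(abs(res$value - oracle), diff(range(grid)) / 999)

  expect_error(
    threshold_search("spec", target = 5e5, bounds = c(0.8, 1.0),
                     icer_fn = icer_fn),
    "not bracketed")
  wiggly <- function(x) sin(20 * x)
  expect_error(
    threshold_search("spec", target = 0, bounds = c(0, 1),
                     icer_fn = wiggly),
    "not monotone")
})

test_that("threshold search is deterministic on the real model", {
  p <- base_params()
  # ICER of annual LDCT screening vs none as a function of LDCT specificity
  # is monotone (fewer false positives -> cheaper screening); target the
  # midpoint of the endpoint ICERs so the crossing is guaranteed
  f <- function(x) {
    pp <- param_set(p, "spec_ldct", x)
    evaluate_pair(list(2L, "none"), one_cohort(), pp)$icer
  }
  target <- (f(0.65) + f(0.97)) / 2
  r1 <- threshold_search("spec_ldct", target = target, bounds = c(0.65, 0.97),
                         icer_fn = f, tol_icer = 1)
  r2 <- threshold_search("spec_ldct", target = target, bounds = c(0.65, 0.97),
                         icer_fn = f, tol_icer = 1)
  expect_identical(r1$value, r2$value)
  expect_lt(abs(r1$icer - target), 1 + 1e-9)
})
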