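# Screening strategies, test arithmetic, stage-at-detection, and the
# per-cycle overlay.

test_that("the catalog holds exactly the eight published strategies", {
  cat <- strategy_catalog()
  expect_identical(nrow(cat), 8L)
  expect_identical(cat$id, 0:7)
  s0 <- get_strategy(0)
  expect_identical(c(s0$tool, s0$frequency, s0$pack_years),
                   c("LDCT", "annual", "30"))
  s2 <- get_strategy(2)
  expect_identical(c(s2$tool, s2$frequency, s2$pack_years),
                   c("LDCT", "annual", "20"))
  s5 <- get_strategy(5)
  expect_identical(c(s5$tool, s5$frequency, s5$pack_years),
                   c("LDCT_MSC", "once", "30"))
  s7 <- get_strategy(7)
  expect_identical(c(s7$tool, s7$frequency, s7$pack_years),
                   c("LDCT_MSC", "once", "20"))
  expect_error(get_strategy(8), "no such strategy")
})

test_that("classification fractions follow the 2x2 arithmetic", {
  p <- base_params()
  c1 <- screen_classification(0.01, "LDCT", p)
  expect_equal(c1$tp, 0.0079)
  expect_equal(c1$fn, 0.0021)
  expect_equal(c1$fp, 0.1881)
  expect_equal(c1$tn, 0.8019)

  c0 <- screen_classification(0, "LDCT", p)
  expect_equal(c0$fp, 0.19)
  expect_equal(c0$tn, 0.81)
  expect_identical(c0$tp + c0$fn, 0)

  c2 <- screen_classification(0.01, "LDCT_MSC", p)
  expect_equal(c2$tp, 0.0069)
  expect_equal(c2$fp, 0.0396)

  # property: fractions sum to 1 for random prevalence
  set.seed(11)
  for (prev in stats::runif(20)) {
    for (tool in c("LDCT", "LDCT_MSC")) {
      cl <- screen_classification(prev, tool, p)
      expect_equal(cl$tp + cl$fn + cl$fp + cl$tn, 1, tolerance = 1e-12)
    }
  }
})

test_that("stage-at-detection vectors match the published proportions", {
  p <- base_params()
  expect_equal(unname(detected_stage_distribution("LDCT", p)),
               c(0.0370, 0.6852, 0.0370, 0.1852, 0.0556))
  msc <- detected_stage_distribution("LDCT_MSC", p)
  expect_identical(msc[["CIS"]], 0)
  expect_equal(sum(msc), 1)

  expect_equal(unname(clinical_stage_distribution(p)),
               c(0, 0.0370, 0.6852, 0.0370, 0.2408))
  uniform <- p
  uniform$clinical_stage_dist[] <- 0.2
  expect_equal(unname(clinical_stage_distribution(uniform)), rep(0.2, 5))
  bad <- p
  bad$clinical_stage_dist[] <- 0.18
  expect_error(clinical_stage_distribution(bad), "simplex")
})

test_that("cycle screening cost prices scan, triage and workup", {
  p <- base_params()
  expect_equal(cycle_screening_cost(0.01, "LDCT", p),
               245.86 + 0.1881 * 628.36 + 0.0079 * (628.36 + 1232.44))
  expect_equal(cycle_screening_cost(0.01, "LDCT_MSC", p),
               245.86 + 0.1960 * 400 + 0.0396 * 628.36 +
                 0.0069 * (628.36 + 1232.44))
  perfect <- p
  perfect$spec_ldct <- 1
  expect_equal(cycle_screening_cost(0, "LDCT", perfect), 245.86)

  # optional biopsy-for-false-positives lever raises the cost
  fpb <- p
  fpb$options$fp_workup <- "prediag_biopsy"
  expect_gt(cycle_screening_cost(0.01, "LDCT", fpb),
            cycle_screening_cost(0.01, "LDCT", p))
})

test_that("conjunctive screening yields fewer false positives per screenee", {
  p <- base_params()
  prev <- 0.01
  expect_lt(screen_classification(prev, "LDCT_MSC", p)$fp,
            screen_classification(prev, "LDCT", p)$fp)
})

test_that("screening activity honours frequency and the stop age", {
  s_annual <- get_strategy(0)
  s_once <- get_strategy(1)
  expect_true(screening_active(s_annual, 60, 5L))
  expect_false(screening_active(s_annual, 75, 5L))
  expect_true(screening_active(s_once, 60, 0L))
  expect_false(screening_active(s_once, 60, 3L))
  expect_false(screening_active(NULL, 60, 0L))
})

test_that("the overlay splits incident mass and prices the cycle", {
  p <- base_params()
  s2 <- get_strategy(2)

  # annual LDCT: sens fraction takes the screen-detected stage vector
  ov <- apply_screening_overlay(1, 60, s2, 3L, p, sex = "male",
                                threshold = "30")
  p_inc <- adjusted_incidence(60, "male", 30, p)
  expected <- p_inc * (0.79 * p$detect_stage_ldct +
                         0.21 * p$clinical_stage_dist)
  expect_equal(ov$stage_entries, expected)
  expect_equal(sum(ov$stage_entries), p_inc, tolerance = 1e-12)

  # once-strategy after cycle 0: no screening flows or costs
  s1 <- get_strategy(1)
  ov_off <- apply_screening_overlay(1, 60, s1, 3L, p, sex = "male",
                                    threshold = "30")
  expect_false(ov_off$active)
  expect_identical(ov_off$screening_cost, 0)
  expect_equal(ov_off$stage_entries, p_inc * p$clinical_stage_dist)

  # beyond the stop age screening is inactive
  ov75 <- apply_screening_overlay(1, 75, s2, 20L, p, sex = "male",
                                  threshold = "30")
  expect_false(ov75$active)
  expect_identical(sum(ov75$stage_entries), 0)  # no incidence band either

  # mass conservation across the detected/clinical split, random sens
  set.seed(5)
  for (i in 1:10) {
    ps <- p
    ps$sens_ldct <- stats::runif(1)
    ovr <- apply_screening_overlay(0.8, 62, s2, 1L, ps, sex = "female",
                                   threshold = "20only")
    expect_equal(sum(ovr$stage_entries),
                 0.8 * adjusted_incidence(62, "female", "20only", ps),
                 tolerance = 1e-12)
  }
})
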