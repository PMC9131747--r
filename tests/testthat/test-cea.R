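# CEA: pairwise ICERs, dominance, frontier (with brute-force oracle),
# NMB and CEAC counting.

test_that("pairwise ICER reproduces published-table arithmetic", {
  # age-65 block, strategy 2 vs 0, from the printed cost/QALY columns
  icer <- pairwise_icer(list(cost = 1709.14e6, qaly = 81.37e4),
                        list(cost = 1865.10e6, qaly = 80.97e4))
  expect_equal(icer$delta_cost, -155.96e6)
  expect_equal(icer$delta_qaly, 4000)
  expect_equal(icer$icer, -38990, tolerance = 1e-6)
  expect_identical(icer$label, "dominant")
  # printed ICER -39002.09 agrees within the 2-decimal column rounding
  expect_lt(abs(icer$icer - (-39002.09)) / 39002.09, 0.001)
})

test_that("dominance labels cover the degenerate quadrants", {
  same <- list(cost = 10, qaly = 5)
  self <- pairwise_icer(same, same)
  expect_identical(self$label, "comparator")
  expect_true(self$undefined)
  expect_identical(self$delta_cost, 0)

  free <- pairwise_icer(list(cost = 10, qaly = 6), list(cost = 10, qaly = 5))
  expect_identical(free$label, "dominant")
  expect_identical(free$icer, 0)

  waste <- pairwise_icer(list(cost = 11, qaly = 5), list(cost = 10, qaly = 5))
  expect_identical(waste$label, "dominated")
  expect_true(waste$undefined)
  expect_true(is.na(waste$icer))
})

test_that("frontier removes dominated and extended-dominated points", {
  r1 <- efficiency_frontier(data.frame(id = 1:3,
                                       cost = c(0, 10, 5),
                                       qaly = c(0, 1, 2)))
  expect_identical(r1$label[r1$id == 2], "dominated")
  expect_identical(r1$label[r1$id %in% c(1, 3)],
                   c("nondominated", "nondominated"))

  # (4,1) has incremental ICER 4 > segment ICER 5/3 to (5,3)
  r2 <- efficiency_frontier(data.frame(id = 1:3,
                                       cost = c(0, 4, 5),
                                       qaly = c(0, 1, 3)))
  expect_identical(r2$label[r2$id == 2], "extended_dominated")
  expect_true(all(diff(stats::na.omit(r2$frontier_icer)) > 0 |
                    length(stats::na.omit(r2$frontier_icer)) <= 1))
})

# brute-force oracle: a point is on the frontier iff no single point nor
# convex combination of two points gives >= QALYs at <= cost (one strict)
frontier_oracle <- function(df) {
  n <- nrow(df)
  on_frontier <- rep(TRUE, n)
  eps <- 1e-12
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (df$cost[j] <= df$cost[i] && df$qaly[j] >= df$qaly[i] &&
          (df$cost[j] < df$cost[i] - eps || df$qaly[j] > df$qaly[i] + eps ||
           df$id[j] < df$id[i])) {
        on_frontier[i] <- FALSE
      }
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        for (lam in seq(0, 1, by = 0.001)) {
          cmix <- lam * df$cost[j] + (1 - lam) * df$cost[k]
          qmix <- lam * df$qaly[j] + (1 - lam) * df$qaly[k]
          if (cmix <= df$cost[i] + eps && qmix >= df$qaly[i] - eps &&
              (cmix < df$cost[i] - 1e-9 || qmix > df$qaly[i] + 1e-9)) {
            on_frontier[i] <- FALSE
          }
        }
      }
    }
  }
  sort(df$id[on_frontier])
}

test_that("frontier agrees with a brute-force convex-hull oracle", {
  set.seed(99)
  for (rep in 1:5) {
    df <- data.frame(id = 1:8,
                     cost = round(stats::runif(8, 0, 100), 1),
                     qaly = round(stats::runif(8, 0, 10), 2))
    got <- efficiency_frontier(df)
    expect_setequal(got$id[got$label == "nondominated"], frontier_oracle(df))
    ic <- got$frontier_icer[order(got$cost)]
    ic <- ic[!is.na(ic)]
    expect_true(all(diff(ic) > 0) || length(ic) <= 1)
  }
})

test_that("net monetary benefit is wtp * dQ - dC", {
  expect_equal(net_monetary_benefit(list(cost = 0, qaly = 1),
                                    list(cost = 0, qaly = 0), 70892),
               70892)
  # printed age-65 strategy-2 increments at 1x GDP
  expect_equal(net_monetary_benefit(list(cost = 1709.14e6, qaly = 81.37e4),
                                    list(cost = 1865.10e6, qaly = 80.97e4),
                                    70892),
               70892 * 4000 + 155.96e6)
  expect_equal(net_monetary_benefit(list(cost = 30, qaly = 2),
                                    list(cost = 10, qaly = 1), 0),
               -20)
  expect_error(net_monetary_benefit(list(cost = 0, qaly = 0),
                                    list(cost = 0, qaly = 0), -1))
})

test_that("CEAC counts cost-effective draws with both rules", {
  # four hand-made draws: NMB signs (+, +, -, -) at wtp = 10
  samples <- data.frame(
    iter = rep(1:4, each = 2),
    strategy_id = rep(c(1L, 0L), 4),
    cost = c(5, 10, 8, 10, 30, 10, 25, 10),
    qaly = c(2, 1, 2, 1, 2, 1, 1, 1),
    ly = 1
  )
  cv <- ceac(samples, 1L, 0L, wtp_grid = 10)
  expect_equal(cv$prob, 0.5)
  expect_identical(attr(cv, "n_samples"), 4L)

  # all dominant -> probability 1 at every positive wtp
  dom <- samples
  dom$cost[dom$strategy_id == 1L] <- 1
  dom$qaly[dom$strategy_id == 1L] <- 2
  cvd <- ceac(dom, 1L, 0L, wtp_grid = c(10, 1000))
  expect_equal(cvd$prob, c(1, 1))

  # monotone in wtp when all dQ > 0, bounded in [0, 1]
  cvm <- ceac(samples, 1L, 0L, wtp_grid = seq(0, 50, 5))
  expect_true(all(diff(cvm$prob) >= 0))
  expect_true(all(cvm$prob >= 0 & cvm$prob <= 1))

  expect_error(ceac(samples, 3L, 0L, 10), "no PSA samples")
})

test_that("cea_table lays out strategies with the comparator marked", {
  p <- base_params()
  cache <- new.env(parent = emptyenv())
  outs <- lapply(c(0L, 1L, 2L), run_strategy, cohorts = one_cohort(),
                 params = p, .cache = cache)
  tab <- cea_table(outs, comparator_id = 0L)
  expect_identical(tab$strategy, c(0L, 1L, 2L))
  expect_identical(tab$label[1], "comparator")
  expect_true(is.na(tab$icer[1]))
  expect_true(all(is.finite(tab$icer[-1])))
})
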