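# Cohort engine: run the state-transition model cycle by cycle and
# accumulate discounted costs, life-years and QALYs.
#
# Event ordering within a cycle is fixed (a model choice, not a config):
# payoffs accrue on start-of-cycle occupancy, the screening overlay splits
# this cycle's incident cancers and prices the cycle, then the transition
# matrix advances occupancy. Cycle 0 is undiscounted. One-off entry costs
# (diagnosis + treatment) attach to the entry flows of the cycle in which
# the transition happens, so no entries are generated by the final accrual
# cycle at the horizon.

#' Discount factor for a cycle
#'
#' @param cycle_index 0-based cycle counter.
#' @param rate annual discount rate (>= 0 in practice; must be > -1).
#' @return `(1 + rate)^(-cycle_index)`.
#' @export
#' @examples
#' discount_factor(10, 0.05)  # 0.6139133
discount_factor <- function(cycle_index, rate) {
  stopifnot(all(cycle_index >= 0))
  if (rate <= -1) stop("discount rate must be > -1")
  (1 + rate)^(-cycle_index)
}

# per-state utility vector in health_states() order
state_utilities <- function(params) {
  u <- numeric(12L)
  names(u) <- health_states()
  u["Normal"] <- params$utility_normal
  u[cancer_stages()] <- params$utility
  u[maintenance_states()] <- params$utility  # partner-stage utility
  u["Death"] <- params$utility_death
  u
}

# Run one homogeneous subcohort: fixed sex, one pack-year stratum, screened
# or not. Returns the occupancy trace and undiscounted-per-person totals.
run_subcohort <- function(entry_age, sex, screened, strategy, params,
                          threshold = NULL) {
  st <- health_states()
  n_cycles <- params$max_age - entry_age  # transitions; accruals = n_cycles+1
  if (n_cycles < 0) stop("entry age beyond model horizon")
  if (is.null(threshold)) {
    threshold <- if (screened) as.character(strategy$pack_years) else "none"
  }

  u <- state_utilities(params)
  mcost <- params$maintenance_fraction * params$cost_treat  # by stage
  names(mcost) <- maintenance_states()
  r <- params$discount_rate
  dc <- discount_factor(0:n_cycles, r)
  de <- if (isTRUE(params$options$discount_effects)) dc else rep(1, n_cycles + 1)
  hcc <- isTRUE(params$options$half_cycle_correction)

  trace <- matrix(0, n_cycles + 1L, 12L, dimnames = list(NULL, st))
  v <- c(1, numeric(11L))
  cost <- ly <- qaly <- 0
  # transition matrix and overlay depend on age only through the mortality
  # band (which determines the incidence band below 75) and the screening-
  # active flag, so at most 12 distinct cells arise per run
  ages <- entry_age + 0:n_cycles
  band_idx <- findInterval(ages, c(50, 55, 60, 65, 70, 75))
  active_vec <- vapply(seq_along(ages), function(i) {
    screened && !is.null(strategy) &&
      screening_active(strategy, ages[i], i - 1L)
  }, logical(1L))
  cell_idx <- band_idx * 2L - active_vec
  cache <- vector("list", 12L)

  for (t in 0:n_cycles) {
    age <- ages[t + 1L]
    active <- active_vec[t + 1L]
    ci <- cell_idx[t + 1L]
    cell <- cache[[ci]]
    if (is.null(cell)) {
      ctx <- list(threshold = threshold, active = active,
                  tool = if (is.null(strategy)) NULL else strategy$tool)
      P <- build_transition_matrix(age, sex, ctx, params)
      ov <- apply_screening_overlay(1, age, if (screened) strategy else NULL,
                                    t, params, sex = sex,
                                    threshold = threshold)
      cell <- list(P = P, ov = ov)
      cache[[ci]] <- cell
    }
    N <- v[1L]
    w_hcc <- if (hcc && (t == 0L || t == n_cycles)) 0.5 else 1
    # maintenance accrues on occupancy; overlay costs scale with Normal mass
    cyc_cost <- sum(v[7:11] * mcost) * w_hcc
    if (t < n_cycles) {
      cyc_cost <- cyc_cost + N * cell$ov$cost_total
    }
    cost <- cost + dc[t + 1L] * cyc_cost
    qaly <- qaly + de[t + 1L] * sum(v * u) * w_hcc
    ly <- ly + de[t + 1L] * (1 - v[12L]) * w_hcc
    trace[t + 1L, ] <- v
    if (t < n_cycles) {
      v <- as.numeric(v %*% cell$P)
      drift <- abs(sum(v) - 1)
      if (drift > 1e-9) {
        stop("cohort trace mass drift ", drift, " at cycle ", t + 1L)
      }
    }
  }
  list(trace = trace, cost = cost, ly = ly, qaly = qaly)
}

#' Define a cohort
#'
#' @param entry_age age at model entry (50--74); equals `entry_year -
#'   birth_year`.
#' @param size persons in the cohort.
#' @param birth_year optional; defaults to `entry_year - entry_age`.
#' @param entry_year calendar year of cycle 0.
#' @return A one-row data.frame.
#' @export
cohort_spec <- function(entry_age, size = 10000L, birth_year = NULL,
                        entry_year = 2021L) {
  if (is.null(birth_year)) birth_year <- entry_year - entry_age
  if (entry_age != entry_year - birth_year) {
    stop("entry_age must equal entry_year - birth_year")
  }
  if (entry_age < 50 || entry_age > 74) {
    stop("entry age must be within 50-74, got ", entry_age)
  }
  data.frame(entry_age = as.integer(entry_age), size = as.integer(size),
             birth_year = as.integer(birth_year),
             entry_year = as.integer(entry_year))
}

#' Default cohort configuration
#'
#' Eight cohorts of 10,000 persons entering in 2021, born 1947--1971 at
#' approximately even spacing, i.e. entry ages 74, 71, 67, 64, 60, 57, 53,
#' 50 -- a simulated population of 80,000 aged 50 or older.
#' `cohorts_at_age()` instead puts all eight cohorts at one explicit start
#' age (the layout of the published base-case table, which reports blocks
#' at start ages 50, 55, 60, 65, 70).
#'
#' @return A data.frame of cohort rows (see [cohort_spec()]).
#' @export
default_cohorts <- function() {
  by <- c(1947L, 1950L, 1954L, 1957L, 1961L, 1964L, 1968L, 1971L)
  do.call(rbind, lapply(by, function(b) {
    cohort_spec(2021L - b, size = 10000L, birth_year = b)
  }))
}

#' @rdname default_cohorts
#' @param start_age single entry age for every cohort.
#' @param n_cohorts,size number and size of cohorts.
#' @export
cohorts_at_age <- function(start_age, n_cohorts = 8L, size = 10000L) {
  do.call(rbind, lapply(seq_len(n_cohorts), function(i) {
    cohort_spec(start_age, size = size)
  }))
}

# normalize the strategy argument: integer id, one-row data.frame, or
# NULL/"none" for the unscreened sentinel
as_strategy <- function(strategy) {
  if (is.null(strategy)) return(NULL)
  if (is.character(strategy) && identical(strategy, "none")) return(NULL)
  if (is.numeric(strategy)) return(get_strategy(strategy))
  stopifnot(is.data.frame(strategy), nrow(strategy) == 1L)
  strategy
}

#' Smoking strata of the simulated population
#'
#' The population is a fixed mixture of three smoking strata whose relative
#' risks are properties of the population, not of the strategy: the 30
#' pack-year stratum (RR 3.87), the 20--30 pack-year stratum (RR implied by
#' pooling consistency, so that the whole >= 20 pack-year group keeps its
#' published RR of 2.84), and the never/light remainder (RR 1). A strategy
#' only chooses which strata are screened, so every strategy -- and the
#' no-screening sentinel -- runs on the identical population.
#'
#' @param params an `lcs_params` object.
#' @return data.frame with columns `stratum`, `fraction`, `threshold` (the
#'   pack-year code passed to [adjusted_incidence()]).
#' @export
population_strata <- function(params) {
  f20 <- params$eligible_fraction_20py
  f30 <- params$eligible_fraction_30py
  out <- data.frame(
    stratum = c("py30", "py20only", "rest"),
    fraction = c(f30, f20 - f30, 1 - f20),
    threshold = c("30", "20only", "none"),
    stringsAsFactors = FALSE
  )
  out[out$fraction > 0, , drop = FALSE]
}

# which strata does a strategy screen?
strata_screened <- function(strategy, strata) {
  if (is.null(strategy)) return(rep(FALSE, nrow(strata)))
  switch(as.character(strategy$pack_years),
         "30" = strata$stratum == "py30",
         "20" = strata$stratum %in% c("py30", "py20only"),
         stop("unknown pack-year threshold"))
}

#' Run one cohort under one strategy
#'
#' The cohort is a mixture of four homogeneous subcohorts -- sex (mixed by
#' `params$male_fraction`) crossed with screening eligibility (the
#' strategy's pack-year stratum is screened at its elevated incidence; the
#' ineligible remainder is unscreened at baseline risk) -- so that all
#' strategies are compared on the same total population.
#'
#' @param cohort one-row data.frame from [cohort_spec()].
#' @param strategy strategy id (0--7), one-row catalog data.frame, or
#'   `NULL`/`"none"` for no screening.
#' @param params an `lcs_params` object.
#' @param .cache optional environment reusing unscreened subcohort runs
#'   across strategies evaluated on the same parameter set.
#' @return List with the population-weighted `trace` and `outcome` (an
#'   `lcs_outcome` with per-person discounted cost/LY/QALY).
#' @export
run_cohort <- function(cohort, strategy, params, .cache = NULL) {
  strategy <- as_strategy(strategy)
  strata <- population_strata(params)
  screened <- strata_screened(strategy, strata)
  mf <- params$male_fraction

  trace <- NULL
  tot <- c(cost = 0, ly = 0, qaly = 0)
  for (i in seq_len(nrow(strata))) {
    for (sex in c("male", "female")) {
      w <- strata$fraction[i] * if (sex == "male") mf else 1 - mf
      if (w <= 0) next
      res <- NULL
      # subcohort runs depend only on (sex, entry age, stratum) and -- when
      # screened -- the tool and frequency, so they are shareable across
      # strategies evaluated on the same parameter set
      key <- if (screened[i]) {
        paste("screen", sex, cohort$entry_age, strata$threshold[i],
              strategy$tool, strategy$frequency)
      } else {
        paste("noscreen", sex, cohort$entry_age, strata$threshold[i])
      }
      if (!is.null(.cache)) res <- .cache[[key]]
      if (is.null(res)) {
        res <- run_subcohort(cohort$entry_age, sex, screened[i],
                             if (screened[i]) strategy else NULL, params,
                             threshold = strata$threshold[i])
        if (!is.null(.cache)) .cache[[key]] <- res
      }
      trace <- if (is.null(trace)) w * res$trace else trace + w * res$trace
      tot <- tot + w * c(res$cost, res$ly, res$qaly)
    }
  }
  outcome <- new_outcome(strategy, tot[["cost"]], tot[["ly"]], tot[["qaly"]],
                         n = cohort$size)
  list(trace = trace, outcome = outcome)
}

new_outcome <- function(strategy, cost_pp, ly_pp, qaly_pp, n) {
  out <- list(
    strategy_id = if (is.null(strategy)) NA_integer_ else strategy$id,
    n = n,
    per_person = c(cost = cost_pp, ly = ly_pp, qaly = qaly_pp),
    population = c(cost = cost_pp * n, ly = ly_pp * n, qaly = qaly_pp * n)
  )
  class(out) <- "lcs_outcome"
  out
}

#' Run a strategy over a cohort set
#'
#' Population-weighted aggregation of per-cohort outcomes.
#'
#' @param strategy strategy id, catalog row, or `NULL`/`"none"`.
#' @param cohorts data.frame of cohort rows (default [default_cohorts()]).
#' @param params an `lcs_params` object.
#' @param .cache optional environment shared across strategies (see
#'   [run_cohort()]).
#' @return An `lcs_outcome` with per-person and population-scaled totals.
#' @export
#' @examples
#' \donttest{
#' p <- default_parameter_set()
#' run_strategy(0, cohorts_at_age(65, n_cohorts = 1), p)
#' }
run_strategy <- function(strategy, cohorts = default_cohorts(), params,
                         .cache = NULL) {
  stopifnot(nrow(cohorts) >= 1L)
  strategy <- as_strategy(strategy)
  pop <- c(cost = 0, ly = 0, qaly = 0)
  n <- 0L
  for (i in seq_len(nrow(cohorts))) {
    res <- run_cohort(cohorts[i, , drop = FALSE], strategy, params,
                      .cache = .cache)
    pop <- pop + res$outcome$population
    n <- n + cohorts$size[i]
  }
  new_outcome(strategy, pop[["cost"]] / n, pop[["ly"]] / n,
              pop[["qaly"]] / n, n = n)
}

#' Presentation units of the published outcome table
#'
#' Converts a population-scaled outcome to the published layout: cost in
#' CNY millions, life-years and QALYs in 10,000s.
#'
#' @param outcome an `lcs_outcome`.
#' @return Named numeric vector `cost_millions`, `ly_10k`, `qaly_10k`.
#' @export
as_table_units <- function(outcome) {
  stopifnot(inherits(outcome, "lcs_outcome"))
  c(cost_millions = outcome$population[["cost"]] / 1e6,
    ly_10k = outcome$population[["ly"]] / 1e4,
    qaly_10k = outcome$population[["qaly"]] / 1e4)
}

#' @export
print.lcs_outcome <- function(x, ...) {
  cat("<lcs_outcome> strategy",
      if (is.na(x$strategy_id)) "none" else x$strategy_id,
      "| n =", x$n, "\n")
  cat(sprintf("  per person: cost %.2f CNY | %.4f LY | %.4f QALY\n",
              x$per_person[["cost"]], x$per_person[["ly"]],
              x$per_person[["qaly"]]))
  invisible(x)
}

#' Accumulate discounted payoffs over an arbitrary occupancy trace
#'
#' Generic dot-product accumulator used both by the engine tests and the
#' toy-chain oracles: per-cycle payoffs are the start-of-cycle occupancy
#' times per-state cost/utility, discounted at `(1 + rate)^(-t)`. One-off
#' entry costs are outside its scope (they attach to entry flows in the
#' engine, not to occupancy).
#'
#' @param trace cycles x states occupancy matrix (row sums 1).
#' @param payoff list with per-state numeric vectors `cost` and `utility`,
#'   matching the trace columns.
#' @param discount_rate annual rate applied to both costs and effects.
#' @param dead_states column names counted as not-alive for life-years.
#' @return Named vector `cost`, `ly`, `qaly`.
#' @export
accumulate_outcomes <- function(trace, payoff, discount_rate = 0,
                                dead_states = "Death") {
  stopifnot(is.matrix(trace))
  k <- ncol(trace)
  if (length(payoff$cost) != k || length(payoff$utility) != k) {
    stop("payoff schedule must supply cost and utility for all ", k,
         " states")
  }
  d <- discount_factor(seq_len(nrow(trace)) - 1L, discount_rate)
  alive <- if (!is.null(colnames(trace))) {
    1 - rowSums(trace[, colnames(trace) %in% dead_states, drop = FALSE])
  } else {
    rep(1, nrow(trace))
  }
  c(cost = sum(d * (trace %*% payoff$cost)),
    ly = sum(d * alive),
    qaly = sum(d * (trace %*% payoff$utility)))
}

#' Iterate a transition matrix into an occupancy trace
#'
#' Production-path trace builder shared with the toy-chain tests: repeated
#' vector-matrix multiplication from a start distribution.
#'
#' @param P row-stochastic transition matrix.
#' @param v0 start occupancy (defaults to all mass in state 1).
#' @param n_cycles number of transitions; the trace has `n_cycles + 1` rows.
#' @return Occupancy matrix with one row per cycle.
#' @export
chain_trace <- function(P, v0 = NULL, n_cycles = 100L) {
  n <- nrow(P)
  stopifnot(ncol(P) == n, all(abs(rowSums(P) - 1) < 1e-9))
  if (is.null(v0)) v0 <- c(1, numeric(n - 1L))
  trace <- matrix(0, n_cycles + 1L, n, dimnames = list(NULL, rownames(P)))
  v <- v0
  trace[1L, ] <- v
  for (t in seq_len(n_cycles)) {
    v <- as.numeric(v %*% P)
    trace[t + 1L, ] <- v
  }
  trace
}

#' Export a cohort trace as delimited text
#'
#' @param trace occupancy matrix from [run_cohort()].
#' @param entry_age age at cycle 0.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, entry_age, path) {
  df <- data.frame(cycle = seq_len(nrow(trace)) - 1L,
                   age = entry_age + seq_len(nrow(trace)) - 1L,
                   trace, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
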