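# Sensitivity analysis: one-way deterministic sweeps (tornado), PSA, and
# threshold search on test operating characteristics.

#' ICER of a strategy pair under a parameter set
#'
#' Convenience evaluator used by the sweep and threshold machinery:
#' runs both strategies on the same cohorts and returns the pairwise
#' comparison of the first (intervention) versus the second (comparator).
#'
#' @param pair length-2 vector of strategy ids `c(intervention, comparator)`.
#' @param cohorts cohort data.frame.
#' @param params an `lcs_params` object.
#' @return The [pairwise_icer()] list.
#' @export
evaluate_pair <- function(pair, cohorts, params) {
  stopifnot(length(pair) == 2L)
  cache <- new.env(parent = emptyenv())
  a <- run_strategy(pair[[1L]], cohorts, params, .cache = cache)
  b <- run_strategy(pair[[2L]], cohorts, params, .cache = cache)
  pairwise_icer(a, b)
}

#' Specify a one-way sweep
#'
#' @param path dotted parameter path (see [param_get()]).
#' @param low,high sweep endpoints on the parameter's own units; for
#'   `mode = "fraction"` they are interpreted as fractions of the base value
#'   (e.g. -0.3, 0.3).
#' @param n_points grid size (>= 2).
#' @param mode `"absolute"` or `"fraction"`.
#' @return A `lcs_sweep` list.
#' @export
sweep_spec <- function(path, low, high, n_points = 11L,
                       mode = c("absolute", "fraction")) {
  mode <- match.arg(mode)
  if (!(low < high)) stop("sweep requires low < high")
  if (n_points < 2L) stop("sweep requires n_points >= 2")
  structure(list(path = path, low = low, high = high,
                 n_points = as.integer(n_points), mode = mode),
            class = "lcs_sweep")
}

resolve_sweep_grid <- function(spec, params) {
  base <- param_get(params, spec$path)
  if (spec$mode == "fraction") {
    base * (1 + seq(spec$low, spec$high, length.out = spec$n_points))
  } else {
    seq(spec$low, spec$high, length.out = spec$n_points)
  }
}

#' One-way deterministic sweep
#'
#' Re-evaluates the pairwise ICER over a grid of values of one parameter,
#' leaving the base set untouched (asserted by digest).
#'
#' @param spec an `lcs_sweep` from [sweep_spec()].
#' @param pair strategy pair `c(intervention, comparator)`.
#' @param cohorts cohort data.frame.
#' @param params base-case `lcs_params`.
#' @return data.frame `value`, `icer`, `delta_cost`, `delta_qaly`, sorted by
#'   value, with attributes `path` and `base_icer`.
#' @export
one_way_sweep <- function(spec, pair, cohorts, params) {
  stopifnot(inherits(spec, "lcs_sweep"))
  digest0 <- parameter_digest(params)
  grid <- sort(resolve_sweep_grid(spec, params))
  rows <- lapply(grid, function(x) {
    p <- param_set(params, spec$path, x)
    viol <- validate_parameter_set(p)
    if (nrow(viol)) {
      stop("sweep value ", x, " invalidates '", spec$path, "': ",
           viol$rule[1L])
    }
    r <- evaluate_pair(pair, cohorts, p)
    data.frame(value = x, icer = r$icer, delta_cost = r$delta_cost,
               delta_qaly = r$delta_qaly)
  })
  out <- do.call(rbind, rows)
  if (!identical(parameter_digest(params), digest0)) {
    stop("sweep mutated the shared base parameter set")
  }
  attr(out, "path") <- spec$path
  attr(out, "base_icer") <- evaluate_pair(pair, cohorts, params)$icer
  out
}

#' Default one-way sweep set
#'
#' The published univariate analysis varies: screening cost and maintenance
#' cost and the CPI rate by +/-30%, the discount rate over 0--8%, and the
#' test operating characteristics over their published ranges (LDCT
#' sensitivity 0.63--0.95, specificity 0.65--0.97; conjunctive sensitivity
#' 0.41--0.98, specificity 0.81--0.99).
#'
#' @param n_points interior grid size per sweep.
#' @param cost_fraction half-width of the relative cost sweeps.
#' @return Named list of `lcs_sweep` objects.
#' @export
default_sweeps <- function(n_points = 11L, cost_fraction = 0.30) {
  list(
    screening_cost = sweep_spec("cost_ldct", -cost_fraction, cost_fraction,
                                n_points, mode = "fraction"),
    maintenance_cost = sweep_spec("maintenance_fraction", -cost_fraction,
                                  cost_fraction, n_points,
                                  mode = "fraction"),
    discount_rate = sweep_spec("discount_rate", 0, 0.08, n_points),
    cpi_rate = sweep_spec("cpi_rate", -cost_fraction, cost_fraction,
                          n_points, mode = "fraction"),
    sens_ldct = sweep_spec("sens_ldct", 0.63, 0.95, n_points),
    spec_ldct = sweep_spec("spec_ldct", 0.65, 0.97, n_points),
    sens_msc_conj = sweep_spec("sens_msc_conj", 0.41, 0.98, n_points),
    spec_msc_conj = sweep_spec("spec_msc_conj", 0.81, 0.99, n_points)
  )
}

#' Tornado table
#'
#' Runs each sweep and ranks parameters by the width of their ICER interval,
#' widest first (the ordering rule of a tornado diagram).
#'
#' @param sweeps named list of `lcs_sweep` objects.
#' @param pair,cohorts,params as in [one_way_sweep()].
#' @return data.frame `parameter`, `path`, `value_low`, `value_high`,
#'   `icer_min`, `icer_max`, `width`, `rank`, plus attribute `base_icer`.
#' @export
tornado_table <- function(sweeps, pair, cohorts, params) {
  if (!length(sweeps)) stop("tornado requires at least one sweep")
  base_icer <- evaluate_pair(pair, cohorts, params)$icer
  rows <- lapply(names(sweeps), function(nm) {
    sw <- one_way_sweep(sweeps[[nm]], pair, cohorts, params)
    data.frame(parameter = nm, path = attr(sw, "path"),
               value_low = min(sw$value), value_high = max(sw$value),
               icer_min = min(sw$icer), icer_max = max(sw$icer),
               width = max(sw$icer) - min(sw$icer),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width, out$parameter), ]
  out$rank <- seq_len(nrow(out))
  attr(out, "base_icer") <- base_icer
  rownames(out) <- NULL
  out
}

#' Probabilistic sensitivity analysis
#'
#' Draws `n_iter` parameter sets from `dist_table` and re-evaluates every
#' strategy on each. Draws are index-seeded (`seed + iter`), so any
#' execution order -- or an interrupted, resumed run -- yields identical
#' samples. Unscreened subcohorts are cached within an iteration and shared
#' across strategies.
#'
#' @param n_iter number of iterations (the published analysis uses 10,000).
#' @param seed base integer seed.
#' @param dist_table named list of `lcs_dist` (default
#'   [default_psa_distributions()]).
#' @param strategies vector of strategy ids to evaluate.
#' @param cohorts cohort data.frame.
#' @param params base-case `lcs_params`.
#' @param max_failure_rate abort when more than this fraction of draws fail
#'   validation (a sign of distribution mis-specification).
#' @return An `lcs_psa` object: `samples` data.frame (`iter`, `strategy_id`,
#'   `cost`, `ly`, `qaly`, population scale), `seed`, `n_iter`.
#' @export
run_psa <- function(n_iter, seed, dist_table = NULL, strategies = c(0L, 2L),
                    cohorts = default_cohorts(), params,
                    max_failure_rate = 0.01) {
  stopifnot(n_iter >= 1L)
  if (is.null(dist_table)) dist_table <- default_psa_distributions(params)
  n_str <- length(strategies)
  total <- n_iter * n_str
  iter_col <- integer(total); id_col <- integer(total)
  cost_col <- numeric(total); ly_col <- numeric(total)
  qaly_col <- numeric(total)
  failures <- 0L
  k <- 0L
  for (i in seq_len(n_iter)) {
    p_i <- tryCatch(
      sample_parameter_set(params, dist_table, seed = seed + i),
      error = function(e) e
    )
    if (inherits(p_i, "error")) {
      failures <- failures + 1L
      if (failures > max(1, ceiling(max_failure_rate * n_iter))) {
        stop("PSA aborted: >", 100 * max_failure_rate,
             "% of draws failed validation; last error: ",
             conditionMessage(p_i))
      }
      p_i <- NULL
    }
    cache <- new.env(parent = emptyenv())
    for (s in strategies) {
      k <- k + 1L
      iter_col[k] <- i
      id_col[k] <- s
      if (is.null(p_i)) {
        cost_col[k] <- NA_real_; ly_col[k] <- NA_real_; qaly_col[k] <- NA_real_
      } else {
        o <- run_strategy(s, cohorts, p_i, .cache = cache)
        cost_col[k] <- o$population[["cost"]]
        ly_col[k] <- o$population[["ly"]]
        qaly_col[k] <- o$population[["qaly"]]
      }
    }
  }
  samples <- data.frame(iter = iter_col, strategy_id = id_col,
                        cost = cost_col, ly = ly_col, qaly = qaly_col)
  samples <- samples[!is.na(samples$cost), ]
  structure(list(samples = samples, seed = seed, n_iter = n_iter,
                 strategies = strategies, failures = failures),
            class = "lcs_psa")
}

#' @export
print.lcs_psa <- function(x, ...) {
  cat("<lcs_psa>", x$n_iter, "iterations | seed", x$seed, "| strategies",
      paste(x$strategies, collapse = ", "), "\n")
  invisible(x)
}

#' Threshold search on a model parameter
#'
#' Finds the parameter value at which the pairwise ICER crosses a target
#' (e.g. 1x per-capita GDP) by bisection, after checking on a coarse sample
#' that the ICER is monotone over the bounds and that the target is
#' bracketed. Deterministic and seed-free.
#'
#' @param path dotted parameter path.
#' @param target ICER target, CNY/QALY.
#' @param pair strategy pair `c(intervention, comparator)`.
#' @param bounds length-2 numeric search interval.
#' @param params base-case `lcs_params`.
#' @param cohorts cohort data.frame.
#' @param icer_fn optional `function(value) -> ICER` overriding the model
#'   evaluation (used for closed-form verification).
#' @param tol_icer absolute ICER tolerance, CNY/QALY.
#' @param tol_x parameter tolerance.
#' @param n_check points of the monotonicity pre-check.
#' @return List: `value`, `icer`, `endpoints` (ICER at the bounds),
#'   `iterations`.
#' @export
threshold_search <- function(path, target, pair = NULL, bounds, params = NULL,
                             cohorts = NULL, icer_fn = NULL, tol_icer = 1,
                             tol_x = 1e-6, n_check = 9L) {
  stopifnot(length(bounds) == 2L, bounds[1L] < bounds[2L])
  f <- if (!is.null(icer_fn)) icer_fn else function(x) {
    evaluate_pair(pair, cohorts, param_set(params, path, x))$icer
  }
  grid <- seq(bounds[1L], bounds[2L], length.out = n_check)
  vals <- vapply(grid, f, numeric(1L))
  d <- diff(vals)
  if (!(all(d <= 0) || all(d >= 0))) {
    stop("ICER is not monotone in '", path, "' over the bounds; ",
         "refusing to bisect")
  }
  lo <- bounds[1L]; hi <- bounds[2L]
  flo <- vals[1L]; fhi <- vals[n_check]
  if ((flo - target) * (fhi - target) > 0) {
    stop("target ", target, " not bracketed: ICER ranges from ",
         signif(flo, 8), " to ", signif(fhi, 8))
  }
  it <- 0L
  repeat {
    it <- it + 1L
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - target) <= tol_icer || (hi - lo) / 2 <= tol_x) {
      return(list(value = mid, icer = fm,
                  endpoints = c(low = flo, high = fhi), iterations = it))
    }
    if ((flo - target) * (fm - target) <= 0) {
      hi <- mid; fhi <- fm
    } else {
      lo <- mid; flo <- fm
    }
    if (it > 200L) stop("bisection failed to converge")
  }
}
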