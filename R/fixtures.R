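# Synthetic fixtures and independent oracles. These deliberately share no
# transition-assembly code with the production engine: the closed form uses
# the fundamental matrix of an absorbing chain, the microsimulation is a
# first-order multinomial sampler, so agreement with the cohort trace is
# evidence, not tautology.

#' Generate a random absorbing toy chain
#'
#' A row-stochastic chain of 2--6 states whose last state is absorbing and
#' receives at least `min_absorb` probability from every transient state
#' (guaranteeing geometric absorption), with random non-negative per-state
#' costs and utilities in \[0, 1\] (zero in the absorbing state).
#'
#' @param n_states 2--6.
#' @param seed integer seed; the same seed yields the identical chain.
#' @param min_absorb minimum one-step absorption probability.
#' @return An `lcs_toy_chain`: `P`, `cost`, `utility`, `absorbing` (index).
#' @export
make_toy_chain <- function(n_states, seed, min_absorb = 0.05) {
  if (n_states < 2L || n_states > 6L) {
    stop("n_states must be between 2 and 6")
  }
  set.seed(as.integer(seed %% 2147483647))
  n <- as.integer(n_states)
  P <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    raw <- stats::rgamma(n, shape = 1)
    p <- raw / sum(raw)
    p <- (1 - min_absorb) * p
    p[n] <- p[n] + min_absorb
    P[i, ] <- p
  }
  P[n, n] <- 1
  dimnames(P) <- list(paste0("S", seq_len(n)), paste0("S", seq_len(n)))
  cost <- c(stats::runif(n - 1L, 0, 100), 0)
  utility <- c(stats::runif(n - 1L, 0, 1), 0)
  structure(list(P = P, cost = cost, utility = utility, absorbing = n,
                 n_states = n, seed = seed),
            class = "lcs_toy_chain")
}

#' Closed-form expected discounted payoffs of an absorbing chain
#'
#' With transient block Q and per-cycle discount factor `beta`, the expected
#' discounted number of cycles spent in each transient state (payoff accrued
#' at start-of-cycle occupancy, cycle 0 undiscounted) is the fundamental-
#' matrix row `(I - beta * Q)^-1`. Payoff totals follow by dot product with
#' the per-state cost/utility vectors.
#'
#' @param chain an `lcs_toy_chain`.
#' @param beta per-cycle discount factor in (0, 1].
#' @return List: `cycles` (transient x transient matrix of expected
#'   discounted cycles-in-state by start state), and per-start-state `cost`,
#'   `ly`, `qaly` totals.
#' @export
closed_form_expected_payoff <- function(chain, beta = 1) {
  stopifnot(inherits(chain, "lcs_toy_chain"), beta > 0, beta <= 1)
  n <- chain$n_states
  tr <- seq_len(n - 1L)
  Q <- chain$P[tr, tr, drop = FALSE]
  M <- solve(diag(n - 1L) - beta * Q)
  list(cycles = M,
       cost = as.numeric(M %*% chain$cost[tr]),
       ly = as.numeric(M %*% rep(1, n - 1L)),
       qaly = as.numeric(M %*% chain$utility[tr]))
}

#' First-order microsimulation of a chain
#'
#' Simulates `n_individuals` independent paths (as per-state multinomial
#' counts) and returns the empirical occupancy trace with per-cell binomial
#' standard errors, for comparison against the deterministic cohort trace.
#'
#' @param P row-stochastic transition matrix.
#' @param n_individuals >= 1.
#' @param seed integer seed.
#' @param n_cycles number of transitions.
#' @param start start state index (default 1).
#' @return List: `trace` (empirical fractions, `n_cycles + 1` rows), `se`
#'   (binomial SE of each cell), `counts`.
#' @export
microsim_trace <- function(P, n_individuals, seed, n_cycles = 100L,
                           start = 1L) {
  if (n_individuals < 1L) stop("n_individuals must be >= 1")
  stopifnot(all(abs(rowSums(P) - 1) < 1e-9))
  set.seed(as.integer(seed %% 2147483647))
  n <- nrow(P)
  counts <- matrix(0L, n_cycles + 1L, n)
  cur <- integer(n)
  cur[start] <- as.integer(n_individuals)
  counts[1L, ] <- cur
  for (t in seq_len(n_cycles)) {
    nxt <- integer(n)
    for (s in which(cur > 0L)) {
      nxt <- nxt + as.integer(stats::rmultinom(1L, cur[s], P[s, ]))
    }
    cur <- nxt
    counts[t + 1L, ] <- cur
  }
  trace <- counts / n_individuals
  se <- sqrt(trace * (1 - trace) / n_individuals)
  list(trace = trace, se = se, counts = counts)
}

#' Per-individual microsimulation of discounted payoffs
#'
#' Simulates `n_individuals` full paths through a toy chain and accumulates
#' each individual's discounted cost, life-cycles and utility (payoff at
#' start-of-cycle state, cycle 0 undiscounted), returning Monte Carlo means
#' and standard errors -- the independent first-order oracle for the cohort
#' engine's expected payoffs.
#'
#' @param chain an `lcs_toy_chain`.
#' @param n_individuals paths to simulate.
#' @param seed integer seed.
#' @param beta per-cycle discount factor in (0, 1].
#' @param n_cycles horizon (payoff beyond is negligible for chains with
#'   bounded absorption time).
#' @return List: `mean` and `se`, each named `cost`, `ly`, `qaly`.
#' @export
microsim_payoffs <- function(chain, n_individuals, seed, beta = 1,
                             n_cycles = 60L) {
  stopifnot(inherits(chain, "lcs_toy_chain"), n_individuals >= 1L)
  set.seed(as.integer(seed %% 2147483647))
  n <- chain$n_states
  state <- rep(1L, n_individuals)
  cost <- numeric(n_individuals)
  ly <- numeric(n_individuals)
  qaly <- numeric(n_individuals)
  alive <- c(rep(1, n - 1L), 0)
  for (t in 0:n_cycles) {
    d <- beta^t
    cost <- cost + d * chain$cost[state]
    ly <- ly + d * alive[state]
    qaly <- qaly + d * chain$utility[state]
    if (t == n_cycles) break
    nxt <- state
    for (s in seq_len(n - 1L)) {
      idx <- which(state == s)
      if (length(idx)) {
        nxt[idx] <- sample.int(n, length(idx), replace = TRUE,
                               prob = chain$P[s, ])
      }
    }
    state <- nxt
    if (all(state == n)) {
      # everyone absorbed; remaining cycles accrue nothing
      break
    }
  }
  m <- c(cost = mean(cost), ly = mean(ly), qaly = mean(qaly))
  se <- c(cost = stats::sd(cost), ly = stats::sd(ly),
          qaly = stats::sd(qaly)) / sqrt(n_individuals)
  list(mean = m, se = se)
}

#' Randomly perturb a parameter set (robustness fixture)
#'
#' Applies multiplicative jitter of magnitude at most `scale` to every
#' sampled-type numeric leaf, then repairs validity: probabilities are
#' clipped to \[0, 1\], simplex fields renormalized, and per-stage outflow
#' budgets rescaled when they exceed 1. Structural settings (ages, cycle
#' length, options) are untouched. `scale = 0` returns the input exactly.
#'
#' @param params an `lcs_params`.
#' @param scale jitter half-width (>= 0); each leaf is multiplied by a value
#'   in `[1 - scale, 1 + scale]`.
#' @param seed integer seed.
#' @return A validated `lcs_params`.
#' @export
perturb_parameters <- function(params, scale, seed) {
  if (scale < 0) stop("scale must be >= 0")
  if (scale == 0) return(params)
  set.seed(as.integer(seed %% 2147483647))
  p <- params
  jit <- function(x) x * stats::runif(length(x), 1 - scale, 1 + scale)
  prob_fields <- c("sens_ldct", "spec_ldct", "sens_msc_conj", "spec_msc_conj",
                   "utility_normal", "maintenance_fraction",
                   "eligible_fraction_20py", "eligible_fraction_30py",
                   "male_fraction")
  for (f in prob_fields) p[[f]] <- min(max(jit(p[[f]]), 0), 1)
  for (f in c("allcause_mort", "stage_prog", "stage_death", "utility",
              "detect_stage_ldct", "detect_stage_ldct_msc",
              "clinical_stage_dist")) {
    p[[f]] <- pmin(pmax(jit(p[[f]]), 0), 1)
  }
  for (b in names(p$incidence_per_100k)) {
    p$incidence_per_100k[[b]] <- pmax(jit(p$incidence_per_100k[[b]]), 0)
  }
  p$lc_mort_per_100k <- pmax(jit(p$lc_mort_per_100k), 0)
  for (f in c("cost_ldct", "cost_msc", "cost_prediag", "cost_biopsy",
              "wtp_gdp", "rr_20py", "rr_30py", "discount_rate", "cpi_rate")) {
    p[[f]] <- max(jit(p[[f]]), 0)
  }
  p$cost_treat <- pmax(jit(p$cost_treat), 0)
  # repair simplexes
  for (f in lcs_simplex_fields()) {
    s <- sum(p[[f]])
    if (s <= 0) stop("perturbation zeroed simplex field ", f)
    p[[f]] <- p[[f]] / s
  }
  # repair eligibility nesting and stage outflow budgets
  if (p$eligible_fraction_30py > p$eligible_fraction_20py) {
    p$eligible_fraction_30py <- p$eligible_fraction_20py
  }
  for (s in cancer_stages()) {
    sel <- startsWith(names(p$stage_prog), paste0(s, "."))
    total <- sum(p$stage_prog[sel]) + p$stage_death[[s]]
    if (total > 1) {
      p$stage_prog[sel] <- p$stage_prog[sel] / total
      p$stage_death[[s]] <- p$stage_death[[s]] / total
    }
  }
  viol <- validate_parameter_set(p)
  if (nrow(viol)) {
    stop("perturbation produced an irreparable set: ",
         paste(unique(viol$field), collapse = ", "))
  }
  p
}

#' Serialize a toy chain to the package config dialect
#'
#' @param chain an `lcs_toy_chain`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_toy_chain <- function(chain, path) {
  jsonlite::write_json(unclass(chain), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_toy_chain
#' @export
read_toy_chain <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (!is.matrix(x$P)) x$P <- do.call(rbind, lapply(x$P, unlist))
  dimnames(x$P) <- NULL
  structure(x, class = "lcs_toy_chain")
}
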