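# Sampling distributions for probabilistic sensitivity analysis.
#
# Probabilities and utilities are drawn from beta distributions, costs and
# rate-like quantities from gamma distributions, both parameterized by
# method of moments from a (mean, se) pair. A zero standard error yields a
# degenerate point mass. Parameters whose natural scale is not (0, 1) or
# positive reals (e.g. incidence per 100,000) carry a `scale` factor: the
# draw happens on the transformed scale and is multiplied back.

#' Construct a sampling distribution by method of moments
#'
#' @param family one of `"beta"`, `"gamma"`, `"point"`.
#' @param mean target mean, on the parameter's own units.
#' @param se target standard error, same units; `se = 0` collapses any
#'   family to a point mass.
#' @param scale draws are taken on `mean/scale` and multiplied by `scale`
#'   (used for per-100,000 rates modelled as beta probabilities).
#' @return An object of class `lcs_dist` with fields `family`, `mean`, `se`,
#'   `scale`, and the method-of-moments shape parameters.
#' @export
#' @examples
#' d <- make_distribution("beta", 0.5, sqrt(0.05))  # shape1 = shape2 = 2
#' c(d$shape1, d$shape2)
make_distribution <- function(family = c("beta", "gamma", "point"),
                              mean, se = 0, scale = 1) {
  family <- match.arg(family)
  stopifnot(length(mean) == 1L, length(se) == 1L, is.finite(mean))
  if (se < 0) stop("negative se")
  if (scale <= 0) stop("scale must be positive")
  m <- mean / scale
  s <- se / scale
  if (se == 0) family <- "point"
  d <- list(family = family, mean = mean, se = se, scale = scale)
  if (family == "beta") {
    if (m <= 0 || m >= 1) {
      stop("beta requires mean/scale in (0, 1), got ", m)
    }
    if (s^2 >= m * (1 - m)) {
      stop("beta variance ", s^2, " infeasible for mean ", m)
    }
    c0 <- m * (1 - m) / s^2 - 1
    d$shape1 <- m * c0
    d$shape2 <- (1 - m) * c0
  } else if (family == "gamma") {
    if (m <= 0) stop("gamma requires mean > 0, got ", m)
    d$shape <- (m / s)^2
    d$scale_par <- s^2 / m
  }
  class(d) <- "lcs_dist"
  d
}

#' Draw from a distribution spec
#'
#' @param d an `lcs_dist` from [make_distribution()].
#' @param n number of draws.
#' @return Numeric vector of length `n`, on the parameter's own units.
#' @export
draw_dist <- function(d, n = 1L) {
  stopifnot(inherits(d, "lcs_dist"))
  x <- switch(d$family,
    point = rep(d$mean / d$scale, n),
    beta  = stats::rbeta(n, d$shape1, d$shape2),
    gamma = stats::rgamma(n, shape = d$shape, scale = d$scale_par)
  )
  x * d$scale
}

# se such that mean +/- 1.96 se spans [lo, hi] (used where a one-way
# sensitivity range is published)
se_from_range <- function(lo, hi) (hi - lo) / (2 * 1.96)

#' Default PSA distribution table
#'
#' Assigns a sampling distribution to every PSA-varied parameter path:
#' beta for probabilities and utilities, gamma for costs and relative risks.
#' The published supplement with exact standard errors is unavailable, so
#' defaults follow conventional practice: for test sensitivity/specificity,
#' se spans the published one-way range (`(hi - lo) / (2 * 1.96)`); costs use
#' se = 25% of the mean; other probabilities and utilities use se = 10% of
#' the mean. Structural zeros (CIS detection under conjunctive screening,
#' CIS stage-death) stay fixed. All entries can be overridden or dropped.
#'
#' @param params base-case `lcs_params`.
#' @param cost_cv,prob_cv coefficients of variation for costs and for
#'   probabilities without a published range.
#' @return Named list mapping parameter paths to `lcs_dist` objects.
#' @export
default_psa_distributions <- function(params, cost_cv = 0.25, prob_cv = 0.10) {
  tab <- list()
  add <- function(path, d) tab[[path]] <<- d
  beta_cv <- function(mean, scale = 1) {
    make_distribution("beta", mean, prob_cv * mean, scale = scale)
  }
  gamma_cv <- function(mean) {
    make_distribution("gamma", mean, cost_cv * mean)
  }

  for (b in names(params$incidence_per_100k)) {
    for (sx in c("female", "male")) {
      m <- params$incidence_per_100k[[b]][[sx]]
      add(paste0("incidence_per_100k.", b, ".", sx), beta_cv(m, scale = 1e5))
    }
  }
  # the input table lists beta for the relative risks, but a beta variate
  # cannot exceed 1; gamma is the standard positive-support substitute
  add("rr_20py", make_distribution("gamma", params$rr_20py,
                                   prob_cv * params$rr_20py))
  add("rr_30py", make_distribution("gamma", params$rr_30py,
                                   prob_cv * params$rr_30py))

  for (s in cancer_stages()) {
    m <- params$detect_stage_ldct[[s]]
    add(paste0("detect_stage_ldct.", s), beta_cv(m))
    m2 <- params$detect_stage_ldct_msc[[s]]
    if (m2 > 0) add(paste0("detect_stage_ldct_msc.", s), beta_cv(m2))
  }

  # published one-way ranges for the operating characteristics
  add("sens_ldct", make_distribution("beta", params$sens_ldct,
                                     se_from_range(0.63, 0.95)))
  add("spec_ldct", make_distribution("beta", params$spec_ldct,
                                     se_from_range(0.65, 0.97)))
  add("sens_msc_conj", make_distribution("beta", params$sens_msc_conj,
                                         se_from_range(0.41, 0.98)))
  add("spec_msc_conj", make_distribution("beta", params$spec_msc_conj,
                                         se_from_range(0.81, 0.99)))

  for (b in names(params$allcause_mort)) {
    add(paste0("allcause_mort.", b), beta_cv(params$allcause_mort[[b]]))
  }
  for (nm in names(params$stage_prog)) {
    add(paste0("stage_prog.", nm), beta_cv(params$stage_prog[[nm]]))
  }
  for (s in cancer_stages()) {
    m <- params$stage_death[[s]]
    if (m > 0) add(paste0("stage_death.", s), beta_cv(m))
  }
  for (s in cancer_stages()) {
    add(paste0("utility.", s), beta_cv(params$utility[[s]]))
  }
  for (f in c("cost_ldct", "cost_msc", "cost_prediag", "cost_biopsy")) {
    add(f, gamma_cv(params[[f]]))
  }
  for (s in cancer_stages()) {
    add(paste0("cost_treat.", s), gamma_cv(params$cost_treat[[s]]))
  }
  tab
}

# parameter-set fields that must stay on the probability simplex after
# element-wise sampling
lcs_simplex_fields <- function() {
  c("detect_stage_ldct", "detect_stage_ldct_msc", "clinical_stage_dist")
}

#' Draw one sampled parameter set
#'
#' Draws each entry of `dist_table` independently, writes it back by path,
#' renormalizes simplex-valued fields to sum to 1, and re-validates. The
#' same seed always yields the identical set.
#'
#' @param params base-case `lcs_params`.
#' @param dist_table named list of `lcs_dist`, as from
#'   [default_psa_distributions()]; names are parameter paths.
#' @param seed integer seed for this draw.
#' @return A validated `lcs_params`.
#' @export
sample_parameter_set <- function(params, dist_table, seed) {
  stopifnot(length(dist_table) >= 1L, !is.null(names(dist_table)))
  set.seed(as.integer(seed %% 2147483647))
  p <- params
  for (path in names(dist_table)) {
    p <- param_set(p, path, draw_dist(dist_table[[path]], 1L))
  }
  for (f in lcs_simplex_fields()) {
    s <- sum(p[[f]])
    if (s <= 0) stop("sampling error: field ", f, " sums to ", s)
    p[[f]] <- p[[f]] / s
  }
  viol <- validate_parameter_set(p)
  if (nrow(viol)) {
    stop("sampled parameter set invalid: ",
         paste(unique(viol$field), collapse = ", "))
  }
  p
}
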