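# Parameter set: every model input as a typed, validated list.
#
# The defaults reproduce the published base-case input table verbatim
# (incidence, relative risks, stage-at-detection proportions, test operating
# characteristics, mortality, stage transitions, utilities, costs) together
# with the analysis settings stated in the source methods (1-year cycles,
# horizon to age 79, 5% discount rate, screening stop age 74, willingness to
# pay anchored at per-capita GDP). Fields the original analysis used but
# never printed (eligible-smoker fractions, the presentation-stage
# distribution of clinically detected cancers, the CPI rate) carry clearly
# labelled fixture defaults; see the methods vignette.

LCS_SCHEMA_VERSION <- "1.0"

#' Default model parameter set
#'
#' Constructs the complete base-case parameter set. Values tagged
#' `provenance = "published"` in the schema ([parameter_schema()]) are the
#' published estimates; fields tagged `"fixture"` are package defaults for
#' quantities the original analysis used but did not print, and are meant to
#' be overridden from a config file when better data exist.
#'
#' @return A validated object of class `lcs_params` (a named list).
#' @seealso [load_parameter_set()], [validate_parameter_set()]
#' @export
#' @examples
#' p <- default_parameter_set()
#' p$utility[["StageIV"]]
default_parameter_set <- function() {
  p <- list(
    schema_version = LCS_SCHEMA_VERSION,

    # incidence per 100,000 general population per year, by band and sex
    incidence_per_100k = list(
      "50-54" = c(female = 89.6626,  male = 81.0559),
      "55-59" = c(female = 112.4574, male = 162.0833),
      "60-64" = c(female = 154.6871, male = 256.0943),
      "65-69" = c(female = 190.2521, male = 373.6808),
      "70-74" = c(female = 242.6310, male = 498.0681)
    ),
    rr_20py = 2.84,   # relative risk, >= 20 pack-years
    rr_30py = 3.87,   # relative risk, >= 30 pack-years

    # stage-at-detection proportions among screen-detected cancers
    detect_stage_ldct = c(CIS = 0.0370, StageI = 0.6852, StageII = 0.0370,
                          StageIII = 0.1852, StageIV = 0.0556),
    detect_stage_ldct_msc = c(CIS = 0, StageI = 0.5441, StageII = 0.0570,
                              StageIII = 0.1195, StageIV = 0.2794),

    # test operating characteristics (MSC values are the conjunctive
    # LDCT-then-MSC characteristics, not MSC in isolation)
    sens_ldct = 0.79, spec_ldct = 0.81,
    sens_msc_conj = 0.69, spec_msc_conj = 0.96,

    # annual all-cause mortality probability for smokers, by band
    allcause_mort = c("50-54" = 0.0045, "55-59" = 0.0065, "60-64" = 0.0108,
                      "65-69" = 0.0188, "70-74" = 0.0336, "75-79" = 0.0540),
    # lung-cancer deaths per 100,000 per year (used only when the
    # subtract-LC-mortality switch is enabled)
    lc_mort_per_100k = c("50-54" = 28.81, "55-59" = 52.86, "60-64" = 101.93,
                         "65-69" = 153.34, "70-74" = 248.57),

    # annual stage progression probabilities, named "from.to"
    stage_prog = c("CIS.StageI"      = 0.0980,
                   "StageI.StageII"  = 0.3682,
                   "StageI.StageIII" = 0.0328,
                   "StageI.StageIV"  = 0.0745,
                   "StageII.StageIII" = 0.2260,
                   "StageII.StageIV" = 0.1510,
                   "StageIII.StageIV" = 0.1455),
    # annual probability of death from a cancer stage (all-cause
    # within-stage risk; replaces background mortality in stage rows)
    stage_death = c(CIS = 0, StageI = 0.1739, StageII = 0.2842,
                    StageIII = 0.4626, StageIV = 0.5880),

    # utilities (QALY weight per year in state)
    utility = c(CIS = 0.87, StageI = 0.84, StageII = 0.84,
                StageIII = 0.87, StageIV = 0.75),
    utility_normal = 1.0,
    utility_death = 0,

    # unit costs, CNY at the 2018 price level
    cost_ldct = 245.86,
    cost_msc = 400.00,
    cost_prediag = 628.36,
    cost_biopsy = 1232.44,
    cost_treat = c(CIS = 47341.85, StageI = 53344.51, StageII = 83365.95,
                   StageIII = 90643.18, StageIV = 116471.34),
    maintenance_fraction = 0.10,  # of stage treatment cost, per year

    # analysis settings
    discount_rate = 0.05,
    cycle_length = 1,
    max_age = 79,
    stop_screen_age = 74,
    wtp_gdp = 70892,      # CNY per QALY, 1x per-capita GDP
    price_year = 2018,
    cpi_rate = 0.02,      # fixture: used only to re-base non-2018 costs

    # fixture defaults: quantities used but not printed by the source
    eligible_fraction_20py = 0.20,
    eligible_fraction_30py = 0.12,
    clinical_stage_dist = c(CIS = 0, StageI = 0.0370, StageII = 0.6852,
                            StageIII = 0.0370, StageIV = 0.2408),
    male_fraction = 0.5,

    # structural switches (model-form options, not sampled in PSA)
    options = list(
      rate_conversion = "linear",       # or "exponential": p = 1 - exp(-rate)
      subtract_lc_mortality = FALSE,    # remove LC deaths from background
      recurrence_prob = 0,              # maintenance -> partner stage
      fp_workup = "prediag",            # or "prediag_biopsy"
      discount_effects = TRUE,
      half_cycle_correction = FALSE,
      maintenance_utility = "stage"     # maintenance u = partner stage u
    )
  )
  class(p) <- "lcs_params"
  p
}

#' Field-level schema of the parameter set
#'
#' One row per leaf field group: its type, admissible bounds, unit, and
#' provenance (`published` input-table value vs `fixture` package default).
#'
#' @return A data.frame documenting every parameter field.
#' @export
parameter_schema <- function() {
  data.frame(
    field = c("incidence_per_100k", "rr_20py", "rr_30py",
              "detect_stage_ldct", "detect_stage_ldct_msc",
              "sens_ldct", "spec_ldct", "sens_msc_conj", "spec_msc_conj",
              "allcause_mort", "lc_mort_per_100k", "stage_prog",
              "stage_death", "utility", "utility_normal", "utility_death",
              "cost_ldct", "cost_msc", "cost_prediag", "cost_biopsy",
              "cost_treat", "maintenance_fraction", "discount_rate",
              "cycle_length", "max_age", "stop_screen_age", "wtp_gdp",
              "price_year", "cpi_rate", "eligible_fraction_20py",
              "eligible_fraction_30py", "clinical_stage_dist",
              "male_fraction", "options"),
    type = c("map band x sex", "scalar", "scalar", "simplex(5)", "simplex(5)",
             "probability", "probability", "probability", "probability",
             "map band", "map band", "map from.to", "map stage", "map stage",
             "probability", "probability", "cost", "cost", "cost", "cost",
             "map stage", "probability", "rate", "years", "years", "years",
             "cost", "year", "rate", "probability", "probability",
             "simplex(5)", "probability", "list"),
    unit = c("per 100,000/year", "ratio", "ratio", "proportion", "proportion",
             "proportion", "proportion", "proportion", "proportion",
             "probability/year", "per 100,000/year", "probability/year",
             "probability/year", "QALY/year", "QALY/year", "QALY/year",
             "CNY", "CNY", "CNY", "CNY", "CNY", "fraction/year",
             "fraction/year", "years", "years", "years", "CNY/QALY",
             "calendar year", "fraction/year", "proportion", "proportion",
             "proportion", "proportion", ""),
    provenance = c("published", "published", "published", "published",
                   "published", "published", "published", "published",
                   "published", "published", "published", "published",
                   "published", "published", "fixture", "published",
                   "published", "published", "published", "published",
                   "published", "published", "published", "published",
                   "published", "published", "published", "published",
                   "fixture", "fixture", "fixture", "fixture", "fixture",
                   "fixture"),
    stringsAsFactors = FALSE
  )
}

# ---- config i/o -------------------------------------------------------------

#' Load a parameter set from a JSON config file
#'
#' The config dialect is plain JSON mirroring [default_parameter_set()];
#' unknown keys and missing keys are errors (fail-loud). The packaged
#' default config lives at
#' `system.file("extdata", "base_case_parameters.json", package = "lcscreen")`.
#'
#' @param path path to a JSON parameter file; `NULL` loads the packaged
#'   base-case config.
#' @return A validated `lcs_params` object.
#' @export
load_parameter_set <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "base_case_parameters.json",
                        package = "lcscreen")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("parameter file not found: ", path)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  template <- default_parameter_set()
  extra <- setdiff(names(raw), names(template))
  if (length(extra)) {
    stop("unknown parameter key(s): ", paste(extra, collapse = ", "))
  }
  missing <- setdiff(names(template), names(raw))
  if (length(missing)) {
    stop("missing parameter key(s): ", paste(missing, collapse = ", "))
  }
  p <- template
  for (nm in names(template)) {
    tmpl <- template[[nm]]
    val <- raw[[nm]]
    if (is.list(tmpl) && nm != "options") {
      # nested map (incidence): coerce leaves to named numeric
      if (!setequal(names(val), names(tmpl))) {
        stop("field '", nm, "': expected keys ",
             paste(names(tmpl), collapse = ", "))
      }
      p[[nm]] <- lapply(stats::setNames(names(tmpl), names(tmpl)), function(b) {
        leaf <- unlist(val[[b]])
        if (!setequal(names(leaf), names(tmpl[[b]]))) {
          stop("field '", nm, ".", b, "': expected keys ",
               paste(names(tmpl[[b]]), collapse = ", "))
        }
        leaf[names(tmpl[[b]])]
      })
    } else if (nm == "options") {
      opt <- template$options
      extra_o <- setdiff(names(val), names(opt))
      if (length(extra_o)) {
        stop("unknown options key(s): ", paste(extra_o, collapse = ", "))
      }
      for (o in names(val)) {
        opt[[o]] <- if (is.numeric(opt[[o]])) as.numeric(val[[o]]) else
          val[[o]]
      }
      p$options <- opt
    } else if (is.numeric(tmpl) && !is.null(names(tmpl))) {
      leaf <- unlist(val)
      if (!setequal(names(leaf), names(tmpl))) {
        stop("field '", nm, "': expected keys ",
             paste(names(tmpl), collapse = ", "))
      }
      p[[nm]] <- leaf[names(tmpl)]
    } else {
      p[[nm]] <- if (is.character(tmpl)) as.character(val) else
        if (is.numeric(tmpl)) as.numeric(val) else val
    }
  }
  class(p) <- "lcs_params"
  viol <- validate_parameter_set(p)
  if (nrow(viol)) {
    stop("invalid parameter set:\n",
         paste(sprintf("  %s = %s (%s)", viol$field, viol$value, viol$rule),
               collapse = "\n"))
  }
  p
}

#' Write a parameter set to a JSON config file
#'
#' Round-trips with [load_parameter_set()].
#'
#' @param params an `lcs_params` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  stopifnot(inherits(params, "lcs_params"))
  # named numeric vectors must become lists to serialize as JSON objects
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (!is.null(names(x)) && length(x) > 1L) as.list(x)
    else x
  }
  jsonlite::write_json(listify(unclass(params)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# ---- validation -------------------------------------------------------------

#' Validate a parameter set
#'
#' Checks every invariant of the parameter set: probabilities in \[0, 1\],
#' non-negative costs, utilities in \[0, 1\], stage-at-detection vectors on
#' the probability simplex, per-stage outflow budgets (progression + death
#' <= 1), and eligibility nesting (30 pack-year smokers are a subset of 20
#' pack-year smokers). Violations are returned as data, not thrown.
#'
#' @param params an `lcs_params` object.
#' @return A data.frame with columns `field`, `value`, `rule`; zero rows iff
#'   the set is valid.
#' @export
#' @examples
#' nrow(validate_parameter_set(default_parameter_set()))  # 0
validate_parameter_set <- function(params) {
  v_field <- character(); v_value <- character(); v_rule <- character()
  bad <- function(field, value, rule) {
    v_field <<- c(v_field, field)
    v_value <<- c(v_value, paste(signif(value, 10), collapse = ","))
    v_rule <<- c(v_rule, rule)
  }
  chk_prob <- function(field, x) {
    i <- which(!is.finite(x) | x < 0 | x > 1)
    for (j in i) {
      nm <- if (is.null(names(x))) field else paste0(field, ".", names(x)[j])
      bad(nm, x[j], "probability must be in [0, 1]")
    }
  }
  chk_nonneg <- function(field, x) {
    i <- which(!is.finite(x) | x < 0)
    for (j in i) {
      nm <- if (is.null(names(x))) field else paste0(field, ".", names(x)[j])
      bad(nm, x[j], "must be >= 0")
    }
  }
  chk_simplex <- function(field, x, tol = 1e-9) {
    chk_prob(field, x)
    s <- sum(x)
    if (abs(s - 1) > tol) {
      bad(field, s, sprintf("sums to %.10g != 1", s))
    }
  }

  for (f in c("sens_ldct", "spec_ldct", "sens_msc_conj", "spec_msc_conj",
              "utility_normal", "utility_death", "maintenance_fraction",
              "eligible_fraction_20py", "eligible_fraction_30py",
              "male_fraction")) {
    chk_prob(f, params[[f]])
  }
  chk_prob("allcause_mort", params$allcause_mort)
  chk_prob("stage_prog", params$stage_prog)
  chk_prob("stage_death", params$stage_death)
  chk_prob("utility", params$utility)
  chk_prob("options.recurrence_prob", params$options$recurrence_prob)

  chk_simplex("detect_stage_ldct", params$detect_stage_ldct)
  chk_simplex("detect_stage_ldct_msc", params$detect_stage_ldct_msc)
  chk_simplex("clinical_stage_dist", params$clinical_stage_dist)

  for (b in names(params$incidence_per_100k)) {
    x <- params$incidence_per_100k[[b]]
    chk_nonneg(paste0("incidence_per_100k.", b), x)
    chk_prob(paste0("incidence_per_100k.", b), x / 1e5)
  }
  chk_nonneg("lc_mort_per_100k", params$lc_mort_per_100k)

  for (f in c("cost_ldct", "cost_msc", "cost_prediag", "cost_biopsy",
              "wtp_gdp")) {
    chk_nonneg(f, params[[f]])
  }
  chk_nonneg("cost_treat", params$cost_treat)
  chk_nonneg("rr_20py", params$rr_20py)
  chk_nonneg("rr_30py", params$rr_30py)
  chk_nonneg("discount_rate", params$discount_rate)
  chk_nonneg("cpi_rate", params$cpi_rate)

  # per-stage outflow budget: progression out + stage death <= 1
  for (s in cancer_stages()) {
    out <- params$stage_prog[startsWith(names(params$stage_prog),
                                        paste0(s, "."))]
    total <- sum(out) + params$stage_death[[s]]
    if (total > 1 + 1e-9) {
      bad(paste0("stage_death.", s), total,
          sprintf("stage outflow %.6g + death exceeds 1", total))
    }
  }

  if (params$eligible_fraction_30py > params$eligible_fraction_20py + 1e-12) {
    bad("eligible_fraction_30py", params$eligible_fraction_30py,
        "must be <= eligible_fraction_20py (30 py smokers are a subset)")
  }
  if (params$stop_screen_age > params$max_age) {
    bad("stop_screen_age", params$stop_screen_age, "must be <= max_age")
  }
  data.frame(field = v_field, value = v_value, rule = v_rule,
             stringsAsFactors = FALSE)
}

# ---- derived quantities -----------------------------------------------------

#' Annual maintenance cost for a cancer stage
#'
#' Maintenance (periodic post-treatment follow-up) costs a fixed fraction
#' (default 10%) of the stage treatment cost per year.
#'
#' @param stage one of [cancer_stages()].
#' @param params an `lcs_params` object.
#' @return Cost in CNY per maintenance year.
#' @export
#' @examples
#' maintenance_cost("CIS", default_parameter_set())  # 4734.185
maintenance_cost <- function(stage, params) {
  if (!stage %in% cancer_stages()) {
    stop("maintenance cost is defined only for cancer stages, not '",
         stage, "'")
  }
  params$maintenance_fraction * params$cost_treat[[stage]]
}

# ---- path access ------------------------------------------------------------

#' Get or set a parameter by dotted path
#'
#' Paths address leaves of the parameter set, e.g. `"cost_ldct"`,
#' `"cost_treat.StageI"`, `"incidence_per_100k.60-64.male"`,
#' `"stage_prog.StageI.StageII"`. Used by the sensitivity module to sweep
#' and sample individual inputs.
#'
#' @param params an `lcs_params` object.
#' @param path dotted path string.
#' @param value replacement value (for `param_set`).
#' @return `param_get` returns the leaf value; `param_set` returns the
#'   modified parameter set.
#' @export
param_get <- function(params, path) {
  toks <- strsplit(path, ".", fixed = TRUE)[[1L]]
  node <- unclass(params)
  i <- 1L
  while (i <= length(toks)) {
    if (is.list(node)) {
      if (!toks[i] %in% names(node)) stop("no such parameter: ", path)
      node <- node[[toks[i]]]
      i <- i + 1L
    } else {
      key <- paste(toks[i:length(toks)], collapse = ".")
      if (!key %in% names(node)) stop("no such parameter: ", path)
      return(unname(node[[key]]))
    }
  }
  if (is.list(node) || length(node) != 1L) {
    stop("path does not address a scalar leaf: ", path)
  }
  unname(node)
}

#' @rdname param_get
#' @export
param_set <- function(params, path, value) {
  toks <- strsplit(path, ".", fixed = TRUE)[[1L]]
  rec <- function(node, toks) {
    if (is.list(node)) {
      if (!toks[1L] %in% names(node)) stop("no such parameter: ", path)
      if (length(toks) == 1L) {
        node[[toks[1L]]] <- value
      } else {
        node[[toks[1L]]] <- rec(node[[toks[1L]]], toks[-1L])
      }
      node
    } else {
      key <- paste(toks, collapse = ".")
      if (!key %in% names(node)) stop("no such parameter: ", path)
      node[[key]] <- value
      node
    }
  }
  out <- rec(unclass(params), toks)
  class(out) <- "lcs_params"
  out
}

# ---- digest -----------------------------------------------------------------

#' Fingerprint of a parameter set
#'
#' Order-stable polynomial hash over the deparsed parameter values; used by
#' the sweep machinery to assert that the shared base-case set is never
#' mutated, and stamped into output-file headers.
#'
#' @param params an `lcs_params` object.
#' @return An 8-character hexadecimal string.
#' @export
parameter_digest <- function(params) {
  txt <- paste(deparse(unclass(params), control = "exact"), collapse = "")
  bytes <- utf8ToInt(txt)
  h <- 0
  m <- 2147483647  # 2^31 - 1; exact in doubles
  for (chunk in split(bytes, ceiling(seq_along(bytes) / 4096))) {
    for (b in chunk) h <- (h * 31 + b) %% m
  }
  sprintf("%08x", as.integer(h))
}

#' @export
print.lcs_params <- function(x, ...) {
  cat("<lcs_params> schema", x$schema_version,
      "| digest", parameter_digest(x), "\n")
  cat("  discount", x$discount_rate, "| horizon to age", x$max_age,
      "| screening stops at", x$stop_screen_age, "\n")
  cat("  LDCT sens/spec", x$sens_ldct, "/", x$spec_ldct,
      "| LDCT+MSC sens/spec", x$sens_msc_conj, "/", x$spec_msc_conj, "\n")
  invisible(x)
}
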