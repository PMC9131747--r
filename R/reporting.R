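# Report writers and command-line workflow: base-case CEA tables, tornado
# data, PSA samples/CEAC/scatter, threshold search, and config validation.
# All tabular outputs are delimited text with a commented header carrying
# the seed, parameter digest and schema version.

#' Published base-case outcome table
#'
#' The base-case results of the original published analysis (population
#' cost in CNY millions, life-years and QALYs in 10,000s, signed ICER
#' versus strategy 0), shipped as a fixed arithmetic fixture: the package's
#' ICER and dominance routines are verified against these printed columns.
#'
#' @return data.frame with columns `start_age`, `strategy`, `cost_millions`,
#'   `ly_10k`, `qaly_10k`, `icer` (`NA` for the comparator), `dominant`.
#' @export
published_base_case <- function() {
  path <- system.file("extdata", "published_base_case.csv",
                      package = "lcscreen")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Assemble a run configuration
#'
#' @param params_file path to a JSON parameter file; `NULL` for the packaged
#'   base-case config.
#' @param strategies strategy ids to run.
#' @param comparator comparator id (must be among `strategies`).
#' @param start_ages explicit start ages (one CEA block each); `NULL` uses
#'   the default mixed-age cohort set.
#' @param cohort_size,n_cohorts cohort layout per block.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_iter PSA iterations.
#' @return A validated `lcs_config` list.
#' @export
lcs_config <- function(params_file = NULL, strategies = 0:7, comparator = 0L,
                       start_ages = NULL, cohort_size = 10000L,
                       n_cohorts = 8L, out_dir = ".", seed = 1L,
                       n_iter = 10000L) {
  if (!comparator %in% strategies) {
    stop("config error: comparator must be among strategies")
  }
  if (!all(strategies %in% 0:7)) {
    stop("config error: strategies must be ids 0-7")
  }
  structure(list(params_file = params_file, strategies = strategies,
                 comparator = comparator, start_ages = start_ages,
                 cohort_size = cohort_size, n_cohorts = n_cohorts,
                 out_dir = out_dir, seed = seed, n_iter = n_iter),
            class = "lcs_config")
}

config_cohorts <- function(config, start_age = NULL) {
  if (is.null(start_age)) {
    default_cohorts()
  } else {
    cohorts_at_age(start_age, n_cohorts = config$n_cohorts,
                   size = config$cohort_size)
  }
}

output_header <- function(params, seed, extra = character()) {
  c(sprintf("# lcscreen schema %s", params$schema_version),
    sprintf("# parameter digest %s", parameter_digest(params)),
    sprintf("# seed %s", seed),
    extra)
}

#' Write a data frame as delimited text with a commented header
#'
#' @param df data.frame.
#' @param path output file.
#' @param header character vector of `#`-prefixed lines.
#' @return `path`, invisibly.
#' @export
write_output_table <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the base-case analysis
#'
#' One CEA table per start-age block (or a single mixed-age block), in the
#' published layout with dominance labels, written both machine-readable
#' (full precision, tab-separated) and pretty-printed (2 decimals).
#'
#' @param config an `lcs_config`.
#' @return Invisibly, a named list of CEA data.frames, one per block.
#' @export
run_base_case <- function(config) {
  stopifnot(inherits(config, "lcs_config"))
  params <- load_parameter_set(config$params_file)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  blocks <- if (is.null(config$start_ages)) list(mixed = NULL) else
    stats::setNames(as.list(config$start_ages),
                    paste0("age", config$start_ages))
  out <- list()
  for (nm in names(blocks)) {
    cohorts <- config_cohorts(config, blocks[[nm]])
    cache <- new.env(parent = emptyenv())
    outcomes <- lapply(config$strategies, function(s) {
      o <- run_strategy(s, cohorts, params, .cache = cache)
      message(sprintf(
        "base case block %s strategy %d: n=%d cost=%.2f qaly=%.4f", nm,
        s, o$n, o$per_person[["cost"]], o$per_person[["qaly"]]))
      o
    })
    tab <- cea_table(outcomes, comparator_id = config$comparator)
    hdr <- output_header(params, config$seed,
                         sprintf("# block %s | n = %d", nm,
                                 sum(cohorts$size)))
    write_output_table(tab, file.path(config$out_dir,
                                      paste0("cea_", nm, ".tsv")), hdr)
    pretty <- tab
    for (col in c("cost_millions", "ly_10k", "qaly_10k", "icer")) {
      pretty[[col]] <- ifelse(is.na(tab[[col]]), "NA",
                              formatC(tab[[col]], format = "f", digits = 2,
                                      big.mark = " "))
    }
    write_output_table(pretty, file.path(config$out_dir,
                                         paste0("cea_", nm, "_pretty.tsv")),
                       hdr)
    out[[nm]] <- tab
  }
  invisible(out)
}

#' Run the one-way (tornado) sensitivity analysis
#'
#' @param config an `lcs_config`; the pair analysed is
#'   `c(strategies[1], comparator)` unless both coincide, in which case the
#'   published tornado pair (strategy 2 vs 6) is used.
#' @param sweeps named list of sweeps (default [default_sweeps()]).
#' @return Invisibly, the tornado data.frame.
#' @export
run_dsa <- function(config, sweeps = default_sweeps()) {
  stopifnot(inherits(config, "lcs_config"))
  params <- load_parameter_set(config$params_file)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pair <- setdiff(config$strategies, config$comparator)
  pair <- if (length(pair)) c(pair[1L], config$comparator) else c(2L, 6L)
  cohorts <- config_cohorts(config,
                            if (is.null(config$start_ages)) NULL else
                              config$start_ages[1L])
  tor <- tornado_table(sweeps, pair, cohorts, params)
  hdr <- output_header(params, config$seed,
                       sprintf("# pair %d vs %d | base ICER %.4f",
                               pair[1L], pair[2L], attr(tor, "base_icer")))
  write_output_table(tor, file.path(config$out_dir, "tornado.tsv"), hdr)
  invisible(tor)
}

#' Run the probabilistic sensitivity analysis report
#'
#' Emits the raw PSA samples, the incremental cost/QALY scatter versus the
#' comparator, one CEAC per non-comparator strategy over the WTP grid, and
#' a summary line per strategy with the probability of cost-effectiveness
#' at 1x and 3x per-capita GDP.
#'
#' @param config an `lcs_config`.
#' @param wtp_grid thresholds for the CEAC (default [wtp_grid_default()]).
#' @return Invisibly, a list with `psa`, `ceac` (per strategy), `summary`.
#' @export
run_psa_report <- function(config, wtp_grid = wtp_grid_default()) {
  stopifnot(inherits(config, "lcs_config"))
  params <- load_parameter_set(config$params_file)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohorts <- config_cohorts(config,
                            if (is.null(config$start_ages)) NULL else
                              config$start_ages[1L])
  psa <- run_psa(config$n_iter, config$seed,
                 strategies = config$strategies, cohorts = cohorts,
                 params = params)
  hdr <- output_header(params, config$seed,
                       sprintf("# iterations %d", config$n_iter))
  write_output_table(psa$samples,
                     file.path(config$out_dir, "psa_samples.tsv"), hdr)

  comp <- psa$samples[psa$samples$strategy_id == config$comparator, ]
  comp <- comp[order(comp$iter), ]
  others <- setdiff(config$strategies, config$comparator)
  curves <- list(); summaries <- list()
  scatter <- list()
  for (s in others) {
    a <- psa$samples[psa$samples$strategy_id == s, ]
    a <- a[order(a$iter), ]
    scatter[[as.character(s)]] <- data.frame(
      iter = a$iter, strategy = s,
      delta_cost = a$cost - comp$cost,
      delta_qaly = a$qaly - comp$qaly)
    cv <- ceac(psa, s, config$comparator, wtp_grid)
    curves[[as.character(s)]] <- cv
    p1 <- ceac(psa, s, config$comparator, params$wtp_gdp)$prob
    p3 <- ceac(psa, s, config$comparator, 3 * params$wtp_gdp)$prob
    summaries[[as.character(s)]] <- data.frame(
      strategy = s, prob_ce_1x_gdp = p1, prob_ce_3x_gdp = p3)
    message(sprintf(
      "strategy %d vs %d: P(cost-effective) = %.4f at 1x GDP, %.4f at 3x GDP",
      s, config$comparator, p1, p3))
  }
  ceac_df <- do.call(rbind, lapply(names(curves), function(s) {
    cbind(strategy = as.integer(s), curves[[s]])
  }))
  write_output_table(ceac_df, file.path(config$out_dir, "ceac.tsv"), hdr)
  write_output_table(do.call(rbind, scatter),
                     file.path(config$out_dir, "psa_scatter.tsv"), hdr)
  summary_df <- do.call(rbind, summaries)
  write_output_table(summary_df,
                     file.path(config$out_dir, "psa_summary.tsv"), hdr)
  invisible(list(psa = psa, ceac = curves, summary = summary_df))
}

# ---- command line -----------------------------------------------------------

parse_cli_args <- function(args) {
  if (!length(args)) stop("usage: lcscreen <run|dsa|psa|threshold|validate> ",
                          "[--params F] [--out D] [--seed N] ",
                          "[--comparator N] [--start-age A] [--n-iter N]")
  cmd <- args[[1L]]
  opts <- list(params = NULL, out = ".", seed = 1L, comparator = 0L,
               start_age = NULL, n_iter = 10000L)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[[i]])
    if (i + 1L > length(args)) stop("missing value for --", key)
    val <- args[[i + 1L]]
    switch(key,
           params = { opts$params <- val },
           out = { opts$out <- val },
           seed = { opts$seed <- as.integer(val) },
           comparator = { opts$comparator <- as.integer(val) },
           `start-age` = { opts$start_age <- as.integer(val) },
           `n-iter` = { opts$n_iter <- as.integer(val) },
           stop("unknown flag --", key))
    i <- i + 2L
  }
  list(cmd = cmd, opts = opts)
}

#' Command-line entry point
#'
#' Subcommands: `run` (base case), `dsa` (tornado), `psa`, `threshold`,
#' `validate`. Invoked by the script in `inst/cli/lcscreen.R`:
#' `Rscript -e 'lcscreen::lcs_main(commandArgs(TRUE))' run --out results`.
#'
#' @param args character vector of command-line arguments.
#' @return Invisibly, the subcommand's result.
#' @export
lcs_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- parse_cli_args(args)
  o <- parsed$opts
  cfg <- lcs_config(params_file = o$params, comparator = o$comparator,
                    start_ages = o$start_age, out_dir = o$out,
                    seed = o$seed, n_iter = o$n_iter)
  switch(parsed$cmd,
         run = run_base_case(cfg),
         dsa = run_dsa(cfg),
         psa = run_psa_report(cfg),
         threshold = {
           params <- load_parameter_set(o$params)
           res <- threshold_search(
             "spec_msc_conj", params$wtp_gdp, pair = c(6L, 2L),
             bounds = c(0.81, 0.999), params = params,
             cohorts = config_cohorts(cfg, o$start_age))
           message(sprintf("threshold: spec_msc_conj = %.6f (ICER %.2f)",
                           res$value, res$icer))
           invisible(res)
         },
         validate = {
           params <- load_parameter_set(o$params)
           viol <- validate_parameter_set(params)
           if (nrow(viol)) {
             print(viol)
             stop("parameter set invalid")
           }
           message("parameter set valid | digest ",
                   parameter_digest(params))
           invisible(viol)
         },
         stop("unknown subcommand: ", parsed$cmd))
}
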