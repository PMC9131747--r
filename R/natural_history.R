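# Natural history: age-, sex- and smoking-adjusted annual transition
# structure for the unscreened disease process and the post-diagnosis
# pathway.
#
# Structure (see the methods vignette for rationale):
#   * Normal row: incidence mass split across the cancer-stage entry pathway
#     (screen-detected vs clinically presenting, supplied by the screening
#     overlay), plus background mortality, plus a residual self-loop.
#   * Stage rows: progression to worse stages and stage-specific death
#     (which replaces background mortality -- the published stage-death
#     probabilities are within-stage all-cause risks), with the complement
#     flowing to the stage's maintenance partner.
#   * Maintenance rows: quasi-absorbing; background mortality only, plus an
#     optional recurrence probability (default 0).
#   * Death: absorbing.
# Incidence is banded to ages 50-74; beyond 74 no new cancers arise (the
# published incidence table stops there and screening has stopped).

#' Smoking-adjusted annual lung cancer incidence
#'
#' Banded incidence per 100,000 divided by 100,000 (rare-event rate-to-
#' probability conversion; set `options$rate_conversion = "exponential"` for
#' `1 - exp(-rate)`), multiplied by the relative risk of the pack-year
#' stratum: 1 for never/light smokers, 2.84 at >= 20 pack-years, 3.87 at
#' >= 30 pack-years.
#'
#' @param age integer age, 50--74.
#' @param sex `"female"` or `"male"`.
#' @param pack_year_threshold `"none"`, `20`, or `30`.
#' @param params an `lcs_params` object.
#' @return Annual probability of developing lung cancer, clipped to \[0, 1\].
#' @export
#' @examples
#' adjusted_incidence(52, "female", "none", default_parameter_set())
adjusted_incidence <- function(age, sex, pack_year_threshold, params) {
  if (!sex %in% c("female", "male")) stop("unknown sex code: ", sex)
  band <- age_band_label(age, incidence_age_bands())
  rate <- params$incidence_per_100k[[band]][[sex]] / 1e5
  p <- if (identical(params$options$rate_conversion, "exponential")) {
    1 - exp(-rate)
  } else {
    rate
  }
  rr <- switch(as.character(pack_year_threshold),
               none = 1,
               "20" = params$rr_20py,
               "30" = params$rr_30py,
               # 20-30 pack-year stratum: RR implied by pooling consistency
               # with the published >= 20 py RR (see population_strata()),
               # floored at 1 so that risk stays monotone in exposure even
               # for PSA draws of the two RRs that would imply less
               "20only" = {
                 f20 <- params$eligible_fraction_20py
                 f30 <- params$eligible_fraction_30py
                 rr <- (f20 * params$rr_20py - f30 * params$rr_30py) /
                   (f20 - f30)
                 if (!is.finite(rr)) {
                   stop("inconsistent eligibility fractions: implied ",
                        "20-30 pack-year RR is not finite")
                 }
                 max(rr, 1)
               },
               stop("pack_year_threshold must be 'none', '20only', 20 or 30"))
  min(max(p * rr, 0), 1)
}

#' Background (all-cause) annual mortality
#'
#' Banded all-cause mortality for smokers, ages 50--79. With
#' `options$subtract_lc_mortality = TRUE` the banded lung-cancer death rate
#' is removed (ages 50--74) so that cancer deaths are not double counted
#' against the explicit stage-death pathway.
#'
#' @inheritParams adjusted_incidence
#' @return Annual probability of death from background causes.
#' @export
#' @examples
#' background_mortality(57, default_parameter_set())  # 0.0065
background_mortality <- function(age, params) {
  band <- age_band_label(age, mortality_age_bands())
  q <- params$allcause_mort[[band]]
  if (isTRUE(params$options$subtract_lc_mortality) && age <= 74) {
    lc_band <- age_band_label(age, incidence_age_bands())
    q <- max(q - params$lc_mort_per_100k[[lc_band]] / 1e5, 0)
  }
  q
}

#' Annual transition row out of a cancer stage
#'
#' Destinations are the worse stages reachable in one year, death at the
#' stage-specific probability, and the stage's maintenance partner receiving
#' the complement.
#'
#' @param stage one of [cancer_stages()].
#' @param params an `lcs_params` object.
#' @return Named numeric vector of destination probabilities summing to 1.
#' @export
#' @examples
#' stage_transition_row("StageIV", default_parameter_set())
stage_transition_row <- function(stage, params) {
  if (!stage %in% cancer_stages()) stop("not a cancer stage: ", stage)
  pref <- paste0(stage, ".")
  out <- params$stage_prog[startsWith(names(params$stage_prog), pref)]
  dests <- sub(pref, "", names(out), fixed = TRUE)
  death <- params$stage_death[[stage]]
  comp <- 1 - sum(out) - death
  if (comp < -1e-9) {
    stop("stage ", stage, ": progression + death exceed 1 by ", -comp)
  }
  comp <- max(comp, 0)
  row <- c(stats::setNames(as.numeric(out), dests),
           Death = death)
  row[[maintenance_partner(stage)]] <- comp
  row
}

#' Assemble the full 12-state annual transition matrix
#'
#' @param age integer age, 50--79.
#' @param sex `"female"` or `"male"`.
#' @param strategy_context overlay context from [screening_context()] or
#'   [no_screening_context()]: which pack-year stratum applies, whether a
#'   screen happens at this age/cycle, and with which tool.
#' @param params an `lcs_params` object.
#' @return A 12 x 12 row-stochastic matrix (dimnames = [health_states()]).
#' @export
build_transition_matrix <- function(age, sex, strategy_context, params) {
  st <- health_states()
  n <- length(st)
  P <- matrix(0, n, n, dimnames = list(st, st))

  q_bg <- background_mortality(age, params)
  # incidence is banded to 50-74; beyond the banded range no new cancers
  # are generated (documented structural choice, affects all arms equally)
  p_inc <- if (age <= 74) {
    adjusted_incidence(age, sex, strategy_context$threshold, params)
  } else 0

  w <- entry_stage_weights(strategy_context, params)
  P["Normal", cancer_stages()] <- p_inc * w
  P["Normal", "Death"] <- q_bg
  P["Normal", "Normal"] <- 1 - p_inc - q_bg

  for (s in cancer_stages()) {
    row <- stage_transition_row(s, params)
    P[s, names(row)] <- row
  }

  rec <- params$options$recurrence_prob
  for (s in cancer_stages()) {
    m <- maintenance_partner(s)
    P[m, "Death"] <- q_bg
    if (rec > 0) P[m, s] <- rec
    P[m, m] <- 1 - q_bg - rec
  }
  P["Death", "Death"] <- 1

  bad <- abs(rowSums(P) - 1) > 1e-9
  if (any(bad)) {
    stop("transition matrix assembly error: rows not stochastic: ",
         paste(st[bad], collapse = ", "))
  }
  P
}

#' Dump a transition matrix to a plain-text table
#'
#' Audit export: one tab-separated file with fixed row/column order.
#'
#' @param P matrix from [build_transition_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transition_matrix <- function(P, path) {
  utils::write.table(cbind(state = rownames(P), as.data.frame(P)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
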