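# Screening strategies and the per-cycle screening overlay: who is tested,
# test-performance arithmetic, stage at detection, and screening-
# attributable costs.
#
# Conjunctive screening ("LDCT_MSC") applies the plasma micro-RNA signature
# classifier as a triage test to LDCT-positive nodules: the MSC assay cost
# is charged only to LDCT-positive screenees (computed from LDCT-alone
# operating characteristics), while final classification uses the joint
# sensitivity/specificity of the two-test sequence.

#' Catalog of the eight screening strategies
#'
#' Strategy 0 is the 2021 guideline arm (annual LDCT at 30 pack-years) used
#' as the comparator throughout; strategy 2 is the 2018 guideline arm
#' (annual LDCT at 20 pack-years).
#'
#' @return A data.frame with columns `id` (0--7), `tool` (`"LDCT"` or
#'   `"LDCT_MSC"`), `frequency` (`"annual"` or `"once"`), `pack_years`
#'   (20 or 30), `start_age`, `stop_age`.
#' @export
#' @examples
#' strategy_catalog()
strategy_catalog <- function() {
  data.frame(
    id = 0:7,
    tool = rep(c("LDCT", "LDCT_MSC"), each = 4),
    frequency = rep(c("annual", "once"), 4),
    pack_years = rep(rep(c(30L, 20L), each = 2), 2),
    start_age = 50L,
    stop_age = 74L,
    stringsAsFactors = FALSE
  )
}

#' Look up one strategy by id
#'
#' @param id integer 0--7.
#' @return One-row data.frame from [strategy_catalog()].
#' @export
get_strategy <- function(id) {
  cat <- strategy_catalog()
  i <- match(id, cat$id)
  if (is.na(i)) stop("no such strategy id: ", id)
  cat[i, , drop = FALSE]
}

# operating characteristics of a tool (joint values for the conjunctive arm)
tool_characteristics <- function(tool, params) {
  switch(tool,
         LDCT = list(sens = params$sens_ldct, spec = params$spec_ldct),
         LDCT_MSC = list(sens = params$sens_msc_conj,
                         spec = params$spec_msc_conj),
         stop("unknown screening tool: ", tool))
}

#' Classification fractions for one screened cycle
#'
#' Standard 2 x 2 test arithmetic at a given prevalence of (newly incident)
#' cancer among screenees.
#'
#' @param prevalence probability of cancer among the screened group.
#' @param tool `"LDCT"` or `"LDCT_MSC"`.
#' @param params an `lcs_params` object.
#' @return List with fields `tp`, `fn`, `fp`, `tn` summing to 1.
#' @export
#' @examples
#' screen_classification(0.01, "LDCT", default_parameter_set())
screen_classification <- function(prevalence, tool, params) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  oc <- tool_characteristics(tool, params)
  list(tp = prevalence * oc$sens,
       fn = prevalence * (1 - oc$sens),
       fp = (1 - prevalence) * (1 - oc$spec),
       tn = (1 - prevalence) * oc$spec)
}

#' Stage-at-detection distribution of a screening tool
#'
#' @inheritParams screen_classification
#' @return Named probability vector over [cancer_stages()], summing to 1.
#' @export
detected_stage_distribution <- function(tool, params) {
  v <- switch(tool,
              LDCT = params$detect_stage_ldct,
              LDCT_MSC = params$detect_stage_ldct_msc,
              stop("unknown screening tool: ", tool))
  if (abs(sum(v) - 1) > 1e-9 || any(v < 0)) {
    stop("stage-at-detection vector for ", tool, " is not a simplex")
  }
  v
}

#' Presentation-stage distribution of clinically detected cancers
#'
#' Cancers missed by screening (or arising in unscreened strata) present
#' clinically, at later stages than screen-detected ones. The default is a
#' package fixture -- the LDCT stage-at-detection vector shifted one stage
#' later -- because the original analysis never printed this distribution.
#'
#' @param params an `lcs_params` object.
#' @return Named probability vector over [cancer_stages()], summing to 1.
#' @export
clinical_stage_distribution <- function(params) {
  v <- params$clinical_stage_dist
  if (abs(sum(v) - 1) > 1e-9 || any(v < 0)) {
    stop("clinical_stage_dist is not a simplex (sums to ", sum(v), ")")
  }
  v
}

#' Probability of a positive LDCT read (first test of the sequence)
#' @inheritParams screen_classification
#' @export
ldct_positive_rate <- function(prevalence, params) {
  prevalence * params$sens_ldct + (1 - prevalence) * (1 - params$spec_ldct)
}

#' Expected screening cost per screened person for one cycle
#'
#' LDCT alone: the scan, plus prediagnostic workup for false positives,
#' plus prediagnosis + biopsy for true positives. Conjunctive arm adds the
#' MSC assay for every LDCT-positive screenee, with false/true positive
#' fractions computed from the joint operating characteristics. Whether
#' false positives also receive biopsy is a configurable lever
#' (`options$fp_workup`); the default is prediagnostic workup only.
#'
#' @inheritParams screen_classification
#' @return CNY per screened person.
#' @export
#' @examples
#' cycle_screening_cost(0.01, "LDCT", default_parameter_set())  # 378.75
cycle_screening_cost <- function(prevalence, tool, params) {
  cls <- screen_classification(prevalence, tool, params)
  fp_cost <- params$cost_prediag +
    if (identical(params$options$fp_workup, "prediag_biopsy"))
      params$cost_biopsy else 0
  cost <- params$cost_ldct +
    cls$fp * fp_cost +
    cls$tp * (params$cost_prediag + params$cost_biopsy)
  if (tool == "LDCT_MSC") {
    cost <- cost + ldct_positive_rate(prevalence, params) * params$cost_msc
  }
  cost
}

#' Is a strategy actively screening at this age and cycle?
#'
#' Annual strategies screen every cycle while age <= stop age; one-time
#' strategies screen at cycle 0 only. The stop age applies to testing only.
#'
#' @param strategy one-row data.frame from [get_strategy()], or `NULL` for
#'   the no-screening sentinel.
#' @param age current age.
#' @param cycle_index 0-based cycle counter.
#' @return Logical.
#' @export
screening_active <- function(strategy, age, cycle_index) {
  if (is.null(strategy)) return(FALSE)
  if (age > strategy$stop_age) return(FALSE)
  switch(strategy$frequency,
         annual = TRUE,
         once = cycle_index == 0L,
         stop("unknown frequency: ", strategy$frequency))
}

#' Overlay context consumed by the transition-matrix builder
#'
#' Bundles the smoking stratum (which sets the incidence relative risk) with
#' the screen happening this cycle, if any. `no_screening_context()` is the
#' unscreened, baseline-risk overlay.
#'
#' @param strategy one-row strategy data.frame.
#' @param active whether a screen happens this cycle.
#' @param threshold pack-year stratum: `"none"`, `20` or `30`.
#' @return A list with fields `threshold`, `active`, `tool`.
#' @export
screening_context <- function(strategy, active,
                              threshold = strategy$pack_years) {
  list(threshold = threshold, active = isTRUE(active),
       tool = if (is.null(strategy)) NULL else strategy$tool)
}

#' @rdname screening_context
#' @export
no_screening_context <- function(threshold = "none") {
  list(threshold = threshold, active = FALSE, tool = NULL)
}

# Stage-entry weights for this cycle's incident cancers: in a screening
# cycle, a fraction equal to the (joint) sensitivity is screen-detected and
# takes the tool's stage-at-detection vector; the complement -- and 100% in
# non-screening cycles -- presents clinically.
entry_stage_weights <- function(strategy_context, params) {
  clin <- clinical_stage_distribution(params)
  if (!isTRUE(strategy_context$active)) return(clin)
  oc <- tool_characteristics(strategy_context$tool, params)
  det <- detected_stage_distribution(strategy_context$tool, params)
  oc$sens * det + (1 - oc$sens) * clin
}

#' Screening overlay for one cycle of the cohort engine
#'
#' Splits this cycle's incident cancer mass from the `Normal` state between
#' the screen-detected pathway (stage-at-detection vector) and the clinical
#' pathway (presentation-stage vector), and prices the cycle: the screen
#' itself (all screened `Normal` occupants), false-positive workup,
#' diagnosis (prediagnosis + biopsy) at entry, and stage treatment at entry.
#' In a non-screening cycle all incident cancer presents clinically and only
#' diagnosis/treatment costs accrue.
#'
#' @param normal_occupancy fraction of the (sub)cohort in `Normal`.
#' @param age current age.
#' @param strategy one-row strategy data.frame, or `NULL` for no screening.
#' @param cycle_index 0-based cycle counter.
#' @param params an `lcs_params` object.
#' @param sex `"female"` or `"male"`.
#' @param threshold pack-year stratum of this subcohort.
#' @return List: `active`, `stage_entries` (absolute state mass entering
#'   each stage), `screening_cost`, `diagnosis_cost`, `treatment_cost`,
#'   `cost_total` (all per capita of the whole subcohort).
#' @export
apply_screening_overlay <- function(normal_occupancy, age, strategy,
                                    cycle_index, params, sex = "female",
                                    threshold = NULL) {
  if (is.null(threshold)) {
    threshold <- if (is.null(strategy)) "none" else strategy$pack_years
  }
  active <- !is.null(strategy) && screening_active(strategy, age, cycle_index)
  ctx <- list(threshold = threshold, active = active,
              tool = if (is.null(strategy)) NULL else strategy$tool)
  p_inc <- if (age <= 74) adjusted_incidence(age, sex, threshold, params) else 0
  w <- entry_stage_weights(ctx, params)
  entries <- normal_occupancy * p_inc * w

  screening_cost <- 0
  if (active) {
    # screen + MSC triage + false-positive workup (true-positive diagnosis
    # is charged through the entry flows below, once)
    oc <- tool_characteristics(strategy$tool, params)
    fp <- (1 - p_inc) * (1 - oc$spec)
    fp_cost <- params$cost_prediag +
      if (identical(params$options$fp_workup, "prediag_biopsy"))
        params$cost_biopsy else 0
    per_screenee <- params$cost_ldct + fp * fp_cost
    if (strategy$tool == "LDCT_MSC") {
      per_screenee <- per_screenee +
        ldct_positive_rate(p_inc, params) * params$cost_msc
    }
    screening_cost <- normal_occupancy * per_screenee
  }
  diagnosis_cost <- sum(entries) * (params$cost_prediag + params$cost_biopsy)
  treatment_cost <- sum(entries * params$cost_treat[names(entries)])
  list(active = active,
       stage_entries = entries,
       screening_cost = screening_cost,
       diagnosis_cost = diagnosis_cost,
       treatment_cost = treatment_cost,
       cost_total = screening_cost + diagnosis_cost + treatment_cost)
}
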