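# Cost-effectiveness analysis: pairwise ICERs with dominance labels,
# efficiency frontier with extended dominance, net monetary benefit, and
# acceptability curves from PSA draws.

# accept an lcs_outcome or a bare list/vector with cost and qaly
outcome_cq <- function(x) {
  if (inherits(x, "lcs_outcome")) {
    c(cost = x$population[["cost"]], qaly = x$population[["qaly"]])
  } else {
    c(cost = x[["cost"]], qaly = x[["qaly"]])
  }
}

#' Pairwise incremental cost-effectiveness ratio
#'
#' ICER = incremental cost / incremental QALYs of the intervention versus
#' the comparator. A strategy that is cheaper with more (or equal) QALYs is
#' `dominant`; costlier with fewer (or equal) QALYs is `dominated`; equal on
#' both axes is `comparator`. Negative ICERs are reported signed, as the
#' published table prints them, but flagged: the sign alone conflates the
#' dominant and dominated quadrants.
#'
#' @param intervention,comparator `lcs_outcome` objects (population scale)
#'   or lists with `cost` and `qaly` fields.
#' @return List: `delta_cost`, `delta_qaly`, `icer` (`NA` when undefined),
#'   `undefined` (no division when delta QALY is 0), `label`.
#' @export
#' @examples
#' pairwise_icer(list(cost = 1709.14e6, qaly = 81.37e4),
#'               list(cost = 1865.10e6, qaly = 80.97e4))
pairwise_icer <- function(intervention, comparator) {
  a <- outcome_cq(intervention)
  b <- outcome_cq(comparator)
  dc <- a[["cost"]] - b[["cost"]]
  dq <- a[["qaly"]] - b[["qaly"]]
  undefined <- dq == 0
  icer <- if (undefined) NA_real_ else dc / dq
  label <- if (dc == 0 && dq == 0) {
    "comparator"
  } else if (dc <= 0 && dq >= 0) {
    "dominant"
  } else if (dc >= 0 && dq <= 0) {
    "dominated"
  } else {
    "nondominated"
  }
  list(delta_cost = dc, delta_qaly = dq, icer = icer,
       undefined = undefined, label = label)
}

#' Efficiency frontier with extended dominance
#'
#' Sorts strategies by cost, removes strictly dominated points (another
#' strategy has no more cost and no fewer QALYs, with at least one strict
#' inequality; exact ties broken by lower strategy id), then iteratively
#' removes extended-dominated points (incremental ICER higher than that of
#' the next more effective strategy) until frontier ICERs strictly increase.
#'
#' @param rows data.frame with columns `id`, `cost`, `qaly`.
#' @return The input with a `label` column (`nondominated`, `dominated`,
#'   `extended_dominated`) and `frontier_icer` (incremental ICER along the
#'   frontier; `NA` off-frontier and for the cheapest frontier point).
#' @export
efficiency_frontier <- function(rows) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 2L,
            all(c("id", "cost", "qaly") %in% names(rows)))
  n <- nrow(rows)
  label <- rep("nondominated", n)

  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- rows$cost[j]; qj <- rows$qaly[j]
      ci <- rows$cost[i]; qi <- rows$qaly[i]
      if (cj <= ci && qj >= qi &&
          (cj < ci || qj > qi || rows$id[j] < rows$id[i])) {
        label[i] <- "dominated"
        break
      }
    }
  }

  repeat {
    keep <- which(label == "nondominated")
    ord <- keep[order(rows$cost[keep], rows$id[keep])]
    if (length(ord) < 3L) break
    icers <- diff(rows$cost[ord]) / diff(rows$qaly[ord])
    drop <- which(icers[-length(icers)] >= icers[-1L])
    if (!length(drop)) break
    label[ord[drop[1L] + 1L]] <- "extended_dominated"
  }

  rows$label <- label
  rows$frontier_icer <- NA_real_
  keep <- which(label == "nondominated")
  ord <- keep[order(rows$cost[keep], rows$id[keep])]
  if (length(ord) >= 2L) {
    rows$frontier_icer[ord[-1L]] <-
      diff(rows$cost[ord]) / diff(rows$qaly[ord])
  }
  rows
}

#' Net monetary benefit versus a comparator
#'
#' NMB = WTP x incremental QALYs - incremental cost.
#'
#' @inheritParams pairwise_icer
#' @param wtp willingness-to-pay threshold, CNY per QALY (>= 0).
#' @return NMB in CNY.
#' @export
net_monetary_benefit <- function(intervention, comparator, wtp) {
  stopifnot(wtp >= 0)
  a <- outcome_cq(intervention)
  b <- outcome_cq(comparator)
  wtp * (a[["qaly"]] - b[["qaly"]]) - (a[["cost"]] - b[["cost"]])
}

#' Default willingness-to-pay grid
#'
#' 0 to 250,000 CNY/QALY in 2,500-CNY steps, covering 1x to 3x per-capita
#' GDP (70,892 to 212,676 CNY).
#'
#' @return Numeric vector of thresholds.
#' @export
wtp_grid_default <- function() seq(0, 250000, by = 2500)

#' Cost-effectiveness acceptability curve
#'
#' For each threshold, the fraction of PSA draws in which the strategy is
#' cost-effective versus the comparator. The default counting rule is
#' NMB > 0, which subsumes ICER-below-threshold counting and handles
#' dominant draws (negative incremental cost) unambiguously; `mode =
#' "icer"` provides the literal signed-ICER-below-threshold count for
#' comparison.
#'
#' @param psa `lcs_psa` object from [run_psa()], or its `samples`
#'   data.frame (columns `iter`, `strategy_id`, `cost`, `qaly`).
#' @param strategy_id,comparator_id strategy ids present in the samples.
#' @param wtp_grid thresholds to evaluate.
#' @param mode `"nmb"` (default) or `"icer"`.
#' @return data.frame `wtp`, `prob`, with attribute `n_samples`.
#' @export
ceac <- function(psa, strategy_id, comparator_id,
                 wtp_grid = wtp_grid_default(), mode = c("nmb", "icer")) {
  mode <- match.arg(mode)
  samples <- if (inherits(psa, "lcs_psa")) psa$samples else psa
  stopifnot(length(wtp_grid) >= 1L)
  a <- samples[samples$strategy_id == strategy_id, ]
  b <- samples[samples$strategy_id == comparator_id, ]
  if (!nrow(a) || !nrow(b)) stop("no PSA samples for requested strategies")
  a <- a[order(a$iter), ]
  b <- b[order(b$iter), ]
  if (!identical(a$iter, b$iter)) stop("sample iterations do not align")
  dc <- a$cost - b$cost
  dq <- a$qaly - b$qaly
  prob <- vapply(wtp_grid, function(w) {
    if (mode == "nmb") {
      mean(w * dq - dc > 0)
    } else {
      icer <- ifelse(dq == 0, Inf, dc / dq)
      mean(icer < w)
    }
  }, numeric(1L))
  out <- data.frame(wtp = wtp_grid, prob = prob)
  attr(out, "n_samples") <- length(dc)
  out
}

#' Base-case CEA table versus a comparator
#'
#' One row per strategy in the published layout: population cost in CNY
#' millions, life-years and QALYs in 10,000s, signed ICER versus the
#' comparator, and the dominance label (the published table footnotes
#' dominant rows).
#'
#' @param outcomes list of `lcs_outcome` (one per strategy).
#' @param comparator_id id of the comparator strategy (default 0).
#' @return data.frame sorted by strategy id.
#' @export
cea_table <- function(outcomes, comparator_id = 0L) {
  ids <- vapply(outcomes, function(o) o$strategy_id, integer(1L))
  comp <- outcomes[[match(comparator_id, ids)]]
  if (is.null(comp)) stop("comparator not among outcomes: ", comparator_id)
  rows <- lapply(outcomes, function(o) {
    u <- as_table_units(o)
    pi <- pairwise_icer(o, comp)
    data.frame(strategy = o$strategy_id,
               cost_millions = u[["cost_millions"]],
               ly_10k = u[["ly_10k"]],
               qaly_10k = u[["qaly_10k"]],
               icer = if (o$strategy_id == comparator_id) NA_real_ else
                 pi$icer,
               label = if (o$strategy_id == comparator_id) "comparator" else
                 pi$label,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$strategy), ]
}
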