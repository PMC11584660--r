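#' Willingness-to-pay thresholds
#'
#' WHO-style thresholds expressed as multiples of GDP per capita: an
#' intervention costing less than 1x GDP per capita per QALY gained is
#' "highly cost-effective", less than 3x is "cost-effective". The
#' comparisons are strict ("costs less than"), so a ratio exactly at a
#' boundary falls into the next band up.
#'
#' @param gdp_per_capita annual GDP per capita, INR.
#' @param multiplier_highly multiplier for the highly-cost-effective band.
#' @param multiplier_ce multiplier for the cost-effective band.
#' @return A list of class `thresholds`.
#' @export
thresholds <- function(gdp_per_capita = 144000,
                       multiplier_highly = 1,
                       multiplier_ce = 3) {
  stopifnot(gdp_per_capita > 0, multiplier_highly > 0,
            multiplier_ce >= multiplier_highly)
  structure(list(gdp_per_capita = gdp_per_capita,
                 multiplier_highly = multiplier_highly,
                 multiplier_ce = multiplier_ce),
            class = "thresholds")
}

#' Total QALY gain of the programme
#'
#' Scales the per-person discounted lifetime gains by the treated counts.
#' The comparator (no screening programme) contributes zero cost and zero
#' QALYs under the assumption that, without screening, these patients would
#' have lost their sight. Components rounded to whole QALYs are also
#' returned for report parity; downstream ratios use the unrounded values.
#'
#' @param counts a [cascade_counts].
#' @param gain_stdr per-person QALY gain from laser treatment (>= 0).
#' @param gain_cataract per-person QALY gain from cataract surgery (>= 0).
#' @return Named list: `qalys_stdr`, `qalys_cataract`, `total` (unrounded),
#'   and `qalys_stdr_rounded`, `qalys_cataract_rounded`, `total_rounded`
#'   (component-wise integer rounding).
#' @examples
#' total_qalys(cascade_counts(), 0.65, 1.81)$total_rounded  # 514
#' @export
total_qalys <- function(counts, gain_stdr, gain_cataract) {
  stopifnot(inherits(counts, "cascade_counts"))
  if (gain_stdr < 0 || gain_cataract < 0) {
    stop("per-person QALY gains must be non-negative", call. = FALSE)
  }
  qs <- counts$n_stdr_treated * gain_stdr
  qc <- counts$n_cataract_treated * gain_cataract
  list(qalys_stdr = qs, qalys_cataract = qc, total = qs + qc,
       qalys_stdr_rounded = round(qs), qalys_cataract_rounded = round(qc),
       total_rounded = round(qs) + round(qc))
}

#' Incremental cost-effectiveness ratio
#'
#' @param total_cost incremental cost versus the comparator, INR.
#' @param total_qalys incremental QALYs versus the comparator.
#' @return INR per QALY at full precision; `NA` (with the
#'   `"indeterminate"` attribute set) when `total_qalys` is zero — the
#'   ratio is undefined, never a division crash.
#' @export
icer <- function(total_cost, total_qalys) {
  if (total_qalys == 0) {
    return(structure(NA_real_, indeterminate = TRUE))
  }
  total_cost / total_qalys
}

#' Classify an ICER against willingness-to-pay thresholds
#'
#' @param icer INR per QALY (>= 0, finite).
#' @param th a [thresholds].
#' @return One of `"highly cost-effective"`, `"cost-effective"`,
#'   `"not cost-effective"`; `NA` ICERs classify as `"indeterminate"`.
#' @examples
#' classify_icer(22000, thresholds())  # "highly cost-effective"
#' @export
classify_icer <- function(icer, th = thresholds()) {
  stopifnot(inherits(th, "thresholds"))
  vapply(icer, function(x) {
    if (is.na(x)) return("indeterminate")
    if (x < th$multiplier_highly * th$gdp_per_capita) "highly cost-effective"
    else if (x < th$multiplier_ce * th$gdp_per_capita) "cost-effective"
    else "not cost-effective"
  }, character(1L))
}

#' Net monetary benefit
#'
#' \eqn{NMB = wtp \times QALYs - cost}; positive exactly when the ICER lies
#' below the willingness to pay (for positive QALYs). The decision rule
#' behind the cost-effectiveness acceptability curve.
#'
#' @param wtp willingness to pay per QALY, INR (>= 0).
#' @param cost total cost, INR.
#' @param qalys total QALYs.
#' @return NMB in INR (vectorised over any argument).
#' @export
net_monetary_benefit <- function(wtp, cost, qalys) {
  if (any(wtp < 0)) stop("`wtp` must be non-negative", call. = FALSE)
  wtp * qalys - cost
}

#' Assemble the cost-effectiveness result
#'
#' Combines the programme cost ledger with the per-person QALY gains into
#' the headline result: total cost, total QALYs, the ICER and its
#' threshold classification.
#'
#' @param ledger a `cost_ledger` from [build_cost_ledger()].
#' @param gain_stdr,gain_cataract per-person discounted lifetime QALY gains.
#' @param th a [thresholds].
#' @return An object of class `cea_result`: list with `total_cost`,
#'   `qalys` (the [total_qalys()] list), `n_treated`, `avg_qaly_per_treated`,
#'   `icer`, `classification` and `thresholds`.
#' @export
cea_result <- function(ledger, gain_stdr, gain_cataract, th = thresholds()) {
  stopifnot(inherits(ledger, "cost_ledger"))
  counts <- attr(ledger, "counts")
  q <- total_qalys(counts, gain_stdr, gain_cataract)
  tot <- cost_totals(ledger)
  n_treated <- counts$n_stdr_treated + counts$n_cataract_treated
  ic <- icer(tot$programme_total, q$total)
  structure(list(
    total_cost = tot$programme_total,
    qalys = q,
    n_treated = n_treated,
    avg_qaly_per_treated = if (n_treated > 0) q$total / n_treated else NA_real_,
    icer = ic,
    classification = classify_icer(as.numeric(ic), th),
    thresholds = th,
    ledger = ledger
  ), class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("Cost-effectiveness result (comparator: no screening, zero cost and QALYs)\n")
  cat(sprintf("  total cost:  INR %s million\n",
              format(round(x$total_cost / 1e6, 1))))
  cat(sprintf("  total QALYs: %d (%d laser + %d cataract; unrounded %.2f)\n",
              x$qalys$total_rounded, x$qalys$qalys_stdr_rounded,
              x$qalys$qalys_cataract_rounded, x$qalys$total))
  cat(sprintf("  average QALY gain per person treated: %.3f (n = %d)\n",
              x$avg_qaly_per_treated, x$n_treated))
  if (is.na(x$icer)) {
    cat("  ICER: indeterminate (zero QALY gain)\n")
  } else {
    cat(sprintf("  ICER: INR %s per QALY -> %s (GDP per capita %s)\n",
                format(round(x$icer), big.mark = ","), x$classification,
                format(x$thresholds$gdp_per_capita, big.mark = ",")))
  }
  invisible(x)
}
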