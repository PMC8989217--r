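# Incremental cost-effectiveness analysis between two strategies.

#' Compare two strategies' expected outcomes
#'
#' Computes incremental cost and QALYs of `comparator` relative to
#' `reference`, classifies dominance before any ICER division, and evaluates
#' the net monetary benefit at the willingness-to-pay threshold.
#'
#' Verdicts: `dominant` (comparator gains QALYs at lower cost), `dominated`
#' (loses QALYs at higher cost), `indifferent` (both increments zero), or an
#' ICER verdict in the trade-off quadrants. In the north-east quadrant
#' (more effective, more costly) `icer_below_wtp` means the comparator is
#' cost-effective; in the south-west quadrant (less effective, cheaper) the
#' ICER is a saving per QALY forgone and `icer_above_wtp` favours the
#' comparator. No ICER is ever reported for dominant/dominated pairs.
#'
#' @param reference,comparator [cohort_outcome()] objects.
#' @param wtp Willingness-to-pay threshold, USD per QALY (> 0).
#' @return A list of class `ce_comparison`: `delta_cost`, `delta_qalys`,
#'   `icer` (NA when undefined), `verdict`, `nmb`, `wtp`, labels.
#' @export
#' @examples
#' p <- canonical_parameters()
#' sc <- expected_outcomes(p, strategy(TRUE, FALSE))
#' sc_tm <- expected_outcomes(p, strategy(TRUE, TRUE))
#' compare(sc, sc_tm)
compare <- function(reference, comparator, wtp = 46450) {
  stopifnot(inherits(reference, "cohort_outcome"),
            inherits(comparator, "cohort_outcome"), wtp > 0)
  delta_cost <- comparator$cost - reference$cost
  delta_qalys <- comparator$qalys - reference$qalys
  nmb <- wtp * delta_qalys - delta_cost

  icer <- NA_real_
  if (delta_qalys == 0 && delta_cost == 0) {
    verdict <- "indifferent"
  } else if (delta_qalys >= 0 && delta_cost <= 0) {
    verdict <- "dominant"
  } else if (delta_qalys <= 0 && delta_cost >= 0) {
    verdict <- "dominated"
  } else {
    icer <- delta_cost / delta_qalys
    verdict <- if (icer < wtp) "icer_below_wtp" else "icer_above_wtp"
  }

  structure(list(reference = reference$label, comparator = comparator$label,
                 delta_cost = delta_cost, delta_qalys = delta_qalys,
                 icer = icer, verdict = verdict, nmb = nmb, wtp = wtp),
            class = "ce_comparison")
}

#' Comparison table for strategy pairs
#'
#' @param params An `ibd_params` table.
#' @param pairs List of 2-element lists of [strategy()] objects
#'   (reference, comparator). Default: the two published analyses.
#' @param wtp Willingness-to-pay threshold (USD/QALY).
#' @return Data frame, one row per comparison.
#' @export
comparison_table <- function(params, pairs = NULL,
                             wtp = base_values(params)[["wtp"]]) {
  if (is.null(pairs)) {
    s <- default_strategies()
    pairs <- list(list(s$sc_prepandemic, s$sc), list(s$sc, s$sc_tm))
  }
  rows <- lapply(pairs, function(pr) {
    cmp <- compare(expected_outcomes(params, pr[[1]]),
                   expected_outcomes(params, pr[[2]]), wtp = wtp)
    data.frame(reference = cmp$reference, comparator = cmp$comparator,
               delta_cost = cmp$delta_cost, delta_qalys = cmp$delta_qalys,
               icer = cmp$icer, verdict = cmp$verdict, nmb = cmp$nmb,
               wtp = cmp$wtp, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' @export
print.ce_comparison <- function(x, ...) {
  cat(sprintf("Incremental analysis: %s vs %s (reference)\n", x$comparator,
              x$reference))
  cat(sprintf("  delta cost:  %+.1f USD/patient-year\n", x$delta_cost))
  cat(sprintf("  delta QALYs: %+.4f /patient-year\n", x$delta_qalys))
  if (is.na(x$icer)) cat("  ICER:        not reported (", x$verdict, ")\n",
                         sep = "")
  else cat(sprintf("  ICER:        %.0f USD/QALY (%s at WTP %.0f)\n", x$icer,
                   x$verdict, x$wtp))
  cat(sprintf("  NMB at WTP:  %+.1f USD/patient-year\n", x$nmb))
  invisible(x)
}
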