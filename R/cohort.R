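# Analytic cohort engine: expected outcomes of the one-year decision tree.
#
# Tree per disease (UC / CD): outpatient -> hospitalized? -> surgery? ->
# survive/die. Pandemic-related healthcare avoidance scales the
# hospitalization probability by a population-average relative risk and
# reduces outpatient-visit cost in the avoider subgroup; telemonitoring
# scales hospitalization down in the compliant subgroup, increases
# non-invasive imaging use, and adds the programme cost for every enrollee.

#' Define a care strategy
#'
#' @param avoidance Is pandemic-related healthcare avoidance present?
#' @param telemonitoring Is the weekly telemonitoring programme added?
#'   Telemonitoring is only evaluated during the pandemic, so it requires
#'   `avoidance = TRUE`.
#' @param label Human-readable label.
#' @return A list of class `ibd_strategy`.
#' @export
#' @examples
#' strategy(avoidance = TRUE, telemonitoring = TRUE, label = "SC-TM")
strategy <- function(avoidance = FALSE, telemonitoring = FALSE, label = NULL) {
  stopifnot(is.logical(avoidance), length(avoidance) == 1L,
            is.logical(telemonitoring), length(telemonitoring) == 1L)
  if (telemonitoring && !avoidance)
    stop("telemonitoring is modelled during the pandemic: it requires ",
         "avoidance = TRUE", call. = FALSE)
  if (is.null(label))
    label <- if (telemonitoring) "sc_tm"
             else if (avoidance) "sc"
             else "sc_prepandemic"
  structure(list(avoidance = avoidance, telemonitoring = telemonitoring,
                 label = label), class = "ibd_strategy")
}

#' The three strategies of the base-case analyses
#'
#' @return Named list: `sc_prepandemic` (standard care, no avoidance), `sc`
#'   (standard care with pandemic-related avoidance), `sc_tm` (standard care
#'   plus telemonitoring during the pandemic).
#' @export
default_strategies <- function() {
  list(sc_prepandemic = strategy(FALSE, FALSE, "sc_prepandemic"),
       sc = strategy(TRUE, FALSE, "sc"),
       sc_tm = strategy(TRUE, TRUE, "sc_tm"))
}

#' Population-average hospitalization multiplier from healthcare avoidance
#'
#' Avoiders experience the relative risk `rr_avoid` on hospitalization; the
#' rest of the cohort is unaffected, giving the population-average factor
#' `p_avoid * rr_avoid + (1 - p_avoid)`.
#'
#' @param p_avoid Proportion of patients avoiding routine care, in `[0, 1]`.
#' @param rr_avoid Relative risk of hospitalization among avoiders, `> 0`.
#' @return Positive multiplier applied to each disease-specific
#'   hospitalization probability.
#' @export
#' @examples
#' hospitalization_multiplier(0.261, 1.156)
hospitalization_multiplier <- function(p_avoid, rr_avoid) {
  stopifnot(p_avoid >= 0, p_avoid <= 1, rr_avoid > 0)
  p_avoid * rr_avoid + (1 - p_avoid)
}

#' Population-average hospitalization multiplier from telemonitoring
#'
#' Only patients meeting the weekly self-assessment compliance requirement
#' receive the programme's clinical effect `rr_tm`, giving
#' `p_comply * rr_tm + (1 - p_comply)`. Applied multiplicatively on top of
#' the avoidance multiplier.
#'
#' @param p_comply Proportion meeting the compliance requirement, in `[0, 1]`.
#' @param rr_tm Relative risk of hospitalization under telemonitoring, `> 0`.
#' @return Positive multiplier.
#' @export
#' @examples
#' telemonitoring_multiplier(0.59, 0.364)
telemonitoring_multiplier <- function(p_comply, rr_tm) {
  stopifnot(p_comply >= 0, p_comply <= 1, rr_tm > 0)
  p_comply * rr_tm + (1 - p_comply)
}

#' Annual telemonitoring programme cost per patient
#'
#' Annual maintenance fee plus the staff cost of the excess
#' electronic/telephone encounters the programme mediates:
#' `maintenance + encounters * hours * wage`.
#'
#' @param maintenance Annual maintenance fee (USD/year).
#' @param encounters Excess encounters per patient-year.
#' @param hours Length of each encounter (hours).
#' @param wage Specialist staff cost (USD/hour).
#' @return Cost in USD per patient-year.
#' @export
#' @examples
#' tm_program_cost(50, 4.76, 0.25, 101) # ~170
tm_program_cost <- function(maintenance, encounters, hours, wage) {
  stopifnot(maintenance >= 0, encounters >= 0, hours >= 0, wage >= 0)
  maintenance + encounters * hours * wage
}

#' Construct a cohort outcome record
#'
#' @param hosp_per100py Hospitalizations per 100 patient-years.
#' @param mort_per100py Deaths per 100 patient-years.
#' @param cost Expected direct cost, USD per patient-year.
#' @param qalys Expected QALYs per patient-year.
#' @param label Strategy label.
#' @return A list of class `cohort_outcome`.
#' @export
cohort_outcome <- function(hosp_per100py, mort_per100py, cost, qalys,
                           label = "") {
  if (!(mort_per100py >= 0 && mort_per100py <= hosp_per100py &&
        hosp_per100py <= 100))
    stop("invalid outcome: need 0 <= mortality <= hospitalization <= 100 ",
         "per 100 patient-years", call. = FALSE)
  if (cost < 0) stop("invalid outcome: cost < 0", call. = FALSE)
  if (qalys < 0 || qalys > 1)
    stop("invalid outcome: QALYs outside [0, 1] for a one-year horizon",
         call. = FALSE)
  structure(list(hosp_per100py = hosp_per100py,
                 mort_per100py = mort_per100py,
                 cost = cost, qalys = qalys, label = label),
            class = "cohort_outcome")
}

# Core per-disease branch evaluation on a named value vector. Returns the
# unclassed numeric fields (hosp/mort as probabilities). This is the single
# arithmetic path shared by the public API, the DSA and the PSA.
.branch_fields <- function(d, hosp_factor, v, avoidance, telemonitoring) {
  h <- v[[paste0("h_", d)]] * hosp_factor
  if (h > 1)
    stop("effective hospitalization probability exceeds 1 for ", d,
         call. = FALSE)
  s <- v[[paste0("s_", d)]]
  m <- v[[paste0("m_", d)]]

  # decedents accrue zero QALYs; survivors their state utility for the year
  qalys <- (1 - h) * v[["u_out"]] +
    h * (1 - s) * (1 - m) * v[["u_hosp"]] +
    h * s * (1 - m) * v[["u_surg"]]

  visit_scale <- if (avoidance) 1 - v[["p_avoid"]] * v[["visit_reduction"]] else 1
  imaging_scale <- if (telemonitoring)
    1 + v[["p_comply"]] * (v[["rr_imaging_tm"]] - 1) else 1
  tm_cost <- if (telemonitoring)
    tm_program_cost(v[["tm_maintenance"]], v[["tm_encounters"]],
                    v[["tm_encounter_hours"]], v[["tm_wage"]]) else 0

  # visits, medications and non-invasive imaging accrue to all patients;
  # endoscopy, ward, surgery and terminal-care costs only with admission
  cost <- v[[paste0("cost_visit_", d)]] * visit_scale +
    v[[paste0("cost_meds_", d)]] +
    v[[paste0("cost_imaging_", d)]] * imaging_scale +
    h * (v[[paste0("cost_endoscopy_", d)]] + v[[paste0("cost_hosp_", d)]] +
           s * v[[paste0("cost_surgery_", d)]] +
           m * v[[paste0("cost_death_", d)]]) +
    tm_cost
  c(hosp = h, mort = h * m, cost = cost, qalys = qalys)
}

.strategy_factor <- function(v, strat) {
  f <- 1
  if (strat$avoidance)
    f <- f * hospitalization_multiplier(v[["p_avoid"]], v[["rr_avoid"]])
  if (strat$telemonitoring)
    f <- f * telemonitoring_multiplier(v[["p_comply"]], v[["rr_tm"]])
  f
}

# Disease-mix-weighted expected outcomes on a named value vector.
.outcomes <- function(v, strat) {
  f <- .strategy_factor(v, strat)
  uc <- .branch_fields("uc", f, v, strat$avoidance, strat$telemonitoring)
  cd <- .branch_fields("cd", f, v, strat$avoidance, strat$telemonitoring)
  w <- v[["p_uc"]]
  w * uc + (1 - w) * cd
}

#' Expected outcomes of one decision-tree branch (single disease)
#'
#' Evaluates the hospitalization/surgery/death cascade and the cost assembly
#' for one disease type at a given hospitalization multiplier.
#'
#' @param disease `"uc"` or `"cd"`.
#' @param hosp_factor Multiplier already applied to the disease's
#'   hospitalization probability (product of avoidance and telemonitoring
#'   multipliers for the strategy).
#' @param params An `ibd_params` table or named value vector.
#' @param strat An [strategy()] (controls which cost adjustments apply).
#' @return A [cohort_outcome()].
#' @export
disease_branch_outcome <- function(disease = c("uc", "cd"), hosp_factor,
                                   params, strat) {
  disease <- match.arg(disease)
  stopifnot(hosp_factor > 0, inherits(strat, "ibd_strategy"))
  v <- if (inherits(params, "ibd_params")) base_values(params) else params
  x <- .branch_fields(disease, hosp_factor, v, strat$avoidance,
                      strat$telemonitoring)
  cohort_outcome(100 * x[["hosp"]], 100 * x[["mort"]], x[["cost"]],
                 x[["qalys"]], label = paste(strat$label, disease, sep = ":"))
}

#' Expected cohort outcomes for one strategy
#'
#' Disease-mix-weighted expectation of the per-disease branches, with the
#' strategy's hospitalization multipliers applied.
#'
#' @param params An `ibd_params` table.
#' @param strat An [strategy()].
#' @param values Optional named value vector overriding the base-case values
#'   (used by the sensitivity analyses).
#' @return A [cohort_outcome()] with rates per 100 patient-years.
#' @export
#' @examples
#' p <- canonical_parameters()
#' expected_outcomes(p, strategy(FALSE, FALSE)) # pre-pandemic standard care
expected_outcomes <- function(params, strat, values = NULL) {
  stopifnot(inherits(strat, "ibd_strategy"))
  v <- if (!is.null(values)) values else base_values(params)
  x <- .outcomes(v, strat)
  cohort_outcome(100 * x[["hosp"]], 100 * x[["mort"]], x[["cost"]],
                 x[["qalys"]], label = strat$label)
}

#' Outcome table for several strategies
#'
#' @param params An `ibd_params` table.
#' @param strategies List of [strategy()] objects.
#' @return Data frame, one row per strategy, with full-precision outcome
#'   columns and display-rounded companions (rates to 2 dp, cost to whole
#'   USD, QALYs to 4 dp).
#' @export
outcomes_table <- function(params, strategies = default_strategies()) {
  rows <- lapply(strategies, function(s) {
    o <- expected_outcomes(params, s)
    data.frame(strategy = s$label, hosp_per100py = o$hosp_per100py,
               mort_per100py = o$mort_per100py, cost = o$cost,
               qalys = o$qalys, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$hosp_display <- round(out$hosp_per100py, 2)
  out$mort_display <- round(out$mort_per100py, 2)
  out$cost_display <- round(out$cost)
  out$qalys_display <- round(out$qalys, 4)
  out
}

#' @export
print.cohort_outcome <- function(x, ...) {
  cat(sprintf(paste0("Cohort outcome%s\n",
                     "  hospitalization: %.2f /100 patient-years\n",
                     "  mortality:       %.2f /100 patient-years\n",
                     "  cost:            %.0f USD/patient-year\n",
                     "  QALYs:           %.4f /patient-year\n"),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$hosp_per100py, x$mort_per100py, x$cost, x$qalys))
  invisible(x)
}

#' @export
print.ibd_strategy <- function(x, ...) {
  cat(sprintf("Strategy '%s': avoidance=%s, telemonitoring=%s\n", x$label,
              x$avoidance, x$telemonitoring))
  invisible(x)
}
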