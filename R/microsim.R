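# Patient-level microsimulation oracle: draws individual Bernoulli
# trajectories through the decision tree and aggregates them. Used to
# cross-validate the analytic cohort engine (same cost-assembly rules,
# applied per patient) by Monte Carlo convergence.

#' Simulate individual patient trajectories
#'
#' Each patient is assigned a disease type, avoidance and compliance flags,
#' then hospitalization, surgery and death by independent coin flips. The
#' per-patient hospitalization probability is the disease base probability
#' scaled by the relative risks of the flags actually drawn for that patient
#' (an error is raised if it exceeds 1). Cost and QALY accrual follow the
#' cohort engine's assembly rules exactly: avoiders get the visit-cost
#' reduction, compliant patients the imaging increase, every telemonitoring
#' enrollee the programme cost, decedents zero QALYs.
#'
#' @param params An `ibd_params` table.
#' @param strat An [strategy()].
#' @param n_patients Number of simulated patients (>= 1).
#' @param seed Integer seed; identical seed gives identical records. `NULL`
#'   uses the current RNG state.
#' @return A list of class `ibd_microsim`: `records` (one row per patient:
#'   disease, avoider, compliant, hospitalized, surgical, died, cost, qalys)
#'   and `aggregate` (a [cohort_outcome()] of the per-patient means).
#' @export
#' @examples
#' p <- canonical_parameters()
#' sim <- simulate_cohort(p, strategy(TRUE, TRUE), 5000, seed = 7)
#' sim$aggregate
simulate_cohort <- function(params, strat, n_patients, seed = NULL) {
  stopifnot(inherits(strat, "ibd_strategy"), n_patients >= 1)
  v <- base_values(params)
  n <- as.integer(n_patients)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }

  # draw order: disease, avoider, compliant, hospitalization, surgery, death
  is_uc <- rbinom(n, 1L, v[["p_uc"]]) == 1L
  avoider <- if (strat$avoidance) rbinom(n, 1L, v[["p_avoid"]]) == 1L
             else rep(FALSE, n)
  compliant <- if (strat$telemonitoring) rbinom(n, 1L, v[["p_comply"]]) == 1L
               else rep(FALSE, n)

  pick <- function(nm) ifelse(is_uc, v[[paste0(nm, "_uc")]],
                              v[[paste0(nm, "_cd")]])
  factor <- ifelse(avoider, v[["rr_avoid"]], 1) *
    ifelse(compliant, v[["rr_tm"]], 1)
  p_hosp <- pick("h") * factor
  if (any(p_hosp > 1))
    stop("per-patient effective hospitalization probability exceeds 1",
         call. = FALSE)
  hospitalized <- rbinom(n, 1L, p_hosp) == 1L
  surgical <- hospitalized & (runif(n) < pick("s"))
  died <- hospitalized & (runif(n) < pick("m"))

  qalys <- ifelse(died, 0,
                  ifelse(surgical, v[["u_surg"]],
                         ifelse(hospitalized, v[["u_hosp"]], v[["u_out"]])))

  tm_cost <- if (strat$telemonitoring)
    tm_program_cost(v[["tm_maintenance"]], v[["tm_encounters"]],
                    v[["tm_encounter_hours"]], v[["tm_wage"]]) else 0
  cost <- pick("cost_visit") *
    (1 - ifelse(avoider, v[["visit_reduction"]], 0)) +
    pick("cost_meds") +
    pick("cost_imaging") *
    ifelse(compliant, v[["rr_imaging_tm"]], 1) +
    hospitalized * (pick("cost_endoscopy") + pick("cost_hosp")) +
    surgical * pick("cost_surgery") +
    died * pick("cost_death") +
    tm_cost

  records <- data.frame(
    disease = ifelse(is_uc, "uc", "cd"), avoider = avoider,
    compliant = compliant, hospitalized = hospitalized, surgical = surgical,
    died = died, cost = cost, qalys = qalys, stringsAsFactors = FALSE)
  aggregate <- cohort_outcome(100 * mean(hospitalized), 100 * mean(died),
                              mean(cost), mean(qalys),
                              label = paste0(strat$label, " (microsim)"))
  structure(list(records = records, aggregate = aggregate,
                 n_patients = n, seed = seed, strategy = strat$label),
            class = "ibd_microsim")
}

#' Write the canonical and perturbed parameter fixtures
#'
#' Emits the bundled base-case parameter file plus one variant per non-point
#' parameter per range end (the parameter's base moved to its low or high,
#' everything else unchanged), for use by test harnesses and external tools.
#'
#' @param params An `ibd_params` table.
#' @param dir Destination directory (created if absent).
#' @return Character vector of file paths, invisibly.
#' @export
write_fixture <- function(params, dir) {
  stopifnot(inherits(params, "ibd_params"))
  if (nrow(params) == 0) stop("empty parameter set", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "ibd_model_inputs.csv")
  write_parameters(params, paths)
  varying <- params$name[params$low < params$high]
  for (nm in varying) {
    for (end in c("low", "high")) {
      pert <- as.data.frame(params)
      i <- match(nm, pert$name)
      pert$base[i] <- pert[[end]][i]
      path <- file.path(dir, sprintf("perturbed_%s_%s.csv", nm, end))
      write_parameters(model_parameters(pert), path)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' @export
print.ibd_microsim <- function(x, ...) {
  cat(sprintf("Microsimulation: %d patients, strategy '%s'%s\n", x$n_patients,
              x$strategy,
              ifelse(is.null(x$seed), "", sprintf(" (seed %d)", x$seed))))
  print(x$aggregate)
  invisible(x)
}
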