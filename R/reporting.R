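# Run configuration and report generation: delimited-text exports of the
# base-case table, the one-way sensitivity analyses, the PSA and the
# microsimulation cross-validation. Every file carries a comment header with
# the package version, seed and config echo, and contains no timestamps so
# that identical config + seed regenerates files bit-identically.

#' Build and validate a run configuration
#'
#' @param analysis One of `"basecase"`, `"dsa"`, `"psa"`, `"microsim"`.
#' @param params_file Path to a parameter file; `NULL` uses the bundled
#'   base-case table.
#' @param out_dir Output directory (created if absent).
#' @param strategies Character vector of strategy labels among
#'   `"sc_prepandemic"`, `"sc"`, `"sc_tm"`.
#' @param n_draws Monte Carlo draws (PSA) or patients (microsim).
#' @param seed Integer seed (required for `psa` and `microsim`).
#' @param wtp Willingness-to-pay (USD/QALY); `NULL` uses the parameter
#'   table's value.
#' @return A list of class `run_config`.
#' @export
run_config <- function(analysis = c("basecase", "dsa", "psa", "microsim"),
                       params_file = NULL, out_dir = ".",
                       strategies = c("sc", "sc_tm"), n_draws = 10000,
                       seed = 12345, wtp = NULL) {
  analysis <- match.arg(analysis)
  known <- names(default_strategies())
  bad <- setdiff(strategies, known)
  if (length(bad))
    stop("unknown strategies: ", paste(bad, collapse = ", "),
         "; choose among ", paste(known, collapse = ", "), call. = FALSE)
  if (analysis %in% c("psa", "microsim")) {
    if (is.null(seed) || is.null(n_draws) || n_draws < 1)
      stop(analysis, " requires n_draws >= 1 and a seed", call. = FALSE)
  }
  params <- if (is.null(params_file)) canonical_parameters()
            else load_parameters(params_file)
  if (is.null(wtp)) wtp <- base_values(params)[["wtp"]]
  structure(list(analysis = analysis, params_file = params_file,
                 params = params, out_dir = out_dir, strategies = strategies,
                 n_draws = n_draws, seed = seed, wtp = wtp),
            class = "run_config")
}

.config_header <- function(config) {
  c(sprintf("# ibdcea %s", as.character(packageVersion("ibdcea"))),
    sprintf("# analysis: %s", config$analysis),
    sprintf("# params: %s",
            ifelse(is.null(config$params_file), "<bundled>",
                   config$params_file)),
    sprintf("# strategies: %s", paste(config$strategies, collapse = ",")),
    sprintf("# seed: %s", ifelse(is.null(config$seed), "none", config$seed)),
    sprintf("# n_draws: %s", config$n_draws),
    sprintf("# wtp: %s", config$wtp))
}

.write_report <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.csv(df, con, row.names = FALSE)
  path
}

.config_strategies <- function(config) {
  default_strategies()[config$strategies]
}

#' Base-case report
#'
#' Writes the expected outcomes of the configured strategies (full precision
#' plus display-rounded columns) and the pairwise incremental analyses
#' between consecutive strategies.
#'
#' @param config A [run_config()].
#' @return Named character vector of written file paths, invisibly.
#' @export
run_basecase <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  strat <- .config_strategies(config)
  hdr <- .config_header(config)
  tab <- outcomes_table(config$params, strat)
  pairs <- if (length(strat) >= 2)
    lapply(seq_len(length(strat) - 1), function(i) list(strat[[i]],
                                                        strat[[i + 1]]))
  else list()
  cmp <- if (length(pairs)) comparison_table(config$params, pairs,
                                             wtp = config$wtp)
  f1 <- .write_report(tab, file.path(config$out_dir, "basecase_results.csv"),
                      hdr)
  files <- c(outcomes = f1)
  if (!is.null(cmp))
    files <- c(files, comparisons = .write_report(
      cmp, file.path(config$out_dir, "basecase_comparisons.csv"), hdr))
  invisible(files)
}

#' One-way sensitivity analysis report
#'
#' Sweeps every non-point parameter over its published range for the
#' configured strategy pair, writes one sweep file per parameter, a
#' threshold table (zero crossings of incremental cost and QALYs, searched
#' over the published range and, when no crossing lies inside it, over an
#' extended interval), and an NMB tornado ranking.
#'
#' @param config A [run_config()] with two strategies.
#' @return Named character vector of file paths, invisibly.
#' @export
run_dsa <- function(config) {
  stopifnot(inherits(config, "run_config"))
  strat <- .config_strategies(config)
  if (length(strat) != 2) stop("dsa needs exactly two strategies",
                               call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- .config_header(config)
  params <- config$params
  pair <- list(strat[[1]], strat[[2]])
  varying <- params$name[params$low < params$high]

  files <- character()
  thr_rows <- list()
  for (nm in varying) {
    sw <- sweep_parameter(params, nm, pair, wtp = config$wtp)
    df <- data.frame(value = sw$grid, delta_cost = sw$delta_cost,
                     delta_qalys = sw$delta_qalys, nmb = sw$nmb)
    files[paste0("sweep_", nm)] <- .write_report(
      df, file.path(config$out_dir, sprintf("sweep_%s.csv", nm)), hdr)
    for (q in c("delta_cost", "delta_qalys")) {
      est <- param_estimate(params, nm)
      root <- find_threshold(params, nm, q, pair,
                             interval = c(est$low, est$high),
                             wtp = config$wtp)
      extended <- FALSE
      if (is.null(root)) {
        ext <- .extended_interval(params, nm)
        if (!is.null(ext))
          ext <- .shrink_to_valid(params, nm, ext, pair, config$wtp)
        if (!is.null(ext)) {
          root <- find_threshold(params, nm, q, pair, interval = ext,
                                 wtp = config$wtp)
          extended <- !is.null(root)
        }
      }
      thr_rows[[length(thr_rows) + 1L]] <- data.frame(
        parameter = nm, quantity = q,
        threshold = ifelse(is.null(root), NA_real_, root),
        extended_search = extended, stringsAsFactors = FALSE)
    }
  }
  thr <- do.call(rbind, c(thr_rows, list(make.row.names = FALSE)))
  files["thresholds"] <- .write_report(
    thr, file.path(config$out_dir, "thresholds.csv"), hdr)
  files["tornado"] <- .write_report(
    tornado(params, pair, "nmb", wtp = config$wtp),
    file.path(config$out_dir, "tornado.csv"), hdr)
  invisible(files)
}

# Extended search interval for thresholds outside the published range:
# probabilities/proportions/utilities extend to [0, 1], relative risks and
# positive quantities to a wide positive span around base.
.extended_interval <- function(params, nm) {
  reg <- .param_registry()
  kind <- reg$kind[match(nm, reg$name)]
  est <- param_estimate(params, nm)
  eps <- 1e-9
  switch(kind,
         probability = ,
         utility = c(eps, 1 - eps),
         rate_ratio = c(est$base / 10, est$base * 10),
         cost = ,
         count = c(0, est$base * 20 + 1),
         NULL)
}

# Shrink an extended search interval's ends toward the base value until the
# model is evaluable there (large relative risks can push an effective
# probability past 1, which the engine rejects).
.shrink_to_valid <- function(params, nm, interval, pair, wtp) {
  base <- param_estimate(params, nm)$base
  ok <- function(x) !inherits(tryCatch(.incremental_at(params, nm, x, pair,
                                                       wtp),
                                       error = function(e) e), "error")
  lo <- interval[1]; hi <- interval[2]
  for (i in 1:60) if (ok(hi)) break else hi <- (hi + base) / 2
  for (i in 1:60) if (ok(lo)) break else lo <- (lo + base) / 2
  if (!ok(lo) || !ok(hi) || lo >= hi) return(NULL)
  c(lo, hi)
}

#' Probabilistic sensitivity analysis report
#'
#' Runs [run_psa()] with the configured draws and seed, writes a per-draw
#' cost-effectiveness plane file per comparison and a summary table.
#'
#' @param config A [run_config()].
#' @return Named character vector of file paths, invisibly.
#' @export
run_psa_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- .config_header(config)
  strat <- .config_strategies(config)
  res <- run_psa(config$params, strat, n_draws = config$n_draws,
                 seed = config$seed, wtp = config$wtp)
  files <- character()
  sum_rows <- list()
  for (nm in names(res$comparisons)) {
    files[paste0("ce_plane_", nm)] <- .write_report(
      ce_plane_export(res, nm),
      file.path(config$out_dir, sprintf("ce_plane_%s.csv", nm)), hdr)
    s <- res$comparisons[[nm]]$summary
    sum_rows[[nm]] <- data.frame(
      comparison = nm, mean_delta_cost = s$mean_delta_cost,
      sd_delta_cost = s$sd_delta_cost,
      ci_delta_cost_lo = s$ci_delta_cost[1],
      ci_delta_cost_hi = s$ci_delta_cost[2],
      mean_delta_qalys = s$mean_delta_qalys,
      sd_delta_qalys = s$sd_delta_qalys,
      ci_delta_qalys_lo = s$ci_delta_qalys[1],
      ci_delta_qalys_hi = s$ci_delta_qalys[2],
      prop_dominant = s$quadrants[["more_effective_cheaper"]],
      prop_cost_effective = s$prop_cost_effective,
      prop_qaly_loss = s$prop_qaly_loss, prop_costlier = s$prop_costlier,
      rejected = res$rejected, stringsAsFactors = FALSE)
  }
  files["summary"] <- .write_report(
    do.call(rbind, c(sum_rows, list(make.row.names = FALSE))),
    file.path(config$out_dir, "psa_summary.csv"), hdr)
  invisible(files)
}

#' Microsimulation cross-validation report
#'
#' Simulates `n_draws` patients per configured strategy and tabulates the
#' simulated versus analytic value of each outcome field with the Monte
#' Carlo standard error and z-score.
#'
#' @param config A [run_config()].
#' @return Named character vector of file paths, invisibly.
#' @export
run_microsim <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- .config_header(config)
  strat <- .config_strategies(config)
  rows <- list()
  for (i in seq_along(strat)) {
    s <- strat[[i]]
    sim <- simulate_cohort(config$params, s, config$n_draws,
                           seed = config$seed + i - 1L)
    ana <- expected_outcomes(config$params, s)
    r <- sim$records
    n <- nrow(r)
    fields <- list(
      hosp_per100py = list(sim = 100 * mean(r$hospitalized),
                           se = 100 * stats::sd(r$hospitalized) / sqrt(n),
                           ana = ana$hosp_per100py),
      mort_per100py = list(sim = 100 * mean(r$died),
                           se = 100 * stats::sd(r$died) / sqrt(n),
                           ana = ana$mort_per100py),
      cost = list(sim = mean(r$cost), se = stats::sd(r$cost) / sqrt(n),
                  ana = ana$cost),
      qalys = list(sim = mean(r$qalys), se = stats::sd(r$qalys) / sqrt(n),
                   ana = ana$qalys))
    for (f in names(fields)) {
      x <- fields[[f]]
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = s$label, field = f, simulated = x$sim, analytic = x$ana,
        se = x$se, z = (x$sim - x$ana) / x$se, stringsAsFactors = FALSE)
    }
  }
  path <- .write_report(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                        file.path(config$out_dir, "microsim_comparison.csv"),
                        hdr)
  invisible(c(microsim = path))
}
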