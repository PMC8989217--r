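# Probabilistic sensitivity analysis: distribution fitting from base value
# and sensitivity range, seeded Monte Carlo, CE-plane summaries.
#
# Parameterization convention: each published low/high range is read as a
# 95% interval, so sd = (high - low)/3.92. Beta and Gamma are fitted by
# method of moments to (mean = base, sd); Normal directly; Lognormal is
# anchored at natural-scale median = base with log-scale
# sd = (ln high - ln low)/3.92. Zero-width ranges degenerate to point
# masses.

#' Fit a sampling distribution to one parameter estimate
#'
#' @param estimate A [parameter_estimate()].
#' @return A list of class `psa_dist`: `parameter`, `family`, `pars`
#'   (family-specific), `support`.
#' @export
#' @examples
#' fit_distribution(parameter_estimate("tm_encounters", 4.76, 4.046, 5.474,
#'                                     "normal"))
fit_distribution <- function(estimate) {
  stopifnot(inherits(estimate, "parameter_estimate"))
  name <- estimate$name
  m <- estimate$base
  sd <- (estimate$high - estimate$low) / 3.92
  family <- estimate$family
  if (sd == 0 || family == "point") {
    family <- "point"
    pars <- list(value = m)
    support <- c(m, m)
  } else if (family == "beta") {
    v <- sd^2
    if (v >= m * (1 - m))
      stop("beta moment fit infeasible for '", name,
           "': sd^2 >= mean*(1-mean)", call. = FALSE)
    k <- m * (1 - m) / v - 1
    pars <- list(shape1 = m * k, shape2 = (1 - m) * k)
    support <- c(0, 1)
  } else if (family == "gamma") {
    v <- sd^2
    pars <- list(shape = m^2 / v, rate = m / v)
    support <- c(0, Inf)
  } else if (family == "normal") {
    pars <- list(mean = m, sd = sd)
    support <- c(-Inf, Inf)
  } else if (family == "lognormal") {
    pars <- list(meanlog = log(m),
                 sdlog = (log(estimate$high) - log(estimate$low)) / 3.92)
    support <- c(0, Inf)
  } else stop("unknown family: ", family, call. = FALSE)
  structure(list(parameter = name, family = family, pars = pars,
                 support = support), class = "psa_dist")
}

#' Draw from a fitted parameter distribution
#'
#' @param dist A `psa_dist` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(dist, n) {
  stopifnot(inherits(dist, "psa_dist"), n >= 0)
  p <- dist$pars
  switch(dist$family,
         point = rep(p$value, n),
         beta = rbeta(n, p$shape1, p$shape2),
         gamma = rgamma(n, shape = p$shape, rate = p$rate),
         normal = rnorm(n, p$mean, p$sd),
         lognormal = rlnorm(n, p$meanlog, p$sdlog))
}

# Sample an n x k matrix of parameter values, column by column in canonical
# table order (the fixed, documented draw order); point parameters are held
# at base. Rows whose effective hospitalization probability exceeds 1 for
# any requested strategy are rejected and redrawn.
.sample_draws <- function(params, fits, n, strategies) {
  k <- nrow(params)
  draws <- matrix(0, n, k, dimnames = list(NULL, params$name))
  for (j in seq_len(k)) draws[, j] <- sample_distribution(fits[[j]], n)
  rejected <- 0L
  for (round in seq_len(100L)) {
    bad <- .invalid_rows(draws, strategies)
    if (!any(bad)) break
    rejected <- rejected + sum(bad)
    for (j in seq_len(k))
      draws[bad, j] <- sample_distribution(fits[[j]], sum(bad))
  }
  if (any(.invalid_rows(draws, strategies)))
    stop("rejection resampling failed to produce valid parameter draws",
         call. = FALSE)
  attr(draws, "rejected") <- rejected
  draws
}

.invalid_rows <- function(draws, strategies) {
  fmax <- rep(1, nrow(draws))
  for (s in strategies) {
    f <- rep(1, nrow(draws))
    if (s$avoidance)
      f <- f * (draws[, "p_avoid"] * draws[, "rr_avoid"] +
                  (1 - draws[, "p_avoid"]))
    if (s$telemonitoring)
      f <- f * (draws[, "p_comply"] * draws[, "rr_tm"] +
                  (1 - draws[, "p_comply"]))
    fmax <- pmax(fmax, f)
  }
  (draws[, "h_uc"] * fmax > 1) | (draws[, "h_cd"] * fmax > 1) |
    (draws[, "h_uc"] < 0) | (draws[, "h_cd"] < 0)
}

.summarize_comparison <- function(dc, dq, wtp) {
  n <- length(dc)
  ci <- function(x) mean(x) + c(-1, 1) * 1.96 * stats::sd(x) / sqrt(n)
  nmb <- wtp * dq - dc
  quadrants <- c(
    more_effective_cheaper = mean(dq > 0 & dc <= 0),
    more_effective_costlier = mean(dq > 0 & dc > 0),
    less_effective_cheaper = mean(dq <= 0 & dc <= 0),
    less_effective_costlier = mean(dq <= 0 & dc > 0))
  list(mean_delta_cost = mean(dc), sd_delta_cost = stats::sd(dc),
       ci_delta_cost = ci(dc),
       mean_delta_qalys = mean(dq), sd_delta_qalys = stats::sd(dq),
       ci_delta_qalys = ci(dq),
       quadrants = quadrants,
       prop_cost_effective = mean(dq > 0 & nmb > 0),
       prop_qaly_loss = mean(dq < 0),
       prop_costlier = mean(dc > 0))
}

#' Probabilistic sensitivity analysis by Monte Carlo
#'
#' Draws every non-point model input independently from its fitted
#' distribution (fixed canonical order), evaluates the cohort engine for all
#' strategies on the same draw (paired parameters across arms), and
#' summarises per-comparison incremental cost and QALYs, cost-effectiveness
#' plane quadrant proportions, and the proportion cost-effective at the WTP
#' threshold. Draws producing an effective hospitalization probability above
#' 1 are rejected and redrawn (count recorded in `rejected`).
#'
#' @param params An `ibd_params` table.
#' @param strategies List of [strategy()] objects (order matters: default
#'   comparisons are between consecutive strategies).
#' @param n_draws Number of Monte Carlo draws (default 10000).
#' @param seed Integer seed; identical seed and inputs give a bit-identical
#'   result. `NULL` uses the current RNG state.
#' @param wtp Willingness-to-pay (USD/QALY).
#' @param comparisons List of integer pairs `c(reference, comparator)`
#'   indexing `strategies`; default consecutive pairs.
#' @return A list of class `ibd_psa`: `n_draws`, `seed`, `wtp`, `rejected`,
#'   `draws` (parameter matrix), `outcomes` (per-strategy cost/QALY data
#'   frames), `comparisons` (per-draw deltas + summary per pair).
#' @export
#' @examples
#' p <- canonical_parameters()
#' psa <- run_psa(p, default_strategies(), n_draws = 200, seed = 1)
#' psa$comparisons$sc_tm_vs_sc$summary$quadrants
run_psa <- function(params, strategies = default_strategies(),
                    n_draws = 10000, seed = NULL,
                    wtp = base_values(params)[["wtp"]],
                    comparisons = NULL) {
  stopifnot(n_draws >= 1, length(strategies) >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  fits <- lapply(seq_len(nrow(params)), function(i)
    fit_distribution(param_estimate(params, params$name[i])))
  draws <- .sample_draws(params, fits, n_draws, strategies)

  labels <- vapply(strategies, `[[`, "", "label")
  cost <- matrix(0, n_draws, length(strategies),
                 dimnames = list(NULL, labels))
  qalys <- cost
  base <- base_values(params)
  for (i in seq_len(n_draws)) {
    v <- draws[i, ]
    for (j in seq_along(strategies)) {
      x <- .outcomes(v, strategies[[j]])
      cost[i, j] <- x[["cost"]]
      qalys[i, j] <- x[["qalys"]]
    }
  }

  if (is.null(comparisons) && length(strategies) >= 2)
    comparisons <- lapply(seq_len(length(strategies) - 1),
                          function(i) c(i, i + 1))
  cmp <- list()
  for (pr in comparisons) {
    ref <- pr[1]; com <- pr[2]
    dc <- cost[, com] - cost[, ref]
    dq <- qalys[, com] - qalys[, ref]
    nm <- paste0(labels[com], "_vs_", labels[ref])
    cmp[[nm]] <- list(reference = labels[ref], comparator = labels[com],
                      delta_cost = dc, delta_qalys = dq,
                      summary = .summarize_comparison(dc, dq, wtp))
  }

  structure(list(n_draws = n_draws, seed = seed, wtp = wtp,
                 rejected = attr(draws, "rejected"), draws = draws,
                 outcomes = list(cost = cost, qalys = qalys),
                 comparisons = cmp),
            class = "ibd_psa")
}

#' Cost-effectiveness plane scatter table
#'
#' One row per Monte Carlo draw with the incremental QALYs and cost of a
#' comparison, suitable for plotting the CE plane; the WTP line slope is
#' attached as an attribute.
#'
#' @param result An `ibd_psa` from [run_psa()].
#' @param comparison Comparison name (e.g. `"sc_tm_vs_sc"`); default the
#'   first one.
#' @return Data frame with columns `draw`, `delta_qalys`, `delta_cost`;
#'   attribute `wtp`.
#' @export
ce_plane_export <- function(result, comparison = NULL) {
  stopifnot(inherits(result, "ibd_psa"))
  if (is.null(comparison)) comparison <- names(result$comparisons)[1]
  cmp <- result$comparisons[[comparison]]
  if (is.null(cmp)) stop("unknown comparison: ", comparison, call. = FALSE)
  out <- data.frame(draw = seq_len(result$n_draws),
                    delta_qalys = cmp$delta_qalys,
                    delta_cost = cmp$delta_cost)
  attr(out, "wtp") <- result$wtp
  out
}

#' @export
print.ibd_psa <- function(x, ...) {
  cat(sprintf("PSA: %d draws (seed %s, %d rejected), WTP %.0f USD/QALY\n",
              x$n_draws, ifelse(is.null(x$seed), "none", x$seed), x$rejected,
              x$wtp))
  for (nm in names(x$comparisons)) {
    s <- x$comparisons[[nm]]$summary
    cat(sprintf(paste0("  %s: mean dCost %+.1f (sd %.1f), mean dQALYs",
                       " %+.5f (sd %.5f)\n    dominant %.2f%%,",
                       " cost-effective at WTP %.2f%%\n"),
                nm, s$mean_delta_cost, s$sd_delta_cost, s$mean_delta_qalys,
                s$sd_delta_qalys, 100 * s$quadrants[["more_effective_cheaper"]],
                100 * s$prop_cost_effective))
  }
  invisible(x)
}
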