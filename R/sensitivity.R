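# One-way deterministic sensitivity analysis: parameter sweeps, bisection
# threshold finding, tornado ranking.

# Incremental quantities for one parameter value, all others at base.
.incremental_at <- function(params, name, x, pair, wtp) {
  v <- base_values(params)
  if (!name %in% names(v)) stop("unknown parameter: ", name, call. = FALSE)
  v[[name]] <- x
  ref <- .outcomes(v, pair[[1]])
  comp <- .outcomes(v, pair[[2]])
  dc <- comp[["cost"]] - ref[["cost"]]
  dq <- comp[["qalys"]] - ref[["qalys"]]
  icer <- if (dq != 0 && sign(dc) == sign(dq)) dc / dq else NA_real_
  list(delta_cost = dc, delta_qalys = dq, nmb = wtp * dq - dc, icer = icer)
}

.quantity_fn <- function(params, name, quantity, pair, wtp) {
  force(quantity)
  function(x) {
    inc <- .incremental_at(params, name, x, pair, wtp)
    switch(quantity,
           delta_cost = inc$delta_cost,
           delta_qalys = inc$delta_qalys,
           nmb = inc$nmb,
           icer_minus_wtp = inc$icer - wtp,
           stop("unknown quantity: ", quantity, call. = FALSE))
  }
}

#' One-way sweep of a parameter over its sensitivity range
#'
#' Evaluates the incremental cost and QALYs of `pair[[2]]` versus
#' `pair[[1]]` on an evenly spaced grid over the parameter's published
#' low/high range, all other parameters at base.
#'
#' @param params An `ibd_params` table.
#' @param name Parameter identifier.
#' @param pair List of two [strategy()] objects: reference, comparator.
#' @param n_grid Number of grid points (>= 2; default 101).
#' @param wtp Willingness-to-pay (USD/QALY) for the NMB curve.
#' @return A list of class `oneway_sweep`: `parameter`, `grid`,
#'   `delta_cost`, `delta_qalys`, `nmb`, plus any zero crossings of the
#'   incremental cost and QALY curves (`thresholds`).
#' @export
sweep_parameter <- function(params, name, pair, n_grid = 101,
                            wtp = base_values(params)[["wtp"]]) {
  stopifnot(n_grid >= 2)
  est <- param_estimate(params, name)
  grid <- seq(est$low, est$high, length.out = n_grid)
  vals <- lapply(grid, function(x) .incremental_at(params, name, x, pair, wtp))
  dc <- vapply(vals, `[[`, 0, "delta_cost")
  dq <- vapply(vals, `[[`, 0, "delta_qalys")
  nmb <- vapply(vals, `[[`, 0, "nmb")
  thresholds <- list(
    delta_cost = if (est$low < est$high && min(dc) < 0 && max(dc) > 0)
      find_threshold(params, name, "delta_cost", pair,
                     interval = c(est$low, est$high), wtp = wtp) else NULL,
    delta_qalys = if (est$low < est$high && min(dq) < 0 && max(dq) > 0)
      find_threshold(params, name, "delta_qalys", pair,
                     interval = c(est$low, est$high), wtp = wtp) else NULL)
  structure(list(parameter = name, grid = grid, delta_cost = dc,
                 delta_qalys = dq, nmb = nmb, thresholds = thresholds,
                 wtp = wtp),
            class = "oneway_sweep")
}

#' Threshold (root) of an incremental quantity in one parameter
#'
#' Bisection root finding of the chosen incremental quantity as a function
#' of a single parameter, all others at base. The incremental quantities of
#' this tree model are monotone (affine in most parameters), so bisection is
#' unconditionally robust. The search interval may extend beyond the
#' published sensitivity range when the crossing lies outside it.
#'
#' @param params An `ibd_params` table.
#' @param name Parameter identifier.
#' @param quantity One of `"delta_cost"`, `"delta_qalys"`, `"nmb"`,
#'   `"icer_minus_wtp"`.
#' @param pair List of two [strategy()] objects: reference, comparator.
#' @param interval Numeric length-2 search interval; default the parameter's
#'   published range.
#' @param wtp Willingness-to-pay (USD/QALY).
#' @param tol Absolute tolerance on the parameter value (default 1e-6).
#' @param maxit Maximum bisection iterations (default 200).
#' @return The root, or `NULL` when the quantity has the same sign at both
#'   endpoints (no threshold in the interval).
#' @export
#' @examples
#' p <- canonical_parameters()
#' pair <- list(strategy(FALSE, FALSE), strategy(TRUE, FALSE))
#' find_threshold(p, "rr_avoid", "delta_cost", pair, interval = c(1, 1.329))
find_threshold <- function(params, name,
                           quantity = c("delta_cost", "delta_qalys", "nmb",
                                        "icer_minus_wtp"),
                           pair, interval = NULL,
                           wtp = base_values(params)[["wtp"]],
                           tol = 1e-6, maxit = 200) {
  quantity <- match.arg(quantity)
  est <- param_estimate(params, name)
  if (is.null(interval)) interval <- c(est$low, est$high)
  stopifnot(length(interval) == 2, interval[1] < interval[2])
  f <- .quantity_fn(params, name, quantity, pair, wtp)
  lo <- interval[1]; hi <- interval[2]
  flo <- f(lo); fhi <- f(hi)
  if (!is.finite(flo) || !is.finite(fhi))
    stop("quantity '", quantity, "' is not finite at a search endpoint",
         call. = FALSE)
  if (flo == 0) return(lo)
  if (fhi == 0) return(hi)
  if (sign(flo) == sign(fhi)) return(NULL)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) / 2 < tol) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

#' Tornado ranking of parameter influence
#'
#' Evaluates the chosen incremental quantity at each parameter's published
#' low and high (all others at base) and ranks parameters by descending
#' span. For a dominant base case the ICER is undefined, so the default
#' quantity is the net monetary benefit at the WTP threshold.
#'
#' @param params An `ibd_params` table.
#' @param pair List of two [strategy()] objects: reference, comparator.
#' @param quantity `"nmb"` (default), `"delta_cost"` or `"delta_qalys"`.
#' @param names Parameters to rank; default every model input.
#' @param wtp Willingness-to-pay (USD/QALY).
#' @return Data frame sorted by descending span with columns `parameter`,
#'   `at_low`, `at_high`, `span`.
#' @export
tornado <- function(params, pair,
                    quantity = c("nmb", "delta_cost", "delta_qalys"),
                    names = NULL, wtp = base_values(params)[["wtp"]]) {
  quantity <- match.arg(quantity)
  if (is.null(names)) names <- params$name
  stopifnot(length(names) >= 1)
  rows <- lapply(names, function(nm) {
    est <- param_estimate(params, nm)
    f <- .quantity_fn(params, nm, quantity, pair, wtp)
    lo <- f(est$low); hi <- f(est$high)
    data.frame(parameter = nm, at_low = lo, at_high = hi,
               span = abs(hi - lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(-out$span, seq_len(nrow(out))), , drop = FALSE]
}

#' @export
print.oneway_sweep <- function(x, ...) {
  cat(sprintf("One-way sweep of '%s' over [%g, %g] (%d points)\n",
              x$parameter, min(x$grid), max(x$grid), length(x$grid)))
  cat(sprintf("  delta cost:  [%.2f, %.2f]\n", min(x$delta_cost),
              max(x$delta_cost)))
  cat(sprintf("  delta QALYs: [%.5f, %.5f]\n", min(x$delta_qalys),
              max(x$delta_qalys)))
  for (q in names(x$thresholds))
    if (!is.null(x$thresholds[[q]]))
      cat(sprintf("  threshold (%s = 0): %.6f\n", q, x$thresholds[[q]]))
  invisible(x)
}
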