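# Parameter table: one row per model input, mirroring the published input
# table one-to-one. Each row carries a base-case value, a low/high range for
# sensitivity analysis, and a sampling distribution family for the PSA.

# Registry of every model input the engine understands. `kind` drives
# cross-cutting validation: probabilities and utilities live in [0, 1],
# costs and counts are non-negative, rate ratios are strictly positive.
.param_registry <- function() {
  reg <- rbind(
    c("p_uc",               "probability", "proportion",        "Proportion of ulcerative colitis among IBD patients"),
    c("h_uc",               "probability", "per patient-year",  "UC: probability of IBD-related hospitalization"),
    c("s_uc",               "probability", "per hospitalization", "UC: probability of surgery in hospitalization"),
    c("m_uc",               "probability", "per hospitalization", "UC: in-hospital mortality"),
    c("h_cd",               "probability", "per patient-year",  "CD: probability of IBD-related hospitalization"),
    c("s_cd",               "probability", "per hospitalization", "CD: probability of surgery in hospitalization"),
    c("m_cd",               "probability", "per hospitalization", "CD: in-hospital mortality"),
    c("p_avoid",            "probability", "proportion",        "Proportion with medical avoidance during the pandemic"),
    c("rr_avoid",           "rate_ratio",  "relative risk",     "RR of hospitalization with healthcare avoidance"),
    c("p_comply",           "probability", "proportion",        "Proportion meeting telemonitoring compliance requirement"),
    c("rr_tm",              "rate_ratio",  "relative risk",     "RR of hospitalization with weekly telemonitoring"),
    c("cost_visit_uc",      "cost",        "USD/patient-year",  "UC: outpatient visits"),
    c("cost_meds_uc",       "cost",        "USD/patient-year",  "UC: medications"),
    c("cost_imaging_uc",    "cost",        "USD/patient-year",  "UC: non-invasive diagnostic imaging"),
    c("cost_endoscopy_uc",  "cost",        "USD/patient-year",  "UC: endoscopy"),
    c("cost_hosp_uc",       "cost",        "USD/patient-year",  "UC: hospitalization"),
    c("cost_surgery_uc",    "cost",        "USD/patient-year",  "UC: surgery"),
    c("cost_death_uc",      "cost",        "USD/patient-year",  "UC: in-hospital death"),
    c("cost_visit_cd",      "cost",        "USD/patient-year",  "CD: outpatient visits"),
    c("cost_meds_cd",       "cost",        "USD/patient-year",  "CD: medications"),
    c("cost_imaging_cd",    "cost",        "USD/patient-year",  "CD: non-invasive diagnostic imaging"),
    c("cost_endoscopy_cd",  "cost",        "USD/patient-year",  "CD: endoscopy"),
    c("cost_hosp_cd",       "cost",        "USD/patient-year",  "CD: hospitalization"),
    c("cost_surgery_cd",    "cost",        "USD/patient-year",  "CD: surgery"),
    c("cost_death_cd",      "cost",        "USD/patient-year",  "CD: in-hospital death"),
    c("visit_reduction",    "probability", "proportion",        "Relative reduction in outpatient-visit cost among avoiders"),
    c("tm_maintenance",     "cost",        "USD/year",          "Telemonitoring annual maintenance fee"),
    c("tm_encounters",      "count",       "per patient-year",  "Excess telemonitoring-mediated encounters"),
    c("tm_encounter_hours", "count",       "hours",             "Length of each telemonitoring encounter"),
    c("tm_wage",            "cost",        "USD/hour",          "Specialist medical staff cost"),
    c("rr_imaging_tm",      "rate_ratio",  "relative risk",     "Relative increase of non-invasive diagnostics with telemonitoring"),
    c("u_out",              "utility",     "utility",           "Utility: outpatient care"),
    c("u_hosp",             "utility",     "utility",           "Utility: non-surgical hospitalization"),
    c("u_surg",             "utility",     "utility",           "Utility: surgical hospitalization"),
    c("wtp",                "scalar",      "USD/QALY",          "Willingness-to-pay threshold (1x GDP per capita)"),
    c("horizon",            "scalar",      "years",             "Model time horizon"),
    c("usd_to_hkd",         "scalar",      "HKD per USD",       "Currency conversion (metadata only)")
  )
  data.frame(name = reg[, 1], kind = reg[, 2], units = reg[, 3],
             label = reg[, 4], stringsAsFactors = FALSE)
}

.families <- c("beta", "gamma", "lognormal", "normal", "point")

#' Construct a single parameter estimate
#'
#' A parameter estimate is one model input: a base-case value, a low/high
#' range used for one-way sensitivity analysis and PSA distribution fitting,
#' and a distribution family.
#'
#' @param name Parameter identifier (snake_case, must be one of the model's
#'   input names; see [canonical_parameters()]).
#' @param base Base-case value in native units.
#' @param low,high Sensitivity-analysis range; `low <= base <= high`.
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"normal"`,
#'   `"point"`.
#' @param units Free-text units.
#' @return A list of class `parameter_estimate`.
#' @export
#' @examples
#' parameter_estimate("rr_tm", 0.364, 0.310, 0.419, "lognormal")
parameter_estimate <- function(name, base, low, high, family, units = "") {
  est <- structure(
    list(name = as.character(name), base = as.numeric(base),
         low = as.numeric(low), high = as.numeric(high),
         family = as.character(family), units = as.character(units)),
    class = "parameter_estimate")
  msgs <- .validate_estimate(est)
  if (length(msgs)) stop(paste(msgs, collapse = "; "), call. = FALSE)
  est
}

# Invariants for one estimate; returns character vector of violations.
.validate_estimate <- function(est) {
  msgs <- character()
  bad <- function(fmt, ...) sprintf(paste0("parameter '%s': ", fmt), est$name, ...)
  if (!est$family %in% .families)
    return(bad("unknown distribution family '%s'", est$family))
  if (!all(is.finite(c(est$base, est$low, est$high))))
    return(bad("non-finite value"))
  if (!(est$low <= est$base && est$base <= est$high))
    msgs <- c(msgs, bad("range must satisfy low <= base <= high (got %g, %g, %g)",
                        est$low, est$base, est$high))
  if (est$family == "beta" && (est$low < 0 || est$high > 1))
    msgs <- c(msgs, bad("beta family requires the range inside [0, 1]"))
  if (est$family == "gamma" && est$low < 0)
    msgs <- c(msgs, bad("gamma family requires low >= 0"))
  if (est$family == "point" && !(est$low == est$base && est$base == est$high))
    msgs <- c(msgs, bad("point family requires low = base = high"))
  msgs
}

# Kind-specific invariants given the registry kind.
.validate_kind <- function(est, kind) {
  msgs <- character()
  bad <- function(fmt) sprintf(paste0("parameter '%s': ", fmt), est$name)
  rng <- c(est$low, est$base, est$high)
  switch(kind,
    probability = ,
    utility = if (any(rng < 0) || any(rng > 1))
      msgs <- c(msgs, bad("probability out of [0,1]")),
    rate_ratio = if (any(rng <= 0))
      msgs <- c(msgs, bad("relative risk must be > 0")),
    cost = ,
    count = if (any(rng < 0))
      msgs <- c(msgs, bad("value must be >= 0")),
    scalar = if (est$base <= 0)
      msgs <- c(msgs, bad("scalar must be > 0"))
  )
  msgs
}

#' Assemble and validate the full model parameter set
#'
#' Takes a data frame with columns `name`, `base`, `low`, `high`, `family`
#' (and optionally `units`), checks it against the model's parameter
#' registry (unknown names rejected, missing names reported collectively),
#' validates every row's invariants, and returns the canonical-ordered
#' parameter table.
#'
#' @param df Data frame of parameter rows.
#' @return A data.frame of class `ibd_params` with one validated row per
#'   model input, in canonical order.
#' @export
model_parameters <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("name", "base", "low", "high", "family")
  if (!all(needed %in% names(df)))
    stop("parameter table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (!"units" %in% names(df)) df$units <- ""
  reg <- .param_registry()

  unknown <- setdiff(df$name, reg$name)
  if (length(unknown))
    stop("unknown parameters: ", paste(unknown, collapse = ", "), call. = FALSE)
  missing <- setdiff(reg$name, df$name)
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$name))
    stop("duplicated parameters: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)

  df <- df[match(reg$name, df$name),
           c("name", "base", "low", "high", "family", "units")]
  rownames(df) <- NULL
  for (col in c("base", "low", "high")) df[[col]] <- as.numeric(df[[col]])
  df$name <- as.character(df$name)
  df$family <- as.character(df$family)
  df$units <- as.character(df$units)

  msgs <- character()
  for (i in seq_len(nrow(df))) {
    est <- structure(as.list(df[i, ]), class = "parameter_estimate")
    m <- .validate_estimate(est)
    if (!length(m)) m <- .validate_kind(est, reg$kind[i])
    msgs <- c(msgs, m)
  }
  if (length(msgs)) stop(paste(msgs, collapse = "\n"), call. = FALSE)

  # cross-parameter sanity: utilities ordered is not required, but the UC
  # share implies the CD share; nothing further to check since CD share is
  # derived as 1 - p_uc.
  structure(df, class = c("ibd_params", "data.frame"))
}

#' The built-in base-case parameter set
#'
#' Returns the full published input table: disease mix, per-disease
#' hospitalization/surgery/mortality probabilities, avoidance and
#' telemonitoring effects, per-disease annual costs, telemonitoring
#' programme cost components, utilities, and scalar settings (WTP threshold,
#' one-year horizon, currency conversion metadata). All values in USD.
#'
#' @return An `ibd_params` table (see [model_parameters()]).
#' @export
#' @examples
#' p <- canonical_parameters()
#' param_estimate(p, "rr_tm")
canonical_parameters <- function() {
  rows <- list(
    # name,               base,   low,    high,   family
    c("p_uc",              0.568,  0.483,  0.654,  "beta"),
    c("h_uc",              0.186,  0.158,  0.213,  "beta"),
    c("s_uc",              0.051,  0.043,  0.059,  "beta"),
    c("m_uc",              0.003,  0.003,  0.003,  "beta"),
    c("h_cd",              0.225,  0.191,  0.258,  "beta"),
    c("s_cd",              0.331,  0.282,  0.381,  "beta"),
    c("m_cd",              0.018,  0.015,  0.021,  "beta"),
    c("p_avoid",           0.261,  0.222,  0.300,  "beta"),
    c("rr_avoid",          1.156,  1.050,  1.329,  "lognormal"),
    c("p_comply",          0.590,  0.502,  0.679,  "beta"),
    c("rr_tm",             0.364,  0.310,  0.419,  "lognormal"),
    c("cost_visit_uc",     858,    729,    987,    "gamma"),
    c("cost_meds_uc",      3060,   2607,   3528,   "gamma"),
    c("cost_imaging_uc",   74,     63,     85,     "gamma"),
    c("cost_endoscopy_uc", 3647,   3100,   4194,   "gamma"),
    c("cost_hosp_uc",      7290,   6197,   8384,   "gamma"),
    c("cost_surgery_uc",   5765,   4900,   6630,   "gamma"),
    c("cost_death_uc",     26990,  22942,  31039,  "gamma"),
    c("cost_visit_cd",     1129,   960,    1298,   "gamma"),
    c("cost_meds_cd",      2894,   2460,   3328,   "gamma"),
    c("cost_imaging_cd",   485,    412,    558,    "gamma"),
    c("cost_endoscopy_cd", 3328,   2829,   3827,   "gamma"),
    c("cost_hosp_cd",      9389,   7981,   10797,  "gamma"),
    c("cost_surgery_cd",   5534,   4704,   6364,   "gamma"),
    c("cost_death_cd",     44596,  37907,  51285,  "gamma"),
    c("visit_reduction",   0.261,  0.222,  0.300,  "lognormal"),
    c("tm_maintenance",    50,     43,     58,     "gamma"),
    c("tm_encounters",     4.760,  4.046,  5.474,  "normal"),
    c("tm_encounter_hours", 0.250, 0.213,  0.288,  "normal"),
    c("tm_wage",           101,    86,     116,    "gamma"),
    c("rr_imaging_tm",     1.565,  1.331,  1.800,  "lognormal"),
    c("u_out",             0.830,  0.789,  0.872,  "beta"),
    c("u_hosp",            0.550,  0.523,  0.578,  "beta"),
    c("u_surg",            0.400,  0.380,  0.420,  "beta"),
    c("wtp",               46450,  46450,  46450,  "point"),
    c("horizon",           1,      1,      1,      "point"),
    c("usd_to_hkd",        7.8,    7.8,    7.8,    "point")
  )
  df <- data.frame(
    name = vapply(rows, `[`, "", 1),
    base = as.numeric(vapply(rows, `[`, "", 2)),
    low = as.numeric(vapply(rows, `[`, "", 3)),
    high = as.numeric(vapply(rows, `[`, "", 4)),
    family = vapply(rows, `[`, "", 5),
    stringsAsFactors = FALSE)
  reg <- .param_registry()
  df$units <- reg$units[match(df$name, reg$name)]
  model_parameters(df)
}

#' Extract one parameter estimate from a parameter table
#'
#' @param params An `ibd_params` table.
#' @param name Parameter identifier.
#' @return A `parameter_estimate`.
#' @export
param_estimate <- function(params, name) {
  stopifnot(inherits(params, "ibd_params"))
  i <- match(name, params$name)
  if (is.na(i)) stop("unknown parameter: ", name, call. = FALSE)
  structure(as.list(params[i, ]), class = "parameter_estimate")
}

#' Named vector of base-case values
#'
#' @param params An `ibd_params` table.
#' @return Named numeric vector of base-case values, canonical order.
#' @export
base_values <- function(params) {
  stopifnot(inherits(params, "ibd_params"))
  setNames(params$base, params$name)
}

#' Read a parameter table from file
#'
#' Accepts a flat delimited table (CSV with columns
#' name/base/low/high/family/units) or a structured config (YAML or JSON
#' mapping each name to base/low/high/family/units). The result is fully
#' validated: unknown names are rejected and all missing names are reported
#' in a single error.
#'
#' @param path File path; format inferred from the extension unless given.
#' @param format `"auto"`, `"csv"`, `"json"` or `"yaml"`.
#' @return An `ibd_params` table.
#' @export
load_parameters <- function(path, format = c("auto", "csv", "json", "yaml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", json = "json", yaml = , yml = "yaml",
                     stop("cannot infer parameter file format from '.", ext,
                          "'; pass format=", call. = FALSE))
  }
  df <- switch(format,
    csv = read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    json = .records_to_df(jsonlite::read_json(path, simplifyVector = FALSE)),
    yaml = .records_to_df(yaml::read_yaml(path)))
  model_parameters(df)
}

# name -> {base, low, high, family, units} mapping to flat table
.records_to_df <- function(recs) {
  if (!length(recs) || is.null(names(recs)))
    stop("structured parameter file must map parameter names to records",
         call. = FALSE)
  get <- function(r, f, default = NA) if (is.null(r[[f]])) default else r[[f]]
  data.frame(
    name = names(recs),
    base = vapply(recs, function(r) as.numeric(get(r, "base")), 0),
    low = vapply(recs, function(r) as.numeric(get(r, "low")), 0),
    high = vapply(recs, function(r) as.numeric(get(r, "high")), 0),
    family = vapply(recs, function(r) as.character(get(r, "family", "point")), ""),
    units = vapply(recs, function(r) as.character(get(r, "units", "")), ""),
    stringsAsFactors = FALSE)
}

#' Write a parameter table to file
#'
#' Values are written at full double precision so that
#' `load_parameters(write_parameters(p, f))` round-trips exactly.
#'
#' @param params An `ibd_params` table.
#' @param path Destination path.
#' @param format `"auto"`, `"csv"`, `"json"` or `"yaml"`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path,
                             format = c("auto", "csv", "json", "yaml")) {
  stopifnot(inherits(params, "ibd_params"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", json = "json", yaml = , yml = "yaml",
                     stop("cannot infer parameter file format from '.", ext,
                          "'; pass format=", call. = FALSE))
  }
  df <- as.data.frame(params)
  if (format == "csv") {
    out <- df
    for (col in c("base", "low", "high"))
      out[[col]] <- vapply(df[[col]], function(x)
        format(x, digits = 15, scientific = FALSE, trim = TRUE), "")
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    recs <- lapply(seq_len(nrow(df)), function(i)
      list(base = df$base[i], low = df$low[i], high = df$high[i],
           family = df$family[i], units = df$units[i]))
    names(recs) <- df$name
    if (format == "json")
      jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    else
      yaml::write_yaml(recs, path, precision = 15)
  }
  invisible(path)
}

#' @export
print.parameter_estimate <- function(x, ...) {
  cat(sprintf("<%s> base %g, range [%g, %g], %s%s\n", x$name, x$base, x$low,
              x$high, x$family,
              if (nzchar(x$units)) paste0(" (", x$units, ")") else ""))
  invisible(x)
}

#' @export
print.ibd_params <- function(x, ...) {
  cat("IBD cost-effectiveness model parameters (", nrow(x), " inputs)\n",
      sep = "")
  print.data.frame(x, ...)
  invisible(x)
}
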