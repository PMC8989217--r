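# Shared fixtures: the canonical parameter table and an editor that moves a
# parameter's base (and, by default, its whole range) to a new value while
# keeping the table valid.

canon <- canonical_parameters()

set_param <- function(params, name, base, low = base, high = base,
                      family = NULL) {
  df <- as.data.frame(params)
  i <- match(name, df$name)
  stopifnot(!is.na(i))
  df$base[i] <- base
  df$low[i] <- low
  df$high[i] <- high
  if (!is.null(family)) df$family[i] <- family
  model_parameters(df)
}

# collapse every input to a point mass at its base value
point_mass_params <- function(params = canon) {
  df <- as.data.frame(params)
  df$low <- df$base
  df$high <- df$base
  df$family <- "point"
  model_parameters(df)
}
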