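# internal helpers shared across modules

# round-half-up at a fixed number of decimals, for non-negative display
# quantities (percentages, odds ratios, chi-square statistics). base::round
# rounds half to even; tables in the clinical literature round half up.
# A tiny snap-to-grid guard keeps exact decimal halves (e.g. 2.675) from
# falling below .5 through binary representation.
roundHalfUp <- function(x, digits = 0) {
  scaled <- x * 10^digits
  snap <- !is.na(scaled) & abs(scaled - round(scaled)) < 1e-9
  scaled[snap] <- round(scaled[snap])
  floor(scaled + 0.5) / 10^digits
}

# treat an absent (NA) score as 0 so that "no score" can never clear a
# strict > threshold
naZero <- function(x) {
  x[is.na(x)] <- 0
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-row access into a variant data.frame as a named list
variantRow <- function(variants, i) as.list(variants[i, , drop = FALSE])

stopIfNotScalarCount <- function(x, name) {
  if (length(x) != 1 || is.na(x) || x < 0 || x != as.integer(x))
    stop(name, " must be a single non-negative integer")
}
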