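# Small shared helpers.

# Half-up rounding to `digits` decimals (report percentages round half away
# from zero, unlike base round()'s banker's rounding).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Percentage with an explicit denominator; empty denominator -> NA.
pct <- function(num, den) {
  if (den == 0) return(NA_real_)
  100 * num / den
}
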