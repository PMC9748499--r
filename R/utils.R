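# Internal numeric helpers.

# log(sum(exp(x))) without overflow; -Inf for an all--Inf input
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Deterministic nearest-integer rounding, ties away from zero (round()
# rounds half to even, which would make blending proportions irreproducible
# across platforms in edge cases).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

is_count <- function(x) {
  is.numeric(x) && !anyNA(x) && all(x >= 0) && all(x == floor(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a per-task 31-bit seed from a master seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 7919) %% 2147483647)
}
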