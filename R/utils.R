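# Run expr with a local RNG state seeded by `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Counter scheme deriving independent per-iteration seeds from one master
# seed; kept inside 32-bit integer range.
derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) %% 1e6) * 2039 + 104729 * counter) %% 2147483646L + 1L
}
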