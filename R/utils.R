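# Small shared helpers.

# Evaluate expr with a temporarily fixed RNG state, restoring the caller's
# stream afterwards, so library calls are deterministic without side effects.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Tukey fence (upper) with linear-interpolation quartiles (type 7).
tukey_upper_fence <- function(x, k = 1.5) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  q[2L] + k * (q[2L] - q[1L])
}
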