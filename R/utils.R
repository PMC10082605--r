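# Internal helpers: seed streams and small validators.

# Derive a child seed from a parent seed and a stream index. Linear
# congruential mix modulo a Mersenne prime keeps results in 32-bit range and
# gives well-separated streams for sample/region/channel hierarchies.
derive_seed <- function(seed, index) {
  m <- 2147483629
  as.integer((as.double(seed) %% m * 48271 + as.double(index) * 8191 + 1) %% m)
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(lower), format(upper)),
          class = "fibrotype_parameter_error")
  }
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  check_number(x, name, lower = lower)
  if (x != round(x)) {
    abort(sprintf("`%s` must be an integer.", name),
          class = "fibrotype_parameter_error")
  }
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
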