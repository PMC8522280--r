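# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Stable seed derivation for replicate i of a run seeded with `seed`.
# Documented contract: seed_i = (seed * 1000003 + i) mod (2^31 - 1).
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 1000003 + i) %% 2147483647)
}

# trapezoidal quadrature weights for a sorted grid
trapezoid_weights <- function(grid) {
  n <- length(grid)
  if (n == 1L) return(0)
  w <- numeric(n)
  d <- diff(grid)
  w[1] <- d[1] / 2
  w[n] <- d[n - 1] / 2
  if (n > 2L) w[2:(n - 1)] <- (d[-(n - 1)] + d[-1]) / 2
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a
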