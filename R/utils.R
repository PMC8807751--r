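# Internal helpers shared across modules.

# Numerical guard used for divisions and variance floors throughout.
.eps <- 1e-12

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

check_symmetric <- function(m, tol = 1e-8) {
  max(abs(m - t(m))) <= tol
}

# seeded RNG scope: runs expr under a temporary seed, restoring the
# caller's RNG state afterwards so library calls do not perturb user code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}
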