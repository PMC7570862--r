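# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
## RNG state afterwards so library calls never clobber user randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Deterministic child seed from a master seed and a few small indices.
## Mixed by repeated multiply-add modulo a Mersenne prime; all arithmetic
## stays below 2^53 so doubles are exact, and the result is < 2^31.
child_seed <- function(master, ...) {
  p <- 2147483647 # 2^31 - 1
  h <- as.numeric(master) %% p
  for (k in as.numeric(c(...))) {
    h <- (h * 48271 + k + 1) %% p
  }
  as.integer(h)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

## Clip into [eps, 1 - eps] before taking logs.
clip_unit <- function(x, eps = 1e-12) pmin(pmax(x, eps), 1 - eps)

stop_invalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
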