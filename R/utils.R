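#' @keywords internal
"_PACKAGE"

## Run code under a fixed RNG seed without disturbing the caller's stream.
## seed = NULL leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  code
}

## Deterministic fan-out of one master seed into n sub-seeds (31-bit ints).
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_input <- function(...) stop(..., call. = FALSE)

is_wholenumber <- function(x, tol = 1e-9) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}
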