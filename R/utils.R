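#' @keywords internal
"_PACKAGE"

## RNG scoping: every stochastic routine in the package runs inside
## with_seed() so that a call is a pure function of its arguments and the
## global RNG stream of the caller is never disturbed.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic sub-seed from a master seed and string tags. Plain 32-bit
## style mixing done in doubles (exact below 2^53), reduced mod 2^31 - 1 so
## the result is always a valid set.seed() input.
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- as.numeric(seed) %% m
  for (tag in as.character(unlist(list(...)))) {
    for (code in utf8ToInt(tag)) {
      h <- (h * 131 + code) %% m
    }
    h <- (h * 2654435761) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x == round(x)
}

db_to_amp <- function(db) 10^(db / 20)

## Root-mean-square of a numeric vector.
rms <- function(x) sqrt(mean(x^2))
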