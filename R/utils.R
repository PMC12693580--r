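#' @keywords internal
"_PACKAGE"

## Seed plumbing: every stochastic operation takes an optional `seed`. When
## given, the RNG state is set locally and restored on exit, so callers can
## reproduce a single draw without disturbing an enclosing stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  expr
}

#' Derive a named substream seed from a master seed
#'
#' All randomness in the experiment drivers flows from a single master seed
#' through named substreams (cohort, effects, noise, ...), so that runs are
#' bit-reproducible and substreams do not collide. The derived seed is kept
#' below 2^31 - 1.
#'
#' @param master Integer master seed.
#' @param stream Character name of the substream.
#' @param index Optional non-negative integer (e.g. replicate number).
#' @return A single integer seed.
#' @export
derive_seed <- function(master, stream, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  val <- (abs(as.numeric(master)) * 69069 + h * 2654435761 + index * 40503) %%
    2147483563
  as.integer(val) + 1L
}

stop_param <- function(...) stop(..., call. = FALSE)

check_prob <- function(x, name, open = FALSE) {
  if (!is.numeric(x) || anyNA(x)) stop_param(name, " must be numeric without NA")
  if (open) {
    if (any(x <= 0 | x >= 1)) stop_param(name, " must lie strictly in (0, 1)")
  } else if (any(x < 0 | x > 1)) {
    stop_param(name, " must lie in [0, 1]")
  }
  invisible(x)
}
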