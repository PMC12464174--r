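#' @keywords internal
"_PACKAGE"

# Internal assertion helper: stop with a classed condition so callers/tests can
# match on error class rather than message text.
abort <- function(msg, class) {
  stop(structure(
    class = c(class, "seizr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert <- function(cond, msg, class = "seizr_invalid_input") {
  if (!isTRUE(cond)) abort(msg, class)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

#' Derive a stream of per-record seeds from one master seed
#'
#' A simple counter scheme: record `i` uses `(seed + i * 10007) mod 2^31-1`.
#' Keeps every derived seed a valid 32-bit integer and makes individual
#' records reproducible without generating their predecessors.
#'
#' @param seed master integer seed
#' @param i zero-based counter
#' @return an integer seed
#' @keywords internal
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i) * 10007) %% 2147483647)
}

# Run expr with a temporarily-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  force(expr)
}
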