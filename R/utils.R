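#' @keywords internal
"_PACKAGE"

# Structured errors: every user-facing failure carries a condition class so
# callers (and tests) can dispatch on the kind of failure, not the message.
tk_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "tapkin_error")))
}

tk_assert <- function(cond, msg, class) {
  if (!isTRUE(cond)) tk_stop(msg, class)
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
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
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one parent seed, all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}

# Sample coefficient of variation: sd(x, n-1) / mean(x).
cv <- function(x) stats::sd(x) / mean(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
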