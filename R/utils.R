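# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
local_seed <- function(seed, code) {
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
  force(code)
}

# Coerce ExpressionMatrix or plain matrix to a numeric matrix.
as_values <- function(x) {
  if (is_expression_matrix(x)) x$values else as.matrix(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mc <- function(...) stop(..., call. = FALSE)
warn_mc <- function(...) warning(..., call. = FALSE)
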