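# Internal helpers: typed errors and seeded evaluation.

stop_totonou <- function(msg, type, call. = FALSE) {
  stop(errorCondition(msg,
    class = c(paste0("totonou_error_", type), "totonou_error", "error", "condition")
  ))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop_totonou(
      sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper),
      "bad_parameter"
    )
  }
  invisible(x)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so seeded generators do not disturb the session.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  check_scalar_number(seed, "seed")
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

# Derive a child seed from a base seed and a stream index, staying below 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 1103L + k * 7919) %% 2147483629)
}
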