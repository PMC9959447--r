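## internal helpers shared across modules

stop_agrecoeff <- function(msg, class) {
  stop(structure(class = c(class, "agrecoeff_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_that <- function(cond, msg, class = "agrecoeff_validation_error") {
  if (!isTRUE(cond)) stop_agrecoeff(msg, class)
  invisible(TRUE)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it, evaluates `expr`, and restores the
#' previous state on exit, so package randomness never leaks into (or depends
#' on) the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## significance stars at the 10/5/1% conventions used in the output tables
stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}
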