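#' Evaluate an expression with a local, restorable random seed
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that (i) identical seeds give identical results and (ii) the
#' caller's global RNG state is left untouched.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != round(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# stopifnot-style check with a custom message
check_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
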