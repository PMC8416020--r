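#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then restores
#' the caller's RNG state so that seeded helpers never perturb an enclosing
#' simulation. All seeded generators in the package route through this helper,
#' which is what makes them pure functions of `(parameters, seed)`.
#'
#' @param seed integer seed, or `NULL` to run unseeded.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# internal: stop without the call in the message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# internal: check a single finite numeric
check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    abort("`%s` must be a single finite number in [%s, %s]", name, lower, upper)
  invisible(x)
}
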