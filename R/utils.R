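#' @importFrom methods new validObject is slot
#' @importFrom stats approx fivenum quantile rnorm runif sd median
#' @importFrom utils read.csv write.csv
NULL

## Classed conditions so callers (and the cohort runner) can distinguish
## degenerate inputs from genuine bugs.
.tpStop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "thermopatternError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

degenerateInputError <- function(fmt, ...) .tpStop("degenerateInputError", fmt, ...)
configError  <- function(fmt, ...) .tpStop("configError",  fmt, ...)
formatError  <- function(fmt, ...) .tpStop("formatError",  fmt, ...)
inputError   <- function(fmt, ...) .tpStop("inputError",   fmt, ...)
alignmentError <- function(fmt, ...) .tpStop("alignmentError", fmt, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state, so seeded generators do not perturb an enclosing
#' simulation. A `NULL` seed evaluates `expr` under the current RNG state.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-sample seed from a master seed
#'
#' Fixed counter scheme: sample `i` of a cohort seeded with `master` always
#' receives the same child seed, and distinct counters give distinct
#' streams, so cohorts are reproducible while samples stay independent.
#' Result is kept strictly below 2^31.
#'
#' @param master Integer master seed (or `NULL`, returning `NULL`).
#' @param i Non-negative integer counter.
#' @return Integer seed below 2^31, or `NULL`.
#' @export
#' @examples
#' deriveSeed(42, 1)
deriveSeed <- function(master, i) {
  if (is.null(master)) return(NULL)
  stopifnot(is.numeric(master), is.numeric(i), i >= 0)
  as.integer((abs(as.numeric(master)) * 1000003 + as.numeric(i) * 7919 + 12345) %%
               2147483647)
}

.checkNumber <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    configError("'%s' must be a single finite number", name)
  if (x < lower || x > upper || (strict_lower && x <= lower))
    configError("'%s' = %g outside its valid range", name, x)
  invisible(x)
}
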