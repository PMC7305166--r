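#' @keywords internal
"_PACKAGE"

## Canonical biomarker order. Every ratio column is stored as earlier/later in
## this order; resolve_feature() handles the reverse orientation.
BIOMARKERS <- c(
  "adiponectin_HMW", "adiponectin_LMW", "adipsin", "chemerin", "leptin",
  "visfatin", "CRP", "IL8", "MCP1"
)

RISK_FACTORS <- c("age", "gender", "bmi")

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package internals never clobber the user's stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed
#'
#' Deterministic stream splitting: child seeds for sub-tasks (resplits, swarm
#' inits, cohort draws) are drawn from the master seed so that one integer
#' fixes the whole pipeline. Kept strictly below 2^31.
#'
#' @param seed master integer seed.
#' @param ... integer tags identifying the sub-task.
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  tags <- c(as.integer(seed), as.integer(c(...)))
  h <- 0
  for (t in tags) h <- (h * 69069 + t + 12345) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
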