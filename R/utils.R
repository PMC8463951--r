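#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm lm.fit logLik median model.frame model.matrix
#'   model.response delete.response terms optimize optim plogis pnorm qlogis
#'   quantile rbinom rnorm runif sd setNames simulate var predict residuals
#'   fitted IQR complete.cases na.omit dist as.formula glm binomial
#' @importFrom utils head read.csv write.csv modifyList
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Expand one user-facing seed into `n` deterministic substream seeds, so that
# e.g. adding covariate draws does not perturb the count draws.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

#' Format a percentage from a count pair
#'
#' Helper used throughout the provenance logs: `100 * k / n` rounded
#' half-up to `digits` decimal places (the convention used when reporting
#' filter and imputation counts).
#'
#' @param k Numerator count.
#' @param n Denominator count (must be positive).
#' @param digits Decimal places to round to.
#' @return Numeric percentage.
#' @examples
#' format_pct(9, 472)   # 1.9
#' @export
format_pct <- function(k, n, digits = 1) {
  stopifnot(n > 0)
  x <- 100 * k / n
  # round half away from zero (reporting convention), not banker's rounding
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_arg <- function(...) stop(..., call. = FALSE)
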