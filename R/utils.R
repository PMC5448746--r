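#' @keywords internal
"_PACKAGE"

# Shared small helpers. Lengths are in cm, angles in radians throughout the
# package; the CLI converts degrees at the boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = "riceCanopy_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

validation_error <- function(fmt, ...) {
  stopf(fmt, ..., class = "riceCanopy_validation_error")
}

#' Evaluate a polynomial with ascending coefficients
#'
#' `coef[1]` is the constant term, `coef[k]` multiplies `x^(k-1)`.
#'
#' @param coef numeric coefficient vector, ascending degree.
#' @param x points at which to evaluate.
#' @return numeric vector of polynomial values.
#' @keywords internal
poly_eval <- function(coef, x) {
  y <- rep(coef[length(coef)], length(x))
  for (k in seq(length(coef) - 1L, 1L)) y <- y * x + coef[k]
  y
}

poly_deriv <- function(coef) {
  n <- length(coef)
  if (n <= 1L) return(0)
  coef[-1L] * seq_len(n - 1L)
}

norm3 <- function(v) sqrt(sum(v^2))

unit3 <- function(v) {
  n <- norm3(v)
  if (n == 0) return(v)
  v / n
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Wrap an angle into [0, 2*pi)
wrap_angle <- function(a) a %% (2 * pi)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
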