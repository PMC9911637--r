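#' Age-transform specification
#'
#' The piecewise log-linear age transformation used as the regression
#' response when training a clock: logarithmic below the "adult age" knot,
#' linear above it. The knot defaults to 20 years; setting `enabled = FALSE`
#' turns the transform into the identity (the clock is then trained directly
#' on years).
#'
#' @param adult_age Knot in years, strictly positive. Default 20.
#' @param enabled Logical; apply the transform (default `TRUE`).
#' @return A list of class `transform_spec`.
#' @export
transform_spec <- function(adult_age = 20, enabled = TRUE) {
  stopifnot(is.numeric(adult_age), length(adult_age) == 1, adult_age > 0,
            is.logical(enabled), length(enabled) == 1)
  structure(list(adult_age = adult_age, enabled = enabled),
            class = "transform_spec")
}

#' Transform chronological age to the clock's response scale
#'
#' For age `a` and adult-age knot `A`, the transform is
#' `log((a + 1) / (A + 1))` for `a <= A` and `(a - A) / (A + 1)` above it —
#' continuous and strictly increasing, equal to 0 at `a = A`. With
#' `enabled = FALSE` the input is returned unchanged.
#'
#' @param age Numeric vector of ages in years; must exceed -1.
#' @param spec A [transform_spec()].
#' @return Transformed ages (unit-free).
#' @seealso [inverse_transform_age()]
#' @examples
#' transform_age(c(9.5, 20, 41))   # -0.693, 0, 1
#' @export
transform_age <- function(age, spec = transform_spec()) {
  stopifnot(inherits(spec, "transform_spec"))
  if (any(!is.finite(age)) || any(age <= -1)) {
    stop("Ages must be finite and greater than -1 year.", call. = FALSE)
  }
  if (!spec$enabled) return(age)
  A <- spec$adult_age
  ifelse(age <= A, log((age + 1) / (A + 1)), (age - A) / (A + 1))
}

#' Invert the age transformation back to years
#'
#' Exact inverse of [transform_age()]: `(A + 1) * exp(t) - 1` for `t <= 0`,
#' `A + t * (A + 1)` above. Identity when the spec is disabled.
#'
#' @param t Numeric vector of transformed ages; must be finite.
#' @param spec A [transform_spec()].
#' @return Ages in years.
#' @export
inverse_transform_age <- function(t, spec = transform_spec()) {
  stopifnot(inherits(spec, "transform_spec"))
  if (any(!is.finite(t))) stop("Transformed ages must be finite.", call. = FALSE)
  if (!spec$enabled) return(t)
  A <- spec$adult_age
  ifelse(t <= 0, (A + 1) * exp(t) - 1, A + t * (A + 1))
}
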