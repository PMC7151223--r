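#' Logit and inverse-logit transforms
#'
#' `logit()` maps a probability in (0, 1) to the real line, `inv_logit()`
#' maps back. Both are thin, vectorised wrappers around the numerically
#' stable [stats::qlogis()] / [stats::plogis()].
#'
#' @param p Numeric vector of probabilities, strictly inside (0, 1).
#' @param x Numeric vector on the logit (log-odds) scale.
#' @return Numeric vector of the same length.
#' @examples
#' logit(0.5)          # 0
#' inv_logit(logit(0.3))
#' @export
logit <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 1)) {
    stop("'p' must be strictly inside (0, 1)")
  }
  stats::qlogis(p)
}

#' @rdname logit
#' @export
inv_logit <- function(x) {
  if (!is.numeric(x) || anyNA(x)) stop("'x' must be numeric and non-missing")
  stats::plogis(x)
}

#' Rasch probability of a correct response
#'
#' One-parameter logistic item response model: the probability that a
#' person with ability `theta` answers an item of difficulty `beta`
#' correctly is `exp(theta - beta) / (1 + exp(theta - beta))`. The
#' difference parameterisation makes the model invariant under a common
#' shift of both parameters.
#'
#' @param theta Ability on the logit scale (finite).
#' @param beta Difficulty on the logit scale (finite).
#' @return Probability of a correct response, vectorised over inputs.
#' @examples
#' rasch_probability(0, 0)         # 0.5
#' rasch_probability(logit(0.7), logit(0.3))
#' @export
rasch_probability <- function(theta, beta) {
  if (!is.numeric(theta) || !is.numeric(beta) ||
      any(!is.finite(theta)) || any(!is.finite(beta))) {
    stop("'theta' and 'beta' must be finite numerics")
  }
  stats::plogis(theta - beta)
}

# Logit of an urn proportion with a half-marble continuity correction so
# that full and empty urns stay on the scale (used for matchmaking).
.clamped_logit <- function(green, size) {
  g <- pmin(pmax(green, 0.5), size - 0.5)
  log(g / (size - g))
}

# scalar variant for the update hot path
.clamped_logit1 <- function(green, size) {
  if (green < 0.5) green <- 0.5 else if (green > size - 0.5) green <- size - 0.5
  log(green / (size - green))
}
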