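#' One- and two-parameter Box-Cox transformation
#'
#' The power transformation \eqn{g(x) = ((x+c)^\lambda - 1)/\lambda} (and
#' \eqn{\log(x+c)} for \eqn{\lambda = 0}) used to bring skewed daily intake
#' amounts close to normality before variance decomposition. The shift
#' \eqn{c} is zero for the one-parameter form; the two-parameter form adds a
#' positive shift so that negative working values (e.g. regression
#' residuals) can be transformed.
#'
#' @param x Numeric vector; requires `x + shift > 0`.
#' @param lam Box-Cox exponent \eqn{\lambda}, in \eqn{[0, 1]}.
#' @param shift Additive shift \eqn{c \ge 0} applied before transforming.
#' @return Numeric vector of transformed values.
#' @seealso [bc_inverse()], [bc_fit_lambda()], [bc_fit_lambda_restricted()]
#' @examples
#' bc_forward(97.65625, lam = 0.2) # 7.5
#' bc_inverse(7.5, lam = 0.2)      # 97.65625
#' @export
bc_forward <- function(x, lam, shift = 0) {
  stopifnot(lam >= 0, lam <= 1, shift >= 0)
  xs <- x + shift
  if (any(xs <= 0)) {
    stop("Box-Cox transform undefined: x + shift must be positive")
  }
  if (lam == 0) log(xs) else (xs^lam - 1) / lam
}

#' Inverse Box-Cox transformation (clamped at zero)
#'
#' Maps transformed-scale values back to the original intake scale. Where
#' \eqn{\lambda y + 1 \le 0} the power inverse is undefined; intakes are
#' non-negative, so the inverse is clamped to 0 there (this is the
#' convention used inside the quadrature tails). The result is floored at 0
#' after subtracting the shift.
#'
#' @param y Numeric vector of transformed-scale values.
#' @inheritParams bc_forward
#' @return Numeric vector of non-negative original-scale values.
#' @export
bc_inverse <- function(y, lam, shift = 0) {
  stopifnot(lam >= 0, lam <= 1, shift >= 0)
  if (lam == 0) {
    out <- exp(y) - shift
  } else {
    out <- pmax(lam * y + 1, 0)^(1 / lam) - shift
  }
  pmax(out, 0)
}

# Profile log-likelihood of the normal model for Box-Cox transformed
# values, including the Jacobian term (lam - 1) * sum(log(x + shift)).
# Pooled over all observations; variance profiled out analytically.
bc_profile_loglik <- function(lam, x, shift = 0) {
  z <- bc_forward(x, lam, shift)
  n <- length(z)
  s2 <- stats::var(z) * (n - 1) / n
  if (s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lam - 1) * sum(log(x + shift))
}

#' Fit the one-parameter Box-Cox exponent by profile maximum likelihood
#'
#' Maximizes the pooled-observation normal profile log-likelihood
#' (including the Jacobian term) over \eqn{\lambda \in [0.01, 1]} by
#' golden-section search. The lower bound stays off 0 to avoid the
#' branch discontinuity at the log transform; request `lam = 0`
#' explicitly via [bc_forward()] if a log model is wanted.
#'
#' @param x Positive numeric vector, at least 10 values.
#' @param lower,upper Search interval for \eqn{\lambda}.
#' @return A list with elements `lam`, `shift` (always 0), `restricted`
#'   (`FALSE`) and `loglik`.
#' @export
bc_fit_lambda <- function(x, lower = 0.01, upper = 1) {
  if (length(x) < 10) stop("need at least 10 values to fit lambda")
  if (any(x <= 0)) stop("values must be positive for the one-parameter fit")
  opt <- stats::optimize(bc_profile_loglik, c(lower, upper), x = x,
                         maximum = TRUE, tol = 1e-6)
  list(lam = opt$maximum, shift = 0, restricted = FALSE,
       loglik = opt$objective)
}

#' Fit a restricted two-parameter Box-Cox exponent on a 1/lambda grid
#'
#' The MSM-style transformation restricts \eqn{1/\lambda} to positive
#' integers. A shift is added when the minimum value is non-positive
#' (\eqn{c = -\min(x) + \delta}, \eqn{\delta} = 1e-6 times the value
#' range), then the same Jacobian-corrected profile log-likelihood is
#' evaluated at each candidate \eqn{\lambda = 1/d} and the maximizer
#' returned.
#'
#' @param x Numeric vector, at least 10 values (may contain non-positive
#'   values; a shift is applied).
#' @param denoms Candidate integer denominators \eqn{d} (default 1..10,
#'   covering \eqn{\lambda} down to 0.1).
#' @return A list with elements `lam`, `shift`, `restricted` (`TRUE`) and
#'   `loglik`.
#' @export
bc_fit_lambda_restricted <- function(x, denoms = 1:10) {
  if (length(x) < 10) stop("need at least 10 values to fit lambda")
  stopifnot(all(denoms >= 1), all(denoms == round(denoms)))
  rng <- diff(range(x))
  if (rng <= 0) stop("all values identical: Box-Cox likelihood degenerate")
  shift <- if (min(x) > 0) 0 else -min(x) + 1e-6 * rng
  cand <- 1 / denoms
  ll <- vapply(cand, bc_profile_loglik, numeric(1), x = x, shift = shift)
  best <- which.max(ll)
  list(lam = cand[best], shift = shift, restricted = TRUE,
       loglik = ll[best])
}
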