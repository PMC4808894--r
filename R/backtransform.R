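# Back-transformation from the transformed (normal-model) scale to the
# original intake scale, integrating out within-person noise:
#   BT(t) = E[ g^{-1}(t + eps) ],  eps ~ N(0, sigma_eps^2),
# with g^{-1} the inverse Box-Cox. Evaluated either by Gauss-Hermite
# quadrature (any lambda) or, when 1/lambda is an integer, by the exact
# closed moment formula.

# Cache of Gauss-Hermite rules keyed by node count.
.gh_cache <- new.env(parent = emptyenv())

gh_rule <- function(nodes) {
  key <- as.character(nodes)
  if (is.null(.gh_cache[[key]])) {
    stopifnot(nodes >= 3)
    .gh_cache[[key]] <- pracma::gaussHermite(nodes)
  }
  .gh_cache[[key]]
}

#' Back-transform by Gauss-Hermite quadrature
#'
#' Computes \eqn{BT(t) = \sum_m w_m\, g^{-1}(t + \sqrt{2}\,\sigma_\epsilon
#' x_m)/\sqrt{\pi}} over the physicists' Gauss-Hermite rule
#' \eqn{(x_m, w_m)}, i.e. the expectation of the inverse Box-Cox of
#' \eqn{t} plus within-person noise. Exact for \eqn{1/\lambda} integer
#' whenever `nodes` exceeds \eqn{1/(2\lambda)}; equals `bc_inverse(t)`
#' when `sigma_eps = 0`. Vectorized over `t`.
#'
#' @param t Transformed-scale value(s).
#' @param sigma_eps Within-person standard deviation (>= 0).
#' @param lam,shift Box-Cox parameters (see [bc_inverse()]).
#' @param nodes Number of quadrature nodes (>= 3).
#' @return Non-negative original-scale value(s), same length as `t`.
#' @export
bt_quadrature <- function(t, sigma_eps, lam, shift = 0, nodes = 60) {
  stopifnot(sigma_eps >= 0)
  if (sigma_eps == 0) return(bc_inverse(t, lam, shift))
  gh <- gh_rule(nodes)
  out <- numeric(length(t))
  scale <- sqrt(2) * sigma_eps
  for (m in seq_along(gh$x)) {
    out <- out + gh$w[m] * bc_inverse(t + scale * gh$x[m], lam, shift)
  }
  out / sqrt(pi)
}

#' Back-transform by the closed moment formula (1/lambda integer)
#'
#' For \eqn{\lambda = 1/r} with integer \eqn{r}, the inverse Box-Cox of a
#' normal variable is a degree-r polynomial, so the within-person
#' expectation has the closed form
#' \deqn{BT(t) = \sum_{m\ even}^{r} \binom{r}{m} (\lambda t + 1)^{r-m}
#'       \lambda^m \sigma_\epsilon^m (m-1)!!}
#' (odd central normal moments vanish), minus the shift, floored at 0.
#' This is the MSM-style back-transformation. Vectorized over `t`.
#'
#' @inheritParams bt_quadrature
#' @return Non-negative original-scale value(s).
#' @export
bt_closed_form <- function(t, sigma_eps, lam, shift = 0) {
  stopifnot(sigma_eps >= 0, lam > 0)
  r <- 1 / lam
  if (abs(r - round(r)) > 1e-8) {
    stop("closed-form back-transform requires 1/lambda to be a positive integer")
  }
  r <- round(r)
  out <- numeric(length(t))
  base <- lam * t + 1
  for (m in seq(0, r, by = 2)) {
    dfact <- if (m == 0) 1 else prod(seq(m - 1, 1, by = -2))
    out <- out + choose(r, m) * base^(r - m) * lam^m * sigma_eps^m * dfact
  }
  pmax(out - shift, 0)
}
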