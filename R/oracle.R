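#' True usual-intake distribution of a generating scenario
#'
#' Computes the exact mean and percentiles of the usual-intake
#' distribution on the original scale directly from the generating
#' parameters, by Gauss-Hermite quadrature: percentile p is
#' \eqn{BT(\mu + z_p \sigma_u)} with the within-person SD integrated out,
#' and the mean is the back-transform of \eqn{\mu} over the total
#' variance \eqn{\sigma_u^2 + \sigma_\epsilon^2}. These are the true
#' values \eqn{\theta} against which estimator bias is scored. At
#' \eqn{\lambda = 0.2} the integrand is a degree-5 polynomial, so the
#' quadrature is exact for any `nodes` >= 3; the default 150 keeps other
#' \eqn{\lambda} accurate too.
#'
#' @param spec A [scenario_spec()].
#' @param probs Percentile probabilities.
#' @param nodes Gauss-Hermite node count (>= 3).
#' @return A `true_distribution` object: list with `mean` and named
#'   `percentiles`.
#' @examples
#' true_distribution(builtin_scenarios()$I)$mean  # 105.5625
#' @export
true_distribution <- function(spec,
                              probs = c(.05, .10, .25, .50, .75, .90, .95),
                              nodes = 150) {
  stopifnot(inherits(spec, "scenario_spec"), nodes >= 3)
  sigma_u <- sqrt(spec$sigma_u_sq)
  sigma_eps <- sqrt(spec$sigma_eps_sq)
  pct <- bt_quadrature(spec$mu + stats::qnorm(probs) * sigma_u,
                       sigma_eps, spec$lam, nodes = nodes)
  m <- bt_quadrature(spec$mu, sqrt(spec$sigma_u_sq + spec$sigma_eps_sq),
                     spec$lam, nodes = nodes)
  structure(list(mean = m,
                 percentiles = stats::setNames(pct, paste0("P", probs * 100)),
                 probs = probs),
            class = "true_distribution")
}

#' @export
print.true_distribution <- function(x, ...) {
  cat(sprintf("True usual-intake distribution: mean = %.4f\n", x$mean))
  print(round(x$percentiles, 4))
  invisible(x)
}

#' Closed-form true mean (independent cross-check)
#'
#' For \eqn{\lambda = 1/r} with integer r, the original-scale mean is
#' \eqn{E[(\lambda Y + 1)^r]} for \eqn{Y \sim N(\mu, \sigma_u^2 +
#' \sigma_\epsilon^2)}, expanded with binomial coefficients and normal
#' central moments; for r = 5 this is \eqn{m^5 + 10 m^3 s^2 + 15 m s^4}
#' with \eqn{m = \lambda\mu + 1}, \eqn{s^2 = \lambda^2(\sigma_u^2 +
#' \sigma_\epsilon^2)}. Serves as an independent verification of the
#' quadrature mean.
#'
#' @param spec A [scenario_spec()] whose `lam` has integral reciprocal.
#' @return The true original-scale mean.
#' @export
closed_form_mean <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  bt_closed_form(spec$mu, sqrt(spec$sigma_u_sq + spec$sigma_eps_sq),
                 spec$lam)
}
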