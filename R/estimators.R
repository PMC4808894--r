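#' Configuration for the usual-intake estimators
#'
#' @param percentile_probs Probabilities at which percentiles are
#'   estimated; default the 5th/10th/25th/50th/75th/90th/95th.
#' @param gh_nodes Gauss-Hermite node count for quadrature
#'   back-transforms (>= 3).
#' @param nci_pseudo_persons Number k of simulated pseudo-persons in the
#'   NCI-style estimator (>= 1000).
#' @param nci_seed Integer seed for the pseudo-person draw (run in its own
#'   substream; never perturbs the caller's RNG).
#' @param msm_denoms Candidate integer denominators for the restricted
#'   Box-Cox exponent of the MSM-style estimator.
#' @return An `estimator_config` list.
#' @export
estimator_config <- function(percentile_probs = c(.05, .10, .25, .50, .75, .90, .95),
                             gh_nodes = 60,
                             nci_pseudo_persons = 50000,
                             nci_seed = 1L,
                             msm_denoms = 1:10) {
  stopifnot(all(percentile_probs > 0), all(percentile_probs < 1),
            !is.unsorted(percentile_probs),
            gh_nodes >= 3, nci_pseudo_persons >= 1000)
  structure(list(percentile_probs = percentile_probs, gh_nodes = gh_nodes,
                 nci_pseudo_persons = as.integer(nci_pseudo_persons),
                 nci_seed = as.integer(nci_seed),
                 msm_denoms = as.integer(msm_denoms)),
            class = "estimator_config")
}

# Long data -> n x k matrix of amounts (rows = persons, cols = days).
# Enforces the balanced design the variance decomposition assumes.
intake_matrix <- function(data) {
  stopifnot(all(c("person", "day", "amount") %in% names(data)))
  if (any(data$amount <= 0)) stop("intake amounts must be positive")
  counts <- table(data$person)
  k <- unique(as.integer(counts))
  if (length(k) != 1) stop("unbalanced data: every person needs the same day count")
  if (k < 2) stop("need at least 2 days per person")
  ord <- order(data$person, data$day)
  matrix(data$amount[ord], ncol = k, byrow = TRUE)
}

new_estimate <- function(method, mean, percentiles, probs, lam_hat, shift,
                         components) {
  structure(
    list(method = method, mean = mean,
         percentiles = stats::setNames(percentiles, paste0("P", probs * 100)),
         probs = probs, lam_hat = lam_hat, shift = shift,
         components = components,
         degenerate = components$sigma_u_sq_hat == 0),
    class = "usual_intake_estimate"
  )
}

#' @export
print.usual_intake_estimate <- function(x, ...) {
  cat(sprintf("Usual intake estimate (%s): mean = %.3f%s\n",
              toupper(x$method), x$mean,
              if (x$degenerate) " [degenerate: between-person variance 0]" else ""))
  print(round(x$percentiles, 3))
  invisible(x)
}

#' SPADE-style usual-intake distribution from fitted parameters
#'
#' Percentile p is the quadrature back-transform of
#' \eqn{\hat\mu + z_p \hat\sigma_u} with the within-person SD; the mean is
#' the quadrature back-transform of \eqn{\hat\mu} over the total variance
#' \eqn{\hat\sigma_u^2 + \hat\sigma_\epsilon^2}.
#'
#' @param vc A [estimate_components()] fit on the transformed scale.
#' @param lam,shift Fitted Box-Cox parameters.
#' @param config An [estimator_config()].
#' @return A `usual_intake_estimate`.
#' @export
spade_from_fit <- function(vc, lam, shift = 0, config = estimator_config()) {
  sigma_u <- sqrt(vc$sigma_u_sq_hat)
  sigma_eps <- sqrt(vc$sigma_eps_sq_hat)
  probs <- config$percentile_probs
  pct <- bt_quadrature(vc$mu_hat + stats::qnorm(probs) * sigma_u,
                       sigma_eps, lam, shift, config$gh_nodes)
  m <- bt_quadrature(vc$mu_hat, sqrt(vc$sigma_u_sq_hat + vc$sigma_eps_sq_hat),
                     lam, shift, config$gh_nodes)
  new_estimate("spade", m, pct, probs, lam, shift, vc)
}

#' NCI-style usual-intake distribution from fitted parameters
#'
#' Simulates `config$nci_pseudo_persons` pseudo-person means from
#' \eqn{N(\hat\mu, \hat\sigma_u^2)} (seeded substream), back-transforms
#' each through the 9-point Gauss-Hermite rule with the within-person SD,
#' and reads the mean and empirical percentiles (interpolated order
#' statistics at position \eqn{p(k-1)+1}) off the back-transformed values.
#'
#' @inheritParams spade_from_fit
#' @return A `usual_intake_estimate`.
#' @export
nci_from_fit <- function(vc, lam, shift = 0, config = estimator_config()) {
  b <- with_seed(config$nci_seed,
                 stats::rnorm(config$nci_pseudo_persons, vc$mu_hat,
                              sqrt(vc$sigma_u_sq_hat)))
  bt <- bt_quadrature(b, sqrt(vc$sigma_eps_sq_hat), lam, shift, nodes = 9)
  pct <- stats::quantile(bt, config$percentile_probs, type = 7, names = FALSE)
  new_estimate("nci", mean(bt), pct, config$percentile_probs, lam, shift, vc)
}

#' Estimate the usual-intake distribution (SPADE style)
#'
#' Fits a free one-parameter Box-Cox exponent by profile MLE, decomposes
#' the transformed values into within- and between-person variance
#' components, and back-transforms mean and percentiles by Gauss-Hermite
#' quadrature (see [spade_from_fit()]).
#'
#' @param data Long-format intake data: columns `person`, `day`, `amount`
#'   (balanced, >= 2 days per person).
#' @param config An [estimator_config()].
#' @return A `usual_intake_estimate` with fields `method`, `mean`,
#'   `percentiles`, `lam_hat`, `components` and the `degenerate` flag
#'   (TRUE when the between-person variance was estimated as zero, in
#'   which case all percentiles are equal).
#' @export
estimate_spade <- function(data, config = estimator_config()) {
  amt <- intake_matrix(data)
  fit <- bc_fit_lambda(as.vector(amt))
  vc <- estimate_components(bc_forward(amt, fit$lam))
  spade_from_fit(vc, fit$lam, 0, config)
}

#' Estimate the usual-intake distribution (NCI amount-model style)
#'
#' Same transformed-scale model fit as [estimate_spade()], followed by the
#' NCI pseudo-person Monte-Carlo back-transformation with the 9-point
#' approximation (see [nci_from_fit()]).
#'
#' @inheritParams estimate_spade
#' @return A `usual_intake_estimate`.
#' @export
estimate_nci <- function(data, config = estimator_config()) {
  amt <- intake_matrix(data)
  fit <- bc_fit_lambda(as.vector(amt))
  vc <- estimate_components(bc_forward(amt, fit$lam))
  nci_from_fit(vc, fit$lam, 0, config)
}

#' Estimate the usual-intake distribution (MSM style)
#'
#' First stage: an intercept-only regression of daily amounts (fitted
#' value = grand mean; the fitted-value plumbing is kept so covariates
#' could be added). Working values \eqn{e_{ij} = y_{ij} - \hat y_{ij} +
#' \bar y} are transformed with a shifted Box-Cox whose exponent is
#' restricted to \eqn{1/\lambda} integer, variance components are
#' estimated, each person's transformed mean is shrunk toward the overall
#' mean by the reliability factor
#' \eqn{\hat\sigma_u^2 / (\hat\sigma_u^2 + \hat\sigma_\epsilon^2/k)},
#' and back-transformed by the closed moment formula. The usual-intake
#' distribution is the empirical distribution of the n person-level
#' values.
#'
#' @inheritParams estimate_spade
#' @return A `usual_intake_estimate`.
#' @export
estimate_msm <- function(data, config = estimator_config()) {
  amt <- intake_matrix(data)
  grand <- mean(amt)
  fitted <- matrix(grand, nrow(amt), ncol(amt))   # intercept-only stage
  e <- amt - fitted + grand
  fit <- bc_fit_lambda_restricted(as.vector(e), config$msm_denoms)
  z <- bc_forward(e, fit$lam, fit$shift)
  vc <- estimate_components(z)
  k <- ncol(amt)
  shrink <- if (vc$sigma_u_sq_hat == 0) 0 else
    vc$sigma_u_sq_hat / (vc$sigma_u_sq_hat + vc$sigma_eps_sq_hat / k)
  t_i <- vc$mu_hat + (rowMeans(z) - vc$mu_hat) * shrink
  bt_i <- bt_closed_form(t_i, sqrt(vc$sigma_eps_sq_hat), fit$lam, fit$shift)
  usual <- rowMeans(fitted) - grand + bt_i        # inverse first-stage model
  pct <- stats::quantile(usual, config$percentile_probs, type = 7,
                         names = FALSE)
  new_estimate("msm", mean(usual), pct, config$percentile_probs,
               fit$lam, fit$shift, vc)
}

#' Run all three estimators on one dataset
#'
#' @inheritParams estimate_spade
#' @return Named list of `usual_intake_estimate` objects
#'   (`spade`, `nci`, `msm`).
#' @export
estimate_all <- function(data, config = estimator_config()) {
  list(spade = estimate_spade(data, config),
       nci = estimate_nci(data, config),
       msm = estimate_msm(data, config))
}
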