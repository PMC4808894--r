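#' Variance components of repeated transformed intakes
#'
#' Method-of-moments (one-way random-effects ANOVA) estimates of the
#' transformed-scale mean and the within- and between-person variances
#' from balanced repeated daily observations: with n persons and k days,
#' \deqn{\hat\sigma_\epsilon^2 = MSW = \sum_{ij}(y_{ij}-\bar y_i)^2 / (n(k-1)),}
#' \deqn{\hat\sigma_u^2 = (MSB - MSW)/k, \quad
#'       MSB = k \sum_i (\bar y_i - \bar y)^2 / (n-1),}
#' with a negative raw between-person estimate truncated to zero. A
#' between-person estimate below `zero_tol` is treated as exactly zero;
#' this drives the degenerate-sample exclusion rule in the evaluation
#' harness.
#'
#' @param y Numeric matrix of transformed daily values, one row per person
#'   (balanced: every person has the same number k >= 2 of columns), or a
#'   per-person list of equal-length numeric vectors.
#' @param zero_tol Threshold under which the between-person variance is
#'   set to exactly 0.
#' @return A `varcomp` object: list with `mu_hat`, `sigma_u_sq_hat`,
#'   `sigma_eps_sq_hat`, `truncated` (TRUE when the raw between-person
#'   estimate was negative), `n`, `k`.
#' @examples
#' estimate_components(rbind(c(1, 3), c(2, 4), c(6, 8)))
#' @export
estimate_components <- function(y, zero_tol = 1e-12) {
  if (is.list(y)) {
    len <- lengths(y)
    if (length(unique(len)) != 1) stop("unbalanced data: equal day counts required")
    y <- do.call(rbind, y)
  }
  stopifnot(is.matrix(y), is.numeric(y))
  n <- nrow(y)
  k <- ncol(y)
  if (n < 2) stop("need at least 2 persons")
  if (k < 2) stop("need at least 2 days per person")
  if (any(!is.finite(y))) stop("non-finite transformed values")
  person_means <- rowMeans(y)
  grand <- mean(y)
  msw <- sum((y - person_means)^2) / (n * (k - 1))
  msb <- k * sum((person_means - grand)^2) / (n - 1)
  raw_between <- (msb - msw) / k
  truncated <- raw_between < 0
  sigma_u_sq <- if (truncated) 0 else raw_between
  if (sigma_u_sq < zero_tol) sigma_u_sq <- 0
  structure(
    list(mu_hat = grand, sigma_u_sq_hat = sigma_u_sq,
         sigma_eps_sq_hat = msw, truncated = truncated, n = n, k = k),
    class = "varcomp"
  )
}

#' @export
print.varcomp <- function(x, ...) {
  cat(sprintf(
    "Variance components (n=%d persons x %d days):\n  mu_hat = %.4f\n  sigma_u^2 = %.4f%s\n  sigma_eps^2 = %.4f\n",
    x$n, x$k, x$mu_hat, x$sigma_u_sq_hat,
    if (x$truncated) " (truncated from negative)" else "",
    x$sigma_eps_sq_hat))
  invisible(x)
}
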