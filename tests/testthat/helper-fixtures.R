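# Shared fixtures: everything is generated in code at test time.

# Transformed-scale two-day data drawn directly (no Box-Cox), as an n x k
# matrix -- used to exercise the variance decomposition on its own model.
transformed_matrix <- function(n, k = 2, mu = 7.5, sigma_u_sq = 0.25,
                               sigma_eps_sq = 1, seed = 1) {
  with_seed(seed, {
    b <- rnorm(n, mu, sqrt(sigma_u_sq))
    matrix(rnorm(n * k, rep(b, each = k), sqrt(sigma_eps_sq)),
           ncol = k, byrow = TRUE)
  })
}

# Long-format intake data built from an amounts matrix.
long_from_matrix <- function(amt) {
  tibble::tibble(
    person = rep(seq_len(nrow(amt)), each = ncol(amt)),
    day = rep(seq_len(ncol(amt)), times = nrow(amt)),
    amount = as.vector(t(amt))
  )
}

# A cheap estimator config for unit tests (full defaults are exercised in
# the acceptance suite).
fast_config <- function(...) {
  estimator_config(nci_pseudo_persons = 2000, gh_nodes = 30, ...)
}

# Hand-built estimate / outcome objects for testing the metrics layer
# against frozen arithmetic without running any estimator.
fake_estimate <- function(method, mean, p50) {
  structure(
    list(method = method, mean = mean,
         percentiles = c(P50 = p50), probs = 0.5,
         lam_hat = 0.2, shift = 0, components = NULL, degenerate = FALSE),
    class = "usual_intake_estimate"
  )
}

fake_outcome <- function(index, values, excluded = FALSE,
                         methods = c("spade", "nci", "msm")) {
  est <- lapply(methods, function(m) fake_estimate(m, values[[1]], values[[2]]))
  structure(
    list(replicate_index = index,
         estimates = stats::setNames(est, methods),
         errors = list(), excluded = excluded),
    class = "replicate_outcome"
  )
}

fake_truth <- function(mean, p50) {
  structure(list(mean = mean, percentiles = c(P50 = p50), probs = 0.5),
            class = "true_distribution")
}
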