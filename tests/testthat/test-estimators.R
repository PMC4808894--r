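test_that("estimator_config validates its fields", {
  expect_error(estimator_config(gh_nodes = 2))
  expect_error(estimator_config(nci_pseudo_persons = 10))
  expect_error(estimator_config(percentile_probs = c(0.5, 0.1)))
  expect_error(estimator_config(percentile_probs = c(0, 0.5)))
})

test_that("intake_matrix enforces the balanced long format", {
  d <- long_from_matrix(matrix(1:6, ncol = 2))
  expect_equal(usualintake:::intake_matrix(d), matrix(1:6, ncol = 2))
  bad <- d[-1, ]
  expect_error(usualintake:::intake_matrix(bad), "unbalanced")
  d$amount[1] <- -1
  expect_error(usualintake:::intake_matrix(d), "positive")
})

test_that("SPADE percentiles reduce to the plain inverse without within-noise", {
  # two identical days per person: within-person variance estimated as 0
  means <- with_seed(41, bc_inverse(rnorm(60, 7.5, 0.5), 0.2))
  d <- long_from_matrix(cbind(means, means))
  est <- estimate_spade(d, fast_config())
  expect_equal(est$components$sigma_eps_sq_hat, 0)
  vc <- est$components
  expected <- bc_inverse(vc$mu_hat + qnorm(est$probs) * sqrt(vc$sigma_u_sq_hat),
                         est$lam_hat)
  expect_equal(unname(est$percentiles), expected, tolerance = 1e-10)
  expect_false(est$degenerate)
})

test_that("all methods flag degenerate samples and equal percentiles", {
  # equal person means with within-person variation only
  amt <- bc_inverse(rbind(c(7.2, 7.8), c(7.8, 7.2), c(7.4, 7.6),
                          c(7.6, 7.4), c(7.5, 7.5), c(7.3, 7.7),
                          c(7.7, 7.3), c(7.45, 7.55), c(7.55, 7.45),
                          c(7.35, 7.65)), 0.2)
  d <- long_from_matrix(amt)
  for (f in list(estimate_spade, estimate_nci, estimate_msm)) {
    est <- f(d, fast_config())
    expect_true(est$degenerate)
    expect_equal(diff(range(est$percentiles)), 0)
  }
})

test_that("NCI estimates are deterministic under a fixed pseudo-person seed", {
  d <- generate_dataset(builtin_scenarios()$I, seed = 5)
  cfg <- fast_config(nci_seed = 77L)
  e1 <- estimate_nci(d, cfg)
  e2 <- estimate_nci(d, cfg)
  expect_identical(e1, e2)
  e3 <- estimate_nci(d, fast_config(nci_seed = 78L))
  expect_false(identical(e1$percentiles, e3$percentiles))
})

test_that("MSM without measurement error returns the empirical person means", {
  means <- with_seed(43, bc_inverse(rnorm(50, 7.5, 0.5), 0.2))
  d <- long_from_matrix(cbind(means, means))
  est <- estimate_msm(d, fast_config())
  # shrinkage factor is 1, back-transform has no noise term: the usual
  # intakes are the observed person means themselves
  expect_equal(est$mean, mean(means), tolerance = 1e-6)
  expect_equal(unname(est$percentiles),
               unname(quantile(means, est$probs, type = 7)),
               tolerance = 1e-6)
})

test_that("MSM with zero between-person variance shrinks completely", {
  amt <- bc_inverse(rbind(c(7.0, 8.0), c(8.0, 7.0), c(7.2, 7.8),
                          c(7.8, 7.2), c(7.4, 7.6), c(7.6, 7.4),
                          c(7.1, 7.9), c(7.9, 7.1), c(7.3, 7.7),
                          c(7.7, 7.3)), 0.2)
  est <- estimate_msm(long_from_matrix(amt), fast_config())
  expect_true(est$degenerate)
  expect_equal(diff(range(est$percentiles)), 0)
})

test_that("percentiles are non-decreasing for every method on random data", {
  sc <- builtin_scenarios()
  cfg <- fast_config()
  for (seed in 1:4) {
    spec <- scenario_spec("p", n = 60,
                          sigma_eps_sq = c(1, 2.7, 1.2, 1)[seed],
                          sigma_u_sq = c(0.25, 0.3, 0.3, 0.11)[seed])
    d <- generate_dataset(spec, seed = seed)
    for (est in estimate_all(d, cfg)) {
      expect_true(all(diff(est$percentiles) >= 0))
      expect_true(all(est$percentiles >= 0))
      expect_gte(est$mean, 0)
    }
  }
})

test_that("larger within-person variance increases shrinkage of the tails", {
  # at fixed between-person variance, raising the generator's
  # within-person variance must widen the gap between a method's P10 and
  # the naive two-day-mean P10
  gap <- function(eps_sq) {
    spec <- scenario_spec("g", n = 300, sigma_eps_sq = eps_sq,
                          sigma_u_sq = 0.3)
    d <- generate_dataset(spec, seed = 50)
    naive <- quantile(tapply(d$amount, d$person, mean), 0.1, names = FALSE)
    est <- estimate_msm(d, fast_config())
    est$percentiles[["P10"]] - naive
  }
  expect_gt(gap(2.7), gap(1.2))
})

test_that("SPADE and NCI back-transform identically given the same fit", {
  vc <- structure(list(mu_hat = 7.5, sigma_u_sq_hat = 0.25,
                       sigma_eps_sq_hat = 1, truncated = FALSE,
                       n = 150L, k = 2L), class = "varcomp")
  cfg <- estimator_config(nci_pseudo_persons = 200000, nci_seed = 9L)
  sp <- spade_from_fit(vc, 0.2, config = cfg)
  nc <- nci_from_fit(vc, 0.2, config = cfg)
  # the 9-node rule is exact for the degree-5 integrand, so the two
  # methods differ only by pseudo-person sampling noise
  expect_equal(unname(nc$percentiles), unname(sp$percentiles),
               tolerance = 5e-3)
  expect_equal(nc$mean, sp$mean, tolerance = 5e-3)
})
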