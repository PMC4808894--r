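test_that("the twelve built-in scenarios match the design grid", {
  sc <- builtin_scenarios()
  expect_length(sc, 12)
  expect_named(sc, c("I", "II", "III", "IV", "V", "VI",
                     "VII", "VIII", "IX", "X", "XI", "XII"))
  expect_equal(sc$I[c("n", "sigma_eps_sq", "sigma_u_sq")],
               list(n = 150L, sigma_eps_sq = 1, sigma_u_sq = 0.25))
  expect_equal(sc$VII[c("n", "sigma_eps_sq", "sigma_u_sq")],
               list(n = 150L, sigma_eps_sq = 1.2, sigma_u_sq = 0.3))
  expect_equal(sc$VIII$sigma_eps_sq, 2.7)
  # scenarios I-VI all have within-person variance 1
  expect_true(all(vapply(sc[1:6], `[[`, numeric(1), "sigma_eps_sq") == 1))
  # nominal variance ratios are 4 and 9, sample sizes 150/300/500
  rvar <- vapply(sc, `[[`, numeric(1), "rvar")
  expect_true(all(round(rvar) %in% c(4, 9)))
  expect_equal(unname(round(rvar[c("I", "II")])), c(4, 9))
  expect_setequal(vapply(sc, `[[`, integer(1), "n"), c(150L, 300L, 500L))
  # shared generating-model parameters
  expect_true(all(vapply(sc, `[[`, numeric(1), "mu") == 7.5))
  expect_true(all(vapply(sc, `[[`, numeric(1), "lam") == 0.2))
  expect_true(all(vapply(sc, `[[`, integer(1), "days_per_person") == 2L))
})

test_that("scenario_spec validates its inputs", {
  expect_error(scenario_spec("x", n = 1, sigma_eps_sq = 1, sigma_u_sq = 0.1))
  expect_error(scenario_spec("x", n = 10, sigma_eps_sq = 0, sigma_u_sq = 0.1))
  expect_error(scenario_spec("x", n = 10, sigma_eps_sq = 1, sigma_u_sq = -1))
  expect_error(scenario_spec("x", n = 10, sigma_eps_sq = 1, sigma_u_sq = 0.1,
                             days_per_person = 1))
})

test_that("degenerate variances collapse to the deterministic back-transform", {
  spec <- scenario_spec("degen", n = 5, sigma_eps_sq = 1e-12,
                        sigma_u_sq = 1e-12)
  d <- generate_dataset(spec, seed = 1)
  expect_equal(d$amount, rep(2.5^5, 10), tolerance = 1e-4)
})

test_that("generated datasets have the declared shape and are reproducible", {
  spec <- builtin_scenarios()$I
  d1 <- generate_dataset(spec, seed = 99)
  expect_equal(nrow(d1), 150 * 2)
  expect_true(all(d1$amount > 0))
  expect_equal(unname(table(d1$person)), rep(2L, 150),
               ignore_attr = TRUE)
  expect_identical(generate_dataset(spec, seed = 99), d1)
  expect_false(identical(generate_dataset(spec, seed = 100), d1))
  expect_false(identical(generate_dataset(spec, seed = 99,
                                          replicate_index = 2), d1))
})

test_that("per-person substreams make prefixes independent of n", {
  small <- scenario_spec("s", n = 50, sigma_eps_sq = 1, sigma_u_sq = 0.25)
  big <- scenario_spec("b", n = 150, sigma_eps_sq = 1, sigma_u_sq = 0.25)
  ds <- generate_dataset(small, seed = 7)
  db <- generate_dataset(big, seed = 7)
  expect_equal(ds$amount, db$amount[seq_len(nrow(ds))])
})

test_that("generator moments match the generating model", {
  spec <- scenario_spec("big-I", n = 10000, sigma_eps_sq = 1,
                        sigma_u_sq = 0.25)
  d <- generate_dataset(spec, seed = 21)
  z <- bc_forward(d$amount, 0.2)
  n <- spec$n
  # transformed-scale mean within 4 SE of 7.5
  expect_lt(abs(mean(z) - 7.5), 4 * sqrt((0.25 + 0.5) / n))
  # ANOVA components within 4 SE of (between 0.25, within 1)
  vc <- estimate_components(matrix(z, ncol = 2, byrow = TRUE))
  se_eps <- sqrt(2 / n)
  se_u <- sqrt(0.5 * ((1 + 0.5)^2 / (n - 1) + 1 / n))
  expect_lt(abs(vc$sigma_eps_sq_hat - 1), 4 * se_eps)
  expect_lt(abs(vc$sigma_u_sq_hat - 0.25), 4 * se_u)
  # original-scale mean within Monte-Carlo error of the oracle value
  truth <- closed_form_mean(spec)
  expect_equal(truth, 105.5625)
  se_amt <- stats::sd(d$amount) / sqrt(n)   # conservative (ignores pairing)
  expect_lt(abs(mean(d$amount) - truth), 4 * se_amt * sqrt(2))
})

test_that("intake datasets round-trip through delimited text", {
  d <- generate_dataset(builtin_scenarios()$I, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_intake(d, path)
  expect_identical(readLines(path, n = 1), "person,day,amount")
  d2 <- read_intake(path)
  expect_equal(d2$person, d$person)
  expect_equal(d2$amount, d$amount, tolerance = 1e-12)
})

test_that("scenario YAML files resolve built-ins and custom specs", {
  path <- withr::local_tempfile(fileext = ".yml")
  writeLines(c(
    "- I",
    "- label: custom",
    "  n: 40",
    "  sigma_eps_sq: 1.5",
    "  sigma_u_sq: 0.2",
    "  mu: 6.0"
  ), path)
  specs <- read_scenarios(path)
  expect_named(specs, c("I", "custom"))
  expect_equal(specs$I, builtin_scenarios()$I)
  expect_equal(specs$custom$n, 40L)
  expect_equal(specs$custom$mu, 6.0)
  expect_equal(specs$custom$lam, 0.2)
  writeLines("- XIII", path)
  expect_error(read_scenarios(path), "unknown built-in")
})

test_that("seed mixing is deterministic, bounded and key-sensitive", {
  s <- mix_seed(1, 2, 3)
  expect_identical(s, mix_seed(1, 2, 3))
  expect_true(s >= 0 && s < 2^31)
  expect_false(mix_seed(1, 2, 3) == mix_seed(1, 3, 2))
  expect_false(mix_seed(0) == mix_seed(1))
  # with_seed restores the caller's RNG state
  set.seed(42); before <- .Random.seed
  with_seed(7, rnorm(5))
  expect_identical(.Random.seed, before)
})
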