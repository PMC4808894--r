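#' Generate and analyse one simulated sample
#'
#' Generates one dataset under `spec` (replicate-specific substreams
#' derived from `seed`), runs the three estimators on it, and applies the
#' exclusion rule: the sample is excluded from the analysis for all
#' methods when at least one method estimates the between-person variance
#' as zero (or fails outright). The NCI pseudo-person draw gets its own
#' substream per replicate so that method order never affects the data.
#'
#' @param spec A [scenario_spec()].
#' @param replicate_index Replicate number (>= 1).
#' @param seed Integer study seed.
#' @param config An [estimator_config()].
#' @return A `replicate_outcome` list: `replicate_index`, `estimates`
#'   (named list, one `usual_intake_estimate` per method), `errors`
#'   (named list of condition messages for methods that failed),
#'   `excluded` flag.
#' @export
run_replicate <- function(spec, replicate_index, seed,
                          config = estimator_config()) {
  data <- generate_dataset(spec, seed, replicate_index)
  config$nci_seed <- mix_seed(seed, replicate_index, 1000003L)
  fits <- list(spade = estimate_spade, nci = estimate_nci,
               msm = estimate_msm)
  estimates <- list()
  errors <- list()
  for (method in names(fits)) {
    res <- tryCatch(fits[[method]](data, config), error = identity)
    if (inherits(res, "error")) errors[[method]] <- conditionMessage(res)
    else estimates[[method]] <- res
  }
  degenerate <- vapply(estimates, `[[`, logical(1), "degenerate")
  structure(
    list(replicate_index = replicate_index, estimates = estimates,
         errors = errors,
         excluded = length(errors) > 0 || any(degenerate)),
    class = "replicate_outcome"
  )
}

# One estimate object -> named vector of mean + percentiles.
estimate_statistics <- function(est) {
  c(mean = est$mean, est$percentiles)
}

# Truth object -> named vector aligned with estimate_statistics().
truth_statistics <- function(truth) {
  c(mean = truth$mean, truth$percentiles)
}

#' Bonferroni-corrected t confidence interval for a mean bias
#'
#' \eqn{\bar b \pm t_{1-\alpha/(2m),\,N-1}\, s_b/\sqrt{N}} with
#' \eqn{\alpha = 1 - } `level` and \eqn{m = } `n_methods`, the number of
#' methods compared within one scenario-statistic panel.
#'
#' @param errors Per-replicate errors \eqn{\hat\theta_j - \theta} for one
#'   method and statistic (length >= 2).
#' @param n_methods Bonferroni family size (>= 1).
#' @param level Overall confidence level.
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
bonferroni_ci <- function(errors, n_methods = 3, level = 0.95) {
  n <- length(errors)
  if (n < 2) stop("need at least 2 replicates for a confidence interval")
  stopifnot(n_methods >= 1, level > 0, level < 1)
  alpha <- 1 - level
  tq <- stats::qt(1 - alpha / (2 * n_methods), df = n - 1)
  half <- tq * stats::sd(errors) / sqrt(n)
  c(ci_low = mean(errors) - half, ci_high = mean(errors) + half)
}

#' Score replicate outcomes against the truth
#'
#' For each method and statistic over the usable replicates, computes mean
#' bias \eqn{B = \sum_j(\hat\theta_j - \theta)/N}, relative bias
#' \eqn{RB = |B/\theta| \times 100}, mean squared error
#' \eqn{MSE = \sum_j(\hat\theta_j - \theta)^2/N}, and the Bonferroni
#' confidence interval for the mean bias.
#'
#' @param outcomes List of [run_replicate()] results.
#' @param truth A [true_distribution()] with the same percentile set the
#'   estimates used.
#' @param n_methods Bonferroni family size.
#' @param level Confidence level for the bias CI.
#' @param include_excluded If TRUE, score all replicates whose estimates
#'   exist, ignoring the exclusion rule (the "all available results"
#'   companion table).
#' @return A tibble with columns `method`, `statistic`, `N`, `theta`,
#'   `bias`, `rel_bias`, `mse`, `ci_low`, `ci_high`.
#' @export
compute_metrics <- function(outcomes, truth, n_methods = 3, level = 0.95,
                            include_excluded = FALSE) {
  usable <- if (include_excluded) outcomes
            else Filter(function(o) !o$excluded, outcomes)
  if (length(usable) < 2) {
    stop("fewer than 2 usable replicates: cannot compute metrics")
  }
  theta <- truth_statistics(truth)
  methods <- unique(unlist(lapply(usable, function(o) names(o$estimates))))
  rows <- list()
  for (method in methods) {
    have <- Filter(function(o) method %in% names(o$estimates), usable)
    est <- t(vapply(have, function(o) estimate_statistics(o$estimates[[method]]),
                    numeric(length(theta))))
    colnames(est) <- names(theta)   # statistic order fixed by the config
    for (stat in names(theta)) {
      th <- theta[[stat]]
      err <- est[, stat] - th
      b <- mean(err)
      ci <- bonferroni_ci(err, n_methods, level)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        method = method, statistic = stat, N = length(err),
        theta = th, bias = b, rel_bias = abs(b / th) * 100,
        mse = mean(err^2), ci_low = ci[["ci_low"]], ci_high = ci[["ci_high"]])
    }
  }
  do.call(rbind, rows)
}

#' Run the full replication study
#'
#' Crosses scenarios with replicates (per-replicate substream seeding),
#' applies the all-methods exclusion rule, and returns the summary metrics
#' table (with the exclusion rule applied and, as a companion, without),
#' a tidy per-replicate bias table suitable for boxplots, and per-scenario
#' exclusion counts.
#'
#' @param specs List of [scenario_spec()] objects (e.g. a subset of
#'   [builtin_scenarios()]).
#' @param replicates Number of simulated samples per scenario (>= 2).
#' @param seed Integer study seed.
#' @param config An [estimator_config()].
#' @param n_methods,level Bonferroni CI settings (see [bonferroni_ci()]).
#' @param oracle_nodes Node count for the truth quadrature.
#' @return An `intake_study` list: `summary` and `summary_all` tibbles
#'   (per scenario x method x statistic metrics, with / without the
#'   exclusion rule), `replicates` (long tibble: scenario, replicate,
#'   method, statistic, estimate, bias, excluded), `exclusions`
#'   (per-scenario counts), `truth` (named list of true distributions),
#'   and `manifest` (seed, replicate count, config, versions).
#' @export
run_study <- function(specs, replicates, seed, config = estimator_config(),
                      n_methods = 3, level = 0.95, oracle_nodes = 150) {
  stopifnot(replicates >= 2)
  if (inherits(specs, "scenario_spec")) specs <- list(specs)
  labels <- vapply(specs, `[[`, character(1), "label")
  names(specs) <- labels
  summary_rows <- list(); summary_all_rows <- list()
  long_rows <- list(); excl_rows <- list()
  truths <- list()
  for (label in labels) {
    spec <- specs[[label]]
    truth <- true_distribution(spec, config$percentile_probs, oracle_nodes)
    truths[[label]] <- truth
    outcomes <- lapply(seq_len(replicates), function(j)
      run_replicate(spec, j, seed, config))
    met <- compute_metrics(outcomes, truth, n_methods, level)
    met_all <- compute_metrics(outcomes, truth, n_methods, level,
                               include_excluded = TRUE)
    summary_rows[[label]] <- tibble::add_column(met, scenario = label,
                                                .before = 1)
    summary_all_rows[[label]] <- tibble::add_column(met_all, scenario = label,
                                                    .before = 1)
    theta <- truth_statistics(truth)
    for (o in outcomes) {
      for (method in names(o$estimates)) {
        s <- estimate_statistics(o$estimates[[method]])
        long_rows[[length(long_rows) + 1L]] <- tibble::tibble(
          scenario = label, replicate = o$replicate_index, method = method,
          statistic = names(theta), estimate = unname(s),
          bias = unname(s - theta), excluded = o$excluded)
      }
    }
    degen <- vapply(c("spade", "nci", "msm"), function(m)
      sum(vapply(outcomes, function(o)
        m %in% names(o$estimates) && o$estimates[[m]]$degenerate,
        logical(1))), numeric(1))
    excl_rows[[label]] <- tibble::tibble(
      scenario = label, replicates = replicates,
      excluded = sum(vapply(outcomes, `[[`, logical(1), "excluded")),
      degenerate_spade = degen[["spade"]], degenerate_nci = degen[["nci"]],
      degenerate_msm = degen[["msm"]],
      failed = sum(vapply(outcomes, function(o) length(o$errors) > 0,
                          logical(1))))
  }
  structure(
    list(summary = do.call(rbind, summary_rows),
         summary_all = do.call(rbind, summary_all_rows),
         replicates = do.call(rbind, long_rows),
         exclusions = do.call(rbind, excl_rows),
         truth = truths,
         manifest = list(seed = seed, replicates = replicates,
                         config = unclass(config), n_methods = n_methods,
                         level = level,
                         package_version =
                           as.character(utils::packageVersion("usualintake")),
                         r_version = R.version.string)),
    class = "intake_study"
  )
}

#' @export
print.intake_study <- function(x, ...) {
  cat(sprintf("Usual-intake simulation study: %d scenario(s) x %d replicates (seed %s)\n",
              length(x$truth), x$manifest$replicates, x$manifest$seed))
  print(x$exclusions)
  invisible(x)
}
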