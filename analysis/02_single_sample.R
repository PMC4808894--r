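#!/usr/bin/env Rscript
# One simulated sample under scenario I, estimated by all three methods.
#
# A worked example at full size: generate 150 persons x 2 recall days,
# estimate the usual-intake distribution with the SPADE-, NCI- and
# MSM-style estimators, and set the estimates against the known truth.

library(usualintake)

dir.create("results", showWarnings = FALSE)

spec <- builtin_scenarios()$I
data <- generate_dataset(spec, seed = 2026)
truth <- true_distribution(spec)

ests <- estimate_all(data)
stat_names <- c("mean", names(truth$percentiles))
tab <- tibble::tibble(
  statistic = stat_names,
  truth = c(truth$mean, unname(truth$percentiles)))
for (m in names(ests)) {
  tab[[m]] <- c(ests[[m]]$mean, unname(ests[[m]]$percentiles))
}
utils::write.csv(tab, "results/single_sample_estimates.csv",
                 row.names = FALSE)

cat("Scenario I, one sample (seed 2026): estimates vs truth\n")
print(as.data.frame(tab), digits = 5, row.names = FALSE)
cat("\nFitted Box-Cox exponents:",
    paste(sprintf("%s %.3f", names(ests),
                  vapply(ests, `[[`, numeric(1), "lam_hat")),
          collapse = ", "), "\n")
cat("wrote results/single_sample_estimates.csv\n")
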