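#!/usr/bin/env Rscript
# Step 4 — univariate subgroup comparisons.
#
# One hierarchical model per dichotomized clinician characteristic (age,
# subspecialty, practice setting, annual volume, surgical technique),
# each reporting the two group probability curves at the median province
# and the posterior probability that the index group is more
# opioid-sparing. The reconstruction randomizes the outcome-by-covariate
# joint structure, so these numbers exercise the machinery; they are not
# reproductions of the original subgroup estimates.

suppressPackageStartupMessages(library(opioidsparing))

seed <- 20260101
dir.create("results", showWarnings = FALSE)

survey <- read_survey_csv("results/02_survey_reconstructed.csv")
prior <- read_prior_yaml("results/01_prior.yaml")

covariates <- c("age", "subspecialty", "setting", "volume", "technique")
rows <- list()
for (k in seq_along(covariates)) {
  cv <- covariates[k]
  res <- fit_univariate(survey, cv, prior, seed = seed + k)
  print(res)
  s <- res$summary
  rows[[cv]] <- data.frame(
    covariate = cv, reference = res$groups[["reference"]],
    index = res$groups[["index"]],
    p_reference = s$mean[1], ref_lower = s$lower[1], ref_upper = s$upper[1],
    p_index = s$mean[2], idx_lower = s$lower[2], idx_upper = s$upper[2],
    superiority = res$superiority_probability, n = res$n)
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/04_comparisons.csv", row.names = FALSE)
cat("\nwrote results/04_comparisons.csv\n")
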