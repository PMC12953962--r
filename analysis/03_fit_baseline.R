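#!/usr/bin/env Rscript
# Step 3 — fit the baseline hierarchical model.
#
# Intercept-only Bernoulli-logit model with province random intercepts on
# the 96 complete cases, elicited prior Normal(logit(0.61), 1.18) on the
# intercept and Exponential(1) on the between-province SD; 4 chains of
# 2000 warmup + 2000 kept iterations. Reports the posterior probability
# of opioid-sparing prescribing at the median province and marginally
# over a new province.

suppressPackageStartupMessages(library(opioidsparing))

seed <- 20260101
dir.create("results", showWarnings = FALSE)

survey <- read_survey_csv("results/02_survey_reconstructed.csv")
df <- complete_case_filter(survey)$respondents
prior <- read_prior_yaml("results/01_prior.yaml")

spec <- model_spec(df$opioid_sparing, NULL, df$province, prior)
fit <- sample_posterior(spec, seed = seed)
print(fit)
write_draws_csv(fit, "results/03_baseline_draws.csv")
write.csv(fit$convergence$table, "results/03_baseline_convergence.csv",
          row.names = FALSE)

p_med <- probability_of_sparing(fit, "median_province")
p_new <- probability_of_sparing(fit, "new_province", seed = seed + 1)
smry <- summarize_posterior(cbind(median_province = p_med,
                                  new_province = p_new), level = 0.90)
print(smry)
write.csv(smry, "results/03_baseline_summary.csv", row.names = FALSE)
cat(sprintf(
  "\nbaseline P(opioid-sparing): %.0f%% [90%% CrI %.0f%%, %.0f%%] at the median province\n",
  100 * smry$mean[1], 100 * smry$lower[1], 100 * smry$upper[1]))
cat("wrote results/03_baseline_{draws,convergence,summary}.csv\n")
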