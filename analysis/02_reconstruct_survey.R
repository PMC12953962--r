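#!/usr/bin/env Rscript
# Step 2 — reconstruct the survey and compute descriptive statistics.
#
# No respondent-level data are deposited, so the survey is reconstructed
# from its printed one-way marginals: 100 respondents, province mix
# ON 33 / QC 22 / BC 13 plus a fixed split of the remaining 32, the
# reported demographics, 73 opioid-sparing outcomes, and 4 incomplete
# questionnaires. The joint distribution across columns is randomized
# under a seed: the reconstruction supports marginal-level checks only.

suppressPackageStartupMessages(library(opioidsparing))

seed <- 20260101
dir.create("results", showWarnings = FALSE)

survey <- paper_margins_dataset(seed = seed)
write_survey_csv(survey, "results/02_survey_reconstructed.csv")
print(survey)

complete <- complete_case_filter(survey)
cat(sprintf("complete cases: %d (of %d), %d opioid-sparing\n",
            n_respondents(complete), n_respondents(survey),
            sum(complete$respondents$opioid_sparing)))

cat("\nMinimum-age responses:\n")
print(summarize_min_age(survey))

for (f in c("opioid_sparing", "preferred_opioid", "least_preferred_opioid",
            "technique")) {
  tab <- tally_preferences(survey, f)
  write.csv(tab, sprintf("results/02_tally_%s.csv", f), row.names = FALSE)
}
cat("\nMost-preferred opioid:\n")
print(tally_preferences(survey, "preferred_opioid"))
cat("\nwrote results/02_survey_reconstructed.csv and tally tables\n")
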