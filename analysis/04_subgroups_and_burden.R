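#!/usr/bin/env Rscript
# Step 4 - subgroup odds ratios and vaccine-attributable burden.
#
# Refits the multivariable model within sex x age-bracket subgroups (matched
# sets are homogeneous in those variables, so subgrouping filters whole
# sets), then converts significantly positive 1-7 day associations into
# attributable cases, excess cases per 100,000 doses and doses per
# attributable case, with delta-method intervals and the final-month
# reporting correction.

suppressPackageStartupMessages(library(vaxcarditis))

registry <- read_registry("results/registry")
sets_all <- read.csv("results/matched_sets.csv",
                     colClasses = c(index_date = "Date"))
cfg <- study_config()

for (cond in c("myocarditis", "pericarditis")) {
  sets <- sets_all[sets_all$condition == cond, ]
  tab <- build_analysis_table(registry, sets)
  sub <- subgroup_or_table(tab)
  write.csv(sub, sprintf("results/subgroup_or_%s.csv", cond),
            row.names = FALSE)
  n_est <- sum(is.na(sub$note))
  message(sprintf("%s: %d of %d subgroup ORs estimable", cond, n_est,
                  nrow(sub)))

  fit <- multivariable_fit(tab, drop_inestimable = TRUE)
  bt <- burden_table(fit, tab, registry,
                     completeness_by_month = cfg$completeness_by_month)
  write.csv(bt, sprintf("results/burden_%s.csv", cond), row.names = FALSE)
  for (i in seq_len(nrow(bt))) {
    message(sprintf(
      "  %s dose %d: %.1f attributable cases, %.2f excess/100k doses, 1 per %s doses",
      bt$brand[i], bt$dose_rank[i], bt$attributable[i],
      bt$excess_per_100k[i],
      format(bt$doses_per_case_display[i], big.mark = ",")))
  }
}
message("subgroup and burden tables written to results/")
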