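#!/usr/bin/env Rscript
# Step 1 - simulate the study registry.
#
# Generates a synthetic claims-style registry for a population of 120,000
# persons aged 12-50 over May 12 - October 31 2021, with the window-specific
# vaccine effects, covariate effects, uptake and reporting-completeness
# parameters of the package defaults (the published multivariable estimates
# act as the true odds ratios, so later steps can be read as a parameter
# recovery exercise). The baseline daily rate is scaled up relative to the
# population-incidence default so that this desk-scale population still
# yields several hundred cases per condition.

suppressPackageStartupMessages(library(vaxcarditis))

out_dir <- "results/registry"
cfg <- simulation_config(n_persons = 120000, n_departments = 8,
                         baseline_daily_rate = 3e-5, seed = 20210512)
registry <- generate_registry(cfg)
write_registry(registry, out_dir)

print(registry)
for (cond in c("myocarditis", "pericarditis")) {
  message(sprintf("%-12s: %4d detectable cases", cond,
                  nrow(detect_cases(registry, cond))))
}
message("registry written to ", out_dir)
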