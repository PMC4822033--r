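#!/usr/bin/env Rscript

# Step 1: generate the synthetic 30-patient paired pre/post-chemotherapy
# cohort with known clonal truth, and write it in the pipeline's input
# formats (per-patient VCF + TSV mirror, clinical table, truth tables).

suppressMessages(library(neoclone))

cohort_dir <- "results/cohort"
cfg <- sim_config(n_patients = 30L, seed = 3001L, probes_per_arm = 200L)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, cohort_dir)

scen <- table(vapply(cohort$patients, `[[`, "", "scenario"))
cat("Simulated", cfg$n_patients, "patients into", cohort_dir, "\n")
cat("Scenario mix:", paste(names(scen), scen, sep = "=", collapse = ", "),
    "\n")
burdens <- vapply(cohort$patients, function(p) {
  sum(!p$truth$artifact & p$truth$ccf_pre > 0)
}, numeric(1))
cat("Pre-treatment burden: median", median(burdens),
    "range", min(burdens), "-", max(burdens), "\n")
cat("Responders:", sum(cohort$clinical$PathR == "Yes"), "of",
    nrow(cohort$clinical), "\n")
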