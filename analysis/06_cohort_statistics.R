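#!/usr/bin/env Rscript

# Step 6: assemble the per-patient master table and run the cohort
# association battery: evolution vs response (2x3 exact), paired burden
# change, T>A fraction vs response, age vs C>T fraction, signature
# change vs response.

suppressMessages(library(neoclone))

cohort_dir <- "results/cohort"
out_dir <- "results/report"

clinical <- read.delim(file.path(cohort_dir, "clinical.tsv"))
calls <- read.delim("results/clonal/evolution_calls.tsv")
shifts <- read.delim("results/signatures/spectrum_shifts.tsv")
labels <- read.delim("results/signatures/predominant_signatures.tsv")
sharing <- read.delim("results/scna/arm_event_sharing.tsv")

lab_of <- function(cs, phase) {
  labels$label[labels$sample == paste0("case", cs, "_", phase)]
}
per_patient <- do.call(rbind, lapply(seq_len(nrow(clinical)), function(i) {
  cs <- clinical$Case[i]
  v <- filter_variants(read_variants(
    file.path(cohort_dir, paste0("case", cs, ".variants.tsv"))))
  data.frame(case = cs,
             responder = response_from_mandard(clinical$Mandard[i]),
             category = calls$called[calls$case == cs],
             burden_pre = calls$burden_pre[calls$case == cs],
             burden_post = calls$burden_post[calls$case == cs],
             ta_fraction_pre = shifts$ta_fraction_pre[shifts$case == cs],
             ct_fraction_pre = shifts$ct_fraction_pre[shifts$case == cs],
             age = clinical$Age[i],
             vaf_cv = vaf_cv(v$pre_vaf[v$pre_vaf >= 0.02]),
             signature_pre = lab_of(cs, "pre"),
             signature_post = lab_of(cs, "post"),
             scna_shared = sharing$shared_fraction[sharing$case == cs])
}))

report <- build_report(per_patient)
write_report(report, out_dir)

cat("Cohort report written to", out_dir, "\n\n")
print(report$stats[, c("test", "p_value", "p_bh", "detail")],
      row.names = FALSE)
cat("\nResponse by evolution category:\n")
print(table(responder = per_patient$responder,
            category = per_patient$category))
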