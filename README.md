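# neoclone

Clonal evolution of paired pre- and post-chemotherapy tumour genomes.

`neoclone` is an R package plus analysis workflow for cohorts of
oesophageal adenocarcinoma (EAC) patients sampled before and after
neo-adjuvant chemotherapy: a biopsy at diagnosis, a resection specimen
after treatment, and a matched normal. From per-patient variant tables
(VCF or TSV with per-sample depths and alt counts) it classifies each
cancer's clonal response to therapy — **stable** (little change in
clonal composition), **genetic bottleneck** (a formerly uncommon
sub-clone survives and repopulates the tumour), or **polyclonal**
(independent lineages, typically multiple discordant same-gene driver
mutations) — and runs the cohort-level association statistics. It is
written for cancer-genomics analysts who have paired somatic call sets
and want an auditable, fully testable re-implementation of this style of
analysis, including a synthetic cohort generator with known clonal truth
so that every stage can be validated without protected data.

## The method in brief

* **Somatic filtering** applies seven empirical rules per tumour sample
  (normal depth ≥ 10 and tumour depth ≥ 8; normal VAF < 0.03; ≥ 4 alt
  reads; tumour VAF > 0.02 (FF) / ≥ 0.05 (FFPE); population frequency
  < 1%; no panel-of-normals hit; mappability ≥ 0.8 outside segmental
  duplications), relaxing the two abundance rules across the pre/post
  pair: only one member of the pair must pass them.
* **Purity** is estimated from the upper mode of per-variant candidate
  purities `p = 2v/(1 + 2v − v·c)`; post-treatment samples are excluded
  when ≥ 2 of {purity halved, histology < 20%, burden < 20% of
  pre-treatment} fire.
* **Cancer cell fractions** invert
  `v = π·φ·m / (π·c + 2(1 − π))`, and shared mutations (≥ 60× in one
  sample, allelic-ratio-<0.03 rescues, drivers always) are clustered by
  a finite mixture of paired binomials over (pre, post) alt counts — EM
  with BIC model selection, a deterministic, desk-scale replacement for
  Dirichlet-process samplers.
* **The evolution call** is an ordered decision rule on explicit
  metrics: discordant same-gene driver sets ⇒ polyclonal; ≥ 25% of
  high-VAF mutations lost beyond binomial sampling expectation
  (`P(alt < 4 | Bin(d_post, v_pre))`), ≥ 20 shared mutations, and a
  cluster expanding from CCF ≤ 0.3 to ≥ 0.5 ⇒ bottleneck; otherwise
  stable.
* **Spectra and signatures**: 96 trinucleotide channels on the
  pyrimidine strand; per-patient pre-vs-post shift tests by Fisher's
  exact test on the 2×6 class table; signatures by multiplicative-update
  NMF (Frobenius) with rank chosen by maximum differentiation (largest
  minimum pairwise cosine distance among adequately fitting ranks).
* **Arm-scale SCNAs**: MAD winsorization, exact penalized-least-squares
  segmentation (`SSE/σ² + γ·breakpoints`, γ = 1000 on the
  noise-standardised scale), ±0.15 logR calls, events covering more than
  half an arm, pre/post sharing by Jaccard on (arm, direction).
* **Cohort statistics**: Freeman–Halton 2×3 exact test of evolution
  against Mandard-derived response, paired Wilcoxon burden change,
  rank-sum T>A-vs-response with median-split odds ratio, Spearman
  age–C>T correlation, 2×2 Fisher for signature change.

## Worked example

Simulate a small cohort, classify one bottlenecked patient, and test the
cohort's evolution-by-response table:

```r
library(neoclone)

cfg <- sim_config(n_patients = 8, purity_pre = 0.6, purity_post = 0.6,
                  seed = 5, probes_per_arm = 12)
cohort <- simulate_cohort(cfg)

p <- cohort$patients[[2]]          # a planted bottleneck
res <- classify_patient(p$variants,
                        histology_content_post = p$clinical$Histology)
res$call$category
#> [1] "bottleneck"
round(unlist(res$call$metrics[c("lost_high_vaf_fraction",
                                "shared_count")]), 2)
#> lost_high_vaf_fraction           shared_count
#>                   0.46                 118.00
res$clusters$clusters
#>   cluster   center_pre center_post size
#> 1       1 1.274420e+00 0.938989390   90
#> 2       2 9.078125e-01 0.011338533  131
#> 3       3 4.615173e-01 0.002600024   24
#> 4       4 1.763673e-01 0.861900447   31
#> 5       5 3.772967e-06 0.573274602   27

tab <- matrix(c(2, 1, 8, 9, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("responder", "non-responder"),
                              c("stable", "polyclonal", "bottleneck")))
evolution_response_test(tab)$p_value
#> [1] 0.01260865
```

The metrics read: 46% of this patient's confidently pre-treatment
(VAF ≥ 0.10) mutations vanished after therapy in a way binomial read
sampling cannot explain, 118 mutations are shared across the pair, and
cluster 4 is a minor pre-treatment clone (CCF 0.18) that expanded to
dominate the resection sample (CCF 0.86) while the dominant
pre-treatment clone (cluster 2) collapsed — the hallmarks of a genetic
bottleneck. The exact test
on the cohort table (p ≈ 0.013) says responders and non-responders are
distributed non-randomly across the three clonal behaviours.

## The analysis workflow

`analysis/01…06` is the narrative pipeline over the package functions:

```sh
Rscript analysis/01_simulate_cohort.R        # 30-patient cohort + truth
Rscript analysis/02_filter_variants.R        # somatic filters + audit flags
Rscript analysis/03_classify_clonal_dynamics.R
Rscript analysis/04_signature_shifts.R
Rscript analysis/05_scna_sharing.R
Rscript analysis/06_cohort_statistics.R
```

Each step prints what it found and writes its tables under `results/`.
On the default cohort (seed 3001) step 3 reports all 30 evolution calls
agreeing with the generating scenarios, step 4 finds significant
(p < 0.01) spectrum shifts in 18 of 30 patients, step 5 a median of 18
arm events per genome with a median 26% shared across the pair, and
step 6 an evolution-by-response exact test of p ≈ 0.029 on this
simulated cohort.

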