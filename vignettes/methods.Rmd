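---
title: "Clonal dynamics of paired pre/post-chemotherapy tumour genomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal dynamics of paired pre/post-chemotherapy tumour genomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoclone)
```

# The scientific problem

Oesophageal adenocarcinoma (EAC) is routinely treated with neo-adjuvant
chemotherapy before resection, and the paired design — a biopsy before
therapy and a resection specimen after — makes it possible to watch a
carcinoma genome respond to a genotoxic intervention. Three qualitatively
different clonal behaviours are of interest:

* **stable** — little change in clonal composition; mutations present at
  low frequency may appear or vanish purely through read sampling;
* **genetic bottleneck** — a dominant pre-treatment clone is lost, a
  formerly uncommon sub-clone expands to dominate the resection specimen,
  and a non-trivial truncal mutation set is retained;
* **polyclonal** — independently arising lineages, typically betrayed by
  several distinct driver mutations in the same gene (classically *TP53*)
  that behave discordantly after therapy, often in hypermutated
  (MSI-positive) cancers.

`neoclone` implements the full analysis chain needed to make such calls
from paired variant tables — somatic filtering, purity QC,
copy-number-corrected cancer cell fraction (CCF) clustering,
trajectory and evolution classification, mutation-spectrum and signature
analysis, arm-scale copy number sharing, and the cohort-level association
statistics — together with a synthetic cohort generator carrying full
generating truth, so that every stage is testable without access to
protected patient data.

# Models and procedures

## Somatic variant filtering

Filtering is rule-based and auditable. Per tumour sample seven empirical
rules are evaluated independently and recorded as flags: insufficient
depth (normal < 10 reads or tumour < 8), normal-sample VAF ≥ 0.03, fewer
than 4 alt reads, tumour VAF at or below the preservation-specific
minimum (0.02 fresh-frozen, where the boundary itself fails; 0.05 FFPE,
where the stated minimum passes), population frequency ≥ 1%,
panel-of-normals membership, and segmental-duplication or mappability
< 0.8. Because the analysis compares the two tumour samples of one
patient, the alt-read and VAF rules are *relaxed across the pair*: a
variant is retained if both samples are clean on the five sample-quality
rules and at least one sample passes the two abundance rules. The
retained set is therefore a superset of the doubly-strict set, which is
asserted as a property test. Population-frequency sources collapse to a
single maximum-frequency column, and panel-of-normals / segmental
duplication status are consumed as boolean annotations: shipping those
databases is out of scope, and any caller's output can be annotated
upstream.

## Purity estimation and sample exclusion

Given retained VAFs and local total copy number, each variant is
inverted to the purity it would imply were it clonal on one copy,
$p = 2v / (1 + 2v - v\,c)$ (reducing to $2v$ when $c = 2$). The clonal
cluster appears as the *upper mode* of a kernel density over these
candidates (fixed bandwidth 0.04; plug-in bandwidths smear the clonal
mode into sub-clonal mass), refined by the local median within three
bandwidths — the raw mode sits left of the cluster centre because the
inversion is convex for $c > 2$. Estimation is refused below 20
variants. On simulated clonal diploid input (500 mutations, 100×) the
median absolute error is below 0.01 across purities 0.3–0.9; with
realistic sub-clonal structure the upper mode is occasionally confounded
by a dominant sub-clone, which is why downstream thresholds carry margin
(below).

A post-treatment sample is excluded when at least 2 of 3 features fire:
estimated purity falling below half the pre-treatment estimate,
histological tumour content below 20% (strict, so exactly 20% does not
fire), and post-treatment burden below 20% of pre-treatment. The 2-of-3
default reflects that the three features are listed as joint evidence
without a stated combination rule; each feature and the count are
configurable.

## CCF computation and clone clustering

CCF inverts the expected-VAF model
$v = \pi\,\phi\,m / (\pi c + 2(1-\pi))$ for purity $\pi$, CCF $\phi$,
multiplicity $m$ (fixed at 1 unless specified) and total copy number
$c$; values above 1.5 are clipped with a flag. The inversion is exact on
the valid domain (tested to 1e-12).

Mutations enter clustering by three rules: detected in both samples with
≥ 60× coverage in at least one; shared positions whose allelic ratio
falls below 0.03 in just one sample; and annotated drivers regardless of
coverage. Hypermutators are down-sampled to 500 included mutations
(drivers always kept) with a seeded draw.

Clone structure across the pair is modelled as a finite mixture of
paired binomials: cluster $k$ has a joint centre
$(\phi^{pre}_k, \phi^{post}_k)$ on CCF scale, each mutation's expected
VAF is the centre scaled by its own purity/copy-number factor, and EM
maximises the exact binomial likelihood of the observed alt counts. The
number of clusters is chosen by BIC over 1…8 (stopping after BIC worsens
twice); each candidate gets 20 seeded initialisations (k-means on naive
CCFs plus random restarts) run short and the winner polished to the full
tolerance (1e-6 relative). This replaces Dirichlet-process MCMC
machinery deliberately: it is deterministic given a seed, desk-scale,
and sufficient for two-sample CCF clustering; MCMC iteration settings
from sampling-based tools therefore do not transfer, and the EM limits
are set independently. Clusters are reported in canonical order
(decreasing pre-centre) so runs are comparable.

## Trajectories, sampling effects, and the evolution call

A mutation is *lost* (`pre_only`) when detected (VAF ≥ 0.02) before but
not after therapy, *gained* symmetrically, *shared* otherwise. Whether a
loss is explainable by sampling alone is answered exactly:
$P(\text{alt} < k_{\min} \mid \mathrm{Bin}(d_{post}, v_{pre}))$, the
probability the mutation would have been missed at the post-treatment
depth were its frequency unchanged; a loss with probability below 0.01
is "not explainable by sampling".

The per-patient call applies, in order:

1. **excluded** — the QC rule above;
2. **polyclonal** — any gene carrying ≥ 3 distinct driver mutations with
   discordant trajectories (≥ 1 lost and ≥ 1 shared/gained), or a
   hypermutated cancer (> 2,000 detected pre-treatment mutations) losing
   and gaining high-VAF mutations (≥ 5 each, beyond sampling);
3. **bottleneck** — all three of: ≥ 25% of high-VAF (pre-VAF ≥ 0.10)
   mutations lost beyond sampling expectation; ≥ 20 shared mutations;
   and an *expanding minor clone* — a cluster of ≥ 5 mutations with
   pre-CCF in [0.02, 0.3] and post-CCF ≥ 0.5;
4. **stable** otherwise.

All cut-offs live in `evolution_thresholds()` and are reported with
every call. They are explicit stand-ins for qualitative descriptions
("not at low VAFs", "a non-trivial number", "an uncommon clone") and
were calibrated on the simulator. Two deserve comment. The expanding
minor clone's lower bound (0.02) distinguishes a clone *present but
uncommon* before therapy from one absent entirely — a cluster whose
pre-centre is indistinguishable from zero is a gained clone, not an
expanding one, and without this bound any patient acquiring
post-treatment sub-clonal mutations would look like a bottleneck. Its
upper bound sits at 0.3 rather than the nominal 0.2 because minor-clone
pre-CCF estimates are biased upward: inclusion conditions on detection
(upward-fluctuated read counts are preferentially included), and purity
underestimation in heavily bottlenecked pre-treatment samples inflates
all CCFs proportionally. On simulated patients the survivor clone
(true prevalence 0.08–0.18) lands at estimated pre-CCF 0.10–0.35, while
genuinely common clones sit far above.

## Mutation spectra and signatures

Substitutions are recorded on the pyrimidine strand over the standard
96 trinucleotide channels (class, then 5′, then 3′, alphabetical);
purine-reference mutations are reverse-complemented, and the 6-class
spectrum is always the row-sum collapse of the 96-channel one (an
invariant under test). Spectrum shifts between mutations that predate
therapy (pre-only or shared) and post-treatment-only mutations are
tested per patient by Fisher's exact test on the 2×6 table (network
algorithm up to table total 200, seeded Monte-Carlo with $10^5$ draws
beyond), and cohort-level by chi-square. The exact test's conditional
discreteness makes it conservative; under the null its rejection rate at
$\alpha = 0.01$ stays at or below nominal (a calibration test asserts
within one percentage point).

Signatures are extracted by multiplicative-update NMF under the
Frobenius objective (objective monotonicity asserted per iteration),
best of several seeded restarts, columns normalised to sum 1 with
exposures rescaled. The Frobenius objective is the standard, stable
choice at this scale; KL-divergence updates were considered and not
needed. Rank selection automates "maximum differentiation": among ranks
whose reconstruction error sits near the achievable floor (within 35% of
the error range — an under-fitted blend sits at the top of the range and
is always excluded, while the true rank's small noise-absorption gap
above the floor is tolerated), pick the rank with the largest minimum
pairwise cosine distance between fitted signatures; ranks whose signatures are
near-duplicates (distance < 0.1) are ineligible, and if every rank is
degenerate the data carry no evidence of multiple processes and the
smallest rank is returned. On mutation-rich samples (thousands of
mutations) this recovers a planted rank of 3 reliably. On exome-scale
burdens (a few hundred mutations per sample) the error curve has no
elbow — additional components keep absorbing multinomial noise — and the
criterion over-selects; the analysis workflow therefore fixes the
working rank after inspecting the criterion table, exactly as the
original study chose its rank manually. Samples below 50 mutations are
not assessable for a predominant signature (argmax exposure share, ties
to the lowest index, logged) and are excluded from fitting in the
workflow.

The three planted signatures emulate the EAC signature landscape: an
ageing-like profile dominated by C>T at CpG with an NTT>NGT shoulder, a
C>A-rich profile, and a T>C (especially NTT>NCT) plus C>A profile.
Post-treatment-only mutations draw from a shifted mixture (mass moved
from the ageing-like to the C>A-rich signature), emulating the observed
post-therapy fall in C>T and rise in C>A.

## Arm-scale copy number

Per-probe logR values are MAD-winsorized (median ± 2.5 MAD; the
constant is a declared default, not inferred from any reference) and
segmented by exact penalized least squares: dynamic programming
minimises $\mathrm{SSE}/\sigma^2 + \gamma \cdot \#\text{breakpoints}$
per chromosome, with $\sigma$ estimated from median absolute successive
differences. Putting the penalty on the noise-standardised scale is what
makes the conventional $\gamma = 1000$ meaningful: at array-like noise
(sd 0.1) it yields arm-scale segments, while the raw-SSE scale would
never split. The DP is exact — equivalence with exhaustive enumeration
over all partitions is asserted on short probe runs — and deterministic.
Calls use the ±0.15 logR threshold with strict inequalities (the
boundary is neutral); an alternative input path accepts absolute-copy-
number segment tables and calls changes deviating by more than 1 from
the probe-weighted genome mean. An arm event ("large SCNA") requires
same-direction called segments to cover more than half the arm, and
pre/post sharing is Jaccard on (arm, direction) identity — arm-scale
events are categories, not breakpoint intervals, so identity rather than
overlap is the right equality.

## Cohort statistics

Clinical response is coded from the Mandard tumour-regression grade
(1–3 responder, 4–5 non-responder). The association battery uses exact
or rank-based tests throughout: Freeman–Halton exact test on the 2×3
evolution-by-response table, Wilcoxon signed-rank for paired burden
change (exact for n ≤ 25 without ties or zero differences), rank-sum
for T>A fraction by response with a median-split odds ratio
(Haldane–Anscombe 0.5 correction on zero cells, flagged), Spearman
correlation of age with C>T fraction (chosen over Pearson for the
skewed fraction scale; Pearson behind a flag), and 2×2 Fisher for
signature change by response. Every exact test is checked against a
brute-force enumeration oracle in the test suite, and null calibration
(type-I error within 1.5 percentage points of nominal) is asserted for
the shift test. No multiple-testing correction is applied to the
headline values — the analysis reports nominal p-values as a cohort
description — but a Benjamini–Hochberg column is emitted alongside for
transparency.

# The synthetic cohort generator

The generator is first-class, tested code, and its defaults *are* the
study conditions: 30 patients, mean pre-treatment burden 373 (lognormal,
log-sd 0.35, floor 50), sequencing depth 75× (Poisson per variant,
binomial alt counts), deep-panel depth 1,800× available in
configuration, purity 0.65/0.60 pre/post, mostly copy number 3
("hypertriploid", per-variant copy number drawn from {2,3,4}), 18
arm-scale copy number events per genome (2 for MSI-like hyperdiploid
cases), and a scenario mix of 11:10:3 stable:bottleneck:polyclonal
over the analysable patients.

Patients are rooted clone trees over cancer cells; a clone's fraction is
its cellular prevalence, so child ≤ parent holds by construction and is
re-asserted per generated patient. Therapy multiplies each clone's
private cell population by a survival factor and renormalises; clones
falling below prevalence 1e-4 — far below any detectable VAF at the
simulated depths — go extinct. Scenario construction:

* **stable** — a single clone (survival 1); observed losses and gains
  then arise from read sampling only;
* **bottleneck** — a trunk, a doomed dominant sub-clone (prevalence
  0.55–0.8, survival 0.002) carrying most private mutations (allocation
  weight 1.2–2.2 against 1.2 for the trunk, reflecting observed
  bottlenecks where losses far outnumber retained mutations), a
  surviving minor sub-clone (prevalence 0.08–0.18, survival 1), and up
  to two further sub-clones;
* **polyclonal** — two founder lineages under a mutation-free root, a
  20× hypermutator burden, and three same-gene (*TP53*) drivers placed
  so that one lineage rises, one persists reduced, and one sub-clone is
  lost — the discordance the detector looks for.

The pre-treatment sub-clone frequency distribution is not something the
study quantifies; the ranges above are the generator's stand-in and are
flagged as such in configuration. Artifact classes (germline
leak-through at VAF 0.5, panel-of-normals hits, segmental-duplication
and low-mappability sites, Poisson mean 10 each) are planted with the
annotations that the corresponding filter rules key on, so the filter
stage has real work to do. Clinical records draw response conditional on
scenario with the observed 2/11, 8/10, 1/3 responder rates, and ages,
stages and histological content from plausible ranges.

What the generator does **not** emulate: read-level artefacts (no
FASTQ/BAM simulation, no indel realignment effects), FFPE deamination
beyond a VAF-threshold difference, focal amplifications, LOH,
allele-specific copy number, mutation multiplicity > 1, normal-sample
tumour contamination (default 0 — no estimate exists to emulate), and
absolute spectrum class fractions tuned to real EAC cohorts (the T>A
fraction, for instance, is structurally present but not calibrated to
the published medians). Passing tests therefore demonstrate that the
pipeline recovers the truth of this explicit generative model at
realistic depth, purity and burden — not that it would reproduce every
idiosyncrasy of real sequencing data.

# Numerical choices and degenerate inputs

* Detection floor 0.02 VAF everywhere a "present/absent" decision is
  needed; ties at filter thresholds follow the stated inequality
  directions exactly (normal VAF 0.03 fails, tumour VAF 0.02 fails for
  fresh-frozen, histology exactly 20% does not fire, logR exactly 0.15
  is neutral).
* EM: probabilities clamped to [1e-6, 0.999]; empty clusters dropped and
  relabelled; all-identical inputs yield one cluster; fewer than 5
  mutations is a refusal, not a guess.
* NMF: multiplicative updates with a 1e-12 guard; restart seeds derived
  deterministically from the user seed.
* Segmentation: prefix-sum SSE, exact DP; a zero MAD skips
  winsorization; fewer than 3 values passes through with a warning.
* Exact tests: `fisher.test` workspace raised for 2×6 tables; Monte-
  Carlo fallback is seeded; all-zero margins are refusals.
* Every stochastic routine takes a seed and restores the caller's RNG
  state, so cohort generation is byte-reproducible.

# Problem sizes

The test suite and the acceptance script exercise the pipeline at the
sizes the methods are specified for: 10,000 random variant records for
filter-oracle equivalence; 500 clonal mutations × 50 replicates × 4
purity levels for purity recovery; 100 patients per scenario at 75× and
purity 0.6 for classification recovery; 30 samples × 2,500 mutations for
signature recovery; 1,000 null replicates for shift-test calibration;
and 3 genomes at 1,000 probes/arm for arm-event recovery. The analysis
workflow (`analysis/01…06`) runs a 30-patient cohort end to end in a few
minutes on one core.

# Known limitations

* The evolution thresholds are explicit stand-ins for expert judgement;
  on real cohorts they should be reviewed against the per-patient
  metrics that every call carries.
* The purity estimator assumes a detectable clonal cluster; in heavily
  bottlenecked pre-treatment samples dominated by a doomed sub-clone it
  can track that sub-clone instead. Classification is robust to this
  (CCF ratios shift together), but absolute purity values from such
  samples deserve caution; polyclonal tumours without a truncal cluster
  have no well-defined single purity at all.
* Automated NMF rank selection needs mutation-rich samples; at
  exome-scale burdens the criterion table should be inspected and the
  rank fixed by hand, as done in the workflow.
* Fisher's exact shift test is conservative on small post-treatment
  mutation sets; patients with very few post-only mutations rarely reach
  significance regardless of the true shift.
* Multi-region data are handled pairwise through the concordance
  measure only; there is no joint multi-sample clone model, and no
  phylogeny beyond cluster centres.
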