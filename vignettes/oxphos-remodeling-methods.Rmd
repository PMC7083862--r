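---
title: "Methods: respirometry, mtDNA heteroplasmy and the severe respiratory phenotype signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respirometry, mtDNA heteroplasmy and the severe respiratory phenotype signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxshift)
library(dplyr)
```

`oxshift` implements an integrative analysis of oxidative-phosphorylation
(OXPHOS) remodeling in paired benign/malignant tissue: high-resolution
respirometry (HRR) state processing, mitochondrial-DNA heteroplasmy
classification with codon-level consequence annotation, duplex-qPCR mtDNA
copy number, and a metagene signature of the "severe" respiratory
phenotype with survival dichotomization. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
seeded synthetic cohort does and does not establish.

## Respirometry model

A substrate–uncoupler–inhibitor titration (SUIT) run steps one tissue
sample through coupling/pathway control states: LEAK respiration with
glutamate&malate (`GM_L`), OXPHOS after ADP (`GM_P_pre`), OXPHOS after an
oxidative-stress step (`GM_P`), after pyruvate (`N_P`), after succinate
(`NS_P`), uncoupled electron-transfer capacity (`NS_E`), the
succinate-pathway capacity after rotenone (`S_E`), and residual oxygen
consumption after full inhibition (`ROX`).

* **Plateau statistic.** Instrument software reads state fluxes from
  manually placed marks, which is not reproducible in code. We read each
  state as the *median* volume-specific flux over the trailing 60 s
  (configurable `window_s`) before the next titration event, scaled by
  chamber volume (default 2 mL) and divided by wet mass, giving
  pmol O~2~ s^-1^ mg^-1^. The median resists titration spikes; the
  plateau coefficient of variation is reported as a quality flag.
* **ROX correction.** `ROX` is subtracted from every state. Corrected
  fluxes can be slightly negative for states near zero; they are kept
  and flagged rather than clamped, because clamping would bias the
  titration-effect deltas.
* **Flux control ratios.** States are normalized to `NS_E`, the maximal
  convergent NS-pathway ET capacity; FCRs are scale-free, so the
  between-subject capacity factor cancels.
* **Effect deltas.** ADP coupling activation (`GM_P_pre - GM_L`), the
  oxidative-stress decrement (`GM_P - GM_P_pre`), pyruvate and succinate
  increments, the uncoupler reserve, and the rotenone-sensitive
  N-pathway share (`NS_E - S_E`).

Substrate concentrations (GM 10/2 mM, ADP 2.5 mM, H~2~O~2~ 500 µM,
pyruvate 5 mM, succinate 10 mM, FCCP 0.5 µM steps, rotenone 0.5 µM,
malonate 5 mM, antimycin A 2.5 µM) are protocol metadata; they never
enter computation.

## mtDNA annotation

The gene model embeds the 37-gene human mitochondrial annotation on
rCRS (NC_012920) coordinates, 1-based inclusive, with the control region
represented as the two segments 16024–16569 and 1–576 around the
replication origin. Codon index for a protein-gene SNV is
`ceiling(offset / 3)` with the offset counted on the coding strand;
light-strand genes (MT-ND6, several tRNAs) are annotated with
complemented alleles. Incomplete terminal stop codons (`T` or `TA`, e.g.
MT-ND4 or MT-CO3) are completed with A's, mirroring polyadenylation.
Variants at the rCRS placeholder position 3107 are rejected as reference
mismatches. Only SNVs are supported; indels raise a typed error.

**The shipped reference sequence is a synthetic stand-in.** The package
ships `inst/extdata/synthetic_rcrs.fa`, generated deterministically by
`build_synthetic_reference()`: real rCRS gene coordinates, valid
vertebrate-mitochondrial open reading frames (including both frames of
the MT-ATP8/MT-ATP6 and MT-ND4L/MT-ND4 overlaps), incomplete stops where
the real genes use them, and documented example codons pinned (e.g. the
phenylalanine codon at MT-ND4 position 411). Coordinate-level outputs —
gene membership, codon indices, region classes — are exact for real rCRS
positions; base-level outputs (reference bases, specific amino acids at
arbitrary positions) reflect the synthetic sequence. Users with the true
NC_012920 FASTA can pass it via the `genome` argument throughout.

Classification into the coding/control dichotomy treats rRNA and tRNA
genes as coding (sub-classified as `rRNA`/`tRNA`), since the study's
coding/non-coding split contrasts the D-loop with everything else.

## Heteroplasmy processing

Calls are merged across duplicate sequencing runs: a variant must occur
in two different runs of a sample, and its heteroplasmy level is the
mean variant allele frequency (VAF) across runs. Filters: level above
2% (`min_vaf`), more than 10 reads per strand for acceptance (5 is the
detection-time setting; both configurable), and forward/reverse VAF
concordance. The strand-bias rule is not specified numerically in the
source protocol, so the default is
`|VAF_fwd - VAF_rev| <= max(0.1, 3 x binomial SD)` and can be disabled
(`strand_tolerance = Inf`). Records at or above 95% level are labeled
homoplasmic and excluded from heteroplasmy counts.

Variants present in both tissues of a pair are `shared`; otherwise
`private_benign`/`private_cancer`. Non-synonymous variants in MT-ND,
MT-CO or MT-CYB genes are flagged *potentially deleterious* (ATP-synthase
genes are excluded by that definition). Allele-frequency strata use
left-closed bins `[thr, 0.10)`, `[0.10, 0.20)`, `[0.20, 0.50)`,
`[0.50, 1]` — a level of exactly 10% falls in 10–20%. The Complex-I
stratum of a sample (`none`, `30-60%`, `>60%`) derives from the maximum
non-synonymous CI-gene level.

## Copy number

Copies per diploid cell from the duplex qPCR (mitochondrial MT-TL1 vs
nuclear B2M amplicon) with a plasmid calibrator:

$$\mathrm{CN} = 2 \cdot E^{-\Delta\Delta C_q}, \qquad
  \Delta\Delta C_q = (C_{q,\mathrm{mt}} - C_{q,\mathrm{n}})_\mathrm{sample}
  - (C_{q,\mathrm{mt}} - C_{q,\mathrm{n}})_\mathrm{plasmid}.$$

`E` defaults to 2 (perfect doubling) because the assay uses a plasmid
standard rather than a measured per-assay efficiency; it is a config
key.

## Statistics

Paired comparisons gate on a Shapiro–Wilk test of the pairwise
differences at `alpha = 0.05`: normal-looking differences use the paired
t-test, otherwise the Wilcoxon signed-rank test. Families of state
comparisons are Holm-corrected; expression screens use
Benjamini–Hochberg. Both corrections are thin wrappers over
`stats::p.adjust` and are verified against definitional step-up/step-down
implementations in the test suite. `fisher_2x2()` reports the exact
two-sided p (point-probability rule) together with *both* odds-ratio
estimators — the sample cross-product ratio and the conditional MLE —
because published 2x2 summaries are ambiguous about which is printed.
The logistic model of heteroplasmy presence uses patient age, free-PSA
percentage and stage (coded pT2/3/4 as the ordered integer 2/3/4; the
coding is not dictated by the data) with per-predictor likelihood-ratio
tests. Capacity comparisons across mutation categories use one-way
ANOVA with Tukey HSD, or the Wilcoxon rank-sum test for two groups.

## Severe respiratory phenotype signature

A malignant sample is `severe` when its relative GM capacity
(`GM_P`/`NS_E`) is at or below 0.27 — the cohort mean of that ratio —
and `mild` above it.

* **Metagene extraction.** Candidate genes (a DE-derived list of genes
  overexpressed in severe tumors) are correlated with the binary severe
  indicator (point-biserial r; correlating against the continuous ratio
  is available via `against = "gm_fcr"`). Genes with `r > 0.4` and
  BH-adjusted correlation-test `p < 0.05` form the signature.
  Expression is log2(x+1)-transformed unless flagged as already log.
* **Score.** The per-subject score is the mean of gene-wise z-scores —
  the source describes no formula, so the simplest standardized average
  was chosen and documented; a first-principal-component alternative
  (`method = "pc1"`, sign-aligned with the mean z-score) is provided.
* **Cut-point.** Candidates are the observed scores inside the inner
  80% quantile band. Each split's log-rank p is corrected for the
  multiplicity of the search — BH across the candidate set by default,
  with the Lausen–Schumacher maximally-selected-statistic bound as an
  option (the source names neither). The cut with minimal corrected p
  wins; ties break by the larger Harrell's C (a lexicographic rule;
  whether the original selection was joint or lexicographic is
  unknowable from the text). Splits leaving a group without events are
  unselectable, and the full candidate audit table is returned.
* **Survival.** Kaplan–Meier curves, the hazard ratio from a
  proportional-hazards fit on the group indicator (stratified by cohort
  in meta-analysis settings), the stratified log-rank test, and
  uni-/multivariate Cox models with binary clinical covariates.
  Harrell's C is computed over usable pairs with ties counted 0.5 and is
  cross-checked against `survival::concordance` and an explicit
  all-pairs loop in the tests.

Under the global null, BH across the (positively correlated) candidate
log-rank tests keeps the rate of corrected p < 0.05 near the nominal 5%;
the test suite verifies ≤ ~7% over 500 null replicates.

## Synthetic cohort

The generators in `cohort_spec()` define the study conditions used by
every test:

* **Respirometry.** 50 pairs, 20% high-grade. Programmed means encode
  the published effect directions and magnitudes: ADP effect 4.5
  (benign) vs 2.4 (tumor) pmol s^-1^ mg^-1^, stress decrement 1.1 vs
  1.7, a larger tumor succinate gain, similar NS capacities, and a tumor
  relative GM capacity averaging ~0.27 (SD ~0.1, carried by a
  log-normal per-sample N-pathway integrity factor with log-SD 0.35).
  Noise is multiplicative: a shared within-pair capacity factor
  (CV 0.15) that cancels in FCRs, plus 8% per-state residual.
* **Heteroplasmy.** Per-patient Poisson counts with means 1.68
  private-cancer, 0.66 private-benign and 0.60 shared variants —
  matching the published per-50-patient totals (84/33/~30). Positions
  are uniform over the genome (so the MT-ND gene-size/count correlation
  emerges without hotspots), levels follow Beta(0.3, 2) truncated at the
  2% threshold (mostly low-level variants, a minority above 50%), runs
  are jittered by SD 0.01, and strand reads are binomial at depth 200
  per strand per run. The three documented example variants can be
  spiked in.
* **qPCR.** Log-normal true copy numbers (median 310, log-SD 0.35,
  range ~150–700), Gaussian Cq noise (SD 0.1 cycles) on the sample
  wells; the plasmid calibrator is reported noise-free, as a
  once-per-plate standard.
* **Expression/survival.** 500 subjects, 1000 genes, 11 planted genes
  shifted by 1.96 log2-SD in severe subjects (point-biserial r ≈ 0.7),
  exponential survival with hazard 0.08 (severe) vs 0.04 (mild) — a true
  mild-vs-severe hazard ratio of 0.5 — and exponential censoring at rate
  0.03 (~30% censoring).

Every generator takes a seed and is bit-reproducible. What passing
tests on this cohort establish: the pipeline recovers programmed
effects of realistic size at the study's sample sizes, controls its
error rates under the null, and is internally consistent against
independent oracles. What they do not establish: behavior under real
instrument drift, alignment artifacts, contamination, non-exponential
hazards, or cohort batch effects — none of which the generators
emulate.

### Problem sizes in the tests

The suite runs the metagene-recovery property at 24 samples (the
smallest size at which the r > 0.4 + BH selection rule recovers ≥9/11
planted genes in ≥90% of replicates; at 16 samples the rule itself
caps recovery near 57%), hazard-ratio recovery at n = 500 over 100
replicates, the cut-point null calibration at n = 60 over 500
replicates, the paired substrate-shift power property at 50 pairs over
200 replicates, and the end-to-end signature recovery at n = 500 with
200 genes over 100 replicates.

## Worked example

```{r example}
ann <- mt_annotate_variant(c(11991, 13495, 10551),
                           c("T", "A", "T"), c("C", "G", "C"))
ann[, c("pos", "gene", "codon_index", "ref_aa", "alt_aa", "synonymy")]
```

The three documented substitutions — F411S in ND4, T387A in ND5 and
S28P in ND4L — fall out of the gene model and the vertebrate
mitochondrial code.

## Known limitations

* The reference sequence is synthetic (above); only coordinate-level
  annotation is exact against real rCRS data.
* No instrument-binary (DatLab) parsing, oxygen-solubility calibration,
  read alignment, variant calling, haplogroup logic or pathogenicity
  scoring: those stages produce this package's *inputs*.
* The metagene score formula and the cut-point correction are this
  package's documented choices among unstated alternatives; both are
  swappable through arguments, and external reproductions of published
  hazard ratios are sensitive to them.
* `fisher_2x2` reports two odds-ratio estimators precisely because a
  printed OR of a 2x2 table may be either; downstream code must choose
  explicitly.
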