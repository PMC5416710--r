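---
title: "Methods: Mendelian randomization of telomere length on cognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomization of telomere length on cognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telomr)
```

## The design

Leukocyte telomere length (TL), measured by qPCR as a T/S ratio, correlates
with cognitive performance in observational data, but both quantities share
many causes. The Mendelian randomization (MR) design replaces the measured
exposure with a genetic instrument: an unweighted count of
telomere-shortening alleles at seven loci (a genetic risk score, GRS,
ranging 0–14). Three per-cohort regressions feed the analysis —
observational TL–trait, first-stage GRS–TL, and reduced-form GRS–trait —
and the causal (instrumental-variable) effect of a one-s.d. change in TL on
a trait is the Wald ratio of pooled reduced-form to pooled first-stage
estimates. The contrast between the observational and IV estimates is
itself informative: under a valid instrument, a significant difference
indicates confounding of the observational association.

## The structural model behind the generator

`simulate_cohort()` draws each individual from a linear-Gaussian structural
model chosen as the simplest one consistent with the analysis assumptions
(all analysis stages are linear regressions, and the confounder enters both
equations additively):

* genotypes: independent Binomial(2, eaf) hard calls per locus (no linkage
  disequilibrium between the seven loci, which is also what the unweighted
  score assumes);
* latent standardized TL:
  `TL = Σ_j β_j (G_j − 2 eaf_j) + γ U + s_a (age − ā) + ε_TL`,
  with a single standard-normal confounder `U`;
* raw T/S ratio: `tl_raw = μ_lab + σ_lab · TL`, floored at 0.01 (a T/S
  ratio is a ratio of positive quantities); the location/spread pair is
  lab-specific, which is exactly why the analysis Z-transforms within
  cohort;
* each available trait:
  `Y_t = θ*_t Z(TL) + λ U + a_t (age − ā) + b_t 1[female] + c_t 1[ε4] + ε_t`,
  where `θ*_t` is the causal effect, multiplied by a configurable modifier
  in APOE ε4 carriers; APOE genotypes are two independent allele draws with
  frequencies ε2 0.08 / ε3 0.77 / ε4 0.15.

### Default parameter choices

The defaults are fixed once and encode the study conditions rather than
tuning knobs:

* **Cohort structure** (`table1_configs()`): the published per-cohort sizes
  (163–4117, total 17 052), age means/s.d.s, sex ratios, raw T/S scales
  (0.68–3.7) and trait-availability pattern.
* **Per-allele TL effect** −0.05 s.d. per counted allele at every locus:
  reproduces the magnitude of the reported pooled first stage
  (−0.048 s.d./allele) without asserting unpublished per-SNP values. The
  counted allele is defined as the telomere-*shortening* allele, which is
  what makes the pooled GRS–TL slope negative.
* **Counted-allele frequencies** (0.18, 0.30, 0.50, 0.625, 0.78, 0.92,
  0.97): chosen so the Hardy–Weinberg score mean `Σ 2·eaf = 8.55` and
  s.d. `√(Σ 2·eaf(1−eaf)) ≈ 1.49` match the reported GRS mean 8.55 and
  s.d. 1.51. These are placeholders with the right moments, not published
  frequencies.
* **Noise scales**: TL residual s.d. 0.9 and confounder loading 0.3 put the
  latent TL variance near 1, so the per-allele truth is approximately on
  the standardized scale the analysis reports; trait residual s.d. 0.95
  similarly. TL declines 0.02 s.d./year of age; traits decline 0.01–0.015
  s.d./year (STROOP, an interference *time*, increases), all within the
  range reported for ageing cohorts.
* **Causal effects** default to small values of the observed sign
  (+0.03…+0.05 for positively scored traits, −0.06 for STROOP); tests that
  need a null or a specific effect set `theta` explicitly.

What the generator deliberately does **not** emulate: linkage
disequilibrium, twin/family clustering within cohorts (several source
studies are twin registries), measurement batch effects beyond a global
lab scale, tissue differences (blood vs saliva), and longitudinal telomere
attrition. Passing tests therefore demonstrate the statistical machinery
under the stated structural model, not robustness to those real-data
complications.

## Analysis choices

* **Z-transform** uses the sample s.d. (n−1) and is computed within cohort
  — and within stratum for APOE-stratified runs — since raw T/S scales are
  lab-specific and incomparable.
* **Age groups** 0–29 / 30–59 / 60–79 / 80+ enter as dummies with the
  youngest *present* group as reference; single-age cohorts simply drop the
  age terms (rank-deficient columns are removed with a warning, not an
  error).
* **Missing data**: listwise deletion within each model; the GRS imputes
  missing dosages at `2·eaf` by default (a `drop` policy is available for
  sensitivity analysis).
* **Minimum stratum size** 30 complete cases before fitting — arbitrary but
  fixed, logged, and configurable; smaller strata are skipped with a
  recorded message rather than fitted unstably.
* **Meta-analysis**: fixed-effect inverse variance, with a switch to
  DerSimonian–Laird random effects when Cochran's Q has P < 0.05. The
  random-effects variant had to be pinned down (method-of-moments DL);
  REML/Paule–Mandel alternatives are out of scope. CIs use beta ± 1.96·se
  and p-values are two-sided normal; no multiple-testing correction is
  applied by default.
* **Common first stage**: the Wald denominator is the GRS–TL estimate
  pooled over *all* cohorts in the stratum (trait label `"ALL"`), giving
  one instrument and one F statistic shared by every trait, rather than a
  trait-specific first stage restricted to that trait's cohorts. The
  per-trait GRS–TL estimates remain available in the estimates table.
* **IV standard error**: first-order delta method,
  `sqrt(se_GY²/β_GX² + β_GY² se_GX²/β_GX⁴)`. Reconstructing the published
  STROOP IV interval from this formula and the printed inputs agrees to
  rounding, supporting the choice.
* **Difference test**: `z = (β_obs − β_IV)/√(se_obs² + se_IV²)`, treating
  the two estimates as independent. In one-sample data they are correlated,
  so this is an approximation — but it reproduces all six published Diff-P
  values exactly after rounding, and is therefore taken as the reference
  procedure.
* **Weak instruments**: `wald_iv()` refuses first stages with |z| < 2
  (configurable), naming the F statistic. The default study design never
  approaches this floor (simulated F ≈ 95 at full size).
* **Palindromic SNPs**: A/T and C/G pairs with effect-allele frequency in
  [0.4, 0.6] are refused as strand-ambiguous; outside that band the
  frequency side decides orientation.
* **F statistic**: computed as `(β/se)²` of the pooled first stage. From
  the printed pooled estimate and CI this gives 34.6, whereas the
  publication reports F = 36; the published computation (possibly a
  first-stage regression F on individual-level data) is not recoverable
  from printed quantities, and no attempt is made to force agreement.

## Numerical and reproducibility choices

All stochastic operations require an explicit integer seed; per-cohort
streams are derived as `seed + seed_offset`, so a multi-cohort dataset is a
pure function of (configs, truth, seed) and a full pipeline run with a
fixed seed is byte-identical across invocations. Report files are
tab-separated text with `NA` markers and a `# seed:` header comment.
Degenerate inputs fail loudly: zero-variance Z-transforms, all-missing
dosage columns, non-positive standard errors, unknown APOE strings and
out-of-range dosages are all rejected with located messages.

## Problem sizes used in the checks

The test suite exercises the pipeline at the full published scale where the
property demands it (confounded-null coverage over 1000 replicate 17k
multi-cohort datasets; byte-level determinism of the full stratified run)
and at reduced scale where only calibration is at stake (Cochran-Q
rejection over 500 replicates of twelve 150-person cohorts; null p-value
uniformity over 500 replicate 300-person cohorts; 200-instance
least-squares oracle comparisons). These sizes are the package's chosen
trade-off between Monte-Carlo resolution and runtime.

## Known limitations

The difference test ignores the one-sample correlation between the
observational and IV estimates; the generator's per-SNP effects and allele
frequencies are moment-matched placeholders; family structure is not
modelled, so "study-specific covariates" stand in for relatedness
adjustments; and the two-sample module assumes non-overlapping GWAS samples
(overlap-induced bias corrections are out of scope).
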