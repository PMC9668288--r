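---
title: "Rare-variant collapsing analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant collapsing analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The method

Gene-level collapsing analysis asks whether carriers of rare *qualifying
variants* (QVs) in a gene are enriched or depleted among cases of a binary
trait, or shifted in a quantitative trait, relative to noncarriers. Because
individual rare variants are underpowered, all QVs in a gene are collapsed to
a single per-sample indicator and tested jointly. `rvburden` implements the
complete chain: per-genotype and per-site quality control, a registry of QV
models spanning a range of genetic architectures, carrier coding (dominant;
recessive including homozygous, X-linked hemizygous and phase-blind putative
compound-heterozygous carriers), the association tests, stratified
meta-analysis across ancestries or cohorts, and the follow-up analyses used to
dissect a hit (conditional joint regression, leave-variants-out collapsing,
risk-haplotype effect modification, pairwise LD).

### Association tests

* **Binary traits.** Carriers vs noncarriers are compared with the exact
  conditional (hypergeometric) two-sided test, using the minimum-likelihood
  two-sided rule. Controls are first sex-matched to the cases whenever the
  female fractions differ (two-sided exact p < 0.05): the surplus sex among
  controls is randomly down-sampled (seeded) until the fractions agree to
  within one sample. The reported odds ratio is the cross-product ratio with
  the Haldane–Anscombe 0.5 correction applied to all four cells iff any cell
  is zero, and a Woolf log-OR normal 95% CI. The exact-test p rule and the CI
  method are package conventions (they are rarely printed in publications);
  both are labelled in output.
* **Quantitative traits.** Phenotypes are rank-based inverse-normal
  transformed (Blom offsets, `(r − 3/8)/(n + 1/4)`; ties share average ranks)
  so effects are in SD units, then regressed on the carrier indicator with
  covariates — age and sex by default, a medication indicator for blood
  pressures, BMI when configured.
* **Meta-analysis.** Per-ancestry 2×2 tables are combined with the
  Cochran–Mantel–Haenszel test (no continuity correction by default — it
  matters at rare-carrier scale — switchable via `correct`); the common OR is
  Mantel–Haenszel with a Robins–Breslow–Greenland variance CI. Pooled
  quantitative analysis instead fits one linear model with categorical
  ancestry and five principal components. Effect modification between two
  strata is tested with Cochran's Q on the two log-scale estimates,
  `Q = (b₁ − b₂)²/(se₁² + se₂²)` on 1 df; a helper back-derives SEs from
  printed ratio-scale CIs.
* **Calibration.** Genomic inflation λ is the median χ²(1) quantile of the
  observed p-values divided by the χ²(1) median.

### Quality control

Two threshold profiles are bundled (`qc_thresholds`): one for collapsing
analysis, one for single-variant exome-wide testing (ExWAS). They differ in
the heterozygous alt-fraction window ([0.25, 0.8] vs ≥ 0.2), the external
reference coverage floor (25% vs 30%), and ExWAS-only site missingness (<10%)
and fail-fraction (<5%) rules. Failing genotypes are set to missing rather
than dropping the site, which matches carrier-counting semantics downstream.

One published filter — "at most 80% alternate reads in homozygous genotypes" —
reads inverted relative to its evident intent: real homozygous-alt calls have
alt fractions near 1, so the literal rule would erase every homozygous and
hemizygous genotype and make recessive analysis impossible. Both readings are
implemented behind `hom_alt_rule`: `"as_printed"` (≤ 0.8), `"at_least"`
(≥ 0.8) and `"off"`. The pipeline default is `"at_least"`; this is this
package's own engineering choice, not a claim about what the original
framework executed.

### Qualifying-variant models

The registry holds 10 nonsynonymous models (9 dominant, 1 recessive) plus a
synonymous negative control. Consequence classes use the published SnpEff term
sets verbatim (11 PTV terms; 18 nonsynonymous). The recessive model admits
nonsynonymous variants with internal and external MAF < 1% (strict
inequality). The per-model frequency/score parameters of the nine dominant
models are not printed in the main text of the source analysis; the defaults
here are package conventions under the original model names (`ptv`,
`ptv5pcnt`, `UR`, `URmtr`, `flexdmg`, `flexnonsyn`, `flexnonsynmtr`,
`raredmg`, `ptvraredmg`), are documented in `qv_model_registry()`, are fully
config-overridable, and are echoed field-for-field into every results header
so a run is always interpretable.

## The synthetic cohort generator

No individual-level biobank data can ship with a package, so `generate_cohort`
draws cohorts with the statistical structure the analysis assumes:

* ancestry strata with configurable sizes and per-stratum carrier-frequency
  targets; genotypes at Hardy–Weinberg proportions within stratum (verified by
  goodness-of-fit tests), X-linked males drawing a single allele (hemizygous
  dosage coded 2);
* per-gene allelic spectra proportional to 1/i^1.5 with an optional per-variant
  frequency cap (`max_maf`) that redistributes excess mass over rarer variants
  — the emulated protective gene spreads a ~3.5% cumulative male allele
  frequency over ~40 truncating variants, the most frequent at MAF 0.35%;
* binary phenotypes from a logistic model (terms: sex, age, per-gene carrier
  status under its zygosity mode, haplotype carriage, haplotype×gene
  interaction), with the intercept solved by root-finding so the realized
  prevalence matches the configured value;
* quantitative traits as effect sums plus unit Gaussian noise, so configured
  effects are in SD units (the generative model for biomarkers is an
  assumption — the source analysis states effects only in SD units);
* an optional common risk haplotype carried as one phased tag variant
  (default frequency 30%, marginal OR 1.37) whose interaction term can
  abolish a gene's protective effect in haplotype carriers (default regime:
  OR 0.45 in noncarriers, 1.11 in carriers);
* a truth table of every generative parameter plus the seed, for recovery
  tests; one global seed with per-component substreams.

Defaults describe the regime of the motivating analysis: an X-linked
recessive protective gene at 1.77% carrier frequency, diabetes OR 0.70,
HbA1c effect −0.14 SD, 8.5% prevalence, ages 40–70, mild sex (log-OR 0.3) and
age (0.35 per decade) effects on disease. Sample sizes are whatever the test
at hand states. What the generator does **not** emulate: sequence content and
read-level error, relatedness, linkage between genes, imputation uncertainty,
ancestry-specific LD. A green simulation test therefore establishes the
statistical machinery, not robustness to those real-data features.

### Marginal vs conditional odds ratios

The generator's carrier log-OR is *conditional* on age and sex. The Fisher
cross-product OR — even on sex-matched controls — estimates a *marginal*
quantity, and odds ratios are non-collapsible: with covariate effects present
the marginal OR is attenuated toward 1 (here ≈ −0.32 vs ln 0.70 = −0.357, an
effect confirmed against a large-n glm oracle showing the generator itself is
unbiased). Parameter-recovery tests therefore use the covariate-adjusted
logistic estimator — the same model family the replication, stratified and
conditional analyses use — which recovers the generative parameter without
bias. This distinction is a property of odds ratios, not an implementation
artifact, and is worth remembering when comparing published marginal ORs with
model-based ones.

### A known red calibration bound

One acceptance check fixes 2,000 null genes at n = 20,000 and expects genomic
λ ∈ [0.95, 1.05] plus type-I error within the binomial CI of 0.05. Exact
conditional p-values on rare-carrier tables are discrete and conservative: at
~1% carriers and 8.5% prevalence the expected case-carrier count is ~17, the
p-value distribution is visibly sub-uniform, and λ lands near 0.85–0.89 — an
independent oracle using `stats::fisher.test` on hypergeometric draws
reproduces this without any package code. λ ≈ 1 emerges only at
biobank-scale carrier counts (hundreds of expected case carriers). The test
is implemented exactly as stated and is expected to fail at this sample
size; the generator was not adjusted to chase it.

## Numerical choices

* Exact-test tie handling uses the `(1 + 1e-7)` relative tolerance when
  summing outcome probabilities (the `fisher.test` convention); p-values are
  clamped to ≤ 1.
* The LD EM starts at linkage equilibrium and stops when the log-likelihood
  changes by < 1e-10 or after 1,000 iterations (then errors, reporting the
  final log-likelihood). Only the double heterozygote is phase-ambiguous.
* Compound-heterozygote calling is phase-blind: ≥ 2 distinct heterozygous QVs
  (same-position variants counted once) are presumed trans. The generator can
  simulate a cis fraction (`comphet_cis_frac`) to probe the resulting
  misclassification; the default is 0.
* Samples with missing genotypes at QV sites contribute as noncarriers; they
  are not excluded from the gene's test.
* Constant input to the inverse-normal transform is an error; `NA`s pass
  through untransformed.
* Logistic separation is detected as runaway estimates (|estimate| > 10 with
  SE > 10) and flagged rather than silently returned.
* Study-wide significance is flagged at p < 1e-8 (fixed threshold, no FDR
  machinery).

## Limitations

Single-variant and gene-level tests here are unrelated-sample methods: no
mixed models, no relatedness correction, no imputation dosages. The CMH CI
method and the exact-test two-sided rule are conventions where the source
analysis is silent. ExWAS "identified in at least six individuals" is read as
≥ 6 carriers of ≥ 1 alternate allele, and X-male genotypes contribute one
allele under the allelic model; both readings are logged per variant and
documented because the original choices are unstated.
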