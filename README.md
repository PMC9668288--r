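# rvburden

Gene-level rare-variant collapsing association analysis for exome cohorts,
with stratified meta-analysis, effect-modification follow-ups and a synthetic
cohort simulator.

## Who this is for

Statistical geneticists running (or teaching) biobank-style case–control and
quantitative-trait burden analyses: the setting where individually rare
protein-coding variants — e.g. protein-truncating variants (PTVs) in a gene
that protect against disease — are aggregated per gene into a carrier
indicator and tested jointly because no single variant has power. The
motivating use case is an X-linked recessive protective architecture:
hemizygous/homozygous/compound-heterozygous carriers of rare nonsynonymous
variants at ~1.8% carrier frequency reducing the odds of a common disease by
~30% (OR ≈ 0.70) and lowering a biomarker by ~0.14 SD, with a common risk
haplotype that abolishes the effect in its carriers.

## What it computes

For carriers *C* vs noncarriers of qualifying variants (QVs) in a gene:

* **Binary traits** — Fisher's exact two-sided test on the 2×2
  carrier-by-case table with sex-matched controls; OR = *ad/bc* with
  Haldane–Anscombe correction when a cell is zero, Woolf 95% CI.
* **Quantitative traits** — rank-based inverse-normal transformation
  (Blom: Φ⁻¹((r − 3/8)/(n + 1/4))), then OLS of the trait on the carrier
  indicator with age, sex and configured covariates; β in SD units.
* **Carrier coding** — dominant (≥ 1 QV allele) or recessive: homozygous, or
  hemizygous X-linked male (dosage coded 2), or ≥ 2 distinct heterozygous QVs
  (phase-blind putative compound heterozygote).
* **Pan-ancestry** — Cochran–Mantel–Haenszel 2×2×N:
  OR_MH = Σ(aᵢdᵢ/nᵢ) / Σ(bᵢcᵢ/nᵢ), χ² = (Σaᵢ − ΣE[aᵢ])² / ΣV[aᵢ] on 1 df,
  Robins–Breslow–Greenland CI; pooled linear models with categorical ancestry
  + 5 PCs for quantitative traits.
* **Effect modification** — per-stratum logistic/linear fits and Cochran's
  Q = (b₁ − b₂)²/(se₁² + se₂²), χ²(1).
* **Diagnostics** — genomic inflation λ = median(χ²₁(1−p)) / 0.4549, QQ data.
* **Follow-ups** — conditional joint regression on several variant
  indicators, leave-variants-out collapsing, dominant single-SNP logistic
  models, pairwise LD (D, D′, r²; closed form for phased haplotypes, EM for
  unphased genotypes).

Variant-level ExWAS tests (allelic / dominant / recessive / genotypic, ≥ 6
carriers) mirror the gene-level machinery.

## Worked example

Simulate the default world (one X-linked recessive protective gene, carrier
frequency 1.77%, diabetes OR 0.70, HbA1c −0.14 SD; one null autosomal gene)
and run the recessive and synonymous-control models:

```r
library(rvburden)
cfg <- sim_config(n = 50000, call_metrics = FALSE)
sim <- generate_cohort(cfg, seed = 42)
res <- run_collapsing(sim$samples, sim$genotypes, sim$variants,
                      list(phenotype_spec("diabetes", "binary"),
                           phenotype_spec("hba1c", "quantitative")),
                      models = c("rec", "syn"), seed = 42)
res[1:4, c("gene","model","phenotype","case_carrier","control_carrier",
           "f_ctrl","or","ci_lo","ci_hi","beta","p")]
#>        gene model phenotype case_carrier control_carrier   f_ctrl    or  ci_lo   ci_hi   beta      p
#> 1   GENE_XR   rec  diabetes           72             780 0.019487 0.879  0.689  1.1212     NA 0.3159
#> 2 GENE_NULL   rec  diabetes            0               1 0.000025 3.181  0.130 78.0946     NA 1.0000
#> 3   GENE_XR   rec     hba1c           NA              NA       NA    NA -0.169 -0.0334 -0.101 0.0034
#> 4 GENE_NULL   rec     hba1c           NA              NA       NA    NA -1.344  2.5548  0.605 0.5429
```

Row 1: 852 recessive carriers, control carrier frequency 1.95%, OR 0.88 — a
single 50k cohort is underpowered for OR 0.70 (the paper-scale signal needs
~400k samples; across 200 replicate seeds the covariate-adjusted log-OR
averages ln 0.70, see `tests/testthat/test-acceptance.R`). Row 3: the HbA1c
effect −0.10 SD (95% CI −0.17 to −0.03), consistent with the simulated −0.14.
Rows 2/4: the null gene is flat, and `syn` rows (not shown) are labelled
`negative_control`.

Reproduce a printed effect-modification test from its confidence intervals:

```r
h <- heterogeneity_test(log(0.45), se_from_ci(0.28, 0.69),
                        log(1.11), se_from_ci(0.86, 1.40))
#> Q = 11.92   p = 0.00056
```

## Command line

```sh
Rscript inst/cli/rvburden simulate --out cohort --n 10000 --seed 1
Rscript inst/cli/rvburden qc --in cohort --out cohort_qc --profile collapsing
Rscript inst/cli/rvburden collapse --in cohort_qc \
    --phenotypes diabetes:binary,hba1c:quantitative --out results
Rscript inst/cli/rvburden exwas --in cohort_qc --phenotype diabetes:binary --out exwas.tsv
Rscript inst/cli/rvburden meta --in cohort_qc --phenotypes diabetes:binary \
    --by ancestry --out meta_results
Rscript inst/cli/rvburden run --out full_run --n 20000 --seed 7
```

Inputs/outputs are VCF 4.2 (GT:DP:GQ:AD) plus TSV annotation, phenotype and
truth tables; results are TSV with a JSON run manifest (inputs, checksums,
model registry, thresholds, seed, row counts).
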