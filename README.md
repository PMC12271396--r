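# AdmixScreen

Admixture inference and ancestry-enriched variant screening for cohorts
assembled from heterogeneous genomic variant datasets.

Population cohorts in admixed countries are often stitched together from
sources characterized on different platforms — genotyping arrays (WGG),
whole-exome (WES) and whole-genome (WGS) sequencing — each contributing a
different site set with different missingness. AdmixScreen provides the
full analysis path for such cohorts:

1. **Harmonize** — normalize variant identities to `chrom:pos:ref:alt`,
   union-merge datasets on that key, remove duplicates/relatives with a
   structure-robust kinship estimator, apply missingness and MAF filters,
   and rank sites by cross-dataset occupancy.
2. **Infer ancestry** — reference-panel PCA with sample projection;
   three-way (African / Indigenous American / European) ancestry fractions
   by EM on the admixture likelihood

   ℓ(Q,P) = Σᵢⱼ [gᵢⱼ log Σₖ qᵢₖ pₖⱼ + (2−gᵢⱼ) log Σₖ qᵢₖ(1−pₖⱼ)],

   with a provably monotone likelihood trace; categorical ancestry groups
   by K-means on the Q rows with an elbow (log-inertia curvature)
   criterion, and dominance-based cluster naming (AFR/AME/EUR/ADX1/ADX2).
3. **Screen** — for every site, a two-sided exact test on the 2×k table of
   reference/alternate allele counts across ancestry clusters
   (branch-and-bound enumeration with certified bounds and seeded
   Monte-Carlo fallbacks), the multi-group weighted fixation index
   F_ST = 1 − H̄_S/H_T, Poisson `genotype ~ ancestry` regressions, and a
   genome-wide threshold (default P < 5×10⁻⁸).
4. **Report** — diagnostic yield D (percentage of carried variants with
   uncertain / conflicting / pathogenic-or-likely-pathogenic annotations)
   per ancestry group, pharmacogenomic evidence-level filtering, and
   per-dataset allele-frequency summaries.

A synthetic-cohort generator (Balding–Nichols ancestral divergence,
Dirichlet admixture clusters, platform site masks, sparse annotation
catalog, planted strongly-divergent variants) provides ground truth for
every stage, so the whole pipeline is testable without any private data.

## Worked example

```r
library(AdmixScreen)

res <- runPipeline(defaultPipelineConfig(), seed = 1)
res$summary
```

With the default configuration (300 samples, 8,000 sites, three platforms)
and seed 1 this prints, among other fields:

```
$n_samples      298          # two planted duplicates were removed
$n_sites        4145         # after missingness and MAF filters
$mean_ancestry  AFR 0.166, AME 0.340, EUR 0.495
$chosen_k       5            # elbow on K-means of the Q matrix
$n_hits         124          # sites with exact-test p < 5e-8
$n_clinical_hits 13
$n_pharm_hits   10
```

The cohort-mean ancestry recovers the generator's calibration (16.7%
African, 32.8% Indigenous American, 50.6% European), the elbow finds the
five planted ancestry clusters, and the screen's top hits are the planted
divergent variants — e.g. the strongest clinical hit is a planted
pathogenic-annotated site with fisher_p ≈ 1e-34, F_ST ≈ 0.24, enriched in
the EUR cluster. Individual stages are available as plain functions
(`unionMerge()`, `fitAdmixtureEm()`, `kmeansElbow()`, `screenGenome()`,
`diagnosticYield()`, …) operating on `GenotypeCohort` objects
(SummarizedExperiment subclasses); `writeCohortVcf()` / `readCohortVcf()`
round-trip VCFv4.2.

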