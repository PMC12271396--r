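---
title: "Models and methods: admixture inference and ancestry-enriched variant screening"
author: "AdmixScreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

AdmixScreen analyses cohorts assembled from heterogeneous genomic variant
datasets — genotyping arrays (WGG), exome sequencing (WES) and genome
sequencing (WGS) — for the relationship between continental ancestry and
clinically annotated variation. This vignette documents the statistical
models, the tunable parameters, the numerical choices, and what the bundled
synthetic cohorts do and do not establish about real data.

## The generative model behind the synthetic cohorts

Because cohorts of this kind are typically private, every stage of the
pipeline is exercised on synthetic data with known ground truth. The
generator composes four standard population-genetics ingredients:

1. **Ancestral allele frequencies** follow a Balding–Nichols model: for each
   site a base frequency $p$ is drawn (uniform on $(0.05, 0.95)$ by default,
   so sites stay informative), and each of the $K=3$ ancestral populations
   (AFR, AME, EUR) receives a frequency from
   $\mathrm{Beta}\!\big(p\tfrac{1-F}{F},\,(1-p)\tfrac{1-F}{F}\big)$, which
   has mean $p$ and variance $F\,p(1-p)$. The divergence default $F = 0.15$
   per population reflects continental-scale differentiation among African,
   Indigenous American and European reference panels.
2. **Admixture profiles** come from a five-cluster mixture on the ancestry
   simplex. Each sample joins a cluster by its mixing weight and draws its
   ancestry vector from $\mathrm{Dirichlet}(c \cdot \text{centroid})$. The
   default weights (149, 75, 232, 603, 350)/1409 and centroids are
   calibrated so the weighted cohort mean is approximately 16.7% African,
   32.8% Indigenous American and 50.6% European ancestry, with one
   European-leaning admixed cluster (ADX1) and one Indigenous-American-
   leaning admixed cluster with a minor African component (ADX2). The
   concentration default $c = 100$ (per-component spread ≈ 0.05) was chosen
   once so that the five groups form a dispersed but separable cloud, the
   structure the clustering stage is meant to detect; at much smaller $c$
   the admixed clusters genuinely merge and no method could (or should)
   find five groups.
3. **Genotypes** are drawn as $g_{ij} \sim \mathrm{Binomial}(2, \pi_{ij})$
   with $\pi_{ij} = \sum_k q_{ik} p_{kj}$ — each allele copy descends from
   an ancestral population chosen by the sample's ancestry fractions.
4. **Platform structure**: datasets receive site subsets (arrays ~45% of
   sites, exomes ~20%, genomes all) and independent missing-completely-at-
   random genotype dropout (2%/5%/1%). A handful of *planted divergent
   sites* (one population near fixation for the alternate allele, the
   others near zero, mimicking variants such as the Duffy-null
   malaria-resistance allele) are always included on every platform — the
   clinically annotated content that arrays and exome capture deliberately
   target — and carry pathogenic or high-evidence pharmacogenomic
   annotations in the simulated catalog.

What the synthetic cohorts deliberately omit: linkage disequilibrium
(sites are independent given ancestry), phasing, indels and multiallelic
records, sex chromosomes, batch effects, and any dependence of annotation
on ancestry. Passing tests therefore demonstrate algorithmic correctness
under the stated model, not robustness to LD structure, allele-coding
inconsistencies between real platforms, or annotation bias; the
missingness-by-platform confounding that real diagnostic-yield comparisons
face is represented only through the site subsets.

## Harmonization

Variants are matched across datasets purely on the normalized
`chrom:pos:ref:alt` key (chr prefixes stripped, alleles upper-cased);
merging is an exact union keyed on that identity, with a sample's genotype
at a site missing from its dataset set to `NA` and per-site *occupancy*
(the number of datasets containing the site) recorded. Strand flips and
allele swaps are out of scope — the generator emits consistent alleles —
and this is a documented limitation for real multi-platform data.

QC order: kinship filter → sample missingness filter → site
missingness/MAF filter → occupancy ranking (→ LD pruning, for ancestry
inference only). Sample-level QC runs first so that per-site statistics
are computed on the de-duplicated cohort. Defaults: sites are dropped at
> 75% missingness or minor-allele frequency strictly below 5% (computed
over non-missing alleles — the union-merge missingness forces this
denominator); samples are dropped above 99% missingness. The 99% default
is unusually permissive but deliberate: in a union-merged multi-platform
cohort most missingness is structural (an array sample is missing at
every non-array site), so an aggressive sample filter would simply delete
the smallest platform. Both thresholds are arguments.

Kinship uses a heterozygote-concordance estimator robust to population
structure, $\varphi = (N_{\text{het,het}} - 2N_{\text{opp,hom}}) /
(N^{(i)}_{\text{het}} + N^{(j)}_{\text{het}})$ over jointly observed
sites: duplicates score ≈ 0.5, first-degree pairs ≈ 0.25, unrelated pairs
≈ 0 even under admixture. Flagging uses the conventional cut points
$2^{-3/2}$ (duplicate) and $2^{-5/2}$ (first degree); the member of a
flagged pair with more missingness is removed. Occupancy ranking keeps
the `topN` sites by occupancy, ties broken by genomic coordinate
(ascending), in global mode by default; a per-dataset mode ranks within
each dataset's site set and unions the selections — the global mode is
the cleaner definition when one merged matrix feeds a single downstream
analysis. LD pruning is a greedy sliding-window filter on squared Pearson
correlation of dosages (window 50 sites, step 5, $r^2 \le 0.5$ for the
pipeline default), with monomorphic sites treated as uncorrelated.

## Ancestry inference

**Reference PCA.** Dosages at panel sites are centered by $2\hat p$ and
scaled by $\sqrt{2\hat p(1-\hat p)}$, missing entries imputed to the
reference mean (zero after centering), monomorphic sites excluded; the
decomposition is the SVD of the standardized matrix. Cohort samples are
projected through the model's loadings, so array/exome samples project
through whatever subset of model sites they observe (a warning fires
below 50% overlap).

**Admixture EM.** Ancestry fractions maximize the binomial admixture
log-likelihood
$$\ell(Q, P) = \sum_{ij}\Big[g_{ij}\log\sum_k q_{ik}p_{kj} +
(2-g_{ij})\log\sum_k q_{ik}(1-p_{kj})\Big]$$
by classical EM updates in which each allele copy's ancestral origin is
latent; both $Q$ and $P$ update each pass, the log-likelihood is provably
non-decreasing, and the trace is exposed so tests assert monotonicity at
every iteration. EM was chosen over quasi-Newton block relaxation for its
simplicity and guaranteed monotonicity; at the package's desk scale
(thousands of sites) its slower convergence is immaterial. Defaults:
`tol = 1e-4` on the log-likelihood gain, `maxIter = 2000`. Missing
genotypes are skipped in the likelihood; monomorphic sites are dropped
with a warning (they carry no ancestry signal and destabilize frequency
updates); frequencies are clamped to $[10^{-6}, 1-10^{-6}]$. With a
labeled reference panel the fit warm-starts by updating $Q$ alone against
panel allele frequencies (also an EM step on the same likelihood, so the
trace stays monotone) before releasing $P$ — this removes most of the
label-switching and drift that a cold unsupervised start incurs — and
components are aligned to (AFR, AME, EUR) by maximal correlation of
inferred frequencies with panel frequencies. Without a panel the
component order is arbitrary and a warning says so.

**Cluster count.** K-means (25 restarts per candidate K) runs on the Q
rows for $K = 1..10$ and the chosen K maximizes the second difference of
the **log** within-cluster sum of squares, ties toward smaller K. The log
scale is a deliberate choice: inertia decays roughly geometrically in K
on clustered data, so the raw second difference peaks at $K = 2\text{–}3$
regardless of the true cluster count — even for arbitrarily tight,
well-separated clusters — whereas curvature of log-inertia peaks where
the geometric decay breaks, which is the elbow the method name refers to.
Clusters are then named: a centroid whose largest component reaches the
dominance threshold 0.65 takes that ancestry's name (the more dominant
cluster wins a conflict); the rest become ADX1, ADX2, … ordered by
descending European fraction, so ADX1 is the admixed cluster nearest the
European-like one.

## The enrichment screen

For every site, reference/alternate allele counts are tabulated across
the named clusters (missing genotypes contribute nothing; a cluster with
no observed genotypes keeps a (0,0) column that is dropped before
testing), and a two-sided exact test on the 2×k table is computed under
the probability-mass ordering: $p$ is the total multivariate-
hypergeometric probability (fixed column totals, fixed alternate-allele
total) of tables at most as probable as the one observed, with a
relative tie tolerance of $10^{-7}$. This matches the convention of
standard exact-test implementations.

The enumeration is a branch-and-bound network search over alt-allele
compositions, with suffix DP bounds on the achievable log-probability:
subtrees entirely beyond the threshold collapse to a closed-form binomial
mass (Vandermonde identity) on the extreme side, or are excluded outright
on the non-extreme side; children are visited mode-first so high-mass
regions resolve earliest. Three regimes follow:

* **Exact** — the search completes within the node budget (`mcCutoff`,
  default $3\times 10^5$ nodes per site in the screen; $5\times 10^7$ for
  single-table calls). In the screen the search additionally truncates
  subtrees carrying less than `alpha/100` of total certified mass in
  aggregate, and stops once all unresolved mass is below that tolerance —
  the reported $p$ then carries a certified absolute error under 1% of
  the significance threshold, invisible at any reported digit.
* **Certified bounds** — when the budget is exhausted the partial search
  still yields rigorous bounds (extreme mass found; one minus the
  certified non-extreme mass). If the bounds do not straddle `alpha`, the
  significance decision is exact even though the value is not; if they
  do, the budget escalates 100-fold once.
* **Monte-Carlo** — clearly-null tables (a chi-square statistic routes
  approximate $p > 0.01$; the chi-square value itself is never reported)
  and budget-exhausted tables get a sampled value: plain fixed-margin
  sampling with staged replicates ($10^4$ then $10^5$, escalating only
  while fewer than 20 extreme draws have been seen), and for far-tail
  tables below the plain-MC floor, an importance-sampled estimator —
  per-column binomials at the observed frequencies conditioned on the
  alt total (conditioning constant computed exactly by convolution),
  giving an unbiased estimate of the extreme mass within the proposal's
  support. The IS value is clipped into the certified bounds. Its known
  bias direction (it misses extreme mass far from the proposal, so it
  underestimates) matters only within an order of magnitude of `alpha`,
  a regime the certified bounds already decide; for the far-tail tables
  it serves, the estimate sits dozens of orders of magnitude past any
  threshold. Every sampled value is seeded and the method tag
  (`exact` / `monte_carlo`) is recorded per site.

Sites with $p < \alpha$ (default $5\times10^{-8}$, the conventional
genome-wide threshold; a stricter $10^{-8}$ is a one-argument change) are
annotated with: the multi-group FST
$F_{ST} = 1 - \bar{H_S}/H_T$ with $H_T = 2pq$ from pooled allele
frequencies and $\bar{H_S} = \sum_i 2p_iq_i f(i)$ weighted by the
*individual* (not allele) proportions per cluster — in the screen, the
non-missing individuals at that site, so the weights and the frequencies
describe the same individuals; the enrichment cluster (highest
alternate-allele frequency, ties to the larger column then name order);
three Poisson regressions `genotype ~ ancestry` (log link, fitted by
IRLS via `glm` with tolerance $10^{-8}$ and at most 100 iterations, Wald
test on the slope; an all-zero genotype vector is reported as
unidentified rather than as a number); and the catalog's ClinVar-style
class and PharmGKB-style evidence level. No multiple-testing correction
is applied beyond the fixed genome-wide threshold. Monomorphic tables
return $F_{ST}=0$ with a flag.

## Diagnostic yield

For each ancestry group, the yield per pathogenicity class is
$D_i^p = 100 \cdot \#\{\text{carried variants of class } p\} /
\#\{\text{carried variants}\}$, where a group *carries* a variant if at
least one alternate allele is observed among its non-missing genotypes.
The carried-variant denominator makes yields comparable across groups of
very different size; an all-cohort denominator is available by argument.
Raw numerators and denominators are always emitted alongside the
percentages.

## Problem sizes and determinism

The default end-to-end configuration simulates 300 samples at 8,000
sites across three platforms, retains 4,000 occupancy-ranked sites for
ancestry inference, and runs EM for at most 800 iterations — sizes chosen
so a complete run finishes in a few minutes on one core while every
stage still has realistic structure. Parameter-recovery checks use
n = 200, m = 5,000 (admixture), n = 1,000 (cluster count), m = 10,000
(null calibration) and 2,500-allele tables (power). Every stochastic
stage derives its stream from one master seed, so a fixed seed reproduces
the entire run bit-identically; tests assert this on the full pipeline.

## Known limitations

At the default 300-sample scale the smallest ancestry cluster holds only
~15 samples; on EM-inferred (noisy) ancestry fractions the elbow can
merge it with its admixed neighbour at some seeds and report four
clusters. This is a small-sample property, not an algorithmic one:
cluster-count recovery on the same blueprint is essentially perfect from
n ≈ 700 on ground-truth fractions and 100/100 at n = 1000, the scale at
which the package's recovery checks assess it.
Exact/bound decisions at the screen threshold are certified, but a
reported Monte-Carlo value for a table whose true $p$ sits within the
certified bounds is only as accurate as the sampler; allele-swap and
strand harmonization are not attempted; the admixture model assumes
unlinked sites, so Q standard errors (not computed) would be
anti-conservative under LD; diagnostic-yield comparisons inherit any
platform site-set confounding present in the input, as they do for real
cohorts.
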