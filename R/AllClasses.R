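#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#'   rowData<- colData<-
NULL

.CLINVAR_CLASSES <- c("none", "uncertain", "conflicting", "pathogenic_lp")
.PHARM_LEVELS <- c("none", "1A", "1B", "2A", "2B", "3", "4")
.PLATFORMS <- c("WGG", "WES", "WGS")
.ANCESTRY_COMPONENTS <- c("AFR", "AME", "EUR")

#' GenotypeCohort: genotype matrix with variant and sample annotations
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `"GT"` assay of alternate-allele dosages (sites in rows, samples in
#' columns; values 0, 1, 2 or `NA` for missing). `rowData` carries the
#' normalized variant identity (`chrom`, `pos`, `ref`, `alt`) and, after
#' merging, the per-site dataset `occupancy`. `colData` carries `sample_id`,
#' `dataset` and `platform` (WGG/WES/WGS).
#'
#' @export
setClass("GenotypeCohort", contains = "SummarizedExperiment")

setValidity("GenotypeCohort", function(object) {
  msg <- character()
  if (!"GT" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'GT' is required")
  else {
    gt <- SummarizedExperiment::assay(object, "GT")
    bad <- gt[!is.na(gt)]
    if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
      msg <- c(msg, "GT values must be 0, 1, 2 or NA")
  }
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% colnames(rowData(object))))
    msg <- c(msg, "rowData must contain chrom, pos, ref, alt")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "variant keys (rownames) must be unique")
  if (length(msg)) msg else TRUE
})

#' AncestralPanel: per-population alternate-allele frequencies
#'
#' Holds the alternate-allele frequency of each simulated ancestral
#' population at each site, the ordered population labels and the variant
#' keys. This is the ground-truth frequency layer from which admixed
#' genotypes are drawn.
#'
#' @slot popLabels ordered ancestry names (default AFR, AME, EUR)
#' @slot freqs numeric matrix, populations x sites, entries in \[0, 1\]
#' @slot sites character vector of variant keys (`chrom:pos:ref:alt`)
#' @export
setClass("AncestralPanel", representation(
  popLabels = "character", freqs = "matrix", sites = "character"))

setValidity("AncestralPanel", function(object) {
  msg <- character()
  if (nrow(object@freqs) != length(object@popLabels))
    msg <- c(msg, "freqs must have one row per population label")
  if (ncol(object@freqs) != length(object@sites))
    msg <- c(msg, "freqs must have one column per site")
  if (length(object@freqs) && (min(object@freqs) < 0 || max(object@freqs) > 1))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  if (anyDuplicated(object@sites))
    msg <- c(msg, "sites must be unique")
  if (length(msg)) msg else TRUE
})

#' ClusterSpec: admixture-cluster blueprint for cohort simulation
#'
#' Describes a mixture of Dirichlet-distributed ancestry profiles: each
#' cluster has a centroid on the ancestry simplex, a mixing weight, and a
#' common concentration controlling within-cluster spread.
#'
#' @slot centroids numeric matrix, clusters x components, rows on the simplex
#' @slot weights mixing proportions summing to 1
#' @slot concentration positive Dirichlet scale (larger = tighter clusters)
#' @slot nSamples number of samples to draw
#' @export
setClass("ClusterSpec", representation(
  centroids = "matrix", weights = "numeric", concentration = "numeric",
  nSamples = "integer"))

setValidity("ClusterSpec", function(object) {
  msg <- character()
  if (nrow(object@centroids) == 0L)
    msg <- c(msg, "at least one centroid is required")
  if (length(object@weights) != nrow(object@centroids))
    msg <- c(msg, "one weight per centroid is required")
  if (nrow(object@centroids) &&
      any(abs(rowSums(object@centroids) - 1) > 1e-9))
    msg <- c(msg, "centroid rows must sum to 1")
  if (length(object@weights) && abs(sum(object@weights) - 1) > 1e-9)
    msg <- c(msg, "weights must sum to 1")
  if (length(object@concentration) != 1L || object@concentration <= 0)
    msg <- c(msg, "concentration must be a single positive number")
  if (length(object@nSamples) != 1L || object@nSamples < 0L)
    msg <- c(msg, "nSamples must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' QMatrix: per-sample ancestry fractions
#'
#' An n x K matrix of ancestry fractions whose rows lie on the probability
#' simplex, optionally carrying a per-sample cluster index (used both for
#' simulated ground truth and for inferred cluster assignments).
#'
#' @slot Q numeric matrix, samples x components, rows summing to 1
#' @slot cluster integer cluster index per sample (NA when unassigned)
#' @export
setClass("QMatrix", representation(Q = "matrix", cluster = "integer"))

setValidity("QMatrix", function(object) {
  msg <- character()
  q <- object@Q
  if (length(q)) {
    if (min(q) < -1e-9 || max(q) > 1 + 1e-9)
      msg <- c(msg, "ancestry fractions must lie in [0, 1]")
    if (any(abs(rowSums(q) - 1) > 1e-6))
      msg <- c(msg, "rows must sum to 1 (tolerance 1e-6)")
  }
  if (length(object@cluster) && length(object@cluster) != nrow(q))
    msg <- c(msg, "cluster must have one entry per sample")
  if (length(msg)) msg else TRUE
})

#' AncestryClusters: categorical ancestry groups in Q-space
#'
#' The result of K-means clustering of ancestry fractions: the chosen K, a
#' per-sample assignment, cluster centroids on the simplex, cluster names
#' (AFR/AME/EUR for ancestry-dominated clusters, ADX1, ADX2, ... for admixed
#' ones) and the inertia profile used by the elbow criterion.
#'
#' @slot k chosen number of clusters
#' @slot assignment integer cluster index per sample
#' @slot centroids numeric matrix, clusters x components
#' @slot clusterNames character names, unique, parallel to centroid rows
#' @slot inertia named numeric vector of within-cluster sums of squares per
#'   candidate K (elbow diagnostics)
#' @export
setClass("AncestryClusters", representation(
  k = "integer", assignment = "integer", centroids = "matrix",
  clusterNames = "character", inertia = "numeric"))

setValidity("AncestryClusters", function(object) {
  msg <- character()
  if (length(object@k) != 1L || object@k < 1L)
    msg <- c(msg, "k must be a single positive integer")
  if (anyNA(object@assignment))
    msg <- c(msg, "every sample must be assigned")
  if (length(object@assignment) &&
      (min(object@assignment) < 1L || max(object@assignment) > object@k))
    msg <- c(msg, "assignments must index centroids")
  if (nrow(object@centroids) != object@k)
    msg <- c(msg, "one centroid per cluster is required")
  if (length(object@clusterNames) &&
      (length(object@clusterNames) != object@k ||
       anyDuplicated(object@clusterNames)))
    msg <- c(msg, "clusterNames must be unique, one per cluster")
  if (length(msg)) msg else TRUE
})

#' PCModel: reference-panel principal component model
#'
#' Standardization parameters (per-site allele frequency and scale) plus the
#' orthonormal loadings of a PCA fitted on a labeled reference panel, used to
#' project cohort samples into the reference PC space.
#'
#' @slot sites variant keys entering the model
#' @slot refFreq per-site reference-panel alternate-allele frequency
#' @slot scale per-site standardization scale `sqrt(2 p (1 - p))`
#' @slot loadings sites x components orthonormal matrix
#' @slot eigenvalues non-increasing, one per retained component
#' @slot pctVar percent variance explained per component
#' @export
setClass("PCModel", representation(
  sites = "character", refFreq = "numeric", scale = "numeric",
  loadings = "matrix", eigenvalues = "numeric", pctVar = "numeric"))

setValidity("PCModel", function(object) {
  msg <- character()
  if (nrow(object@loadings) != length(object@sites))
    msg <- c(msg, "loadings must have one row per site")
  if (ncol(object@loadings)) {
    ortho <- crossprod(object@loadings)
    if (max(abs(ortho - diag(ncol(object@loadings)))) > 1e-8)
      msg <- c(msg, "loadings must be orthonormal (tolerance 1e-8)")
  }
  if (length(object@pctVar)) {
    if (min(object@pctVar) < -1e-9 || max(object@pctVar) > 100 + 1e-9)
      msg <- c(msg, "percent variance must lie in [0, 100]")
    if (any(diff(object@pctVar) > 1e-9))
      msg <- c(msg, "percent variance must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' ContingencyTable2xK: per-variant allele counts across ancestry clusters
#'
#' Reference and alternate allele counts per ancestry cluster for one
#' biallelic site; each column total equals twice the number of non-missing
#' diploid samples in that cluster.
#'
#' @slot clusters cluster names (columns)
#' @slot ref reference-allele counts per cluster
#' @slot alt alternate-allele counts per cluster
#' @export
setClass("ContingencyTable2xK", representation(
  clusters = "character", ref = "integer", alt = "integer"))

setValidity("ContingencyTable2xK", function(object) {
  msg <- character()
  k <- length(object@clusters)
  if (length(object@ref) != k || length(object@alt) != k)
    msg <- c(msg, "ref and alt must have one count per cluster")
  if (length(object@ref) && (min(object@ref) < 0 || min(object@alt) < 0))
    msg <- c(msg, "counts must be non-negative")
  if (k && all(object@ref + object@alt == 0L))
    msg <- c(msg, "at least one column must have a positive total")
  if (length(msg)) msg else TRUE
})
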