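#' @include AllClasses.R
NULL

#' Construct a GenotypeCohort
#'
#' @param gt integer matrix of alternate-allele dosages, sites x samples,
#'   with `NA` for missing genotypes. Rownames, if absent, are derived from
#'   `variants`.
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (one row per site).
#' @param samples data.frame with at least `sample_id`; `dataset` and
#'   `platform` default to `"COHORT"` / `"WGS"`.
#' @return A [GenotypeCohort-class] object.
#' @export
GenotypeCohort <- function(gt, variants, samples = NULL) {
  gt <- as.matrix(gt)
  storage.mode(gt) <- "integer"
  keys <- variantKey(variants$chrom, variants$pos, variants$ref, variants$alt)
  rownames(gt) <- keys
  if (is.null(samples)) {
    ids <- colnames(gt)
    if (is.null(ids)) ids <- sprintf("S%04d", seq_len(ncol(gt)))
    samples <- data.frame(sample_id = ids)
  }
  if (is.null(samples$dataset)) samples$dataset <- "COHORT"
  if (is.null(samples$platform)) samples$platform <- "WGS"
  colnames(gt) <- samples$sample_id
  rd <- S4Vectors::DataFrame(chrom = as.character(variants$chrom),
                             pos = as.integer(variants$pos),
                             ref = as.character(variants$ref),
                             alt = as.character(variants$alt),
                             row.names = keys)
  if (!is.null(variants$occupancy)) rd$occupancy <- as.integer(variants$occupancy)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(GT = gt), rowData = rd,
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
  new("GenotypeCohort", se)
}

#' Extract the genotype dosage matrix
#' @param x a [GenotypeCohort-class]
#' @return integer matrix, sites x samples, `NA` for missing.
#' @export
genotypes <- function(x) SummarizedExperiment::assay(x, "GT")

#' Variant keys of a cohort or panel
#' @param x a [GenotypeCohort-class] or [AncestralPanel-class]
#' @return character vector of `chrom:pos:ref:alt` keys.
#' @export
variantKeys <- function(x) {
  if (is(x, "AncestralPanel")) return(x@sites)
  rownames(x)
}

#' Sample identifiers
#' @param x a [GenotypeCohort-class]
#' @export
sampleIds <- function(x) colnames(x)

#' Per-sample dataset codes / platforms
#' @param x a [GenotypeCohort-class]
#' @rdname datasetOf
#' @export
datasetOf <- function(x) setNames(colData(x)$dataset, colnames(x))

#' @rdname datasetOf
#' @export
platformOf <- function(x) setNames(colData(x)$platform, colnames(x))

#' Ancestry fraction matrix of a QMatrix
#' @param x a [QMatrix-class]
#' @return numeric matrix, samples x components.
#' @export
qvalues <- function(x) x@Q

#' Cluster assignment of a QMatrix or AncestryClusters
#' @param x a [QMatrix-class] or [AncestryClusters-class]
#' @export
clusterAssignment <- function(x) {
  if (is(x, "AncestryClusters")) return(x@assignment)
  x@cluster
}

#' Cluster names of an AncestryClusters
#' @param x an [AncestryClusters-class]
#' @export
clusterNames <- function(x) x@clusterNames

#' Construct a QMatrix
#' @param Q samples x components matrix; rows are renormalized to sum to 1
#'   exactly once (guard against floating drift).
#' @param cluster optional integer cluster index per sample.
#' @param components column names (default AFR, AME, EUR ordering).
#' @export
QMatrix <- function(Q, cluster = NA_integer_, components = NULL) {
  Q <- as.matrix(Q)
  if (!is.null(components)) colnames(Q) <- components
  if (is.null(colnames(Q)) && ncol(Q) == 3L) colnames(Q) <- .ANCESTRY_COMPONENTS
  Q <- pmin(pmax(Q, 0), 1)
  Q <- Q / rowSums(Q)
  if (length(cluster) == 1L && is.na(cluster))
    cluster <- rep(NA_integer_, nrow(Q))
  new("QMatrix", Q = Q, cluster = as.integer(cluster))
}

#' Construct a ContingencyTable2xK
#' @param ref,alt integer allele counts per cluster.
#' @param clusters cluster names.
#' @export
ContingencyTable2xK <- function(ref, alt, clusters = NULL) {
  if (is.null(clusters)) clusters <- paste0("C", seq_along(ref))
  new("ContingencyTable2xK", clusters = as.character(clusters),
      ref = as.integer(ref), alt = as.integer(alt))
}

setMethod("show", "GenotypeCohort", function(object) {
  cat(sprintf("GenotypeCohort: %d sites x %d samples\n",
              nrow(object), ncol(object)))
  ds <- table(colData(object)$dataset)
  cat("  datasets:", paste(sprintf("%s(%d)", names(ds), ds), collapse = ", "),
      "\n")
  gt <- genotypes(object)
  cat(sprintf("  missing: %.2f%%\n", 100 * mean(is.na(gt))))
})

setMethod("show", "AncestralPanel", function(object) {
  cat(sprintf("AncestralPanel: %d populations (%s) x %d sites\n",
              length(object@popLabels),
              paste(object@popLabels, collapse = ", "),
              length(object@sites)))
})

setMethod("show", "QMatrix", function(object) {
  cat(sprintf("QMatrix: %d samples x %d components (%s)\n",
              nrow(object@Q), ncol(object@Q),
              paste(colnames(object@Q), collapse = ", ")))
  if (nrow(object@Q))
    cat("  mean fractions:",
        paste(sprintf("%.3f", colMeans(object@Q)), collapse = ", "), "\n")
})

setMethod("show", "AncestryClusters", function(object) {
  cat(sprintf("AncestryClusters: K = %d\n", object@k))
  cnt <- tabulate(object@assignment, object@k)
  nm <- if (length(object@clusterNames)) object@clusterNames
        else paste0("C", seq_len(object@k))
  cat("  ", paste(sprintf("%s: %d", nm, cnt), collapse = ", "), "\n")
})

setMethod("show", "ContingencyTable2xK", function(object) {
  m <- rbind(ref = object@ref, alt = object@alt)
  colnames(m) <- object@clusters
  print(m)
})

setMethod("show", "PCModel", function(object) {
  cat(sprintf("PCModel: %d sites, %d components\n",
              length(object@sites), ncol(object@loadings)))
  cat("  %var:", paste(sprintf("%.1f", utils::head(object@pctVar, 5)),
                       collapse = ", "), "...\n")
})
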