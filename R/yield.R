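#' @include accessors.R utils.R
NULL

#' Diagnostic yield per ancestry group and pathogenicity class
#'
#' For each named ancestry group, the denominator is the number of variants
#' carried by the group (at least one alternate allele among the group's
#' non-missing genotypes); the numerator for each ClinVar-style class
#' (uncertain, conflicting, pathogenic_lp) is the number of carried variants
#' with that catalog class; the yield is `100 * numerator / denominator`.
#' The alternative `"all"` denominator counts every cohort variant
#' regardless of carriage.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param clusters a named [AncestryClusters-class] parallel to the cohort
#'   samples.
#' @param catalog annotation data.frame (`key`, `clinvar_class`, ...).
#' @param denominator `"carried"` (default) or `"all"`.
#' @return data.frame with columns `group`, `class`, `numerator`,
#'   `denominator`, `percent`; the group x class percentage matrix is
#'   attached as attribute `"matrix"`.
#' @export
diagnosticYield <- function(cohort, clusters, catalog,
                            denominator = c("carried", "all")) {
  denominator <- match.arg(denominator)
  gt <- genotypes(cohort)
  assign <- clusters@assignment
  stopifnot(length(assign) == ncol(gt))
  classes <- setdiff(.CLINVAR_CLASSES, "none")
  cls <- catalog$clinvar_class[match(rownames(gt), catalog$key)]
  cls[is.na(cls)] <- "none"
  rows <- list()
  for (c in seq_len(clusters@k)) {
    group <- clusters@clusterNames[c]
    cols <- assign == c
    if (!any(cols)) {
      warning("empty ancestry group: ", group)
      carried <- rep(FALSE, nrow(gt))
    } else {
      carried <- rowSums(gt[, cols, drop = FALSE], na.rm = TRUE) > 0
    }
    den <- if (denominator == "carried") sum(carried) else nrow(gt)
    for (p in classes) {
      num <- if (denominator == "carried") sum(carried & cls == p) else
        sum(cls == p)
      rows[[length(rows) + 1L]] <- data.frame(
        group = group, class = p, numerator = num, denominator = den,
        percent = if (den > 0) 100 * num / den else 0,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  m <- matrix(out$percent, nrow = clusters@k, byrow = TRUE,
              dimnames = list(clusters@clusterNames, classes))
  attr(out, "matrix") <- m
  out
}

#' Filter screen results by pharmacogenomic evidence level
#'
#' Retains results whose `pharm_level` is in `keepLevels`, preserving order.
#' The default keeps the strongest curation tiers (1A, 1B, 2A, 2B).
#'
#' @param results data.frame from [screenGenome()] (needs a `pharm_level`
#'   column).
#' @param keepLevels character vector of levels to keep.
#' @return the retained subset of `results`.
#' @export
filterByEvidence <- function(results,
                             keepLevels = c("1A", "1B", "2A", "2B")) {
  if (!nrow(results)) return(results)
  results[results$pharm_level %in% keepLevels, , drop = FALSE]
}

#' Per-dataset allele counts and frequencies
#'
#' For every dataset and every variant present in it: the allele count is
#' twice the number of non-missing samples, the alternate frequency is the
#' alternate-allele count over the allele count, and the reference frequency
#' is its complement. Variants absent from a dataset produce no row.
#'
#' @param datasets list of [GenotypeCohort-class] objects (one per source
#'   dataset).
#' @return data.frame with `dataset`, `key`, `allele_count`, `ref_freq`,
#'   `alt_freq`.
#' @export
summarizeFrequencies <- function(datasets) {
  rows <- lapply(datasets, function(d) {
    gt <- genotypes(d)
    nm <- rowSums(!is.na(gt))
    ac <- 2L * nm
    keep <- ac > 0L
    altFreq <- rowSums(gt, na.rm = TRUE)[keep] / ac[keep]
    data.frame(dataset = unname(datasetOf(d))[1],
               key = rownames(gt)[keep],
               allele_count = as.integer(ac[keep]),
               ref_freq = 1 - altFreq, alt_freq = altFreq,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
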