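#' @include accessors.R utils.R
NULL

#' Normalize raw variant records to canonical keys
#'
#' Maps raw `(chrom, pos, ref, alt)` records to the canonical
#' `chrom:pos:ref:alt` form used for cross-dataset matching: `chr` prefixes
#' are stripped, alleles upper-cased. Records with equal ref/alt, empty
#' alleles or non-positive positions are rejected with a reason. The
#' normalization is idempotent.
#'
#' @param records data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @return data.frame with `key`, `valid` (logical) and `reason` (empty for
#'   valid records).
#' @export
normalizeVariantIds <- function(records) {
  chrom <- sub("^chr", "", as.character(records$chrom), ignore.case = TRUE)
  ref <- toupper(as.character(records$ref))
  alt <- toupper(as.character(records$alt))
  pos <- suppressWarnings(as.integer(records$pos))
  reason <- character(nrow(records))
  reason[is.na(pos) | pos < 1L] <- "position must be >= 1"
  reason[!nzchar(ref) | !nzchar(alt)] <- "empty allele"
  reason[nzchar(ref) & nzchar(alt) & ref == alt] <- "ref equals alt"
  valid <- !nzchar(reason)
  key <- rep(NA_character_, nrow(records))
  key[valid] <- paste(chrom[valid], pos[valid], ref[valid], alt[valid],
                      sep = ":")
  data.frame(key = key, valid = valid, reason = reason,
             stringsAsFactors = FALSE)
}

#' Union-merge datasets on variant identity
#'
#' Combines per-dataset genotype matrices into one cohort whose site set is
#' the exact union of the dataset site sets, keyed on the canonical variant
#' key (ref/alt sensitive: the same chrom:pos with different alleles are
#' distinct sites). A sample's genotype at a site absent from its dataset is
#' missing. Per-site occupancy (number of datasets containing the site) is
#' recorded in `rowData`. Sites are ordered by (chrom, pos, ref, alt).
#'
#' @param datasets list of [GenotypeCohort-class] objects with disjoint
#'   sample ids.
#' @return A merged [GenotypeCohort-class] with `occupancy` in `rowData`.
#' @export
unionMerge <- function(datasets) {
  if (length(datasets) < 1L) stop("at least one dataset is required")
  allIds <- unlist(lapply(datasets, sampleIds))
  if (anyDuplicated(allIds))
    stop("duplicate sample ids across datasets: ",
         paste(utils::head(unique(allIds[duplicated(allIds)]), 3),
               collapse = ", "))
  keyList <- lapply(datasets, variantKeys)
  keys <- unique(unlist(keyList))
  vp <- parseVariantKey(keys)
  ord <- order(.chromOrder(vp$chrom), vp$pos, vp$ref, vp$alt)
  keys <- keys[ord]
  vp <- vp[ord, , drop = FALSE]
  occupancy <- integer(length(keys))
  names(occupancy) <- keys
  gt <- matrix(NA_integer_, nrow = length(keys), ncol = length(allIds),
               dimnames = list(keys, allIds))
  samples <- do.call(rbind, lapply(datasets, function(d)
    data.frame(sample_id = sampleIds(d),
               dataset = unname(datasetOf(d)),
               platform = unname(platformOf(d)),
               stringsAsFactors = FALSE)))
  for (d in datasets) {
    idx <- match(variantKeys(d), keys)
    occupancy[idx] <- occupancy[idx] + 1L
    gt[idx, sampleIds(d)] <- genotypes(d)
  }
  vp$occupancy <- occupancy
  GenotypeCohort(gt, vp, samples)
}

#' Rank sites by dataset occupancy and keep the top n
#'
#' Sites are ranked by the number of datasets in which they are present
#' (descending), with ties broken by ascending genomic coordinate, and the
#' first `min(nKeep, total)` are returned. In `"per_dataset"` mode the
#' ranking and truncation are applied within each dataset's site set and the
#' union of the per-dataset selections is returned.
#'
#' @param cohort a merged [GenotypeCohort-class] with `occupancy` in
#'   `rowData`.
#' @param nKeep number of sites to retain.
#' @param mode `"global"` (default) or `"per_dataset"`.
#' @return character vector of selected variant keys (in rank order for
#'   global mode).
#' @export
rankSitesByOccupancy <- function(cohort, nKeep, mode = c("global",
                                                         "per_dataset")) {
  mode <- match.arg(mode)
  if (nKeep < 0) stop("nKeep must be non-negative")
  rd <- rowData(cohort)
  if (is.null(rd$occupancy)) stop("cohort lacks occupancy (run unionMerge)")
  ord <- order(-rd$occupancy, .chromOrder(rd$chrom), rd$pos)
  ranked <- rownames(cohort)[ord]
  if (mode == "global")
    return(ranked[seq_len(min(nKeep, length(ranked)))])
  sel <- character()
  for (ds in unique(colData(cohort)$dataset)) {
    cols <- colData(cohort)$dataset == ds
    present <- rowSums(!is.na(genotypes(cohort)[, cols, drop = FALSE])) > 0
    inDs <- ranked[ranked %in% rownames(cohort)[present]]
    sel <- union(sel, inDs[seq_len(min(nKeep, length(inDs)))])
  }
  sel
}

#' Filter sites on missingness and minor allele frequency
#'
#' A site is dropped iff its missing fraction exceeds `maxMissing` or its
#' minor-allele frequency, computed over non-missing alleles, is strictly
#' below `minMaf`. Sites missing in every sample are dropped (MAF
#' undefined).
#'
#' @param cohort a [GenotypeCohort-class].
#' @param maxMissing maximum tolerated per-site missing fraction.
#' @param minMaf minimum minor-allele frequency.
#' @return filtered [GenotypeCohort-class]; a filter-log data.frame is
#'   attached as attribute `"log"`.
#' @export
filterSites <- function(cohort, maxMissing = 0.75, minMaf = 0.05) {
  stopifnot(maxMissing >= 0, maxMissing <= 1, minMaf >= 0, minMaf <= 1)
  gt <- genotypes(cohort)
  missFrac <- rowMeans(is.na(gt))
  nonMiss <- rowSums(!is.na(gt))
  altFreq <- ifelse(nonMiss > 0, rowSums(gt, na.rm = TRUE) / (2 * nonMiss),
                    NA_real_)
  maf <- pmin(altFreq, 1 - altFreq)
  keep <- missFrac <= maxMissing & !is.na(maf) & maf >= minMaf
  out <- cohort[keep, ]
  attr(out, "log") <- .filterLog("filter_sites", "sites", nrow(cohort),
                                 sum(keep),
                                 sprintf("maxMissing=%g minMaf=%g",
                                         maxMissing, minMaf))
  out
}

#' Filter samples on genotype missingness
#'
#' A sample is dropped iff its fraction of missing genotypes exceeds
#' `maxMissing`. The permissive default of 0.99 follows common practice for
#' union-merged multi-platform cohorts, where most missingness is
#' structural.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param maxMissing maximum tolerated per-sample missing fraction.
#' @return filtered [GenotypeCohort-class] with attribute `"log"`.
#' @export
filterSamples <- function(cohort, maxMissing = 0.99) {
  stopifnot(maxMissing >= 0, maxMissing <= 1)
  missFrac <- colMeans(is.na(genotypes(cohort)))
  keep <- missFrac <= maxMissing
  out <- cohort[, keep]
  attr(out, "log") <- .filterLog("filter_samples", "samples", ncol(cohort),
                                 sum(keep),
                                 sprintf("maxMissing=%g", maxMissing))
  out
}

#' Greedy sliding-window LD pruning
#'
#' Within each sliding window, sites are visited left to right; for any pair
#' of retained sites whose squared Pearson correlation of genotype dosages
#' (missing entries pairwise-excluded) exceeds `r2Max`, the later site is
#' dropped. Monomorphic sites have undefined correlation and are treated as
#' uncorrelated.
#'
#' @param cohort a [GenotypeCohort-class] (or a sites x samples dosage
#'   matrix).
#' @param window window size in sites.
#' @param step window step in sites.
#' @param r2Max maximum tolerated squared correlation.
#' @return character vector of retained variant keys.
#' @export
ldPrune <- function(cohort, window = 50L, step = 5L, r2Max = 0.2) {
  stopifnot(window >= 1L, step >= 1L, r2Max >= 0, r2Max <= 1)
  gt <- if (is.matrix(cohort)) cohort else genotypes(cohort)
  m <- nrow(gt)
  if (m == 0L) return(character())
  keep <- rep(TRUE, m)
  if (r2Max < 1) {
    starts <- seq(1L, max(1L, m - 1L), by = step)
    for (s in starts) {
      e <- min(s + window - 1L, m)
      idx <- s:e
      idx <- idx[keep[idx]]
      if (length(idx) < 2L) next
      cc <- suppressWarnings(
        stats::cor(t(gt[idx, , drop = FALSE]),
                   use = "pairwise.complete.obs"))
      cc[is.na(cc)] <- 0
      r2 <- cc^2
      len <- length(idx)
      for (a in seq_len(len - 1L)) {
        if (!keep[idx[a]]) next
        for (b in (a + 1L):len)
          if (keep[idx[b]] && r2[a, b] > r2Max) keep[idx[b]] <- FALSE
      }
    }
  }
  rownames(gt)[keep]
}

#' Pairwise kinship estimation and relative removal
#'
#' Estimates pairwise kinship with a heterozygote-concordance estimator that
#' is robust to population structure:
#' `phi = (N_het_both - 2 N_opposite_hom) / (N_het_i + N_het_j)`, where
#' counts run over sites non-missing in both samples. Duplicate samples have
#' expected kinship 0.5, first-degree relatives 0.25, unrelated pairs about
#' 0. For each flagged pair (kinship above `firstDegreeThreshold`) the
#' member with the higher missing fraction is dropped. Pairs sharing fewer
#' than `minShared` non-missing sites are skipped with a warning.
#'
#' @param cohort a [GenotypeCohort-class] with at least 2 samples (a
#'   single-sample cohort is returned unchanged).
#' @param dupThreshold kinship above which a pair is labeled `duplicate`
#'   (conventional cut 2^(-3/2) ~ 0.354).
#' @param firstDegreeThreshold kinship above which a pair is flagged for
#'   removal (conventional cut 2^(-5/2) ~ 0.177).
#' @param minShared minimum shared non-missing sites per pair.
#' @return list with `cohort` (filtered), `report` (data.frame of flagged
#'   pairs with kinship and class), `removed` (sample ids), and `log`.
#' @export
kinshipFilter <- function(cohort, dupThreshold = 2^(-3/2),
                          firstDegreeThreshold = 2^(-5/2),
                          minShared = 100L) {
  gt <- genotypes(cohort)
  n <- ncol(gt)
  emptyReport <- data.frame(sample1 = character(), sample2 = character(),
                            kinship = numeric(), shared = integer(),
                            class = character(), stringsAsFactors = FALSE)
  if (n < 2L)
    return(list(cohort = cohort, report = emptyReport, removed = character(),
                log = .filterLog("kinship_filter", "samples", n, n)))
  het <- (!is.na(gt)) & gt == 1L
  hom0 <- (!is.na(gt)) & gt == 0L
  hom2 <- (!is.na(gt)) & gt == 2L
  obs <- !is.na(gt)
  hetBoth <- crossprod(het)                       # N_het_both
  oppHom <- crossprod(hom0, hom2) + crossprod(hom2, hom0)
  shared <- crossprod(obs)
  # per-pair het counts restricted to jointly observed sites
  hetI <- crossprod(het, obs)                     # hets of row sample at
  hetSum <- hetI + t(hetI)                        # jointly observed sites
  kin <- (hetBoth - 2 * oppHom) / hetSum
  kin[hetSum == 0] <- 0
  pairs <- which(upper.tri(kin), arr.ind = TRUE)
  skipped <- shared[pairs] < minShared
  if (any(skipped))
    warning(sum(skipped), " pair(s) share fewer than ", minShared,
            " sites and were skipped")
  flagIdx <- pairs[!skipped & kin[pairs] > firstDegreeThreshold, ,
                   drop = FALSE]
  report <- data.frame(
    sample1 = colnames(gt)[flagIdx[, 1]],
    sample2 = colnames(gt)[flagIdx[, 2]],
    kinship = kin[flagIdx],
    shared = as.integer(shared[flagIdx]),
    class = ifelse(kin[flagIdx] > dupThreshold, "duplicate", "first_degree"),
    stringsAsFactors = FALSE)
  missFrac <- colMeans(is.na(gt))
  removed <- character()
  if (nrow(report)) {
    for (r in seq_len(nrow(report))) {
      s1 <- report$sample1[r]; s2 <- report$sample2[r]
      if (s1 %in% removed || s2 %in% removed) next
      removed <- c(removed,
                   if (missFrac[s2] >= missFrac[s1]) s2 else s1)
    }
  }
  out <- cohort[, setdiff(colnames(gt), removed)]
  list(cohort = out, report = report, removed = removed,
       log = .filterLog("kinship_filter", "samples", n, n - length(removed),
                        sprintf("%d flagged pair(s)", nrow(report))))
}

#' Full harmonization of heterogeneous datasets
#'
#' Applies the standard order of operations: union merge on normalized
#' variant keys, kinship-based duplicate/relative removal, sample
#' missingness filter, site missingness/MAF filter, occupancy ranking.
#' Sample-level QC precedes site statistics so that per-site missingness and
#' allele frequencies are computed on the de-duplicated cohort.
#'
#' @param datasets list of [GenotypeCohort-class] objects.
#' @param maxSiteMissing,minMaf site filter thresholds.
#' @param maxSampleMissing sample filter threshold.
#' @param topN occupancy-ranked site count to retain (`Inf` keeps all).
#' @param rankMode `"global"` or `"per_dataset"` occupancy ranking.
#' @return list with `cohort` (harmonized [GenotypeCohort-class]), `kinship`
#'   (flagged-pair report) and `logs` (data.frame, one row per filter with
#'   input/output counts).
#' @export
harmonizeDatasets <- function(datasets, maxSiteMissing = 0.75,
                              minMaf = 0.05, maxSampleMissing = 0.99,
                              topN = Inf, rankMode = "global") {
  merged <- unionMerge(datasets)
  logs <- .filterLog("union_merge", "sites",
                     sum(vapply(datasets, nrow, numeric(1))), nrow(merged),
                     sprintf("%d dataset(s)", length(datasets)))
  kf <- kinshipFilter(merged)
  logs <- rbind(logs, kf$log)
  cohort <- filterSamples(kf$cohort, maxSampleMissing)
  logs <- rbind(logs, attr(cohort, "log"))
  cohort2 <- filterSites(cohort, maxSiteMissing, minMaf)
  logs <- rbind(logs, attr(cohort2, "log"))
  if (is.finite(topN)) {
    sel <- rankSitesByOccupancy(cohort2, topN, rankMode)
    cohort3 <- cohort2[sel, ]
    logs <- rbind(logs, .filterLog("rank_sites", "sites", nrow(cohort2),
                                   nrow(cohort3),
                                   sprintf("topN=%g mode=%s", topN,
                                           rankMode)))
  } else cohort3 <- cohort2
  list(cohort = cohort3, kinship = kf$report, logs = logs)
}
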