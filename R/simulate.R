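#' @include AllClasses.R accessors.R utils.R
NULL

#' Simulate ancestral allele frequencies under the Balding-Nichols model
#'
#' For each site a shared base frequency `p` is drawn from `baseFreqSampler`,
#' and each ancestral population's frequency is then drawn from a Beta
#' distribution with mean `p` and variance `F p (1 - p)`, i.e. shape
#' parameters `p (1 - F) / F` and `(1 - p)(1 - F) / F`. The divergence
#' parameter `F` plays the role of a population-specific fixation index
#' against the shared ancestral pool.
#'
#' @param m number of sites.
#' @param divergence named numeric vector of per-population `F` values in
#'   (0, 1); names become the population labels.
#' @param baseFreqSampler function of `n` returning base frequencies in
#'   (0, 1). The default draws uniformly on (0.05, 0.95) so sites stay
#'   informative for ancestry.
#' @param seed integer seed.
#' @param sites optional character vector of pre-built variant keys
#'   (length `m`); generated on chromosomes 1-22 when omitted.
#' @return An [AncestralPanel-class].
#' @export
simulateAncestralFreqs <- function(m,
                                   divergence = c(AFR = 0.15, AME = 0.15,
                                                  EUR = 0.15),
                                   baseFreqSampler = function(n)
                                     stats::runif(n, 0.05, 0.95),
                                   seed = 1L, sites = NULL) {
  if (length(m) != 1L || is.na(m) || m < 0)
    stop("m must be a single non-negative count")
  if (any(divergence <= 0 | divergence >= 1))
    stop("divergence values must lie strictly in (0, 1)")
  m <- as.integer(m)
  pops <- names(divergence)
  if (is.null(pops)) pops <- paste0("POP", seq_along(divergence))
  set.seed(seed)
  if (is.null(sites)) sites <- .generateSiteKeys(m)
  if (length(sites) != m) stop("sites must have length m")
  freqs <- matrix(0, nrow = length(divergence), ncol = m,
                  dimnames = list(pops, sites))
  if (m > 0) {
    p <- baseFreqSampler(m)
    for (k in seq_along(divergence)) {
      Fk <- divergence[[k]]
      freqs[k, ] <- stats::rbeta(m, p * (1 - Fk) / Fk,
                                 (1 - p) * (1 - Fk) / Fk)
    }
  }
  new("AncestralPanel", popLabels = pops, freqs = freqs,
      sites = as.character(sites))
}

# Unique biallelic SNP keys spread over autosomes 1-22.
.generateSiteKeys <- function(m) {
  if (m == 0L) return(character())
  chrom <- sort(sample.int(22L, m, replace = TRUE))
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- cumsum(sample(500:5000, length(idx), replace = TRUE)) + 10000L
  }
  nuc <- c("A", "C", "G", "T")
  ref <- sample(nuc, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nuc, r), 1L), character(1))
  variantKey(chrom, pos, ref, alt)
}

#' Default five-cluster admixture blueprint
#'
#' Mixing weights follow the relative sizes of the five ancestry groups
#' reported for the motivating Colombian cohort (African-like 149,
#' Indigenous-American-like 75, European-like 232, Admixed1 603, Admixed2
#' 350 of 1409 samples), and the centroids are calibrated so the weighted
#' cohort mean ancestry is approximately 16.7% African, 32.8% Indigenous
#' American and 50.6% European. ADX1 leans European; ADX2 leans Indigenous
#' American with a minor African component.
#'
#' @param nSamples cohort size to draw.
#' @param concentration Dirichlet scale; the default of 100 gives
#'   within-cluster spreads comparable to a dispersed-but-separable ternary
#'   cloud.
#' @return A [ClusterSpec-class].
#' @export
defaultClusterSpec <- function(nSamples = 1409L, concentration = 100) {
  centroids <- rbind(
    AFR  = c(0.800, 0.080, 0.120),
    AME  = c(0.050, 0.850, 0.100),
    EUR  = c(0.030, 0.070, 0.900),
    ADX1 = c(0.099, 0.293, 0.608),
    ADX2 = c(0.130, 0.550, 0.320))
  colnames(centroids) <- .ANCESTRY_COMPONENTS
  weights <- c(149, 75, 232, 603, 350) / 1409
  new("ClusterSpec", centroids = centroids, weights = weights,
      concentration = concentration, nSamples = as.integer(nSamples))
}

#' Draw per-sample admixture profiles from a cluster blueprint
#'
#' Each sample is assigned a cluster according to the mixing weights, then
#' its ancestry fractions are drawn from
#' `Dirichlet(concentration * centroid)`.
#'
#' @param spec a [ClusterSpec-class].
#' @param seed integer seed.
#' @return A [QMatrix-class] carrying the true cluster index per sample.
#' @export
simulateAdmixtureProfiles <- function(spec, seed = 1L) {
  stopifnot(is(spec, "ClusterSpec"))
  validObject(spec)
  set.seed(seed)
  n <- spec@nSamples
  cl <- sample.int(nrow(spec@centroids), n, replace = TRUE,
                   prob = spec@weights)
  Q <- matrix(0, nrow = n, ncol = ncol(spec@centroids))
  for (c in seq_len(nrow(spec@centroids))) {
    idx <- which(cl == c)
    if (length(idx))
      Q[idx, ] <- .rdirichlet(length(idx),
                              spec@concentration * spec@centroids[c, ])
  }
  colnames(Q) <- colnames(spec@centroids)
  rownames(Q) <- sprintf("S%04d", seq_len(n))
  QMatrix(Q, cluster = cl)
}

#' Sample genotypes from ancestral frequencies and admixture profiles
#'
#' Genotype of sample `i` at site `j` is Binomial(2, pi_ij) with
#' `pi_ij = sum_k q_ik p_kj`: each of the two allele copies descends from an
#' ancestral population chosen by the sample's ancestry fractions.
#'
#' @param panel an [AncestralPanel-class].
#' @param q a [QMatrix-class] with the same component count/order.
#' @param seed integer seed.
#' @return A [GenotypeCohort-class] (no missingness yet).
#' @export
simulateGenotypes <- function(panel, q, seed = 1L) {
  stopifnot(is(panel, "AncestralPanel"), is(q, "QMatrix"))
  if (ncol(q@Q) != nrow(panel@freqs))
    stop("panel and Q disagree on the number of ancestral components")
  set.seed(seed)
  pii <- q@Q %*% panel@freqs                 # n x m expected allele freq
  pii <- pmin(pmax(pii, 0), 1)               # guard float overshoot
  g <- matrix(stats::rbinom(length(pii), 2L, pii), nrow = nrow(pii))
  gt <- t(g)                                  # sites x samples
  variants <- parseVariantKey(panel@sites)
  samples <- data.frame(sample_id = rownames(q@Q))
  GenotypeCohort(gt, variants, samples)
}

#' Platform mask constructor
#'
#' Describes which sites a genotyping platform observes and its genotype
#' missingness rate. By convention WGS covers all sites.
#'
#' @param platform one of `"WGG"`, `"WES"`, `"WGS"`.
#' @param nSites total number of sites in the source cohort.
#' @param fraction fraction of sites covered (ignored for WGS, which always
#'   covers everything).
#' @param missingRate per-genotype missing probability in \[0, 1).
#' @param seed integer seed for the site subset draw.
#' @param include site indices always included in the subset (arrays and
#'   exome capture deliberately target clinically annotated content, so
#'   planted annotated sites are covered by every platform).
#' @return list with `platform`, `siteSubset` (sorted indices),
#'   `missingRate`.
#' @export
platformMask <- function(platform, nSites, fraction = 1, missingRate = 0,
                         seed = 1L, include = integer()) {
  platform <- match.arg(platform, .PLATFORMS)
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must lie in [0, 1)")
  if (platform == "WGS" || fraction >= 1) {
    subset <- seq_len(nSites)
  } else {
    set.seed(seed)
    subset <- sort(union(
      sample.int(nSites, max(0L, round(fraction * nSites))),
      as.integer(include)))
  }
  list(platform = platform, siteSubset = subset, missingRate = missingRate)
}

#' Split a cohort into platform-specific datasets with missingness
#'
#' Restricts each dataset to its mask's site subset and independently sets
#' genotypes missing at the mask's rate (missing completely at random). The
#' datasets partition the samples of the input cohort.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param assignment named character vector mapping every sample id to a
#'   dataset id.
#' @param masks named list of [platformMask()] results, one per dataset id.
#' @param seed integer seed.
#' @return named list of [GenotypeCohort-class] datasets.
#' @export
applyPlatformMasks <- function(cohort, assignment, masks, seed = 1L) {
  ids <- sampleIds(cohort)
  if (!all(ids %in% names(assignment)))
    stop("every sample must be assigned to a dataset")
  dsIds <- unique(assignment[ids])
  if (!all(dsIds %in% names(masks)))
    stop("missing platform mask for: ",
         paste(setdiff(dsIds, names(masks)), collapse = ", "))
  set.seed(seed)
  out <- list()
  gt <- genotypes(cohort)
  variants <- as.data.frame(rowData(cohort))[, c("chrom", "pos", "ref", "alt")]
  for (ds in dsIds) {
    mask <- masks[[ds]]
    cols <- ids[assignment[ids] == ds]
    sub <- gt[mask$siteSubset, cols, drop = FALSE]
    if (mask$missingRate > 0 && length(sub))
      sub[stats::runif(length(sub)) < mask$missingRate] <- NA_integer_
    out[[ds]] <- GenotypeCohort(
      sub, variants[mask$siteSubset, , drop = FALSE],
      data.frame(sample_id = cols, dataset = ds, platform = mask$platform))
  }
  out
}

#' Simulate a sparse clinical/pharmacogenomic annotation catalog
#'
#' Assigns every site an independent categorical ClinVar-style pathogenicity
#' class and PharmGKB-style evidence level; the residual probability mass
#' goes to `"none"`. Stands in for a real annotation source so that
#' ancestry-stratified yield and evidence filtering are testable.
#'
#' @param sites character vector of variant keys.
#' @param classProbs named probabilities for `uncertain`, `conflicting`,
#'   `pathogenic_lp` (sum must be <= 1). Defaults reflect the usual ordering
#'   uncertain > conflicting > pathogenic/likely-pathogenic.
#' @param levelProbs named probabilities for evidence levels
#'   `1A, 1B, 2A, 2B, 3, 4` (sum <= 1).
#' @param seed integer seed.
#' @return data.frame with columns `key`, `clinvar_class`, `pharm_level`,
#'   `label` (free-text drug/disease placeholder).
#' @export
simulateAnnotations <- function(sites,
                                classProbs = c(uncertain = 0.030,
                                               conflicting = 0.012,
                                               pathogenic_lp = 0.004),
                                levelProbs = c(`1A` = 0.001, `1B` = 0.001,
                                               `2A` = 0.002, `2B` = 0.002,
                                               `3` = 0.006, `4` = 0.008),
                                seed = 1L) {
  if (any(classProbs < 0) || any(levelProbs < 0))
    stop("probabilities must be non-negative")
  if (sum(classProbs) > 1 + 1e-12 || sum(levelProbs) > 1 + 1e-12)
    stop("probability vectors must sum to at most 1")
  set.seed(seed)
  n <- length(sites)
  cls <- sample(c(names(classProbs), "none"), n, replace = TRUE,
                prob = c(classProbs, 1 - sum(classProbs)))
  lvl <- sample(c(names(levelProbs), "none"), n, replace = TRUE,
                prob = c(levelProbs, 1 - sum(levelProbs)))
  label <- ifelse(cls == "none" & lvl == "none", "",
                  sprintf("trait_%04d", sample.int(9999L, n, replace = TRUE)))
  data.frame(key = as.character(sites), clinvar_class = cls,
             pharm_level = lvl, label = label, stringsAsFactors = FALSE)
}

#' Default configuration for a full synthetic multi-platform cohort
#'
#' Desk-scale analogue of a multi-source national cohort: three datasets
#' (one array, one exome, one genome), a five-cluster admixture structure
#' and a handful of strongly ancestry-divergent sites planted with clinical
#' or pharmacogenomic annotations.
#'
#' @param nSamples cohort size (default 300).
#' @param m site count (default 8000).
#' @param nDivergent number of planted ancestry-divergent sites.
#' @param divergence per-population Balding-Nichols `F`.
#' @param concentration Dirichlet scale of the cluster spec.
#' @return list of generator settings consumed by [simulateCohortDatasets()].
#' @export
defaultSimulationConfig <- function(nSamples = 300L, m = 8000L,
                                    nDivergent = 12L,
                                    divergence = c(AFR = 0.15, AME = 0.15,
                                                   EUR = 0.15),
                                    concentration = 100) {
  list(
    nSamples = as.integer(nSamples), m = as.integer(m),
    nDivergent = as.integer(nDivergent), divergence = divergence,
    concentration = concentration,
    # dataset id -> (platform, fraction of samples, site fraction, missing)
    datasets = list(
      ARR = list(platform = "WGG", sampleFrac = 0.50, siteFrac = 0.45,
                 missingRate = 0.02),
      EXO = list(platform = "WES", sampleFrac = 0.30, siteFrac = 0.20,
                 missingRate = 0.05),
      GEN = list(platform = "WGS", sampleFrac = 0.20, siteFrac = 1.00,
                 missingRate = 0.01)),
    nDuplicates = 2L,     # planted duplicate samples (kinship QC exercise)
    referencePerPop = 60L)
}

#' Generate a complete synthetic multi-platform cohort with ground truth
#'
#' Runs the whole generative model: ancestral frequencies (with a set of
#' planted strongly-divergent sites mimicking variants like the
#' malaria-resistance Duffy-null allele), admixture profiles, genotypes,
#' platform masks with missingness, duplicate samples, a labeled reference
#' panel drawn from the same ancestral frequencies, and an annotation
#' catalog in which planted divergent sites carry pathogenic or
#' high-evidence pharmacogenomic annotations.
#'
#' @param config list from [defaultSimulationConfig()].
#' @param seed integer seed; all internal streams derive from it.
#' @return list with `datasets` (list of [GenotypeCohort-class]), `panel`
#'   ([AncestralPanel-class]), `trueQ` ([QMatrix-class]), `catalog`
#'   (annotation data.frame), `reference` (labeled [GenotypeCohort-class]),
#'   `referenceLabels`, `divergentKeys`, `duplicatePairs`.
#' @export
simulateCohortDatasets <- function(config = defaultSimulationConfig(),
                                   seed = 1L) {
  panel <- simulateAncestralFreqs(config$m, config$divergence,
                                  seed = .childSeed(seed, 1L))
  # Plant divergent sites: one focal population nearly fixed for the
  # alternate allele, the others nearly devoid of it.
  divergentKeys <- character()
  idx <- integer()
  if (config$nDivergent > 0L) {
    set.seed(.childSeed(seed, 2L))
    idx <- sample.int(config$m, config$nDivergent)
    focal <- rep_len(seq_len(nrow(panel@freqs)), config$nDivergent)
    for (ii in seq_along(idx)) {
      panel@freqs[, idx[ii]] <- 0.02
      panel@freqs[focal[ii], idx[ii]] <- 0.85
    }
    divergentKeys <- panel@sites[idx]
  }

  spec <- defaultClusterSpec(config$nSamples, config$concentration)
  trueQ <- simulateAdmixtureProfiles(spec, seed = .childSeed(seed, 3L))
  cohort <- simulateGenotypes(panel, trueQ, seed = .childSeed(seed, 4L))

  # Planted duplicates: copy the genotypes of the first samples onto the
  # last ones so the kinship filter has work to do.
  dupPairs <- NULL
  nd <- min(config$nDuplicates, floor(config$nSamples / 10))
  if (nd > 0L) {
    gt <- genotypes(cohort)
    src <- seq_len(nd)
    dst <- ncol(gt) - seq_len(nd) + 1L
    gt[, dst] <- gt[, src]
    cohort <- GenotypeCohort(
      gt, parseVariantKey(variantKeys(cohort)),
      data.frame(sample_id = sampleIds(cohort)))
    dupPairs <- data.frame(original = sampleIds(cohort)[src],
                           duplicate = sampleIds(cohort)[dst])
  }

  # Assign samples to datasets proportionally, then mask.
  set.seed(.childSeed(seed, 5L))
  ids <- sampleIds(cohort)
  fr <- vapply(config$datasets, function(d) d$sampleFrac, numeric(1))
  dsOf <- sample(rep(names(config$datasets),
                     times = .apportion(length(ids), fr / sum(fr))))
  names(dsOf) <- ids
  masks <- list()
  for (ds in names(config$datasets)) {
    d <- config$datasets[[ds]]
    masks[[ds]] <- platformMask(d$platform, config$m, d$siteFrac,
                                d$missingRate,
                                seed = .childSeed(seed, 10L + match(ds, names(config$datasets))),
                                include = idx)
  }
  datasets <- applyPlatformMasks(cohort, dsOf, masks,
                                 seed = .childSeed(seed, 6L))

  catalog <- simulateAnnotations(panel@sites, seed = .childSeed(seed, 7L))
  # Planted divergent sites get deterministic annotations cycling through
  # pathogenic, high-evidence pharmacogenomic, and both.
  if (length(divergentKeys)) {
    rows <- match(divergentKeys, catalog$key)
    kind <- rep_len(1:3, length(rows))
    catalog$clinvar_class[rows[kind != 2L]] <- "pathogenic_lp"
    catalog$pharm_level[rows[kind != 1L]] <-
      rep_len(c("1A", "2A", "2B", "1B"), sum(kind != 1L))
    catalog$label[rows] <- sprintf("planted_divergent_%02d", seq_along(rows))
  }

  # Labeled reference panel: unadmixed samples from each ancestral source.
  refQ <- QMatrix(diag(nrow(panel@freqs))[rep(seq_len(nrow(panel@freqs)),
                                              each = config$referencePerPop), ,
                                          drop = FALSE],
                  components = panel@popLabels)
  rownames(refQ@Q) <- sprintf("REF%03d", seq_len(nrow(refQ@Q)))
  reference <- simulateGenotypes(panel, refQ, seed = .childSeed(seed, 8L))
  refLabels <- rep(panel@popLabels, each = config$referencePerPop)
  names(refLabels) <- sampleIds(reference)

  list(datasets = datasets, panel = panel, trueQ = trueQ, catalog = catalog,
       reference = reference, referenceLabels = refLabels,
       divergentKeys = divergentKeys, duplicatePairs = dupPairs,
       config = config, seed = seed)
}

# Largest-remainder apportionment of n items into parts with given shares.
.apportion <- function(n, shares) {
  raw <- n * shares
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
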