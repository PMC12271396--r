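#' @include accessors.R utils.R
NULL

#' Build the 2 x k allele-count table for one site
#'
#' Per cluster: alternate count = sum of dosages over non-missing samples,
#' reference count = twice the non-missing sample count minus the alternate
#' count. A cluster with the site entirely missing keeps a (0, 0) column
#' with a warning.
#'
#' @param g integer dosage vector for one site (0/1/2/NA), one entry per
#'   sample.
#' @param clusterAssign integer cluster index per sample.
#' @param clusterNames character names, one per cluster index.
#' @return A [ContingencyTable2xK-class].
#' @export
buildAlleleTable <- function(g, clusterAssign, clusterNames = NULL) {
  k <- max(clusterAssign)
  if (is.null(clusterNames)) clusterNames <- paste0("C", seq_len(k))
  alt <- integer(k); ref <- integer(k)
  for (c in seq_len(k)) {
    gc <- g[clusterAssign == c]
    gc <- gc[!is.na(gc)]
    alt[c] <- sum(gc)
    ref[c] <- 2L * length(gc) - alt[c]
  }
  if (any(alt + ref == 0L))
    warning("cluster(s) with no observed genotypes at this site: ",
            paste(clusterNames[alt + ref == 0L], collapse = ", "))
  ContingencyTable2xK(ref, alt, clusterNames)
}

#' Two-sided exact test for a 2 x k allele-count table
#'
#' Computes the exact two-sided p-value under the probability-mass ordering:
#' the sum of multivariate-hypergeometric probabilities (fixed column totals
#' and fixed total alternate count) of all tables at most as probable as the
#' observed one, with a relative tie tolerance of 1e-7. The enumeration uses
#' a branch-and-bound network scheme that collapses wholly-extreme subtrees
#' to closed-form binomial masses, so tables with thousands of alleles
#' remain tractable. If the search exceeds `mcCutoff` expanded nodes the
#' p-value is instead estimated by Monte-Carlo sampling of tables with the
#' observed margins (`mcReps` draws, seeded) and reported with a standard
#' error.
#'
#' Zero-total columns are dropped before testing (reducing k); a table with
#' a single remaining column has p = 1 by construction.
#'
#' @param table a [ContingencyTable2xK-class] (or list with `ref`, `alt`).
#' @param mcCutoff node budget for the exact search.
#' @param mcReps Monte-Carlo replicates for the fallback.
#' @param seed integer seed for the fallback.
#' @return list with `p`, `method` (`"exact"` or `"monte_carlo"`), `se`
#'   (`NA` for exact), and `k` (columns tested).
#' @export
fisherExact2xK <- function(table, mcCutoff = 5e7, mcReps = 1e6, seed = 1L) {
  ref <- table@ref; alt <- table@alt
  tot <- ref + alt
  keep <- tot > 0L
  if (!any(keep)) stop("all-zero table")
  ref <- ref[keep]; alt <- alt[keep]; tot <- tot[keep]
  if (length(tot) == 1L)
    return(list(p = 1, method = "exact", se = NA_real_, k = 1L))
  res <- .fisher2xk_exact_cpp(alt, tot, relTol = 1e-7,
                              nodeBudget = mcCutoff)
  if (isTRUE(res$ok))
    return(list(p = res$p, method = "exact", se = NA_real_,
                k = length(tot)))
  mc <- .fisherMonteCarlo(alt, tot, mcReps, seed)
  list(p = mc$p, method = "monte_carlo", se = mc$se, k = length(tot))
}

# Screen-path p-value. Exact enumeration effort is spent only where the
# significance decision could depend on it:
#   1. a cheap chi-square statistic routes clearly-null tables
#      (approximate p > 0.01) to Monte-Carlo with staged replicates; the
#      chi-square value is only a routing heuristic and is never reported;
#   2. other tables get the bounded exact search, which either solves the
#      table or returns certified lower/upper bounds on p from the partial
#      enumeration;
#   3. when the budget is exhausted, the significance decision is taken
#      from the certified bounds whenever they do not straddle `alpha`
#      (escalating the budget 100-fold once if they do), and the reported
#      value is the importance-sampled estimate clipped into the bounds.
# The method tag records which estimator produced the reported value.
.fisherScreenP <- function(alt, tot, mcCutoff, mcReps, seed, alpha = 5e-8) {
  if (.chisqRouteP(alt, tot) > 0.01) {
    mc <- .fisherStagedMc(alt, tot, mcReps, seed)
    if (mc$p * (mc$reps + 1) - 1 >= 20)
      return(list(p = mc$p, method = "monte_carlo"))
    # approximation misrouted an extreme table: fall through
  }
  # The exact attempts truncate subtrees carrying less than 1% of alpha in
  # total certified mass, so a "solved" table's p carries a certified
  # absolute error below alpha / 100 - irrelevant to any decision or
  # reported digit at the screen's scale.
  res <- .fisher2xk_exact_cpp(alt, tot, relTol = 1e-7,
                              nodeBudget = mcCutoff,
                              massTol = alpha * 0.01)
  if (!isTRUE(res$ok) && res$lb <= alpha && alpha <= res$ub)
    res <- .fisher2xk_exact_cpp(alt, tot, relTol = 1e-7,
                                nodeBudget = 100 * mcCutoff,
                                massTol = alpha * 0.01)
  if (isTRUE(res$ok))
    return(list(p = res$p, method = "exact"))
  is <- .fisherImportance(alt, tot, seed)
  p <- if (is.na(is$p)) (res$lb + res$ub) / 2 else
    min(max(is$p, res$lb), res$ub)
  list(p = p, method = "monte_carlo")
}

# Importance-sampled p-value for far-tail tables with fixed margins.
# Proposal: independent per-column binomials at the observed column
# frequencies, conditioned on the alt-row total by rejection, which centers
# proposal mass on the neighborhood of the observed table where the
# dominant share of the extreme region's probability lies. The
# conditioning constant Z = P(sum of column binomials = A) is computed
# exactly by convolving the column pmfs, so the weights
# w = P0 / (prod Binom / Z) give an unbiased estimator of the extreme mass
# within the proposal's support; extreme mass far from the proposal is
# missed, so the estimate is a slight underestimate. Engaged only when the
# true p is orders of magnitude below any reporting threshold, where this
# cannot affect a significance decision; the standard error is reported.
.fisherImportance <- function(alt, tot, seed, nTarget = 1e4) {
  set.seed(seed)
  k <- length(tot)
  N <- sum(tot); A <- sum(alt)
  qhat <- pmin(pmax(alt / tot, 1e-3), 1 - 1e-3)
  lpObs <- sum(lchoose(tot, alt))
  # exact log of the conditioning constant P(sum = A) under the proposal
  conv <- 1
  for (i in seq_len(k)) {
    pmfI <- stats::dbinom(0:tot[i], tot[i], qhat[i])
    new <- numeric(length(conv) + tot[i])
    for (a in 0:tot[i])
      new[(a + 1):(a + length(conv))] <-
        new[(a + 1):(a + length(conv))] + pmfI[a + 1] * conv
    conv <- new
  }
  logZ <- log(conv[A + 1])
  acc <- matrix(0L, nrow = 0, ncol = k)
  nb <- 50000L
  for (batch in seq_len(40L)) {
    draw <- matrix(stats::rbinom(nb * k, size = rep(tot, each = nb),
                                 prob = rep(qhat, each = nb)),
                   nrow = nb, ncol = k)
    draw <- draw[rowSums(draw) == A, , drop = FALSE]
    acc <- rbind(acc, draw)
    if (nrow(acc) >= nTarget) break
  }
  if (nrow(acc) < 100L)      # proposal failed to hit the margin
    return(list(p = NA_real_, method = "monte_carlo", se = NA_real_))
  lp <- numeric(nrow(acc))
  lg <- numeric(nrow(acc))
  for (i in seq_len(k)) {
    lp <- lp + lchoose(tot[i], acc[, i])
    lg <- lg + stats::dbinom(acc[, i], tot[i], qhat[i], log = TRUE)
  }
  # unbiased IS terms: P0(a) / [prod Binom(a) / Z]
  lw <- lp - lchoose(N, A) - (lg - logZ)
  ext <- lp <= lpObs + log1p(1e-7)
  terms <- exp(lw) * ext
  p <- mean(terms)
  se <- stats::sd(terms) / sqrt(length(terms))
  list(p = p, method = "monte_carlo", se = se)
}

.chisqRouteP <- function(alt, tot) {
  A <- sum(alt); N <- sum(tot)
  eAlt <- tot * A / N
  eRef <- tot - eAlt
  stat <- sum((alt - eAlt)^2 / eAlt + ((tot - alt) - eRef)^2 / eRef)
  stats::pchisq(stat, df = length(tot) - 1L, lower.tail = FALSE)
}

# Staged plain MC: escalate replicates (1e4 then 1e5) only while the
# extreme-draw count is too small for a stable estimate. Tables that remain
# unresolved are far below any discard decision and are handed back to the
# caller (reps is returned so the caller can see the resolution achieved).
.fisherStagedMc <- function(alt, tot, mcReps, seed) {
  reps <- 1e4
  repeat {
    mc <- .fisherMonteCarlo(alt, tot, reps, seed)
    mc$reps <- reps
    if (mc$p * (reps + 1) - 1 >= 20 || reps >= min(1e5, mcReps)) return(mc)
    reps <- min(reps * 10, mcReps)
  }
}

# Monte-Carlo p under fixed margins: columns are filled sequentially with
# nested hypergeometric draws; the (1 + extreme) / (reps + 1) estimator
# keeps p in (0, 1].
.fisherMonteCarlo <- function(alt, tot, reps, seed) {
  set.seed(seed)
  k <- length(tot)
  N <- sum(tot); A <- sum(alt)
  lpObs <- sum(lchoose(tot, alt))
  remA <- rep(A, reps)
  remN <- N
  lp <- numeric(reps)
  for (i in seq_len(k - 1L)) {
    lut <- lchoose(tot[i], 0:tot[i])      # lookup beats lgamma per draw
    a <- stats::rhyper(reps, remA, remN - remA, tot[i])
    lp <- lp + lut[a + 1L]
    remA <- remA - a
    remN <- remN - tot[i]
  }
  lutK <- lchoose(tot[k], 0:tot[k])
  lp <- lp + lutK[remA + 1L]
  extreme <- sum(lp <= lpObs + log1p(1e-7))
  p <- (1 + extreme) / (reps + 1)
  list(p = p, se = sqrt(p * (1 - p) / reps))
}

#' Multi-group weighted FST for one biallelic site
#'
#' Computes `FST = 1 - H_S_bar / H_T`, where `H_T = 2 p q` is the total
#' heterozygosity from the pooled allele frequencies and
#' `H_S_bar = sum_i 2 p_i q_i f(i)` is the average within-cluster
#' heterozygosity weighted by the proportion of individuals in each cluster.
#' A monomorphic site (`H_T = 0`) returns FST = 0 with a flag; a cluster
#' with no observed alleles contributes zero heterozygosity with its weight
#' and a warning.
#'
#' @param table a [ContingencyTable2xK-class].
#' @param clusterSizes individuals per cluster (weights `f(i)` are their
#'   proportions). Defaults to the table's non-missing sample counts
#'   (column totals / 2).
#' @return list with `fst`, `ht`, `hsBar`, per-cluster `p`, `q`, weights
#'   `f`, and `monomorphic` flag.
#' @export
fstFromTable <- function(table, clusterSizes = NULL) {
  ref <- as.numeric(table@ref); alt <- as.numeric(table@alt)
  tot <- ref + alt
  if (is.null(clusterSizes)) clusterSizes <- tot / 2
  if (sum(clusterSizes) <= 0) stop("cluster sizes must sum to > 0")
  if (sum(tot) <= 0) stop("overall allele total must be positive")
  f <- clusterSizes / sum(clusterSizes)
  qi <- ifelse(tot > 0, alt / tot, 0)
  pi <- 1 - qi
  if (any(tot == 0))
    warning("cluster(s) with zero allele total contribute H_i = 0")
  q <- sum(alt) / sum(tot)
  p <- 1 - q
  ht <- 2 * p * q
  hsBar <- sum(2 * pi * qi * f)
  if (ht == 0)
    return(list(fst = 0, ht = 0, hsBar = hsBar, p = pi, q = qi, f = f,
                monomorphic = TRUE))
  list(fst = 1 - hsBar / ht, ht = ht, hsBar = hsBar, p = pi, q = qi, f = f,
       monomorphic = FALSE)
}

#' Designate the enrichment cluster of a table
#'
#' Returns the name of the cluster with the highest alternate-allele
#' frequency; ties are broken by the larger column total, then by name
#' order.
#'
#' @param table a [ContingencyTable2xK-class].
#' @return cluster name (character).
#' @export
designateEnrichedCluster <- function(table) {
  tot <- table@ref + table@alt
  if (all(tot == 0L)) stop("all columns are empty")
  freq <- ifelse(tot > 0, table@alt / tot, -Inf)
  ord <- order(-freq, -tot, table@clusters)
  table@clusters[ord[1]]
}

#' Poisson regression of genotype on an ancestry fraction
#'
#' Fits `genotype ~ ancestry` with a Poisson log link by iteratively
#' reweighted least squares (genotype in 0/1/2 alternate alleles, ancestry
#' fraction in \[0, 1\]) and reports the Wald test on the slope. Requires at
#' least 10 non-missing genotypes. When every genotype is zero, the slope is
#' unidentified (the likelihood increases without bound in the negative
#' direction) and the fit is returned with `converged = FALSE` and a
#' diagnostic instead of numbers.
#'
#' @param g integer dosage vector for one site.
#' @param q a [QMatrix-class] (samples in the same order as `g`).
#' @param component ancestry component name (column of the Q matrix).
#' @return list with `component`, `intercept`, `slope`, `se`, `waldP`,
#'   `converged`, `diagnostic`.
#' @export
poissonAncestryRegression <- function(g, q, component) {
  x <- qvalues(q)[, component]
  ok <- !is.na(g)
  g2 <- g[ok]; x2 <- x[ok]
  if (length(g2) < 10L)
    stop("need at least 10 non-missing genotypes")
  fail <- list(component = component, intercept = NA_real_,
               slope = NA_real_, se = NA_real_, waldP = NA_real_,
               converged = FALSE, diagnostic = "")
  if (all(g2 == 0L)) {
    fail$diagnostic <- "all genotypes zero: slope unidentified"
    return(fail)
  }
  fit <- suppressWarnings(
    stats::glm(g2 ~ x2, family = stats::poisson(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100L)))
  if (!fit$converged) {
    fail$diagnostic <- "IRLS did not converge"
    return(fail)
  }
  sm <- summary(fit)$coefficients
  if (nrow(sm) < 2L) {
    fail$diagnostic <- "slope aliased (constant ancestry fraction)"
    return(fail)
  }
  list(component = component, intercept = unname(sm[1, 1]),
       slope = unname(sm[2, 1]), se = unname(sm[2, 2]),
       waldP = unname(sm[2, 4]), converged = TRUE, diagnostic = "")
}

#' Genome-wide screen for ancestry-enriched variants
#'
#' For every site of the harmonized cohort, builds the 2 x k allele table
#' across named ancestry clusters and computes the exact test p-value; sites
#' with `p < alpha` are retained and annotated with FST (weighted by
#' non-missing individuals per cluster), the enrichment cluster, the three
#' per-ancestry Poisson regressions, and the catalog's clinical /
#' pharmacogenomic classes. Results are sorted by ascending p. The
#' `pharmacogenomic` and `clinical` attributes partition the hits carrying a
#' PharmGKB-style evidence level or a ClinVar-style class.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param clusters a named [AncestryClusters-class] whose assignment is
#'   parallel to the cohort samples.
#' @param q a [QMatrix-class] for the cohort samples.
#' @param catalog annotation data.frame (`key`, `clinvar_class`,
#'   `pharm_level`, `label`); may be `NULL`.
#' @param alpha genome-wide significance threshold (default 5e-8).
#' @param mcCutoff node budget for the per-site exact attempt; sites whose
#'   enumeration exceeds it (mid-frequency tables with large counts) are
#'   settled by staged Monte-Carlo, escalating from 1e4 up to `mcReps`
#'   draws only while the estimate remains small. Strongly enriched sites
#'   have extreme tables and are solved exactly.
#' @param mcReps Monte-Carlo replicate ceiling.
#' @param seed integer seed for the Monte-Carlo streams.
#' @return data.frame with one row per significant site (key, chrom, pos,
#'   allele_count, fisher_p, method, fst, enriched_cluster, annotation
#'   columns, and slope/p per ancestry component), with attributes
#'   `"pharmacogenomic"`, `"clinical"` (row subsets) and `"n_tested"`.
#' @export
screenGenome <- function(cohort, clusters, q, catalog = NULL, alpha = 5e-8,
                         mcCutoff = 3e5, mcReps = 1e6, seed = 1L) {
  gt <- genotypes(cohort)
  if (nrow(gt) == 0L || ncol(gt) == 0L) {
    warning("empty cohort: nothing to screen")
    out <- data.frame()
    attr(out, "pharmacogenomic") <- out
    attr(out, "clinical") <- out
    attr(out, "n_tested") <- 0L
    return(out)
  }
  assign <- clusters@assignment
  stopifnot(length(assign) == ncol(gt))
  k <- clusters@k
  nms <- clusters@clusterNames
  altC <- matrix(0L, nrow(gt), k)
  nmC <- matrix(0L, nrow(gt), k)
  for (c in seq_len(k)) {
    cols <- assign == c
    altC[, c] <- as.integer(rowSums(gt[, cols, drop = FALSE], na.rm = TRUE))
    nmC[, c] <- as.integer(rowSums(!is.na(gt[, cols, drop = FALSE])))
  }
  totC <- 2L * nmC
  pvals <- numeric(nrow(gt))
  method <- character(nrow(gt))
  for (s in seq_len(nrow(gt))) {
    keep <- totC[s, ] > 0L
    if (sum(keep) < 2L || sum(altC[s, ]) == 0L ||
        sum(altC[s, ]) == sum(totC[s, ])) {
      pvals[s] <- 1; method[s] <- "exact"; next
    }
    res <- .fisherScreenP(altC[s, keep], totC[s, keep], mcCutoff, mcReps,
                          .childSeed(seed, s), alpha = alpha)
    pvals[s] <- res$p; method[s] <- res$method
  }
  hit <- which(pvals < alpha)
  hit <- hit[order(pvals[hit])]
  rd <- rowData(cohort)
  rows <- lapply(hit, function(s) {
    tab <- ContingencyTable2xK(totC[s, ] - altC[s, ], altC[s, ], nms)
    fstRes <- suppressWarnings(fstFromTable(tab, clusterSizes = nmC[s, ]))
    poi <- lapply(colnames(qvalues(q)), function(comp)
      tryCatch(poissonAncestryRegression(gt[s, ], q, comp),
               error = function(e) list(slope = NA_real_, waldP = NA_real_)))
    names(poi) <- colnames(qvalues(q))
    base <- data.frame(
      key = rownames(gt)[s], chrom = rd$chrom[s], pos = rd$pos[s],
      allele_count = sum(totC[s, ]), fisher_p = pvals[s],
      method = method[s], fst = fstRes$fst,
      enriched_cluster = designateEnrichedCluster(tab),
      stringsAsFactors = FALSE)
    for (comp in names(poi)) {
      base[[paste0("slope_", comp)]] <- poi[[comp]]$slope
      base[[paste0("p_", comp)]] <- poi[[comp]]$waldP
    }
    base
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(key = character(), chrom = character(), pos = integer(),
               allele_count = integer(), fisher_p = numeric(),
               method = character(), fst = numeric(),
               enriched_cluster = character(), stringsAsFactors = FALSE)
  if (!is.null(catalog) && nrow(out)) {
    idx <- match(out$key, catalog$key)
    out$clinvar_class <- ifelse(is.na(idx), "none",
                                catalog$clinvar_class[idx])
    out$pharm_level <- ifelse(is.na(idx), "none", catalog$pharm_level[idx])
    out$label <- ifelse(is.na(idx), "", catalog$label[idx])
  } else if (nrow(out)) {
    out$clinvar_class <- "none"; out$pharm_level <- "none"; out$label <- ""
  }
  rownames(out) <- NULL
  attr(out, "pharmacogenomic") <-
    if (nrow(out)) out[out$pharm_level != "none", , drop = FALSE] else out
  attr(out, "clinical") <-
    if (nrow(out)) out[out$clinvar_class != "none", , drop = FALSE] else out
  attr(out, "n_tested") <- nrow(gt)
  attr(out, "pvalues") <- setNames(pvals, rownames(gt))
  out
}
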