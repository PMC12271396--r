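#' @include accessors.R utils.R
NULL

#' Fit a PCA model on a labeled reference panel
#'
#' Genotype dosages are centered by twice the panel allele frequency and
#' scaled by `sqrt(2 p (1 - p))` (the standard genotype standardization for
#' ancestry PCA); missing entries are mean-imputed (zero after centering);
#' monomorphic sites are excluded. The decomposition is the SVD of the
#' standardized sample-by-site matrix, equivalent to the
#' eigendecomposition of the sample covariance.
#'
#' @param ref a [GenotypeCohort-class] of reference samples.
#' @param nComponents number of components to retain.
#' @return A [PCModel-class]; reference-sample scores are attached as
#'   attribute `"scores"`.
#' @export
fitReferencePca <- function(ref, nComponents = 10L) {
  gt <- genotypes(ref)
  n <- ncol(gt)
  if (n < nComponents + 1L)
    stop("need at least nComponents + 1 reference samples")
  p <- rowMeans(gt, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < nComponents)
    stop("fewer polymorphic sites than requested components")
  gt <- gt[poly, , drop = FALSE]
  p <- p[poly]
  sc <- sqrt(2 * p * (1 - p))
  X <- (t(gt) - rep(2 * p, each = n)) / rep(sc, each = n)   # samples x sites
  X[is.na(X)] <- 0
  sv <- svd(X, nu = min(n, nComponents), nv = nComponents)
  eig <- sv$d^2 / (n - 1)
  pctVar <- 100 * eig / sum(eig)
  loadings <- sv$v
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  model <- new("PCModel", sites = rownames(gt), refFreq = unname(p),
               scale = unname(sc), loadings = loadings,
               eigenvalues = eig[seq_len(nComponents)],
               pctVar = pctVar[seq_len(nComponents)])
  scores <- X %*% loadings
  rownames(scores) <- colnames(gt)
  attr(model, "scores") <- scores
  model
}

#' Project samples onto a reference PC space
#'
#' Genotypes at the model's sites are standardized with the model's
#' reference frequencies; entries missing in a sample (or sites absent from
#' its dataset) are imputed to the reference mean before projection. Samples
#' observing fewer than half of the model sites are projected with a
#' warning; samples observing none raise an error.
#'
#' @param model a [PCModel-class].
#' @param cohort a [GenotypeCohort-class].
#' @return numeric matrix of PC coordinates, samples x components.
#' @export
projectSamples <- function(model, cohort) {
  gt <- genotypes(cohort)
  idx <- match(model@sites, rownames(gt))
  present <- !is.na(idx)
  if (!any(present)) stop("no overlap between cohort and model sites")
  n <- ncol(gt)
  G <- matrix(NA_integer_, nrow = length(model@sites), ncol = n)
  G[present, ] <- gt[idx[present], , drop = FALSE]
  obsFrac <- colMeans(!is.na(G))
  if (any(obsFrac == 0))
    stop("sample(s) with no observed genotypes at model sites: ",
         paste(utils::head(colnames(gt)[obsFrac == 0], 3), collapse = ", "))
  if (any(obsFrac < 0.5))
    warning(sum(obsFrac < 0.5),
            " sample(s) observe fewer than 50% of model sites")
  X <- (t(G) - rep(2 * model@refFreq, each = n)) /
    rep(model@scale, each = n)
  X[is.na(X)] <- 0
  scores <- X %*% model@loadings
  rownames(scores) <- colnames(gt)
  scores
}

#' Infer ancestry fractions by EM on the admixture likelihood
#'
#' Maximizes the binomial admixture log-likelihood
#' `l = sum_ij [g_ij log(sum_k q_ik p_kj) + (2 - g_ij) log(sum_k q_ik (1 -
#' p_kj))]` over per-sample ancestry fractions Q (simplex rows) and
#' per-component allele frequencies P, by the classical EM updates in which
#' each allele copy's ancestral origin is the latent variable. The
#' log-likelihood is non-decreasing at every iteration; iteration stops when
#' the increase falls below `tol` or at `maxIter`. Missing genotypes are
#' skipped in the likelihood. Monomorphic sites are dropped with a warning
#' (they carry no ancestry information and destabilize the frequency
#' updates).
#'
#' In supervised mode, P is initialized from (and optionally fixed at) the
#' allele frequencies of a labeled reference panel, and components inherit
#' the panel population order. In unsupervised mode components are aligned
#' post hoc to the panel by maximal correlation of inferred frequencies when
#' a panel is supplied; without one, component order is arbitrary and a
#' warning is issued.
#'
#' @param cohort a [GenotypeCohort-class] (or dosage matrix, sites x
#'   samples).
#' @param K number of ancestral components (the three-way continental model
#'   uses 3).
#' @param maxIter,tol stopping rule: at most `maxIter` iterations, stop when
#'   the log-likelihood gain drops below `tol`.
#' @param seed integer seed for the random initialization.
#' @param supervisedPanel optional list with `genotypes` (a
#'   [GenotypeCohort-class]) and `labels` (named population label per
#'   sample), used for initialization/alignment.
#' @param fixP if `TRUE` (with a panel) the ancestral frequencies are frozen
#'   at the panel values and only Q is updated.
#' @return list with `Q` ([QMatrix-class]), `P` (K x m), `loglik` (trace),
#'   `iterations`, `converged`.
#' @export
fitAdmixtureEm <- function(cohort, K = 3L, maxIter = 2000L, tol = 1e-4,
                           seed = 1L, supervisedPanel = NULL,
                           fixP = FALSE) {
  if (K < 1L) stop("K must be at least 1")
  gt <- if (is.matrix(cohort)) cohort else genotypes(cohort)
  G <- t(gt)                              # samples x sites
  storage.mode(G) <- "integer"
  freq <- colMeans(G, na.rm = TRUE) / 2
  mono <- is.na(freq) | freq <= 0 | freq >= 1
  if (any(mono)) {
    warning(sum(mono), " monomorphic site(s) dropped before EM")
    G <- G[, !mono, drop = FALSE]
    freq <- freq[!mono]
  }
  n <- nrow(G); m <- ncol(G)
  if (m == 0L) stop("no polymorphic sites available")
  if (K == 1L) {                          # closed form
    Q <- matrix(1, n, 1, dimnames = list(rownames(G), "K1"))
    P <- matrix(freq, 1, m, dimnames = list("K1", colnames(G)))
    return(list(Q = QMatrix(Q, components = "K1"), P = P,
                loglik = numeric(0), iterations = 0L, converged = TRUE))
  }
  panelFreq <- NULL
  if (!is.null(supervisedPanel)) {
    pg <- genotypes(supervisedPanel$genotypes)
    labels <- supervisedPanel$labels[colnames(pg)]
    pops <- unique(labels)
    if (length(pops) != K)
      stop("supervised panel must have exactly K population labels")
    panelFreq <- matrix(NA_real_, K, m, dimnames = list(pops, colnames(G)))
    common <- intersect(colnames(G), rownames(pg))
    for (pp in pops) {
      f <- rowMeans(pg[common, labels == pp, drop = FALSE], na.rm = TRUE) / 2
      panelFreq[pp, common] <- f
    }
  }
  set.seed(seed)
  Q <- .rdirichlet(n, rep(1, K))
  if (!is.null(panelFreq)) {
    P <- panelFreq
    P[is.na(P)] <- matrix(freq, K, m, byrow = TRUE)[is.na(P)]
  } else {
    P <- matrix(stats::runif(K * m, 0.05, 0.95), K, m)
  }
  P <- pmin(pmax(P, 1e-6), 1 - 1e-6)
  llTrace <- numeric(0)
  converged <- FALSE
  it <- 0L
  llPrev <- -Inf
  # With a supervised panel, warm-start by updating Q alone against the
  # panel frequencies (also an EM step on the same likelihood, so the trace
  # stays monotone), then release P for joint refinement.
  warm <- !is.null(panelFreq) && !fixP
  warmLimit <- 300L
  while (it < maxIter) {
    it <- it + 1L
    stepRes <- .em_admixture_step_cpp(G, Q, P, updateP = !fixP && !warm)
    ll <- stepRes$loglik
    if (!is.finite(ll))
      stop("non-finite admixture log-likelihood at iteration ", it)
    llTrace <- c(llTrace, ll)
    Q <- stepRes$Q
    P <- stepRes$P
    if (warm) {
      if ((it > 1L && ll - llPrev < max(tol, 0.1)) || it >= warmLimit)
        warm <- FALSE
    } else if (it > 1L && ll - llPrev < tol) {
      converged <- TRUE
      break
    }
    llPrev <- ll
  }
  rownames(Q) <- rownames(G)
  colnames(P) <- colnames(G)
  comp <- paste0("K", seq_len(K))
  if (!is.null(panelFreq)) {
    perm <- .alignComponents(P, panelFreq)
    Q <- Q[, perm, drop = FALSE]
    P <- P[perm, , drop = FALSE]
    comp <- rownames(panelFreq)
  } else {
    warning("no reference panel supplied: component order is arbitrary")
  }
  colnames(Q) <- comp
  rownames(P) <- comp
  list(Q = QMatrix(Q, components = comp), P = P, loglik = llTrace,
       iterations = it, converged = converged)
}

# Greedy assignment of inferred components to panel populations by maximal
# correlation of allele-frequency profiles.
.alignComponents <- function(P, panelFreq) {
  K <- nrow(P)
  ok <- !colSums(is.na(panelFreq)) & apply(P, 2, stats::sd) >= 0
  cc <- stats::cor(t(P), t(panelFreq), use = "pairwise.complete.obs")
  perm <- integer(K)     # perm[target pop] = inferred component
  used <- logical(K)
  for (step in seq_len(K)) {
    best <- which(cc == max(cc, na.rm = TRUE), arr.ind = TRUE)[1, ]
    perm[best[2]] <- best[1]
    cc[best[1], ] <- -Inf
    cc[, best[2]] <- -Inf
  }
  perm
}

#' Choose the number of ancestry clusters by the K-means elbow
#'
#' Runs K-means (multiple restarts) on the ancestry-fraction rows for each
#' candidate K and selects the K maximizing the discrete curvature (second
#' difference) of the log within-cluster sum of squares across K; ties are
#' broken toward smaller K. Curvature is measured on the log scale because
#' the raw inertia profile of clustered data decays geometrically, so its
#' raw second difference always peaks at small K regardless of the true
#' cluster count; the log scale measures relative drops and peaks where the
#' geometric decay breaks. If the points are already (numerically)
#' identical, K = `kMin` with zero inertia is returned.
#'
#' @param q a [QMatrix-class] (or plain matrix of ancestry fractions).
#' @param kMin,kMax candidate range (requires `kMax < n`).
#' @param nRestarts K-means restarts per candidate.
#' @param seed integer seed (the choice is deterministic given the seed).
#' @return An [AncestryClusters-class] with placeholder cluster names
#'   `C1..CK` and the inertia profile in its `inertia` slot.
#' @export
kmeansElbow <- function(q, kMin = 1L, kMax = 10L, nRestarts = 25L,
                        seed = 1L) {
  Q <- if (is(q, "QMatrix")) qvalues(q) else as.matrix(q)
  n <- nrow(Q)
  if (kMax >= n) stop("kMax must be smaller than the number of samples")
  if (kMin < 1L || kMin > kMax) stop("invalid k range")
  set.seed(seed)
  # degenerate input: all points identical, nothing to cluster
  if (sum(scale(Q, scale = FALSE)^2) < 1e-12) {
    wss <- setNames(0, kMin)
    return(new("AncestryClusters", k = as.integer(kMin),
               assignment = rep(1L, n),
               centroids = matrix(colMeans(Q), kMin, ncol(Q),
                                  dimnames = list(NULL, colnames(Q)),
                                  byrow = TRUE),
               clusterNames = paste0("C", seq_len(kMin)), inertia = wss))
  }
  ks <- kMin:kMax
  fits <- vector("list", length(ks))
  wss <- numeric(length(ks))
  for (i in seq_along(ks)) {
    if (ks[i] == 1L) {
      wss[i] <- sum(scale(Q, scale = FALSE)^2)
      fits[[i]] <- list(cluster = rep(1L, n),
                        centers = matrix(colMeans(Q), 1))
    } else {
      fit <- suppressWarnings(
        stats::kmeans(Q, centers = ks[i], nstart = nRestarts,
                      iter.max = 100L))
      wss[i] <- fit$tot.withinss
      fits[[i]] <- fit
    }
  }
  names(wss) <- ks
  if (wss[1] < 1e-12) {
    chosen <- 1L
  } else if (length(ks) < 3L) {
    chosen <- which.min(wss)
  } else {
    lw <- log(pmax(wss, 1e-12))
    curv <- lw[seq_len(length(ks) - 2L)] -
      2 * lw[seq(2L, length(ks) - 1L)] + lw[seq(3L, length(ks))]
    chosen <- which.max(curv) + 1L     # index into ks
  }
  fit <- fits[[chosen]]
  centers <- as.matrix(fit$centers)
  colnames(centers) <- colnames(Q)
  new("AncestryClusters", k = as.integer(ks[chosen]),
      assignment = as.integer(fit$cluster), centroids = centers,
      clusterNames = paste0("C", seq_len(ks[chosen])), inertia = wss)
}

#' Name ancestry clusters from their centroids
#'
#' A cluster whose centroid's largest ancestry component reaches
#' `dominanceThreshold` is named after that component (AFR/AME/EUR); if two
#' clusters claim the same component the more dominant keeps the name.
#' Remaining clusters are named ADX1, ADX2, ... in order of decreasing
#' European centroid fraction, so ADX1 is the admixed cluster closest to
#' the European-like one.
#'
#' @param clusters an [AncestryClusters-class] with simplex centroids.
#' @param q unused placeholder kept for API symmetry (assignments already
#'   live in `clusters`); may be `NULL`.
#' @param dominanceThreshold minimum centroid component for an ancestral
#'   name (default 0.65).
#' @return the [AncestryClusters-class] with `clusterNames` filled in.
#' @export
labelClusters <- function(clusters, q = NULL, dominanceThreshold = 0.65) {
  cent <- clusters@centroids
  if (any(abs(rowSums(cent) - 1) > 1e-6))
    stop("centroids must lie on the simplex")
  comps <- colnames(cent)
  if (is.null(comps)) comps <- .ANCESTRY_COMPONENTS[seq_len(ncol(cent))]
  k <- nrow(cent)
  nm <- rep(NA_character_, k)
  maxComp <- apply(cent, 1, max)
  argComp <- comps[apply(cent, 1, which.max)]
  for (comp in comps) {
    cand <- which(argComp == comp & maxComp >= dominanceThreshold)
    if (length(cand)) {
      winner <- cand[which.max(maxComp[cand])]
      nm[winner] <- comp
    }
  }
  adx <- which(is.na(nm))
  if (length(adx)) {
    eurIdx <- match("EUR", comps)
    ordEur <- if (!is.na(eurIdx)) order(-cent[adx, eurIdx]) else
      seq_along(adx)
    nm[adx[ordEur]] <- paste0("ADX", seq_along(adx))
  }
  clusters@clusterNames <- nm
  rownames(clusters@centroids) <- nm
  clusters
}
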