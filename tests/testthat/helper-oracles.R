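# Independent oracles and small fixture builders shared across tests.

# Brute-force two-sided exact p for a 2 x k table: materializes every table
# with the observed margins via grid expansion and sums the probabilities of
# those at most as probable as the observed table (same tie tolerance as the
# implementation, independent code path).
oracleFisherP <- function(alt, tot) {
  k <- length(tot)
  A <- sum(alt); N <- sum(tot)
  if (A == 0 || A == N || k == 1) return(1)
  if (k == 2) {
    combos <- cbind(0:tot[1])
  } else {
    combos <- as.matrix(do.call(expand.grid,
                                lapply(tot[seq_len(k - 1)], function(t) 0:t)))
  }
  last <- A - rowSums(combos)
  keep <- last >= 0 & last <= tot[k]
  combos <- cbind(combos[keep, , drop = FALSE], last[keep])
  lps <- numeric(nrow(combos))
  for (i in seq_len(k)) lps <- lps + lchoose(tot[i], combos[, i])
  lpObs <- sum(lchoose(tot, alt))
  sum(exp(lps - lchoose(N, A))[lps <= lpObs + log1p(1e-7)])
}

# All exact p-values for every table sharing one margin set, computed at
# once (probabilities sorted + cumulative sums); returns the table matrix
# (alt rows) and the p for each row.
oracleFisherAllTables <- function(tot, A) {
  k <- length(tot)
  combos <- as.matrix(do.call(expand.grid,
                              lapply(tot[seq_len(k - 1)], function(t) 0:t)))
  last <- A - rowSums(combos)
  keep <- last >= 0 & last <= tot[k]
  combos <- cbind(combos[keep, , drop = FALSE], last[keep])
  lps <- numeric(nrow(combos))
  for (i in seq_len(k)) lps <- lps + lchoose(tot[i], combos[, i])
  pr <- exp(lps - lchoose(sum(tot), A))
  ord <- order(lps)
  cum <- cumsum(pr[ord])
  # p_i = total probability of tables with lp <= lp_i (ties share a value)
  lpSorted <- lps[ord]
  pOf <- numeric(length(lps))
  pOf[ord] <- cum[findInterval(lpSorted + log1p(1e-7), lpSorted)]
  list(alt = combos, p = pOf)
}

# Newton-Raphson optimizer of the Poisson log-likelihood for
# genotype ~ intercept + slope * ancestry (independent of glm's IRLS).
oracleNewtonPoisson <- function(y, x, maxIter = 200L, tol = 1e-12) {
  beta <- c(log(max(mean(y), 1e-8)), 0)
  X <- cbind(1, x)
  for (i in seq_len(maxIter)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * mu, X)
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Small deterministic cohort: explicit dosages (sites x samples).
makeToyCohort <- function(gt, chrom = NULL, pos = NULL) {
  m <- nrow(gt)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  variants <- data.frame(chrom = chrom, pos = pos,
                         ref = rep("A", m), alt = rep("C", m))
  GenotypeCohort(gt, variants)
}

# Labeled three-population reference cohort drawn from a panel.
makeReference <- function(panel, nPerPop = 50L, seed = 1L) {
  K <- nrow(panel@freqs)
  q <- QMatrix(diag(K)[rep(seq_len(K), each = nPerPop), , drop = FALSE],
               components = panel@popLabels)
  rownames(q@Q) <- sprintf("REF%03d", seq_len(nrow(q@Q)))
  ref <- simulateGenotypes(panel, q, seed = seed)
  labels <- rep(panel@popLabels, each = nPerPop)
  names(labels) <- sampleIds(ref)
  list(genotypes = ref, labels = labels)
}
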