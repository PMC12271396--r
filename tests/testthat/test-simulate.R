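test_that("ancestral frequencies follow the Balding-Nichols moments", {
  # fixed base frequency, F = 0.15: Beta mean p, variance F p (1 - p)
  m <- 20000
  panel <- simulateAncestralFreqs(
    m, divergence = c(AFR = 0.15, AME = 0.15, EUR = 0.15),
    baseFreqSampler = function(n) rep(0.3, n), seed = 42)
  for (k in 1:3) {
    expect_lt(abs(mean(panel@freqs[k, ]) - 0.3), 0.01)
    v <- var(panel@freqs[k, ])
    expect_lt(abs(v - 0.15 * 0.3 * 0.7) / (0.15 * 0.3 * 0.7), 0.10)
  }
})

test_that("near-zero divergence collapses populations onto the base freq", {
  panel <- simulateAncestralFreqs(
    100, divergence = c(A = 1e-6, B = 1e-6, C = 1e-6), seed = 1)
  maxDiff <- max(apply(panel@freqs, 2, function(f) diff(range(f))))
  expect_lt(maxDiff, 0.01)
})

test_that("degenerate and invalid generator inputs are handled", {
  empty <- simulateAncestralFreqs(0, seed = 1)
  expect_length(variantKeys(empty), 0)
  expect_error(simulateAncestralFreqs(-1), "non-negative")
  expect_error(simulateAncestralFreqs(10, divergence = c(A = 1.5)), "\\(0, 1\\)")
  expect_error(simulateAncestralFreqs(10, divergence = c(A = 0)), "\\(0, 1\\)")
})

test_that("admixture profiles respect the cluster blueprint", {
  # degenerate Dirichlet pins every sample to the centroid
  spec <- new("ClusterSpec",
              centroids = matrix(c(1, 0, 0), 1, 3,
                                 dimnames = list("AFR", c("AFR", "AME", "EUR"))),
              weights = 1, concentration = 1e6, nSamples = 50L)
  q <- simulateAdmixtureProfiles(spec, seed = 3)
  expect_true(all(abs(qvalues(q) - rep(c(1, 0, 0), each = 50)) < 0.01))

  # weights concentrated on one cluster assign every sample to it
  spec5 <- defaultClusterSpec(40)
  spec5@weights <- c(1, 0, 0, 0, 0)
  q5 <- simulateAdmixtureProfiles(spec5, seed = 4)
  expect_true(all(clusterAssignment(q5) == 1L))

  # cohort means land on the calibrated three-way ancestry proportions
  qBig <- simulateAdmixtureProfiles(defaultClusterSpec(1409), seed = 5)
  expect_true(all(abs(colMeans(qvalues(qBig)) -
                        c(0.167, 0.328, 0.506)) < 0.03))
})

test_that("genotypes follow the admixture-binomial law", {
  panel <- simulateAncestralFreqs(2000, seed = 11)
  q <- simulateAdmixtureProfiles(defaultClusterSpec(500), seed = 12)
  cohort <- simulateGenotypes(panel, q, seed = 13)
  gt <- genotypes(cohort)
  expect_true(all(gt %in% 0:2))

  # per-site mean dosage within 4 Monte-Carlo SEs of 2 * qbar %*% p
  pii <- qvalues(q) %*% panel@freqs
  expMean <- 2 * colMeans(pii)
  seSite <- sqrt(colSums(2 * pii * (1 - pii))) / 500
  obs <- rowMeans(gt)
  expect_gt(mean(abs(obs - expMean) <= 4 * seSite), 0.99)

  # boundary frequencies give deterministic genotypes
  p0 <- panel
  p0@freqs[] <- 0
  expect_true(all(genotypes(simulateGenotypes(p0, q, seed = 1)) == 0L))
  p2 <- panel
  p2@freqs[] <- 1
  expect_true(all(genotypes(simulateGenotypes(p2, q, seed = 1)) == 2L))
})

test_that("genotype distribution matches the mixture-binomial law sitewise", {
  panel <- simulateAncestralFreqs(400, seed = 21)
  q <- simulateAdmixtureProfiles(defaultClusterSpec(600), seed = 22)
  cohort <- simulateGenotypes(panel, q, seed = 23)
  gt <- genotypes(cohort)
  pii <- t(qvalues(q) %*% panel@freqs)      # sites x samples
  pvals <- vapply(seq_len(nrow(gt)), function(s) {
    probs <- cbind((1 - pii[s, ])^2, 2 * pii[s, ] * (1 - pii[s, ]),
                   pii[s, ]^2)
    expCnt <- colSums(probs)
    obsCnt <- tabulate(gt[s, ] + 1L, 3L)
    keep <- expCnt > 1e-8
    stat <- sum((obsCnt[keep] - expCnt[keep])^2 / expCnt[keep])
    pchisq(stat, df = sum(keep) - 1L, lower.tail = FALSE)
  }, numeric(1))
  expect_gte(mean(pvals > 0.001), 0.99)
})

test_that("platform masks subset sites and inject missingness at rate", {
  panel <- simulateAncestralFreqs(5000, seed = 31)
  q <- simulateAdmixtureProfiles(defaultClusterSpec(60), seed = 32)
  cohort <- simulateGenotypes(panel, q, seed = 33)
  ids <- sampleIds(cohort)
  assignment <- setNames(rep(c("D1", "D2"), each = 30), ids)
  masks <- list(
    D1 = platformMask("WGS", 5000, missingRate = 0),
    D2 = platformMask("WGG", 5000, fraction = 0.4, missingRate = 0.1,
                      seed = 34))
  out <- applyPlatformMasks(cohort, assignment, masks, seed = 35)

  # WGS at zero missingness reproduces the input restriction exactly
  expect_identical(genotypes(out$D1),
                   genotypes(cohort)[, ids[assignment[ids] == "D1"]])
  # masked dataset only contains its site subset
  expect_identical(variantKeys(out$D2),
                   variantKeys(cohort)[masks$D2$siteSubset])
  # missingness lands in the binomial window around the nominal rate
  obsMiss <- mean(is.na(genotypes(out$D2)))
  expect_gt(obsMiss, 0.08)
  expect_lt(obsMiss, 0.12)
  # empty subset gives an empty dataset
  masks$D2$siteSubset <- integer()
  out2 <- applyPlatformMasks(cohort, assignment, masks, seed = 36)
  expect_equal(nrow(out2$D2), 0L)
  # unassigned samples are rejected
  expect_error(applyPlatformMasks(cohort, assignment[-1], masks, seed = 1),
               "assigned")
})

test_that("annotation catalog draws classes at the requested rates", {
  sites <- sprintf("1:%d:A:C", seq_len(10000))
  cat0 <- simulateAnnotations(sites, classProbs = c(uncertain = 0,
                                                    conflicting = 0,
                                                    pathogenic_lp = 0),
                              seed = 1)
  expect_true(all(cat0$clinvar_class == "none"))
  cat1 <- simulateAnnotations(sites, classProbs = c(uncertain = 0,
                                                    conflicting = 0,
                                                    pathogenic_lp = 1),
                              seed = 2)
  expect_true(all(cat1$clinvar_class == "pathogenic_lp"))
  cat5 <- simulateAnnotations(sites, classProbs = c(uncertain = 0.05,
                                                    conflicting = 0,
                                                    pathogenic_lp = 0),
                              seed = 3)
  nUnc <- sum(cat5$clinvar_class == "uncertain")
  expect_gte(nUnc, 400)
  expect_lte(nUnc, 600)
  expect_error(simulateAnnotations(sites,
                                   classProbs = c(uncertain = -0.1)),
               "non-negative")
})

test_that("a fixed seed reproduces the cohort bit-identically", {
  a <- simulateCohortDatasets(defaultSimulationConfig(nSamples = 40L,
                                                      m = 300L), seed = 9)
  b <- simulateCohortDatasets(defaultSimulationConfig(nSamples = 40L,
                                                      m = 300L), seed = 9)
  expect_identical(lapply(a$datasets, genotypes),
                   lapply(b$datasets, genotypes))
  expect_identical(qvalues(a$trueQ), qvalues(b$trueQ))
  expect_identical(a$catalog, b$catalog)
})

test_that("VCF round trip preserves genotypes, missingness and keys", {
  sim <- simulateCohortDatasets(defaultSimulationConfig(nSamples = 30L,
                                                        m = 200L,
                                                        nDivergent = 0L),
                                seed = 17)
  d <- sim$datasets[[1]]
  path <- file.path(tempdir(), "roundtrip.vcf")
  writeCohortVcf(d, path)
  back <- readCohortVcf(path, dataset = unname(datasetOf(d))[1],
                        platform = unname(platformOf(d))[1])
  expect_identical(variantKeys(back), variantKeys(d))
  expect_identical(sampleIds(back), sampleIds(d))
  expect_identical(unname(genotypes(back)), unname(genotypes(d)))
  unlink(path)
})
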