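test_that("allele tables count alleles per cluster, missing excluded", {
  # one cluster (0,1,2) -> ref 3, alt 3
  t1 <- buildAlleleTable(c(0L, 1L, 2L), rep(1L, 3))
  expect_equal(t1@ref, 3L)
  expect_equal(t1@alt, 3L)

  # five non-missing diploids -> column total 10
  t2 <- buildAlleleTable(rep(1L, 5), rep(1L, 5))
  expect_equal(t2@ref + t2@alt, 10L)

  # clusters {(0,0), (2,2,2)} -> ref (4,0), alt (0,6)
  t3 <- buildAlleleTable(c(0L, 0L, 2L, 2L, 2L), c(1L, 1L, 2L, 2L, 2L))
  expect_equal(t3@ref, c(4L, 0L))
  expect_equal(t3@alt, c(0L, 6L))

  # a fully-missing cluster keeps a (0, 0) column with a warning
  expect_warning(t4 <- buildAlleleTable(c(NA_integer_, 1L), c(1L, 2L)),
                 "no observed")
  expect_equal(t4@ref[1] + t4@alt[1], 0L)
})

test_that("exact test matches hand enumeration on the worked examples", {
  # margins (4,4 | 4,4): five tables, p = 17/35
  r1 <- fisherExact2xK(ContingencyTable2xK(ref = c(3, 1), alt = c(1, 3)))
  expect_equal(r1$p, 17 / 35, tolerance = 1e-12)
  expect_equal(r1$method, "exact")

  # both tables with margins (1,1 | 1,1) have probability 0.5
  r2 <- fisherExact2xK(ContingencyTable2xK(ref = c(1, 0), alt = c(0, 1)))
  expect_equal(r2$p, 1, tolerance = 1e-12)

  # the all-equal 2x5 table is modal: every table is at least as extreme
  r3 <- fisherExact2xK(ContingencyTable2xK(ref = rep(5L, 5),
                                           alt = rep(5L, 5)))
  expect_equal(r3$p, 1, tolerance = 1e-12)

  # zero-total columns are dropped; k = 1 after dropping gives p = 1
  r4 <- fisherExact2xK(ContingencyTable2xK(ref = c(3, 0), alt = c(2, 0)))
  expect_equal(r4$p, 1)
  expect_equal(r4$k, 1L)
  # an all-zero table cannot even be constructed
  expect_error(ContingencyTable2xK(ref = c(0, 0), alt = c(0, 0)),
               "positive")
})

test_that("Monte-Carlo fallback agrees with the exact computation", {
  set.seed(81)
  for (i in 1:5) {
    tot <- sample(4:12, 3, replace = TRUE) * 2L
    alt <- as.integer(rbinom(3, tot, 0.4))
    if (sum(alt) == 0 || sum(alt) == sum(tot)) next
    pEx <- oracleFisherP(alt, tot)
    mc <- AdmixScreen:::.fisherMonteCarlo(alt, tot, 1e5, seed = i)
    expect_lt(abs(mc$p - pEx), 4 * mc$se + 1e-12)
  }
})

test_that("FST reproduces the hand-computed closed forms", {
  # identical frequencies across clusters -> 0
  f0 <- fstFromTable(ContingencyTable2xK(ref = c(50, 50), alt = c(50, 50)),
                     clusterSizes = c(50, 50))
  expect_equal(f0$fst, 0, tolerance = 1e-12)

  # opposite fixation -> 1 (HS = 0, pooled q = 0.5, HT = 0.5)
  f1 <- fstFromTable(ContingencyTable2xK(ref = c(100, 0), alt = c(0, 100)),
                     clusterSizes = c(50, 50))
  expect_equal(f1$fst, 1, tolerance = 1e-12)
  expect_equal(f1$ht, 0.5, tolerance = 1e-12)

  # q = (0.2, 0.8) equal sizes -> HS = 0.32, HT = 0.5, FST = 0.36
  f2 <- fstFromTable(ContingencyTable2xK(ref = c(80, 20), alt = c(20, 80)),
                     clusterSizes = c(50, 50))
  expect_equal(f2$fst, 0.36, tolerance = 1e-12)
  expect_equal(f2$hsBar, 0.32, tolerance = 1e-12)

  # monomorphic site: flagged, FST 0
  fm <- fstFromTable(ContingencyTable2xK(ref = c(10, 10), alt = c(0, 0)),
                     clusterSizes = c(5, 5))
  expect_true(fm$monomorphic)
  expect_equal(fm$fst, 0)
})

test_that("enrichment cluster designation uses frequency then total then name", {
  t1 <- ContingencyTable2xK(ref = c(1L, 9L, 9L, 9L, 9L),
                            alt = c(9L, 1L, 1L, 1L, 1L),
                            clusters = c("A", "B", "C", "D", "E"))
  expect_equal(designateEnrichedCluster(t1), "A")

  # equal frequencies: larger column total wins
  t2 <- ContingencyTable2xK(ref = c(5L, 50L), alt = c(5L, 50L),
                            clusters = c("small", "big"))
  expect_equal(designateEnrichedCluster(t2), "big")

  # single non-empty column wins by default
  t3 <- ContingencyTable2xK(ref = c(0L, 4L), alt = c(0L, 2L),
                            clusters = c("empty", "only"))
  expect_equal(designateEnrichedCluster(t3), "only")
})

test_that("Poisson regression matches glm closed forms and edge cases", {
  set.seed(90)
  x <- runif(60)
  q <- QMatrix(cbind(AFR = x, AME = (1 - x) / 2, EUR = (1 - x) / 2))
  # constant genotype 1: intercept log(1) = 0, slope 0
  fit <- poissonAncestryRegression(rep(1L, 60), q, "AFR")
  expect_true(fit$converged)
  expect_lt(abs(fit$intercept), 1e-6)
  expect_lt(abs(fit$slope), 1e-6)

  # all-zero genotypes: unidentified slope is reported, not a number
  fit0 <- poissonAncestryRegression(rep(0L, 60), q, "AFR")
  expect_false(fit0$converged)
  expect_match(fit0$diagnostic, "unidentified")
  expect_true(is.na(fit0$slope))

  xs <- runif(5)
  qSmall <- QMatrix(cbind(AFR = xs, AME = (1 - xs) / 2, EUR = (1 - xs) / 2))
  expect_error(poissonAncestryRegression(rep(1L, 5), qSmall, "AFR"),
               "at least 10")
})

test_that("Poisson power: a true slope of 1 is detected with n = 500", {
  set.seed(91)
  hits <- 0
  for (r in 1:200) {
    x <- runif(500)
    y <- rpois(500, exp(-0.7 + 1.0 * x))
    q <- QMatrix(cbind(AFR = x, AME = (1 - x) / 2, EUR = (1 - x) / 2))
    fit <- poissonAncestryRegression(as.integer(y), q, "AFR")
    if (fit$converged && fit$slope > 0 && fit$waldP < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 200, 0.9)
})

test_that("genome screen isolates a planted divergent site among nulls", {
  set.seed(92)
  nPer <- 30                               # 150 samples in 5 clusters
  assign <- rep(1:5, each = nPer)
  m <- 100
  freq <- runif(m, 0.2, 0.8)
  gt <- t(sapply(seq_len(m), function(s) rbinom(5 * nPer, 2, freq[s])))
  # site 1: cluster 1 at 0.8, the others at 0.05 (~300 alleles per cluster
  # scaled down to 60 per cluster here, still decisive)
  gt[1, ] <- rbinom(5 * nPer, 2, ifelse(assign == 1, 0.8, 0.05))
  cohort <- makeToyCohort(gt)
  clusters <- new("AncestryClusters", k = 5L, assignment = assign,
                  centroids = matrix(1 / 3, 5, 3,
                                     dimnames = list(NULL,
                                                     c("AFR", "AME", "EUR"))),
                  clusterNames = c("AFR", "AME", "EUR", "ADX1", "ADX2"),
                  inertia = c(`5` = 1))
  q <- QMatrix(matrix(runif(150 * 3), ncol = 3) |> (\(x) x / rowSums(x))())
  res <- screenGenome(cohort, clusters, q, catalog = NULL, alpha = 5e-8,
                      seed = 93)
  expect_equal(res$key, "1:100:A:C")
  expect_equal(res$enriched_cluster, "AFR")

  # alpha = 1 returns every testable site
  resAll <- screenGenome(cohort, clusters, q, alpha = 1.000001, seed = 94)
  expect_equal(nrow(resAll), m)
  expect_true(!is.unsorted(resAll$fisher_p))

  # an empty cohort warns and returns an empty result
  expect_warning(empty <- screenGenome(cohort[0, ], clusters, q),
                 "empty")
  expect_equal(nrow(empty), 0L)
})
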