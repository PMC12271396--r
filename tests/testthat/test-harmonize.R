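test_that("variant id normalization yields canonical keys and is idempotent", {
  rec <- data.frame(chrom = c("1", "chr7", "chrX", "2", "3", "4"),
                    pos = c(159204893, 99767460, 100, 50, 60, 0),
                    ref = c("T", "G", "a", "A", "", "A"),
                    alt = c("C", "A", "t", "A", "C", "C"))
  out <- normalizeVariantIds(rec)
  expect_equal(out$key[1], "1:159204893:T:C")
  expect_equal(out$key[2], "7:99767460:G:A")
  expect_equal(out$key[3], "X:100:A:T")
  expect_false(out$valid[4])            # ref == alt
  expect_match(out$reason[4], "ref equals alt")
  expect_false(out$valid[5])            # empty allele
  expect_false(out$valid[6])            # pos < 1

  # idempotence: normalizing parsed keys changes nothing
  keys <- out$key[out$valid]
  again <- normalizeVariantIds(parseVariantKey(keys))
  expect_identical(again$key, keys)
})

test_that("union merge has exact-union semantics with per-site occupancy", {
  # sites A..E as positions 100..500; datasets {A,B,C} and {B,C,D,E}
  g1 <- makeToyCohort(matrix(c(0L, 1L, 2L, 1L, 0L, 1L), nrow = 3,
                             dimnames = list(NULL, c("s1", "s2"))),
                      pos = c(100L, 200L, 300L))
  g2 <- makeToyCohort(matrix(c(2L, 2L, 0L, 1L), nrow = 4,
                             dimnames = list(NULL, "s3")),
                      pos = c(200L, 300L, 400L, 500L))
  merged <- unionMerge(list(g1, g2))
  expect_equal(nrow(merged), 5L)
  occ <- setNames(rowData(merged)$occupancy, rowData(merged)$pos)
  expect_equal(unname(occ[as.character(c(100, 200, 300, 400, 500))]),
               c(1L, 2L, 2L, 1L, 1L))
  # a sample's genotype at a site absent from its dataset is missing
  expect_true(is.na(genotypes(merged)["1:400:A:C", "s1"]))
  expect_equal(genotypes(merged)["1:200:A:C", "s3"], 2L)

  # single dataset merges to itself with occupancy 1
  solo <- unionMerge(list(g1))
  expect_identical(unname(genotypes(solo)), unname(genotypes(g1)))
  expect_true(all(rowData(solo)$occupancy == 1L))

  # duplicate sample ids across datasets are rejected
  g3 <- makeToyCohort(matrix(0L, 1, 2, dimnames = list(NULL, c("s1", "x"))))
  expect_error(unionMerge(list(g1, g3)), "duplicate sample ids")
})

test_that("union merge is commutative up to ordering", {
  sim <- simulateCohortDatasets(defaultSimulationConfig(nSamples = 30L,
                                                        m = 150L), seed = 2)
  m1 <- unionMerge(sim$datasets)
  m2 <- unionMerge(rev(sim$datasets))
  keys <- variantKeys(m1)
  ids <- sort(sampleIds(m1))
  expect_identical(sort(variantKeys(m2)), sort(keys))
  expect_identical(genotypes(m1)[keys, ids], genotypes(m2)[keys, ids])
})

test_that("occupancy ranking orders by count then coordinate", {
  gt <- matrix(1L, nrow = 4, ncol = 2, dimnames = list(NULL, c("a", "b")))
  cohort <- makeToyCohort(gt, pos = c(10L, 20L, 30L, 40L))
  rowData(cohort)$occupancy <- c(3L, 2L, 3L, 1L)
  expect_equal(rankSitesByOccupancy(cohort, 2),
               c("1:10:A:C", "1:30:A:C"))
  # ties broken by ascending position
  rowData(cohort)$occupancy <- c(2L, 2L, 2L, 2L)
  cohort2 <- makeToyCohort(gt, pos = c(30L, 10L, 20L, 40L))
  rowData(cohort2)$occupancy <- rep(2L, 4)
  expect_equal(rankSitesByOccupancy(cohort2, 2),
               c("1:10:A:C", "1:20:A:C"))
  # nKeep beyond the total returns everything, deterministically
  expect_length(rankSitesByOccupancy(cohort, 99), 4L)
  expect_identical(rankSitesByOccupancy(cohort, 99),
                   rankSitesByOccupancy(cohort, 99))
})

test_that("site filter applies missingness and strict MAF rules", {
  # 10 diploid samples; site 1: one hom-alt carrier -> MAF 0.10 kept;
  # site 2: one het -> MAF 0.05, kept under strict '< 0.05' removal;
  # site 3: 80% missing -> removed; site 4: all missing -> removed
  gt <- rbind(c(2L, rep(0L, 9)),
              c(1L, rep(0L, 9)),
              c(1L, 1L, rep(NA_integer_, 8)),
              rep(NA_integer_, 10))
  cohort <- makeToyCohort(gt)
  out <- filterSites(cohort, maxMissing = 0.75, minMaf = 0.05)
  expect_identical(rownames(out), c("1:100:A:C", "1:200:A:C"))
  lg <- attr(out, "log")
  expect_equal(lg$n_in, 4)
  expect_equal(lg$n_out, 2)

  # a common site with no missingness survives
  common <- makeToyCohort(matrix(c(0L, 1L, 2L, 1L), 1))
  expect_equal(nrow(filterSites(common)), 1L)
})

test_that("sample filter drops only samples above the missingness cap", {
  gt <- matrix(NA_integer_, nrow = 200, ncol = 3,
               dimnames = list(NULL, c("all", "most", "some")))
  gt[, 2] <- c(rep(NA_integer_, 196), rep(0L, 4))    # 98% missing
  gt[, 3] <- c(rep(NA_integer_, 100), rep(1L, 100))  # 50% missing
  cohort <- makeToyCohort(gt)
  # strict '>' rule: 100% dropped, 98% and 50% kept at the 0.99 default
  expect_identical(sampleIds(filterSamples(cohort, 0.99)), c("most", "some"))
  expect_identical(sampleIds(filterSamples(cohort, 0.5)), "some")
  # exactly-at-threshold is kept
  expect_identical(sampleIds(filterSamples(cohort, 0.98)), c("most", "some"))
})

test_that("LD pruning drops later duplicated sites and spares independents", {
  set.seed(40)
  base <- matrix(rbinom(200 * 60, 2, 0.4), nrow = 200)
  dup <- base
  dup[2, ] <- base[1, ]                  # identical neighbor column
  cohort <- makeToyCohort(dup)
  kept <- ldPrune(cohort, window = 10, step = 5, r2Max = 0.2)
  expect_false("1:200:A:C" %in% kept)    # the later duplicate went
  expect_true("1:100:A:C" %in% kept)

  # r2Max = 1 keeps everything
  expect_length(ldPrune(cohort, 10, 5, 1.0), 200L)

  # independent sites: at least 95% survive a strict threshold
  set.seed(41)
  ind <- matrix(rbinom(1000 * 500, 2, 0.5), nrow = 1000)
  keptInd <- ldPrune(makeToyCohort(ind), window = 50, step = 5, r2Max = 0.1)
  expect_gte(length(keptInd), 950L)

  # monomorphic sites have undefined r2 and are treated as uncorrelated
  mono <- makeToyCohort(rbind(rep(1L, 20), rep(0L, 20), rbinom(20, 2, .5)))
  expect_length(ldPrune(mono, 10, 5, 0.1), 3L)
})

test_that("kinship estimator flags duplicates and spares the unrelated", {
  set.seed(50)
  freq <- runif(800, 0.1, 0.9)
  g <- sapply(1:30, function(i) rbinom(800, 2, freq))
  colnames(g) <- sprintf("u%02d", 1:30)
  g[, 30] <- g[, 1]                       # planted duplicate
  g[5, 30] <- NA_integer_                 # give the copy more missingness
  cohort <- makeToyCohort(g)
  res <- kinshipFilter(cohort)
  dupRows <- res$report[res$report$class == "duplicate", ]
  expect_equal(nrow(dupRows), 1L)
  expect_lt(abs(dupRows$kinship - 0.5), 0.05)
  expect_identical(res$removed, "u30")    # the more-missing copy went

  offDiag <- res$report[res$report$class != "duplicate", "kinship"]
  expect_true(length(offDiag) == 0 || all(offDiag < 0.25))

  # mean kinship of unrelated samples is near zero
  resAll <- kinshipFilter(cohort[, 1:29], firstDegreeThreshold = 1,
                          dupThreshold = 1)
  expect_identical(resAll$removed, character(0))
  gg <- genotypes(cohort[, 1:29])
  het <- gg == 1L
  hb <- crossprod(het)
  opp <- crossprod(gg == 0L, gg == 2L); opp <- opp + t(opp)
  hs <- crossprod(het, matrix(TRUE, nrow(gg), ncol(gg)))
  kin <- (hb - 2 * opp) / (hs + t(hs))
  expect_lt(abs(mean(kin[upper.tri(kin)])), 0.02)
})

test_that("harmonization pipeline logs consistent input/output counts", {
  sim <- simulateCohortDatasets(defaultSimulationConfig(nSamples = 60L,
                                                        m = 500L), seed = 6)
  # few shared sites between the small array/exome datasets: the kinship
  # stage legitimately warns about skipped pairs
  res <- suppressWarnings(harmonizeDatasets(sim$datasets, topN = 300))
  logs <- res$logs
  expect_true(all(logs$n_removed == logs$n_in - logs$n_out))
  expect_equal(logs$n_out[logs$step == "kinship_filter"],
               logs$n_in[logs$step == "filter_samples"])
  expect_equal(logs$n_out[logs$step == "filter_sites"],
               logs$n_in[logs$step == "rank_sites"])
  expect_lte(nrow(res$cohort), 300L)
  # planted duplicates were caught
  expect_gte(nrow(res$kinship[res$kinship$class == "duplicate", ]), 1L)
})
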