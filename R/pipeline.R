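#' @include simulate.R harmonize.R ancestry.R enrichment.R yield.R vcf-io.R
NULL

#' Default end-to-end pipeline configuration
#'
#' Desk-scale defaults covering simulation, harmonization, ancestry
#' inference and the enrichment screen.
#'
#' @param nSamples,m cohort size and site count for the generator.
#' @param alpha genome-wide significance threshold for the screen. The
#'   default of 5e-8 is the conventional genome-wide cut; 1e-8 is available
#'   for a stricter screen.
#' @param topN occupancy-ranked sites retained for ancestry inference.
#' @param ... overrides forwarded to [defaultSimulationConfig()].
#' @return list of pipeline settings.
#' @export
defaultPipelineConfig <- function(nSamples = 300L, m = 8000L, alpha = 5e-8,
                                  topN = 4000L, ...) {
  list(simulation = defaultSimulationConfig(nSamples = nSamples, m = m, ...),
       maxSiteMissing = 0.75, minMaf = 0.05, maxSampleMissing = 0.99,
       topN = as.integer(topN), ldWindow = 50L, ldStep = 5L, ldR2 = 0.5,
       emK = 3L, emMaxIter = 800L, emTol = 1e-4,
       kMax = 10L, nRestarts = 25L, alpha = alpha,
       mcCutoff = 3e5, mcReps = 1e6)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes simulate -> harmonize -> ancestry -> screen -> report under one
#' seed: generates the multi-platform cohort with ground truth, union-merges
#' and QC-filters the datasets, infers three-way admixture by EM (aligned to
#' the simulated reference panel), clusters and names ancestry groups,
#' screens genome-wide for ancestry-enriched variants, and assembles the
#' diagnostic-yield and per-dataset frequency summaries together with a
#' structured log of every filter's input/output counts.
#'
#' @param config list from [defaultPipelineConfig()].
#' @param seed integer master seed; every stochastic stage derives its
#'   stream from it, so a fixed seed reproduces the run bit-identically.
#' @param outDir optional directory; when given, Q matrix, PC coordinates,
#'   screen results, yield and frequency tables are written as TSV and the
#'   run summary as JSON.
#' @return list with `simulation`, `harmonized` (cohort + kinship report),
#'   `pca` (model + cohort coordinates), `admixture` (EM fit), `clusters`,
#'   `screen` (hits with partitions), `pharmHits`, `clinicalHits`, `yield`,
#'   `frequencies`, `logs`, `summary`.
#' @export
runPipeline <- function(config = defaultPipelineConfig(), seed = 1L,
                        outDir = NULL) {
  sim <- simulateCohortDatasets(config$simulation, seed = seed)

  harm <- harmonizeDatasets(sim$datasets,
                            maxSiteMissing = config$maxSiteMissing,
                            minMaf = config$minMaf,
                            maxSampleMissing = config$maxSampleMissing)
  cohort <- harm$cohort
  logs <- harm$logs

  # Ancestry inference on occupancy-ranked, LD-pruned sites.
  ancSites <- rankSitesByOccupancy(cohort, config$topN)
  ancCohort <- cohort[ancSites, ]
  kept <- ldPrune(ancCohort, config$ldWindow, config$ldStep, config$ldR2)
  logs <- rbind(logs, .filterLog("ld_prune", "sites", length(ancSites),
                                 length(kept)))
  ancCohort <- ancCohort[kept, ]

  # PCA model on the reference panel restricted to the ancestry site set,
  # so cohort samples project through the sites they actually observe.
  refAnc <- sim$reference[intersect(kept, variantKeys(sim$reference)), ]
  pca <- fitReferencePca(refAnc, nComponents = 10L)
  coords <- projectSamples(pca, ancCohort)

  em <- fitAdmixtureEm(ancCohort, K = config$emK,
                       maxIter = config$emMaxIter, tol = config$emTol,
                       seed = .childSeed(seed, 21L),
                       supervisedPanel = list(genotypes = sim$reference,
                                              labels = sim$referenceLabels))

  clusters <- kmeansElbow(em$Q, kMax = config$kMax,
                          nRestarts = config$nRestarts,
                          seed = .childSeed(seed, 22L))
  clusters <- labelClusters(clusters, em$Q)

  screen <- screenGenome(cohort, clusters, em$Q, sim$catalog,
                         alpha = config$alpha, mcCutoff = config$mcCutoff,
                         mcReps = config$mcReps,
                         seed = .childSeed(seed, 23L))
  logs <- rbind(logs, .filterLog("screen_alpha", "sites",
                                 attr(screen, "n_tested"), nrow(screen),
                                 sprintf("alpha=%g", config$alpha)))
  pharmHits <- attr(screen, "pharmacogenomic")
  clinicalHits <- attr(screen, "clinical")
  evidenceHits <- filterByEvidence(pharmHits)
  logs <- rbind(logs, .filterLog("evidence_filter", "sites",
                                 nrow(pharmHits), nrow(evidenceHits),
                                 "levels 1A/1B/2A/2B"))

  yield <- diagnosticYield(cohort, clusters, sim$catalog)
  freqs <- summarizeFrequencies(sim$datasets)

  summary <- list(
    seed = seed,
    n_samples = ncol(cohort), n_sites = nrow(cohort),
    mean_ancestry = as.list(round(colMeans(qvalues(em$Q)), 4)),
    chosen_k = clusters@k,
    cluster_sizes = as.list(setNames(tabulate(clusters@assignment,
                                              clusters@k),
                                     clusters@clusterNames)),
    n_hits = nrow(screen), n_pharm_hits = nrow(pharmHits),
    n_clinical_hits = nrow(clinicalHits),
    n_evidence_hits = nrow(evidenceHits))

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeQMatrixTsv(em$Q, file.path(outDir, "q_matrix.tsv"), clusters)
    utils::write.table(data.frame(sample = rownames(coords), coords),
                       file.path(outDir, "pc_coordinates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(screen, file.path(outDir, "screen_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(yield, file.path(outDir, "yield.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(freqs, file.path(outDir, "frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(logs, file.path(outDir, "filter_logs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(outDir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(simulation = sim, harmonized = harm,
       pca = list(model = pca, coordinates = coords),
       admixture = em, clusters = clusters, screen = screen,
       pharmHits = pharmHits, clinicalHits = clinicalHits,
       evidenceHits = evidenceHits, yield = yield, frequencies = freqs,
       logs = logs, summary = summary)
}
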