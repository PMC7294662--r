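#' Pipeline configuration
#'
#' Assembles and validates the end-to-end analysis configuration. Every
#' default is either a method constant (70\% precision cutoff, FWER 0.05,
#' 1000 permutations, 6.9 rewiring iterations per edge, minimum 5
#' observations, 5-fraction smoothing window, up to 5 Gaussian components,
#' Jaccard 0.33, 20\% report FDR) or a documented generator choice. The
#' configuration round-trips losslessly through its YAML file form; unknown
#' keys in a file are errors.
#'
#' @param nProteins,nComplexes,sizeRange,rewiredFraction simulation truth
#'   parameters (used when \code{inputDir} is NULL).
#' @param simulation a [simulationConfig()]-style list of generator
#'   parameters (its seed is overridden by the derived stage seed).
#' @param inputDir optional directory of pre-existing chromatogram TSVs
#'   (\code{<replicate>_<channel>.tsv}) plus \code{complexes.tsv}.
#' @param geneSetsFile optional GMT file of gene sets for the differential
#'   stage; by default the planted complexes double as gene sets.
#' @param targetPrecision,fwer,nPerm,nIterFactor,minObs,smoothWidth,
#'   maxComponents,jaccardMin,fdrReport analysis parameters.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(nProteins = 100L, nComplexes = 10L,
                           sizeRange = c(3L, 6L), rewiredFraction = 0.3,
                           simulation = simulationConfig(),
                           inputDir = NULL, geneSetsFile = NULL,
                           targetPrecision = 0.70, fwer = 0.05,
                           nPerm = 1000L, nIterFactor = 6.9, minObs = 5L,
                           smoothWidth = 5L, maxComponents = 5L,
                           jaccardMin = 0.33, fdrReport = 0.20, seed = 1L) {
  stopifnot(targetPrecision > 0, targetPrecision <= 1, fwer > 0, fwer < 1,
            nPerm >= 1L, nIterFactor > 0, minObs >= 1L,
            smoothWidth %% 2L == 1L, maxComponents >= 1L,
            jaccardMin >= 0, jaccardMin <= 1, fdrReport > 0, fdrReport <= 1)
  structure(list(schemaVersion = 1L, nProteins = as.integer(nProteins),
                 nComplexes = as.integer(nComplexes),
                 sizeRange = as.integer(sizeRange),
                 rewiredFraction = rewiredFraction,
                 simulation = unclass(simulation), inputDir = inputDir,
                 geneSetsFile = geneSetsFile,
                 targetPrecision = targetPrecision, fwer = fwer,
                 nPerm = as.integer(nPerm), nIterFactor = nIterFactor,
                 minObs = as.integer(minObs),
                 smoothWidth = as.integer(smoothWidth),
                 maxComponents = as.integer(maxComponents),
                 jaccardMin = jaccardMin, fdrReport = fdrReport,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Write a pipeline configuration to YAML
#' @param config a \code{"PipelineConfig"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys are errors, not warnings; missing keys take their defaults.
#' @param path YAML file written by [writePipelineConfig()] (or hand-written
#'   with the same keys).
#' @return list of class \code{"PipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(pipelineConfig())
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$schemaVersion) && raw$schemaVersion != 1L)
    stop("unsupported schema version: ", raw$schemaVersion)
  raw$schemaVersion <- NULL
  sim <- raw$simulation
  raw$simulation <- NULL
  args <- raw
  if (!is.null(sim)) args$simulation <- do.call(simulationConfig, sim)
  do.call(pipelineConfig, args)
}

stageLog <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

## stage seeds are fixed offsets of the master seed (kept below 2^31)
stageSeed <- function(config, offset) (config$seed + offset) %% .Machine$integer.max

#' Run the end-to-end co-fractionation analysis
#'
#' Stages, in order: simulate (or read) chromatogram matrices; clean
#' (single-gap imputation, minimum-observation filter); MODERN outlier
#' removal; smoothing and Gaussian mixture fitting; pair features per
#' replicate, concatenated per channel; naive Bayes scoring against the
#' complex-derived gold standard; precision thresholding into per-condition
#' networks; network comparison; gene-set rewiring statistics; report.
#' Every intermediate artifact is written under \code{outDir}. A completed
#' run (an existing \code{manifest.json}) is not recomputed unless
#' \code{force} is TRUE; rerunning with the same configuration and seed
#' reproduces the outputs.
#'
#' @param config a \code{"PipelineConfig"} from [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @param force recompute even when a completed manifest exists.
#' @return the run manifest (list), invisibly; also written as
#'   \code{manifest.json}.
#' @export
runPipeline <- function(config, outDir, force = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  manifestPath <- file.path(outDir, "manifest.json")
  if (!force && file.exists(manifestPath)) {
    stageLog("run", "completed run found at %s; skipping (use force = TRUE)",
             manifestPath)
    return(invisible(jsonlite::read_json(manifestPath, simplifyVector = TRUE)))
  }
  t0 <- proc.time()[["elapsed"]]
  manifest <- list(schemaVersion = config$schemaVersion, seed = config$seed,
                   stages = list(), counts = list())
  tick <- function() proc.time()[["elapsed"]]
  mark <- function(stage, start) {
    manifest$stages[[stage]] <<- round(tick() - start, 3)
  }

  ## -- stage: inputs -------------------------------------------------------
  s <- tick()
  if (is.null(config$inputDir)) {
    truth <- generateComplexTruth(config$nProteins, config$nComplexes,
                                  config$sizeRange, config$rewiredFraction,
                                  seed = stageSeed(config, 0L))
    simCfg <- do.call(simulationConfig,
                      utils::modifyList(config$simulation,
                                        list(seed = stageSeed(config, 1L))))
    sim <- simulateChromatograms(truth, simCfg)
    matrices <- sim$matrices
    complexes <- truth@complexes
    writeComplexTruth(truth, file.path(outDir, "complex_truth.tsv"))
    writeSpikeTruth(sim$spikes, file.path(outDir, "spike_truth.tsv"))
    for (nm in names(matrices))
      writeChromatogramMatrix(matrices[[nm]],
                              file.path(outDir, paste0("raw_", nm, ".tsv")))
    stageLog("simulate", "%d matrices, %d planted spikes",
             length(matrices), nrow(sim$spikes))
  } else {
    files <- list.files(config$inputDir, pattern = "^r\\d+_(medium|heavy)\\.tsv$")
    if (!length(files)) stop("simulate: no chromatogram files in inputDir")
    matrices <- list()
    for (f in files) {
      nm <- sub("\\.tsv$", "", f)
      parts <- strsplit(nm, "_")[[1L]]
      cond <- if (parts[2L] == "medium") "unstimulated" else "stimulated"
      matrices[[nm]] <- readChromatogramMatrix(
        file.path(config$inputDir, f), replicate = parts[1L],
        channel = parts[2L], condition = cond)
    }
    complexes <- readComplexes(file.path(config$inputDir, "complexes.tsv"))
    truth <- NULL
    stageLog("read", "%d matrices from %s", length(matrices), config$inputDir)
  }
  manifest$counts$matrices <- length(matrices)
  manifest$counts$proteinsIn <- length(unique(unlist(lapply(matrices, proteins))))
  mark("inputs", s)

  ## -- stage: clean + MODERN ----------------------------------------------
  s <- tick()
  removedPoints <- 0L
  cleaned <- list()
  for (nm in names(matrices)) {
    cm <- filterMinObservations(imputeSingleMissing(matrices[[nm]]),
                                minObs = config$minObs)
    rep <- detectOutliers(cm, fwer = config$fwer)
    removedPoints <- removedPoints + nrow(flaggedPoints(rep))
    cleaned[[nm]] <- removeOutliers(cm, rep)
    writeChromatogramMatrix(cleaned[[nm]],
                            file.path(outDir, paste0("clean_", nm, ".tsv")))
  }
  manifest$counts$chromatogramsPassingQC <-
    sum(vapply(cleaned, function(m) nrow(intensities(m)), integer(1L)))
  manifest$counts$pointsRemovedByModern <- removedPoints
  stageLog("modern", "removed %d points across %d matrices",
           removedPoints, length(cleaned))
  mark("modern", s)

  ## -- stage: smooth + fit -------------------------------------------------
  s <- tick()
  smoothed <- lapply(cleaned, smoothChromatograms, width = config$smoothWidth)
  fits <- lapply(smoothed, fitChromatograms,
                 maxComponents = config$maxComponents)
  for (nm in names(fits))
    writeGaussianFits(fits[[nm]], file.path(outDir, paste0("fits_", nm, ".tsv")))
  manifest$counts$chromatogramsFit <- sum(lengths(fits))
  mark("fit", s)

  ## -- stage: features + scoring per channel -------------------------------
  s <- tick()
  channels <- list(medium = "unstimulated", heavy = "stimulated")
  scoredByChannel <- list()
  netByChannel <- list()
  for (ch in names(channels)) {
    nms <- grep(paste0("_", ch, "$"), names(cleaned), value = TRUE)
    featureList <- lapply(nms, function(nm)
      computePairFeatures(cleaned[[nm]], smoothed[[nm]], fits[[nm]]))
    names(featureList) <- sub(paste0("_", ch, "$"), "", nms)
    features <- assemblePairFeatures(featureList)
    universe <- unique(c(features$proteinA, features$proteinB))
    gold <- buildGoldStandard(complexes, universe)
    scored <- scorePairs(features, gold, seed = stageSeed(config, 2L))
    utils::write.table(scored, file.path(outDir, paste0("scored_", ch, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    scoredByChannel[[ch]] <- scored
    net <- precisionThreshold(scored, config$targetPrecision,
                              condition = channels[[ch]])
    writeNetwork(net, file.path(outDir, paste0("network_", channels[[ch]], ".tsv")))
    netByChannel[[channels[[ch]]]] <- net
    stageLog("network", "%s: %d pairs scored, %d edges at %.0f%% precision",
             channels[[ch]], nrow(scored), edgeCount(net),
             100 * config$targetPrecision)
  }
  manifest$counts$pairsScored <- vapply(scoredByChannel, nrow, integer(1L))
  manifest$counts$edgesAtThreshold <-
    vapply(netByChannel, edgeCount, integer(1L))
  mark("score", s)

  ## -- stage: compare + differential ---------------------------------------
  s <- tick()
  comparison <- compareNetworks(netByChannel$unstimulated,
                                netByChannel$stimulated)
  manifest$counts$sharedEdges <- nrow(comparison$shared)
  manifest$counts$unstimOnlyEdges <- nrow(comparison$aOnly)
  manifest$counts$stimOnlyEdges <- nrow(comparison$bOnly)
  sets <- if (!is.null(config$geneSetsFile)) readGeneSets(config$geneSetsFile)
          else complexes
  sets <- filterGeneSets(sets)
  rewiring <- deltaNppiTest(netByChannel$stimulated,
                            netByChannel$unstimulated, sets,
                            nPerm = config$nPerm,
                            nIterFactor = config$nIterFactor,
                            seed = stageSeed(config, 3L))
  utils::write.table(rewiring, file.path(outDir, "rewiring_results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$counts$termsTested <- nrow(rewiring)
  mark("differential", s)

  manifest$elapsed <- round(tick() - t0, 3)
  generateReport(manifest, rewiring, sets, outDir,
                 fdrReport = config$fdrReport, jaccardMin = config$jaccardMin,
                 comparison = comparison)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Write the tabular report and enrichment-map graph
#'
#' Emits \code{report_overlap.tsv} (shared / condition-specific edge
#' proportions), \code{report_rewiring.tsv} (terms significant at the report
#' FDR) and \code{enrichment_map.json} (nodes = significant terms with z and
#' q; edges = gene-set pairs with Jaccard index at or above the threshold).
#'
#' @param manifest run manifest from [runPipeline()].
#' @param results rewiring results data.frame from [deltaNppiTest()].
#' @param sets the gene sets the results were computed on.
#' @param outDir output directory.
#' @param fdrReport FDR cutoff for the significant-term table (default 0.20).
#' @param jaccardMin inclusive Jaccard threshold for enrichment-map edges.
#' @param comparison optional [compareNetworks()] result for the overlap
#'   table.
#' @return invisible list of written paths.
#' @export
generateReport <- function(manifest, results, sets, outDir,
                           fdrReport = 0.20, jaccardMin = 0.33,
                           comparison = NULL) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  overlapPath <- file.path(outDir, "report_overlap.tsv")
  overlap <- if (!is.null(comparison))
    data.frame(class = names(comparison$proportions),
               proportion = as.numeric(comparison$proportions),
               nEdges = c(nrow(comparison$shared), nrow(comparison$aOnly),
                          nrow(comparison$bOnly)))
  else data.frame(class = character(), proportion = numeric(),
                  nEdges = integer())
  utils::write.table(overlap, overlapPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sig <- if (nrow(results)) results[!is.na(results$q) & results$q <= fdrReport,
                                    , drop = FALSE]
         else results
  utils::write.table(sig, file.path(outDir, "report_rewiring.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mapSets <- sets[names(sets) %in% sig$term]
  mapEdges <- if (length(mapSets) >= 2L)
    enrichmentMapEdges(mapSets, jaccardMin = jaccardMin)
  else data.frame(termA = character(), termB = character(),
                  jaccard = numeric())
  nodes <- if (nrow(sig))
    data.frame(term = sig$term, z = sig$z, q = sig$q)
  else data.frame(term = character(), z = numeric(), q = numeric())
  jsonlite::write_json(list(nodes = nodes, edges = mapEdges),
                       file.path(outDir, "enrichment_map.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(list(overlap = overlapPath,
                 rewiring = file.path(outDir, "report_rewiring.tsv"),
                 enrichmentMap = file.path(outDir, "enrichment_map.json")))
}
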