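# Shared fixtures and helpers, all generated in code.

pkey <- function(a, b) paste(pmin(a, b), pmax(a, b))

# One channel of the analysis: clean -> MODERN -> smooth/fit -> features ->
# cross-validated scoring. Mirrors the pipeline stages but stays independent
# of runPipeline() so stage-level tests do not depend on orchestration.
scoreChannel <- function(sim, ch, seed = 1L, modern = TRUE) {
  nms <- grep(paste0("_", ch, "$"), names(sim$matrices), value = TRUE)
  cleaned <- lapply(sim$matrices[nms], function(m)
    filterMinObservations(imputeSingleMissing(m)))
  if (modern)
    cleaned <- lapply(cleaned, function(cm)
      removeOutliers(cm, suppressWarnings(detectOutliers(cm))))
  sm <- lapply(cleaned, smoothChromatograms)
  fits <- lapply(sm, fitChromatograms)
  fl <- lapply(nms, function(nm)
    computePairFeatures(cleaned[[nm]], sm[[nm]], fits[[nm]]))
  names(fl) <- sub(paste0("_", ch, "$"), "", nms)
  feats <- assemblePairFeatures(fl)
  gold <- buildGoldStandard(sim$truth@complexes,
                            unique(c(feats$proteinA, feats$proteinB)))
  scorePairs(feats, gold, seed = seed)
}

# Truth pair keys for one condition.
truthKeys <- function(truth, condition) {
  tp <- truePairs(truth, condition)
  pkey(tp$proteinA, tp$proteinB)
}

# Precision of a network's edges against condition truth.
truthPrecision <- function(net, truth, condition) {
  ed <- edges(net)
  if (!nrow(ed)) return(NA_real_)
  mean(pkey(ed$proteinA, ed$proteinB) %in% truthKeys(truth, condition))
}

# Gaussian ROC AUC by rank comparison (oracle-style, no package code).
rankAUC <- function(scorePos, scoreNeg) {
  mean(outer(scorePos, scoreNeg, ">") + 0.5 * outer(scorePos, scoreNeg, "=="))
}

# Small fully-complexed study used by calibration and recovery checks:
# every protein is a gold-standard complex member, so the labeled-pair
# precision estimate is representative of the whole scored universe.
calibrationStudy <- function(seed, rewiredFraction = 0.3) {
  truth <- generateComplexTruth(48, 12, c(4L, 4L), rewiredFraction,
                                seed = seed)
  simulateChromatograms(truth, simulationConfig(seed = seed))
}
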