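#' Simulation configuration for synthetic co-fractionation experiments
#'
#' Bundles and validates the generator parameters. The defaults describe a
#' small SEC-PCP-SILAC-like experiment: 60 collected fractions, three
#' biological replicates, two isotope channels carrying the two conditions
#' (medium = unstimulated, heavy = stimulated), multiplicative measurement
#' noise at about 5\% coefficient of variation, 20\% missing quantifications,
#' and rare 50-fold single-point quantitation spikes.
#'
#' @param nFractions number of collected fractions (>= 10).
#' @param nReplicates number of replicates.
#' @param noiseSd multiplicative (log-normal) measurement noise: each
#'   observed value is the noiseless signal times \code{exp(N(0, noiseSd))},
#'   so \code{noiseSd} is approximately the coefficient of variation.
#' @param missingRate proportion of points set missing at random, in [0, 1].
#' @param spikeRate proportion of observed points receiving a quantitation
#'   spike; the realized count is exactly \code{round(spikeRate * nObserved)}.
#' @param spikeMagnitude multiplicative magnitude of each spike (> 1).
#' @param detectionLimit observed values below this limit are censored to
#'   missing, mirroring fractions in which a protein is not quantified; the
#'   default equals the noise standard deviation (0 disables censoring).
#' @param seed integer seed; fully determines all generator output.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nFractions = 60L, nReplicates = 3L,
                             noiseSd = 0.05, missingRate = 0.2,
                             spikeRate = 0.002, spikeMagnitude = 50,
                             detectionLimit = 0.02, seed = 1L) {
  stopifnot(nFractions >= 10L, nReplicates >= 1L, noiseSd >= 0,
            missingRate >= 0, missingRate <= 1,
            spikeRate >= 0, spikeRate <= 1,
            spikeMagnitude > 0, detectionLimit >= 0)
  structure(list(nFractions = as.integer(nFractions),
                 nReplicates = as.integer(nReplicates),
                 noiseSd = noiseSd, missingRate = missingRate,
                 spikeRate = spikeRate, spikeMagnitude = spikeMagnitude,
                 detectionLimit = detectionLimit, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Generate planted protein complexes with condition-dependent membership
#'
#' Assigns disjoint complexes from a protein universe; remaining proteins are
#' singletons (monomers in both conditions). Exactly
#' \code{round(rewiredFraction * nComplexes)} randomly chosen complexes are
#' condition-specific: assembled in the unstimulated condition but dissolved
#' into monomers upon stimulation.
#'
#' @param nProteins size of the protein universe.
#' @param nComplexes number of complexes to plant.
#' @param sizeRange length-2 integer vector, inclusive range of complex sizes
#'   (minimum >= 2).
#' @param rewiredFraction proportion of complexes rewired between conditions.
#' @param seed integer seed.
#' @return A [ComplexTruth-class] object.
#' @examples
#' truth <- generateComplexTruth(40, 5, c(3, 5), rewiredFraction = 0.4,
#'                               seed = 7)
#' truth
#' @export
generateComplexTruth <- function(nProteins, nComplexes, sizeRange = c(3L, 6L),
                                 rewiredFraction = 0, seed = 1L) {
  stopifnot(length(sizeRange) == 2L, rewiredFraction >= 0,
            rewiredFraction <= 1)
  sizeRange <- as.integer(sizeRange)
  if (sizeRange[1L] < 2L)
    stop("minimum complex size must be >= 2")
  if (sizeRange[1L] > sizeRange[2L])
    stop("sizeRange must be non-decreasing")
  if (nComplexes * sizeRange[2L] > nProteins)
    stop(sprintf(
      "infeasible: %d complexes of size up to %d need more than %d proteins",
      nComplexes, sizeRange[2L], nProteins))
  set.seed(seed)
  ids <- sprintf("P%04d", seq_len(nProteins))
  pool <- sample(ids)
  sizes <- if (sizeRange[1L] == sizeRange[2L]) rep(sizeRange[1L], nComplexes)
           else sample(seq(sizeRange[1L], sizeRange[2L]), nComplexes,
                       replace = TRUE)
  complexes <- vector("list", nComplexes)
  at <- 0L
  for (i in seq_len(nComplexes)) {
    complexes[[i]] <- sort(pool[at + seq_len(sizes[i])])
    at <- at + sizes[i]
  }
  names(complexes) <- sprintf("CPX%03d", seq_len(nComplexes))
  nRewired <- round(rewiredFraction * nComplexes)
  rewired <- if (nRewired > 0L) sample(nComplexes, nRewired) else integer()
  membership <- matrix(TRUE, nrow = nComplexes, ncol = 2L,
                       dimnames = list(names(complexes),
                                       c("unstimulated", "stimulated")))
  membership[rewired, "stimulated"] <- FALSE
  new("ComplexTruth", complexes = complexes, membership = membership,
      proteins = ids,
      rewiredFraction = if (nComplexes) nRewired / nComplexes else 0)
}

#' Rewired (condition-specific) complexes of a ComplexTruth
#' @param truth a [ComplexTruth-class].
#' @return character vector of complex ids whose membership differs between
#'   conditions.
#' @export
rewiredComplexes <- function(truth) {
  mm <- truth@membership
  rownames(mm)[mm[, "unstimulated"] != mm[, "stimulated"]]
}

#' Within-complex protein pairs assembled in a given condition
#' @param truth a [ComplexTruth-class].
#' @param condition \code{"unstimulated"} or \code{"stimulated"}.
#' @return data.frame of unordered pairs (\code{proteinA < proteinB}).
#' @export
truePairs <- function(truth, condition = c("unstimulated", "stimulated")) {
  condition <- match.arg(condition)
  keep <- truth@membership[, condition]
  pairs <- lapply(truth@complexes[keep], function(members) {
    if (length(members) < 2L) return(NULL)
    cmb <- utils::combn(sort(members), 2L)
    data.frame(proteinA = cmb[1L, ], proteinB = cmb[2L, ])
  })
  out <- do.call(rbind, pairs)
  if (is.null(out))
    out <- data.frame(proteinA = character(), proteinB = character())
  rownames(out) <- NULL
  out
}

## Per-complex and per-protein elution peak parameters are drawn once and
## shared across replicates: replicates re-measure the same biology.
drawPeakParams <- function(truth, nFractions) {
  nCpx <- length(truth@complexes)
  lo <- max(2, 0.15 * nFractions)
  ## distinct assemblies occupy resolvable elution peaks: centers sit on a
  ## permuted equally spaced grid with jitter, not on independent draws
  grid <- seq(lo, nFractions - lo, length.out = max(nCpx, 2L))[seq_len(nCpx)]
  spacing <- if (nCpx > 1L) diff(grid[1:2]) else nFractions / 2
  cpx <- data.frame(
    center = sample(grid) + stats::runif(nCpx, -spacing / 4, spacing / 4),
    width = stats::runif(nCpx, 2.5, 4.5)
  )
  rownames(cpx) <- names(truth@complexes)
  nProt <- length(truth@proteins)
  mono <- data.frame(
    center = stats::runif(nProt, 0.4 * nFractions, nFractions),
    width = stats::runif(nProt, 2, 3.5)
  )
  rownames(mono) <- truth@proteins
  amp <- stats::runif(nProt, 1, 3)
  names(amp) <- truth@proteins
  list(cpx = cpx, mono = mono, amp = amp)
}

gaussPeak <- function(x, center, width) exp(-(x - center)^2 / (2 * width^2))

## Noiseless signal matrix for one condition (proteins x fractions).
conditionSignal <- function(truth, params, condition, nFractions) {
  x <- seq_len(nFractions)
  sig <- matrix(0, nrow = length(truth@proteins), ncol = nFractions,
                dimnames = list(truth@proteins,
                                paste0("fraction_", x)))
  inComplex <- rep(FALSE, length(truth@proteins))
  names(inComplex) <- truth@proteins
  for (cid in names(truth@complexes)) {
    if (!truth@membership[cid, condition]) next
    shape <- gaussPeak(x, params$cpx[cid, "center"], params$cpx[cid, "width"])
    for (p in truth@complexes[[cid]]) {
      sig[p, ] <- params$amp[[p]] * shape
      inComplex[[p]] <- TRUE
    }
  }
  for (p in truth@proteins[!inComplex]) {
    sig[p, ] <- params$amp[[p]] *
      gaussPeak(x, params$mono[p, "center"], params$mono[p, "width"])
  }
  sig
}

#' Simulate co-fractionation chromatogram matrices with planted complexes
#'
#' Each complex assembled in a condition elutes as one shared Gaussian peak;
#' a member's noiseless profile is that peak scaled by a member-specific
#' amplitude. Monomeric proteins (singletons, and members of dissolved
#' complexes in the stimulated condition) elute as independent
#' low-molecular-weight peaks in the last quarter of the fraction range.
#' Additive Gaussian noise is applied per replicate, negative values are
#' clipped to zero, points are censored below the detection limit and then
#' set missing at random, and exactly \code{round(spikeRate * nObserved)}
#' observed positive points per matrix are multiplied by
#' \code{spikeMagnitude} to emulate single-point quantitation errors
#' (multiplying a zero models no error, so spikes land on positive values).
#'
#' The isotope channels carry the conditions: medium = unstimulated,
#' heavy = stimulated. One matrix is produced per replicate x channel.
#'
#' @param truth a [ComplexTruth-class] from [generateComplexTruth()].
#' @param config a \code{SimulationConfig} from [simulationConfig()]; its
#'   \code{seed} fully determines the output.
#' @return list with elements \code{matrices} (named list of
#'   [ChromatogramMatrix-class], names \code{"<replicate>_<channel>"}),
#'   \code{spikes} (data.frame: replicate, channel, protein, fraction,
#'   original, spiked) and \code{truth}.
#' @examples
#' truth <- generateComplexTruth(30, 4, c(3, 4), seed = 1)
#' sim <- simulateChromatograms(truth, simulationConfig(seed = 1))
#' sim$matrices[["r1_medium"]]
#' @export
simulateChromatograms <- function(truth, config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  validObject(truth)
  set.seed(config$seed)
  nF <- config$nFractions
  params <- drawPeakParams(truth, nF)
  signal <- list(
    unstimulated = conditionSignal(truth, params, "unstimulated", nF),
    stimulated = conditionSignal(truth, params, "stimulated", nF)
  )
  channels <- c(medium = "unstimulated", heavy = "stimulated")
  matrices <- list()
  spikes <- list()
  for (r in seq_len(config$nReplicates)) {
    rid <- paste0("r", r)
    for (ch in names(channels)) {
      cond <- channels[[ch]]
      y <- signal[[cond]]
      if (config$noiseSd > 0)
        y <- y * matrix(exp(stats::rnorm(length(y), sd = config$noiseSd)),
                        nrow = nrow(y))
      if (config$detectionLimit > 0) y[y < config$detectionLimit] <- NA
      if (config$missingRate > 0) {
        drop <- which(stats::runif(length(y)) < config$missingRate)
        y[drop] <- NA
      }
      obs <- which(!is.na(y))
      nSpike <- round(config$spikeRate * length(obs))
      if (nSpike > 0L) {
        eligible <- obs[y[obs] > 0]
        pick <- eligible[sample.int(length(eligible),
                                    min(nSpike, length(eligible)))]
        idx <- arrayInd(pick, dim(y))
        spikes[[paste(rid, ch)]] <- data.frame(
          replicate = rid, channel = ch,
          protein = rownames(y)[idx[, 1L]], fraction = idx[, 2L],
          original = y[pick], spiked = y[pick] * config$spikeMagnitude)
        y[pick] <- y[pick] * config$spikeMagnitude
      }
      matrices[[paste0(rid, "_", ch)]] <- ChromatogramMatrix(
        y, replicate = rid, channel = ch, condition = cond)
    }
  }
  spikes <- if (length(spikes)) do.call(rbind, spikes) else
    data.frame(replicate = character(), channel = character(),
               protein = character(), fraction = integer(),
               original = numeric(), spiked = numeric())
  rownames(spikes) <- NULL
  list(matrices = matrices, spikes = spikes, truth = truth)
}

#' Write a ChromatogramMatrix as TSV
#'
#' Layout: first column \code{protein}, remaining columns
#' \code{fraction_1..fraction_N}; missing points are empty cells. The file
#' round-trips through [readChromatogramMatrix()].
#'
#' @param matrix a [ChromatogramMatrix-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeChromatogramMatrix <- function(matrix, path) {
  m <- intensities(matrix)
  df <- data.frame(protein = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Write complex ground truth as TSV
#'
#' Columns: complex_id, member, unstimulated, stimulated (logical presence
#' flags).
#' @param truth a [ComplexTruth-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeComplexTruth <- function(truth, path) {
  rows <- do.call(rbind, lapply(names(truth@complexes), function(cid) {
    data.frame(complex_id = cid, member = truth@complexes[[cid]],
               unstimulated = truth@membership[cid, "unstimulated"],
               stimulated = truth@membership[cid, "stimulated"])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read complex definitions from TSV
#'
#' Accepts the two-column (complex_id, member) layout, which is what a
#' CORUM-style download reduces to after column mapping, or the four-column
#' layout written by [writeComplexTruth()].
#'
#' @param path TSV file with columns \code{complex_id} and \code{member}
#'   (optional logical \code{unstimulated}/\code{stimulated} columns).
#' @return named list of member character vectors.
#' @export
readComplexes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("complex_id", "member") %in% names(df)))
    stop("complex file needs columns 'complex_id' and 'member'")
  split(df$member, df$complex_id)
}

#' Write the spike ground-truth table as TSV
#' @param spikes the \code{spikes} data.frame from [simulateChromatograms()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSpikeTruth <- function(spikes, path) {
  utils::write.table(spikes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
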