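## Pearson correlation between two profiles over jointly observed entries,
## NA below the minimum overlap or under zero variance.
pairwisePearson <- function(x, y, minOverlap = 3L) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < minOverlap) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

#' Interaction profile of a protein
#'
#' The vector of Pearson correlation coefficients between one protein's
#' chromatogram and every other protein's chromatogram, computed over the
#' fractions observed in both (optionally with one fraction excluded from the
#' focal protein's profile). Entries with fewer than \code{minOverlap}
#' jointly observed fractions, or with zero variance, are \code{NA}.
#'
#' @param matrix a [ChromatogramMatrix-class].
#' @param protein focal protein id.
#' @param excludeFraction optional fraction index dropped from the
#'   computation (the leave-one-out profile).
#' @param minOverlap minimum jointly observed fractions (default 3).
#' @return named numeric vector over the other proteins.
#' @export
interactionProfile <- function(matrix, protein, excludeFraction = NULL,
                               minOverlap = 3L) {
  m <- intensities(matrix)
  if (!protein %in% rownames(m)) stop("unknown protein: ", protein)
  x <- m[protein, ]
  if (!is.null(excludeFraction)) x[excludeFraction] <- NA
  others <- setdiff(rownames(m), protein)
  vapply(others, function(j) pairwisePearson(x, m[j, ], minOverlap),
         numeric(1L))
}

#' Leave-one-out autocorrelation of one chromatogram point
#'
#' The Pearson correlation between a protein's interaction profile and the
#' interaction profile recomputed with one chromatogram point removed,
#' over the profile entries defined in both. A single erroneous quantitation
#' globally rewires the interaction profile, so its removal yields a low
#' autocorrelation.
#'
#' @inheritParams interactionProfile
#' @param fraction observed fraction index to remove.
#' @return autocorrelation in [-1, 1], or \code{NA} when fewer than 3 profile
#'   entries are defined in both (such points are exempt from flagging).
#' @export
leaveOneOutAutocorrelation <- function(matrix, protein, fraction,
                                       minOverlap = 3L) {
  base <- interactionProfile(matrix, protein, minOverlap = minOverlap)
  loo <- interactionProfile(matrix, protein, excludeFraction = fraction,
                            minOverlap = minOverlap)
  ok <- !is.na(base) & !is.na(loo)
  if (sum(ok) < 3L) return(NA_real_)
  ## a removal that leaves every profile entry unchanged is perfect
  ## self-agreement even when the entries are constant
  if (max(abs(base[ok] - loo[ok])) < 1e-12) return(1)
  pairwisePearson(base, loo, minOverlap = 3L)
}

## All leave-one-out autocorrelations of one matrix via running sufficient
## statistics: for each focal protein the pairwise sums (n, Sx, Sy, Sxx, Syy,
## Sxy) against all others are computed once and the excluded fraction's
## contribution subtracted, avoiding a full correlation pass per point.
allAutocorrelations <- function(m, minOverlap = 3L) {
  P <- nrow(m)
  F <- ncol(m)
  out <- matrix(NA_real_, P, F, dimnames = dimnames(m))
  O <- !is.na(m)
  M0 <- m
  M0[!O] <- 0
  Omode <- O * 1
  corFromSums <- function(n, Sx, Sy, Sxx, Syy, Sxy) {
    vx <- n * Sxx - Sx^2
    vy <- n * Syy - Sy^2
    ## relative guard against cancellation noise standing in for zero variance
    zx <- vx <= 1e-10 * pmax(n * Sxx, 1)
    zy <- vy <= 1e-10 * pmax(n * Syy, 1)
    r <- (n * Sxy - Sx * Sy) / sqrt(pmax(vx, 0) * pmax(vy, 0))
    r <- pmin(pmax(r, -1), 1)
    r[n < minOverlap | zx | zy] <- NA_real_
    r
  }
  for (i in seq_len(P)) {
    x <- m[i, ]
    obsX <- Omode[i, ]
    xo <- M0[i, ]
    OY <- Omode[-i, , drop = FALSE]
    Y0 <- M0[-i, , drop = FALSE]
    n <- as.vector(OY %*% obsX)
    Sx <- as.vector(OY %*% xo)
    Sxx <- as.vector(OY %*% xo^2)
    Sy <- as.vector(Y0 %*% obsX)
    Syy <- as.vector(Y0^2 %*% obsX)
    Sxy <- as.vector(Y0 %*% xo)
    rBase <- corFromSums(n, Sx, Sy, Sxx, Syy, Sxy)
    for (f in which(O[i, ])) {
      mf <- OY[, f]
      yf <- Y0[, f]
      xf <- x[f]
      rExcl <- corFromSums(n - mf, Sx - xf * mf, Sy - yf,
                           Sxx - xf^2 * mf, Syy - yf^2, Sxy - xf * yf)
      ok <- !is.na(rBase) & !is.na(rExcl)
      if (sum(ok) < 3L) next
      if (max(abs(rBase[ok] - rExcl[ok])) < 1e-12) {
        out[i, f] <- 1
      } else if (stats::sd(rBase[ok]) > 0 && stats::sd(rExcl[ok]) > 0) {
        out[i, f] <- stats::cor(rBase[ok], rExcl[ok])
      }
    }
  }
  out
}

#' Detect single-point quantitation errors (MODERN)
#'
#' Computes the leave-one-out interaction-profile autocorrelation of every
#' observed point of the matrix, standardizes the pooled autocorrelations to
#' z-scores (matrix-wide mean and standard deviation), and flags points with
#' \deqn{z < \Phi^{-1}\left(\frac{\alpha/2}{N}\right)}
#' where \eqn{\alpha} is the two-tailed family-wise error rate and \eqn{N}
#' the total number of observed points in the matrix. A single pass is made;
#' flags are not re-derived after removal.
#'
#' @param matrix a cleaned [ChromatogramMatrix-class] (imputed and filtered).
#' @param fwer two-tailed family-wise error rate (default 0.05).
#' @param minOverlap minimum jointly observed fractions for any Pearson
#'   correlation (default 3).
#' @return An [OutlierReport-class]. When the pooled autocorrelations are
#'   degenerate (zero standard deviation) no point is flagged and a warning
#'   is raised.
#' @examples
#' truth <- generateComplexTruth(20, 3, c(3, 3), seed = 2)
#' sim <- simulateChromatograms(truth, simulationConfig(
#'   nFractions = 20, nReplicates = 1, missingRate = 0, spikeRate = 0.01,
#'   seed = 2))
#' detectOutliers(sim$matrices[[1]])
#' @export
detectOutliers <- function(matrix, fwer = 0.05, minOverlap = 3L) {
  m <- intensities(matrix)
  ac <- allAutocorrelations(m, minOverlap = minOverlap)
  nPoints <- sum(!is.na(m))
  pooled <- ac[!is.na(ac)]
  zCrit <- stats::qnorm((fwer / 2) / max(nPoints, 1L))
  z <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  flagged <- data.frame(protein = character(), fraction = integer(),
                        autocor = numeric(), z = numeric())
  if (length(pooled) >= 2L && stats::sd(pooled) > 0) {
    z <- (ac - mean(pooled)) / stats::sd(pooled)
    hit <- which(!is.na(z) & z < zCrit, arr.ind = TRUE)
    if (nrow(hit)) {
      flagged <- data.frame(protein = rownames(m)[hit[, 1L]],
                            fraction = unname(hit[, 2L]),
                            autocor = ac[hit], z = z[hit])
      flagged <- flagged[order(flagged$z), ]
      rownames(flagged) <- NULL
    }
  } else {
    warning("degenerate pooled autocorrelations; no points flagged")
  }
  new("OutlierReport", flagged = flagged, autocor = ac, z = z,
      zCrit = zCrit, nPoints = as.integer(nPoints), fwer = fwer)
}

#' Remove flagged quantitation errors from a matrix
#'
#' @param matrix the [ChromatogramMatrix-class] the report was derived from.
#' @param report an [OutlierReport-class] from [detectOutliers()].
#' @return A [ChromatogramMatrix-class] with flagged points set missing; all
#'   other values unchanged.
#' @export
removeOutliers <- function(matrix, report) {
  m <- intensities(matrix)
  fl <- report@flagged
  if (nrow(fl)) {
    if (!all(fl$protein %in% rownames(m)))
      stop("report does not match matrix: unknown protein in flags")
    m[cbind(match(fl$protein, rownames(m)), fl$fraction)] <- NA
  }
  ChromatogramMatrix(m, replicate = matrix@replicate,
                     channel = matrix@channel, condition = matrix@condition)
}
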