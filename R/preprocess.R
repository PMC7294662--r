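#' Read a chromatogram matrix from TSV
#'
#' Expects the layout written by [writeChromatogramMatrix()]: a header row,
#' first column \code{protein}, remaining columns one per fraction in elution
#' order; empty cells are missing quantifications.
#'
#' @param path TSV file path.
#' @param replicate,channel,condition metadata attached to the object.
#' @return A [ChromatogramMatrix-class].
#' @export
readChromatogramMatrix <- function(path, replicate = "r1",
                                   channel = "medium",
                                   condition = "unstimulated") {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("chromatogram file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nCol <- length(fields[[1L]])
  ragged <- which(lengths(fields) != nCol)
  ## trailing empty cells are dropped by strsplit; pad rows short of the header
  fields[-1L] <- lapply(fields[-1L], function(f) {
    if (length(f) < nCol) c(f, rep("", nCol - length(f))) else f
  })
  ragged <- which(lengths(fields) != nCol)
  if (length(ragged))
    stop("ragged row(s) in ", path, ": line ", ragged[1L])
  ids <- vapply(fields[-1L], `[[`, character(1L), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate protein id in ", path, ": ", dup[1L])
  vals <- lapply(fields[-1L], function(f) {
    cells <- f[-1L]
    cells[cells == ""] <- NA
    suppressWarnings(v <- as.numeric(cells))
    bad <- which(!is.na(cells) & is.na(v))
    if (length(bad))
      stop("non-numeric cell for protein ", f[[1L]],
           " at fraction ", bad[1L])
    v
  })
  m <- do.call(rbind, vals)
  rownames(m) <- ids
  colnames(m) <- fields[[1L]][-1L]
  if (any(m < 0, na.rm = TRUE)) {
    bad <- which(apply(m < 0, 1L, any, na.rm = TRUE))[1L]
    stop("negative intensity for protein ", ids[bad])
  }
  ChromatogramMatrix(m, replicate = replicate, channel = channel,
                     condition = condition)
}

#' Impute single missing points as the mean of their neighbors
#'
#' A missing point whose immediate left and right neighbors are both observed
#' becomes their arithmetic mean. Runs of two or more consecutive missing
#' points, and missing endpoints, are left untouched.
#'
#' @param profile numeric vector with \code{NA} for missing points, or a
#'   [ChromatogramMatrix-class] (imputed row-wise).
#' @return Object of the same type with single gaps filled.
#' @examples
#' imputeSingleMissing(c(2, NA, 4))
#' @export
imputeSingleMissing <- function(profile) {
  if (is(profile, "ChromatogramMatrix")) {
    m <- intensities(profile)
    m <- t(apply(m, 1L, imputeSingleMissing))
    colnames(m) <- colnames(intensities(profile))
    return(ChromatogramMatrix(m, replicate = profile@replicate,
                              channel = profile@channel,
                              condition = profile@condition))
  }
  n <- length(profile)
  if (n < 3L) return(profile)
  i <- 2L:(n - 1L)
  single <- is.na(profile[i]) & !is.na(profile[i - 1L]) & !is.na(profile[i + 1L])
  out <- profile
  out[i][single] <- (profile[i - 1L][single] + profile[i + 1L][single]) / 2
  out
}

#' Drop proteins with too few observed points
#'
#' @param matrix a [ChromatogramMatrix-class] (apply after imputation).
#' @param minObs minimum number of observed points to retain a protein
#'   (default 5).
#' @return A [ChromatogramMatrix-class] with only the retained proteins, in
#'   their original order. May be empty.
#' @export
filterMinObservations <- function(matrix, minObs = 5L) {
  m <- intensities(matrix)
  keep <- rowSums(!is.na(m)) >= minObs
  ChromatogramMatrix(m[keep, , drop = FALSE], replicate = matrix@replicate,
                     channel = matrix@channel, condition = matrix@condition)
}

#' Sliding-average smoothing of an elution profile
#'
#' Each output point is the mean of the observed points inside a centered
#' window of \code{width} fractions; windows truncate at the profile ends.
#' Missing input points stay missing in the output.
#'
#' @param profile numeric vector with \code{NA} for missing points.
#' @param width odd window width in fractions (default 5).
#' @return Smoothed numeric vector of the same length.
#' @examples
#' smoothProfile(c(0, 0, 0, 0, 10, 0, 0, 0, 0))
#' @export
smoothProfile <- function(profile, width = 5L) {
  if (width %% 2L == 0L) stop("smoothing width must be odd")
  n <- length(profile)
  half <- (width - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(profile[i])) next
    win <- profile[max(1L, i - half):min(n, i + half)]
    out[i] <- mean(win, na.rm = TRUE)
  }
  out
}

#' Smooth every chromatogram of a matrix
#' @param matrix a [ChromatogramMatrix-class].
#' @param width odd window width in fractions.
#' @return A smoothed [ChromatogramMatrix-class].
#' @export
smoothChromatograms <- function(matrix, width = 5L) {
  m <- intensities(matrix)
  sm <- t(apply(m, 1L, smoothProfile, width = width))
  colnames(sm) <- colnames(m)
  ChromatogramMatrix(sm, replicate = matrix@replicate,
                     channel = matrix@channel, condition = matrix@condition)
}

## k largest local maxima of an observed profile (ties and plateaus resolved
## to the lowest fraction); falls back to the k largest values.
peakCandidates <- function(x, k) {
  obs <- which(!is.na(x))
  v <- x[obs]
  n <- length(v)
  isMax <- vapply(seq_len(n), function(i) {
    left <- if (i > 1L) v[i - 1L] else -Inf
    right <- if (i < n) v[i + 1L] else -Inf
    v[i] > left && v[i] >= right
  }, logical(1L))
  cand <- obs[isMax][order(v[isMax], decreasing = TRUE)]
  if (length(cand) < k)
    cand <- unique(c(cand, obs[order(v, decreasing = TRUE)]))
  cand[seq_len(min(k, length(cand)))]
}

mixturePredict <- function(x, A, mu, sigma) {
  y <- numeric(length(x))
  for (j in seq_along(A)) y <- y + A[j] * gaussPeak(x, mu[j], sigma[j])
  y
}

#' Fit a Gaussian mixture to a smoothed chromatogram
#'
#' Fits \eqn{f(x) = \sum_{k} A_k \exp(-(x-\mu_k)^2/(2\sigma_k^2))} to the
#' observed points by bounded Levenberg-Marquardt least squares for each
#' candidate component count \code{1..maxComponents}, scores each converged
#' fit with the bias-corrected Akaike information criterion
#' \deqn{AICc = n \ln(SSE/n) + 2p + 2p(p+1)/(n-p-1), \quad p = 3k,}
#' and returns the fit minimizing AICc. Component counts with
#' \eqn{n - p - 1 \le 0} are not attempted. Chromatograms for which no
#' candidate converges (e.g. all-zero profiles) are discarded: the function
#' returns \code{NULL}.
#'
#' Initialization places centers at the k largest local maxima, amplitudes at
#' those heights, and widths at 2 fractions, with bounds \eqn{A > 0},
#' \eqn{\mu \in [1 - 5, N + 5]} and \eqn{\sigma \in [0.5, N]}.
#'
#' @param profile smoothed numeric profile (\code{NA} = missing).
#' @param maxComponents maximum number of Gaussians (default 5).
#' @return A [GaussianMixtureFit-class], or \code{NULL} when the chromatogram
#'   cannot be fit (a normal outcome, distinct from an error).
#' @export
fitGaussianMixture <- function(profile, maxComponents = 5L) {
  n <- length(profile)
  obs <- which(!is.na(profile))
  x <- as.numeric(obs)
  y <- profile[obs]
  if (length(y) < 4L || all(y == 0)) return(NULL)
  best <- NULL
  for (k in seq_len(maxComponents)) {
    p <- 3L * k
    if (length(y) - p - 1L <= 0L) break
    init <- peakCandidates(profile, k)
    if (length(init) < k) break
    terms <- paste0("A", seq_len(k), " * exp(-(x - mu", seq_len(k),
                    ")^2 / (2 * s", seq_len(k), "^2))")
    fmla <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
    start <- c(as.list(structure(pmax(profile[init], 1e-3),
                                 names = paste0("A", seq_len(k)))),
               as.list(structure(as.numeric(init),
                                 names = paste0("mu", seq_len(k)))),
               as.list(structure(rep(2, k),
                                 names = paste0("s", seq_len(k)))))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        fmla, data = data.frame(x = x, y = y),
        start = start,
        lower = c(rep(1e-6, k), rep(1 - 5, k), rep(0.5, k)),
        upper = c(rep(Inf, k), rep(n + 5, k), rep(n, k)),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-8)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    nn <- length(y)
    aicc <- nn * log(max(sse, 1e-300) / nn) + 2 * p +
      2 * p * (p + 1) / (nn - p - 1)
    if (is.null(best) || aicc < best@aicc) {
      cf <- stats::coef(fit)
      best <- new("GaussianMixtureFit",
                  components = data.frame(A = unname(cf[seq_len(k)]),
                                          mu = unname(cf[k + seq_len(k)]),
                                          sigma = unname(cf[2L * k + seq_len(k)])),
                  aicc = aicc, nObs = length(y), converged = TRUE)
    }
  }
  best
}

#' Fit Gaussian mixtures to every chromatogram of a matrix
#'
#' @param matrix a smoothed [ChromatogramMatrix-class] that already passed
#'   [filterMinObservations()].
#' @param maxComponents maximum number of Gaussians per chromatogram.
#' @return named list of [GaussianMixtureFit-class] objects; proteins whose
#'   chromatogram could not be fit are absent (attribute
#'   \code{"nDiscarded"} counts them).
#' @export
fitChromatograms <- function(matrix, maxComponents = 5L) {
  m <- intensities(matrix)
  fits <- lapply(seq_len(nrow(m)), function(i)
    fitGaussianMixture(m[i, ], maxComponents = maxComponents))
  names(fits) <- rownames(m)
  discarded <- vapply(fits, is.null, logical(1L))
  out <- fits[!discarded]
  attr(out, "nDiscarded") <- sum(discarded)
  out
}

#' Export fitted mixtures as TSV
#'
#' Columns: protein, component, A, mu, sigma, aicc.
#' @param fits named list from [fitChromatograms()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGaussianFits <- function(fits, path) {
  rows <- do.call(rbind, lapply(names(fits), function(p) {
    cmp <- fits[[p]]@components
    data.frame(protein = p, component = seq_len(nrow(cmp)),
               A = cmp$A, mu = cmp$mu, sigma = cmp$sigma,
               aicc = fits[[p]]@aicc)
  }))
  if (is.null(rows))
    rows <- data.frame(protein = character(), component = integer(),
                       A = numeric(), mu = numeric(), sigma = numeric(),
                       aicc = numeric())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
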