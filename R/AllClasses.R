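#' @import methods
NULL

#' ChromatogramMatrix: protein elution profiles for one replicate and channel
#'
#' Container for a proteins x fractions matrix of co-fractionation ratio
#' intensities from one replicate of one isotope channel. Missing
#' quantifications are explicit \code{NA}s; observed values are non-negative.
#' Row names are protein accessions; fractions are 1-based column positions.
#'
#' @slot intensities numeric matrix, proteins in rows, fractions in columns,
#'   \code{NA} marking missing points.
#' @slot replicate character scalar, replicate identifier.
#' @slot channel character scalar, \code{"medium"} or \code{"heavy"} (the
#'   SILAC channel carrying the unstimulated or stimulated condition).
#' @slot condition character scalar, condition label (e.g. \code{"unstimulated"}).
#'
#' @seealso [ChromatogramMatrix()] constructor, [intensities()],
#'   [readChromatogramMatrix()]
#' @exportClass ChromatogramMatrix
setClass("ChromatogramMatrix",
  representation(
    intensities = "matrix",
    replicate = "character",
    channel = "character",
    condition = "character"
  )
)

setValidity("ChromatogramMatrix", function(object) {
  m <- object@intensities
  msgs <- character()
  if (!is.numeric(m)) msgs <- c(msgs, "intensities must be a numeric matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msgs <- c(msgs, "protein ids (row names) must be present and unique")
  if (is.numeric(m) && any(m < 0, na.rm = TRUE))
    msgs <- c(msgs, "observed intensities must be >= 0")
  if (length(object@replicate) != 1L || length(object@channel) != 1L ||
      length(object@condition) != 1L)
    msgs <- c(msgs, "replicate, channel and condition must be length-1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ChromatogramMatrix
#'
#' @param intensities numeric matrix (proteins x fractions) with row names;
#'   \code{NA} marks missing points.
#' @param replicate,channel,condition character scalars of metadata.
#' @return A [ChromatogramMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 2, NA, 0.5), nrow = 2,
#'             dimnames = list(c("P1", "P2"), NULL))
#' ChromatogramMatrix(m, replicate = "r1", channel = "medium",
#'                    condition = "unstimulated")
#' @export
ChromatogramMatrix <- function(intensities, replicate = "r1",
                               channel = "medium",
                               condition = "unstimulated") {
  if (is.null(colnames(intensities)))
    colnames(intensities) <- paste0("fraction_", seq_len(ncol(intensities)))
  new("ChromatogramMatrix", intensities = intensities,
      replicate = as.character(replicate), channel = as.character(channel),
      condition = as.character(condition))
}

#' ComplexTruth: planted protein complexes with per-condition membership
#'
#' Ground truth for the synthetic-data generator: disjoint protein complexes,
#' a per-condition presence flag for each complex (a complex absent in a
#' condition dissolves into monomers there), and the realized rewired
#' fraction.
#'
#' @slot complexes named list; each element a character vector of >= 2 member
#'   protein ids, disjoint across complexes.
#' @slot membership logical matrix, complexes x conditions
#'   (\code{"unstimulated"}, \code{"stimulated"}); TRUE = complex assembled.
#' @slot proteins character vector of all protein ids in the universe
#'   (complex members plus singletons).
#' @slot rewiredFraction numeric scalar, realized proportion of complexes
#'   whose membership differs between the two conditions.
#' @exportClass ComplexTruth
setClass("ComplexTruth",
  representation(
    complexes = "list",
    membership = "matrix",
    proteins = "character",
    rewiredFraction = "numeric"
  )
)

setValidity("ComplexTruth", function(object) {
  msgs <- character()
  sizes <- lengths(object@complexes)
  if (any(sizes < 2L)) msgs <- c(msgs, "every complex needs >= 2 members")
  members <- unlist(object@complexes, use.names = FALSE)
  if (anyDuplicated(members))
    msgs <- c(msgs, "complexes must be disjoint with unique member ids")
  if (!all(members %in% object@proteins))
    msgs <- c(msgs, "complex members must be drawn from the protein universe")
  mm <- object@membership
  if (!is.logical(mm) || nrow(mm) != length(object@complexes) ||
      !identical(colnames(mm), c("unstimulated", "stimulated")))
    msgs <- c(msgs, "membership must be logical complexes x {unstimulated, stimulated}")
  if (is.logical(mm) && nrow(mm) == length(object@complexes)) {
    realized <- if (nrow(mm)) mean(mm[, 1L] != mm[, 2L]) else 0
    if (abs(realized - object@rewiredFraction) > 1 / max(1, 2 * nrow(mm)))
      msgs <- c(msgs, "rewiredFraction must equal the realized rewired proportion")
  }
  if (length(msgs)) msgs else TRUE
})

#' GaussianMixtureFit: fitted elution-peak mixture for one chromatogram
#'
#' Result of least-squares fitting a mixture of 1-5 Gaussian peaks
#' \eqn{f(x) = \sum_k A_k \exp(-(x - \mu_k)^2 / (2\sigma_k^2))} to a smoothed
#' chromatogram, with the number of components chosen by the bias-corrected
#' Akaike information criterion (AICc).
#'
#' @slot components data.frame with columns \code{A}, \code{mu}, \code{sigma},
#'   one row per fitted Gaussian.
#' @slot aicc numeric scalar, AICc of the selected model.
#' @slot nObs integer, number of observed points used in the fit.
#' @slot converged logical, TRUE when the selected fit converged.
#' @exportClass GaussianMixtureFit
setClass("GaussianMixtureFit",
  representation(
    components = "data.frame",
    aicc = "numeric",
    nObs = "integer",
    converged = "logical"
  )
)

setValidity("GaussianMixtureFit", function(object) {
  cmp <- object@components
  msgs <- character()
  if (!all(c("A", "mu", "sigma") %in% names(cmp)))
    msgs <- c(msgs, "components needs columns A, mu, sigma")
  if (nrow(cmp) < 1L || nrow(cmp) > 5L)
    msgs <- c(msgs, "1 to 5 components required")
  if (all(c("A", "sigma") %in% names(cmp)) &&
      (any(cmp$A <= 0) || any(cmp$sigma <= 0)))
    msgs <- c(msgs, "amplitudes and widths must be positive")
  if (length(msgs)) msgs else TRUE
})

#' OutlierReport: MODERN single-point quantitation-error calls
#'
#' Per-point leave-one-out interaction-profile autocorrelations for one
#' chromatogram matrix, their matrix-wide z-scores, and the points flagged at
#' the family-wise error threshold
#' \eqn{z < \Phi^{-1}((\alpha/2)/N)} with \eqn{N} the total observed points.
#'
#' @slot flagged data.frame with columns \code{protein}, \code{fraction},
#'   \code{autocor}, \code{z}, one row per flagged point.
#' @slot autocor numeric matrix of autocorrelations (NA where unobserved or
#'   undefined), same dimensions as the input matrix.
#' @slot z numeric matrix of z-scores.
#' @slot zCrit numeric, the critical lower-tail z.
#' @slot nPoints integer, total observed points N in the matrix.
#' @slot fwer numeric, the family-wise error rate used.
#' @exportClass OutlierReport
setClass("OutlierReport",
  representation(
    flagged = "data.frame",
    autocor = "matrix",
    z = "matrix",
    zCrit = "numeric",
    nPoints = "integer",
    fwer = "numeric"
  )
)

setValidity("OutlierReport", function(object) {
  msgs <- character()
  fl <- object@flagged
  if (!all(c("protein", "fraction", "autocor", "z") %in% names(fl)))
    msgs <- c(msgs, "flagged needs columns protein, fraction, autocor, z")
  if (nrow(fl) && any(fl$z >= object@zCrit))
    msgs <- c(msgs, "every flagged point must have z < zCrit")
  if (length(msgs)) msgs else TRUE
})

#' InteractionNetwork: thresholded protein-protein interaction network
#'
#' Undirected simple graph of proteins, with each edge carrying the classifier
#' posterior at which it entered, its gold-standard label (if any) and the
#' condition the network belongs to.
#'
#' @slot edges data.frame with columns \code{proteinA}, \code{proteinB},
#'   \code{score}, \code{label} (\code{"positive"}, \code{"negative"} or
#'   \code{NA} for unlabeled). Edges unordered with \code{proteinA < proteinB}.
#' @slot condition character scalar.
#' @slot precision numeric, cumulative labeled-pair precision at the cutoff
#'   (NA for networks not built by thresholding).
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
  representation(
    edges = "data.frame",
    condition = "character",
    precision = "numeric"
  )
)

setValidity("InteractionNetwork", function(object) {
  ed <- object@edges
  msgs <- character()
  if (!all(c("proteinA", "proteinB", "score", "label") %in% names(ed)))
    msgs <- c(msgs, "edges needs columns proteinA, proteinB, score, label")
  if (nrow(ed)) {
    if (any(ed$proteinA == ed$proteinB))
      msgs <- c(msgs, "self-interactions are not allowed")
    key <- paste(pmin(ed$proteinA, ed$proteinB), pmax(ed$proteinA, ed$proteinB))
    if (anyDuplicated(key)) msgs <- c(msgs, "duplicate edges are not allowed")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an InteractionNetwork from an edge table
#'
#' @param edges data.frame with at least \code{proteinA} and \code{proteinB};
#'   \code{score}/\code{label} columns are carried through (NA when absent).
#' @param condition character scalar condition label.
#' @param precision labeled-pair precision at the cutoff, if known.
#' @return An [InteractionNetwork-class].
#' @export
InteractionNetwork <- function(edges, condition = NA_character_,
                               precision = NA_real_) {
  edges <- as.data.frame(edges)
  if (!nrow(edges)) {
    edges <- data.frame(proteinA = character(), proteinB = character(),
                        score = numeric(), label = character())
  } else {
    a <- pmin(as.character(edges$proteinA), as.character(edges$proteinB))
    b <- pmax(as.character(edges$proteinA), as.character(edges$proteinB))
    edges$proteinA <- a
    edges$proteinB <- b
    if (is.null(edges$score)) edges$score <- NA_real_
    if (is.null(edges$label)) edges$label <- NA_character_
    edges <- edges[, c("proteinA", "proteinB", "score", "label")]
    rownames(edges) <- NULL
  }
  new("InteractionNetwork", edges = edges,
      condition = as.character(condition), precision = precision)
}
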