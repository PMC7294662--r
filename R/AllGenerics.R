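#' Accessors for CoFracNet classes
#'
#' @param object a CoFracNet S4 object.
#' @name accessors
NULL

#' @describeIn accessors intensity matrix of a [ChromatogramMatrix-class].
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @describeIn accessors protein identifiers.
#' @export
setGeneric("proteins", function(object) standardGeneric("proteins"))

#' @describeIn accessors number of fractions.
#' @export
setGeneric("nFractions", function(object) standardGeneric("nFractions"))

#' @describeIn accessors replicate identifier.
#' @export
setGeneric("replicateId", function(object) standardGeneric("replicateId"))

#' @describeIn accessors isotope channel.
#' @export
setGeneric("channel", function(object) standardGeneric("channel"))

#' @describeIn accessors condition label.
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))

#' @describeIn accessors edge table of an [InteractionNetwork-class] or the
#'   flagged-point table of an [OutlierReport-class].
#' @export
setGeneric("edges", function(object) standardGeneric("edges"))

#' @describeIn accessors flagged points of an [OutlierReport-class].
#' @export
setGeneric("flaggedPoints", function(object) standardGeneric("flaggedPoints"))

#' @describeIn accessors fitted components of a [GaussianMixtureFit-class].
#' @export
setGeneric("components", function(object) standardGeneric("components"))

setMethod("intensities", "ChromatogramMatrix", function(object) object@intensities)
setMethod("proteins", "ChromatogramMatrix", function(object) rownames(object@intensities))
setMethod("nFractions", "ChromatogramMatrix", function(object) ncol(object@intensities))
setMethod("replicateId", "ChromatogramMatrix", function(object) object@replicate)
setMethod("channel", "ChromatogramMatrix", function(object) object@channel)
setMethod("condition", "ChromatogramMatrix", function(object) object@condition)

setMethod("proteins", "InteractionNetwork", function(object)
  sort(unique(c(object@edges$proteinA, object@edges$proteinB))))
setMethod("edges", "InteractionNetwork", function(object) object@edges)
setMethod("condition", "InteractionNetwork", function(object) object@condition)

setMethod("flaggedPoints", "OutlierReport", function(object) object@flagged)
setMethod("components", "GaussianMixtureFit", function(object) object@components)

#' Number of edges in a network
#' @param network an [InteractionNetwork-class].
#' @return integer edge count.
#' @export
edgeCount <- function(network) nrow(network@edges)

#' Precision recorded at the network cutoff
#' @param network an [InteractionNetwork-class].
#' @return numeric labeled-pair precision at inclusion (NA when unknown).
#' @export
networkPrecision <- function(network) network@precision

#' Convert an InteractionNetwork to an igraph graph
#'
#' @param network an [InteractionNetwork-class].
#' @return an undirected simple \pkg{igraph} graph with edge attributes
#'   \code{score} and \code{label}.
#' @export
asIgraph <- function(network) {
  ed <- network@edges
  if (!nrow(ed)) return(igraph::make_empty_graph(directed = FALSE))
  igraph::graph_from_data_frame(ed, directed = FALSE)
}

setMethod("show", "ChromatogramMatrix", function(object) {
  m <- object@intensities
  cat(sprintf(
    "ChromatogramMatrix: %d proteins x %d fractions (%s / %s / %s)\n",
    nrow(m), ncol(m), object@replicate, object@channel, object@condition))
  cat(sprintf("  observed points: %d (%.1f%% missing)\n",
              sum(!is.na(m)), 100 * mean(is.na(m))))
})

setMethod("show", "ComplexTruth", function(object) {
  cat(sprintf(
    "ComplexTruth: %d complexes over %d proteins (%d singletons)\n",
    length(object@complexes), length(object@proteins),
    length(object@proteins) - length(unlist(object@complexes))))
  cat(sprintf("  rewired fraction: %.3f\n", object@rewiredFraction))
})

setMethod("show", "GaussianMixtureFit", function(object) {
  cat(sprintf("GaussianMixtureFit: %d component(s), AICc = %.3f, n = %d\n",
              nrow(object@components), object@aicc, object@nObs))
})

setMethod("show", "OutlierReport", function(object) {
  cat(sprintf(
    "OutlierReport: %d of %d observed points flagged (FWER %.3g, z_crit %.3f)\n",
    nrow(object@flagged), object@nPoints, object@fwer, object@zCrit))
})

setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork (%s): %d edges over %d proteins\n",
              object@condition, nrow(object@edges),
              length(proteins(object))))
  if (!is.na(object@precision))
    cat(sprintf("  labeled-pair precision at cutoff: %.3f\n", object@precision))
})
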