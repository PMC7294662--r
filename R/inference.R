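pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Co-fractionation features for every protein pair of one matrix
#'
#' For each unordered protein pair computes, over the pairwise-complete
#' fractions (at least \code{minOverlap}, else the feature is missing):
#' the Pearson correlation of the raw chromatograms (\code{rRaw}) and its
#' two-tailed p-value (\code{pRaw}, via the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}}), the Euclidean distance between the raw
#' chromatograms (\code{dRaw}), the Pearson correlation of the smoothed
#' chromatograms (\code{rSmooth}), the number of fractions separating the raw
#' profile maxima (\code{dPeak}; ties resolve to the lowest fraction), and the
#' smallest Euclidean distance between any pair of fitted Gaussian components
#' in \eqn{(\mu, A)} coordinates (\code{dGauss}; missing when either protein
#' has no retained fit).
#'
#' @param raw a [ChromatogramMatrix-class] (after outlier removal).
#' @param smoothed the matching smoothed [ChromatogramMatrix-class].
#' @param fits named list of [GaussianMixtureFit-class] from
#'   [fitChromatograms()].
#' @param minOverlap minimum pairwise-complete fractions (default 3).
#' @return data.frame with columns proteinA, proteinB, rRaw, pRaw, dRaw,
#'   rSmooth, dPeak, dGauss; one row per unordered pair.
#' @export
computePairFeatures <- function(raw, smoothed, fits, minOverlap = 3L) {
  m <- intensities(raw)
  ms <- intensities(smoothed)
  stopifnot(identical(rownames(m), rownames(ms)))
  P <- nrow(m)
  ids <- rownames(m)
  O <- (!is.na(m)) * 1
  nmat <- O %*% t(O)
  rRaw <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
  rRaw[nmat < minOverlap] <- NA
  tt <- rRaw * sqrt(pmax(nmat - 2, 0) / pmax(1 - rRaw^2, 1e-300))
  pRaw <- 2 * stats::pt(-abs(tt), df = pmax(nmat - 2, 1))
  pRaw[is.na(rRaw)] <- NA
  X0 <- m
  X0[is.na(m)] <- 0
  sq <- (X0^2) %*% t(O)
  d2 <- sq + t(sq) - 2 * X0 %*% t(X0)
  dRaw <- sqrt(pmax(d2, 0))
  dRaw[nmat < minOverlap] <- NA
  Os <- (!is.na(ms)) * 1
  nS <- Os %*% t(Os)
  rSmooth <- suppressWarnings(stats::cor(t(ms), use = "pairwise.complete.obs"))
  rSmooth[nS < minOverlap] <- NA
  peak <- apply(m, 1L, function(x) {
    w <- which.max(x)
    if (length(w)) w else NA_integer_
  })
  dPeak <- abs(outer(peak, peak, "-"))
  comps <- lapply(ids, function(p) {
    f <- fits[[p]]
    if (is.null(f)) NULL else as.matrix(f@components[, c("mu", "A")])
  })
  ut <- which(upper.tri(nmat), arr.ind = TRUE)
  dGauss <- rep(NA_real_, nrow(ut))
  for (k in seq_len(nrow(ut))) {
    ci <- comps[[ut[k, 1L]]]
    cj <- comps[[ut[k, 2L]]]
    if (is.null(ci) || is.null(cj)) next
    dd <- outer(ci[, 1L], cj[, 1L], "-")^2 + outer(ci[, 2L], cj[, 2L], "-")^2
    dGauss[k] <- sqrt(min(dd))
  }
  data.frame(
    proteinA = ids[ut[, 1L]], proteinB = ids[ut[, 2L]],
    rRaw = rRaw[ut], pRaw = pRaw[ut], dRaw = dRaw[ut],
    rSmooth = rSmooth[ut], dPeak = dPeak[ut], dGauss = dGauss
  )
}

#' Concatenate per-replicate features for one isotope channel
#'
#' Joins per-replicate feature tables on the unordered pair, suffixing
#' feature columns with the replicate id. With three replicates and six
#' features this yields the eighteen-feature representation a channel's
#' classifier consumes. Pairs absent from a replicate carry missing features
#' there.
#'
#' @param featureList named list of per-replicate feature data.frames from
#'   [computePairFeatures()]; names are replicate ids.
#' @return merged data.frame with proteinA, proteinB and suffixed features.
#' @export
assemblePairFeatures <- function(featureList) {
  stopifnot(length(featureList) >= 1L, !is.null(names(featureList)))
  out <- NULL
  for (rid in names(featureList)) {
    df <- featureList[[rid]]
    fcols <- setdiff(names(df), c("proteinA", "proteinB"))
    names(df)[match(fcols, names(df))] <- paste0(fcols, "_", rid)
    out <- if (is.null(out)) df else
      merge(out, df, by = c("proteinA", "proteinB"), all = TRUE)
  }
  out[order(out$proteinA, out$proteinB), , drop = FALSE]
}

#' Build a co-complex gold standard from complex definitions
#'
#' Pairs of proteins sharing at least one complex are positives; pairs of
#' gold-standard proteins that never share a complex are negatives. Complexes
#' are restricted to members present in the profiled universe first; a
#' complex with fewer than two present members contributes nothing.
#'
#' @param complexes named list of member id vectors (e.g. from
#'   [readComplexes()] or the \code{complexes} slot of a
#'   [ComplexTruth-class]).
#' @param universe character vector of profiled protein ids.
#' @return list of class \code{"GoldStandard"} with data.frames
#'   \code{positives} and \code{negatives} (columns proteinA, proteinB).
#' @examples
#' gs <- buildGoldStandard(list(c1 = c("A", "B", "C"), c2 = c("D", "E")),
#'                         universe = LETTERS[1:5])
#' gs$positives
#' @export
buildGoldStandard <- function(complexes, universe) {
  complexes <- lapply(complexes, function(m) intersect(m, universe))
  complexes <- complexes[lengths(complexes) >= 2L]
  posKeys <- unique(unlist(lapply(complexes, function(m) {
    cmb <- utils::combn(sort(m), 2L)
    pairKey(cmb[1L, ], cmb[2L, ])
  })))
  if (is.null(posKeys)) posKeys <- character()
  goldProteins <- sort(unique(unlist(complexes)))
  allKeys <- if (length(goldProteins) >= 2L) {
    cmb <- utils::combn(goldProteins, 2L)
    pairKey(cmb[1L, ], cmb[2L, ])
  } else character()
  negKeys <- setdiff(allKeys, posKeys)
  toDf <- function(keys) {
    if (!length(keys))
      return(data.frame(proteinA = character(), proteinB = character()))
    parts <- strsplit(keys, "|", fixed = TRUE)
    data.frame(proteinA = vapply(parts, `[[`, character(1L), 1L),
               proteinB = vapply(parts, `[[`, character(1L), 2L))
  }
  structure(list(positives = toDf(posKeys), negatives = toDf(negKeys)),
            class = "GoldStandard")
}

goldLabels <- function(pairsA, pairsB, gold) {
  keys <- pairKey(pairsA, pairsB)
  lab <- rep(NA_character_, length(keys))
  lab[keys %in% pairKey(gold$positives$proteinA, gold$positives$proteinB)] <-
    "positive"
  lab[keys %in% pairKey(gold$negatives$proteinA, gold$negatives$proteinB)] <-
    "negative"
  lab
}

## Gaussian class-conditional naive Bayes; missing features drop out of the
## likelihood product. Variances floored so class-constant features do not
## degenerate.
trainNaiveBayes <- function(X, y, varFloor = 1e-12) {
  classes <- c("negative", "positive")
  if (!all(classes %in% y)) stop("untrainable fold: a class has no examples")
  stats <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xc, na.rm = TRUE)
    vv <- apply(Xc, 2L, stats::var, na.rm = TRUE)
    vv[!is.finite(vv)] <- NA
    vv <- pmax(vv, varFloor)
    list(mu = mu, var = vv, prior = mean(y == cl))
  })
  names(stats) <- classes
  stats
}

predictNaiveBayes <- function(model, X) {
  usable <- is.finite(model$positive$mu) & is.finite(model$negative$mu) &
    is.finite(model$positive$var) & is.finite(model$negative$var)
  logp <- lapply(c(negative = "negative", positive = "positive"),
                 function(cl) {
    st <- model[[cl]]
    ll <- rep(log(st$prior), nrow(X))
    for (j in which(usable)) {
      x <- X[, j]
      obs <- !is.na(x)
      ll[obs] <- ll[obs] +
        stats::dnorm(x[obs], st$mu[j], sqrt(st$var[j]), log = TRUE)
    }
    ll
  })
  1 / (1 + exp(logp$negative - logp$positive))
}

#' Score candidate pairs with a cross-validated naive Bayes classifier
#'
#' Gold-labeled pairs are split into \code{nFolds} folds, stratified by
#' label. Each fold's classifier (Gaussian class-conditional densities per
#' feature, class priors from its training labels, missing features omitted
#' from the likelihood product) is trained on the remaining folds and scores
#' every pair; a pair's final interaction score is the median of the fold
#' scores. Pairs with no observed feature are unscored and dropped (their
#' count is kept in attribute \code{"nUnscored"}).
#'
#' @param features feature data.frame from [assemblePairFeatures()] (or
#'   [computePairFeatures()] for a single replicate).
#' @param gold a \code{"GoldStandard"} from [buildGoldStandard()].
#' @param nFolds number of cross-validation folds (default 10).
#' @param seed integer seed for the fold split.
#' @return data.frame sorted by decreasing score with columns proteinA,
#'   proteinB, score, label (positive/negative/NA) and precision (cumulative
#'   labeled-pair precision at each rank).
#' @export
scorePairs <- function(features, gold, nFolds = 10L, seed = 1L) {
  fcols <- setdiff(names(features), c("proteinA", "proteinB"))
  X <- as.matrix(features[, fcols, drop = FALSE])
  label <- goldLabels(features$proteinA, features$proteinB, gold)
  nPos <- sum(label == "positive", na.rm = TRUE)
  nNeg <- sum(label == "negative", na.rm = TRUE)
  if (nPos < nFolds || nNeg < nFolds)
    stop(sprintf("need >= %d labeled pairs per class (have %d positive, %d negative)",
                 nFolds, nPos, nNeg))
  set.seed(seed)
  fold <- rep(NA_integer_, nrow(X))
  for (cl in c("positive", "negative")) {
    idx <- which(!is.na(label) & label == cl)
    fold[idx] <- sample(rep(seq_len(nFolds), length.out = length(idx)))
  }
  scores <- matrix(NA_real_, nrow(X), nFolds)
  for (f in seq_len(nFolds)) {
    train <- which(!is.na(fold) & fold != f)
    model <- trainNaiveBayes(X[train, , drop = FALSE], label[train])
    scores[, f] <- predictNaiveBayes(model, X)
  }
  score <- apply(scores, 1L, stats::median)
  scored <- data.frame(proteinA = features$proteinA,
                       proteinB = features$proteinB,
                       score = score, label = label)
  unscored <- rowSums(!is.na(X)) == 0L
  scored <- scored[!unscored, , drop = FALSE]
  ord <- order(-scored$score, scored$proteinA, scored$proteinB)
  scored <- scored[ord, , drop = FALSE]
  labeled <- !is.na(scored$label)
  cumLab <- cumsum(labeled)
  cumPos <- cumsum(labeled & scored$label == "positive")
  scored$precision <- ifelse(cumLab > 0, cumPos / cumLab, NA_real_)
  rownames(scored) <- NULL
  attr(scored, "nUnscored") <- sum(unscored)
  scored
}

#' Cut a ranked pair list into a network at a target precision
#'
#' Cumulative precision at rank k is the proportion of gold positives among
#' the gold-labeled pairs in the top k. The network keeps every pair (labeled
#' or not) in the largest prefix whose cumulative precision is at least the
#' target; equal-score blocks enter or leave together. When even the
#' best-scoring block falls short the result is an empty network, with a
#' warning.
#'
#' @param scored ranked data.frame from [scorePairs()].
#' @param targetPrecision target labeled-pair precision (default 0.70).
#' @param condition condition label stored on the network.
#' @return An [InteractionNetwork-class].
#' @examples
#' scored <- data.frame(proteinA = c("A", "B", "C", "D"),
#'                      proteinB = c("X", "Y", "Z", "W"),
#'                      score = c(0.9, 0.8, 0.7, 0.6),
#'                      label = c("positive", "positive", "negative",
#'                                "positive"))
#' edgeCount(precisionThreshold(scored, 0.70))
#' @export
precisionThreshold <- function(scored, targetPrecision = 0.70,
                               condition = NA_character_) {
  stopifnot(nrow(scored) >= 1L, any(!is.na(scored$label)))
  if (is.unsorted(rev(scored$score)))
    scored <- scored[order(-scored$score), , drop = FALSE]
  labeled <- !is.na(scored$label)
  cumLab <- cumsum(labeled)
  cumPos <- cumsum(labeled & scored$label == "positive")
  prec <- ifelse(cumLab > 0, cumPos / cumLab, NA_real_)
  ## equal-score blocks are atomic: evaluate precision at block ends only
  blockEnd <- c(scored$score[-1L] != scored$score[-nrow(scored)], TRUE)
  ok <- which(blockEnd & !is.na(prec) & prec >= targetPrecision)
  if (!length(ok)) {
    warning("target precision unreachable; returning an empty network")
    return(InteractionNetwork(scored[0, ], condition = condition,
                              precision = NA_real_))
  }
  cut <- max(ok)
  InteractionNetwork(scored[seq_len(cut), c("proteinA", "proteinB", "score",
                                            "label")],
                     condition = condition, precision = prec[cut])
}

#' Compare two condition-specific networks
#'
#' Set algebra on unordered edges and node sets.
#'
#' @param netA,netB [InteractionNetwork-class] objects.
#' @return list with edge data.frames \code{shared}, \code{aOnly},
#'   \code{bOnly}, node vectors \code{sharedNodes}, \code{aOnlyNodes},
#'   \code{bOnlyNodes}, and \code{proportions} (shared/aOnly/bOnly over the
#'   union of edges).
#' @export
compareNetworks <- function(netA, netB) {
  ea <- edges(netA)
  eb <- edges(netB)
  ka <- pairKey(ea$proteinA, ea$proteinB)
  kb <- pairKey(eb$proteinA, eb$proteinB)
  shared <- ea[ka %in% kb, , drop = FALSE]
  aOnly <- ea[!ka %in% kb, , drop = FALSE]
  bOnly <- eb[!kb %in% ka, , drop = FALSE]
  na <- proteins(netA)
  nb <- proteins(netB)
  tot <- length(union(ka, kb))
  list(shared = shared, aOnly = aOnly, bOnly = bOnly,
       sharedNodes = intersect(na, nb),
       aOnlyNodes = setdiff(na, nb), bOnlyNodes = setdiff(nb, na),
       proportions = c(shared = nrow(shared) / max(tot, 1L),
                       aOnly = nrow(aOnly) / max(tot, 1L),
                       bOnly = nrow(bOnly) / max(tot, 1L)))
}

#' Write a network as a TSV edge list
#'
#' Columns: proteinA, proteinB, score, label, condition.
#' @param network an [InteractionNetwork-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(network, path) {
  ed <- edges(network)
  ed$condition <- condition(network)
  utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML
#' @param network an [InteractionNetwork-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeNetworkGraphML <- function(network, path) {
  g <- asIgraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
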