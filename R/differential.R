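#' Degree-preserving rewiring of a network
#'
#' Randomizes a simple undirected graph by attempted double-edge swaps
#' (replace edges (a,b),(c,d) with (a,d),(c,b) unless a self-loop or
#' multi-edge would result), keeping every node's degree fixed. The number of
#' attempted swaps is \code{round(nIterFactor * |E|)}, the null model used by
#' all permutation tests in this package. Graphs whose degree sequence has a
#' unique realization come back unchanged.
#'
#' @param network an [InteractionNetwork-class].
#' @param nIterFactor attempted swaps per edge (default 6.9).
#' @param seed integer seed.
#' @return A rewired [InteractionNetwork-class] (edge scores and labels are
#'   not meaningful on the null network and are dropped).
#' @export
rewireDegreePreserving <- function(network, nIterFactor = 6.9, seed = 1L) {
  ne <- edgeCount(network)
  if (ne < 2L) return(network)
  g <- asIgraph(network)
  set.seed(seed)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(
    loops = FALSE, niter = max(1L, round(nIterFactor * ne))))
  el <- igraph::as_edgelist(g2)
  InteractionNetwork(data.frame(proteinA = el[, 1L], proteinB = el[, 2L]),
                     condition = condition(network))
}

## edges-within-set counts for every term at once; el is a 2-column index
## matrix into the rows of the logical membership matrix memb (nodes x terms)
countSetEdges <- function(el, memb) {
  if (!nrow(el)) return(integer(ncol(memb)))
  colSums(memb[el[, 1L], , drop = FALSE] & memb[el[, 2L], , drop = FALSE])
}

networkEdgeIndex <- function(network, nodes) {
  ed <- edges(network)
  cbind(match(ed$proteinA, nodes), match(ed$proteinB, nodes))
}

membershipMatrix <- function(sets, nodes) {
  memb <- matrix(FALSE, length(nodes), length(sets),
                 dimnames = list(nodes, names(sets)))
  for (tt in names(sets)) memb[nodes %in% sets[[tt]], tt] <- TRUE
  memb
}

rewiredEdgeIndex <- function(g, nIterFactor, nodes) {
  g2 <- igraph::rewire(g, igraph::keeping_degseq(
    loops = FALSE, niter = max(1L, round(nIterFactor * igraph::ecount(g)))))
  el <- igraph::as_edgelist(g2)
  cbind(match(el[, 1L], nodes), match(el[, 2L], nodes))
}

#' Gene-set interaction rewiring test (delta n_PPI)
#'
#' For each gene set, counts the interactions among its members in the
#' stimulated and unstimulated networks and their difference
#' \eqn{\Delta n_{PPI} = n_{PPI}^{stim} - n_{PPI}^{unstim}}. Both networks
#' are then rewired degree-preservingly \code{nPerm} times; each permutation
#' rewires both networks and the paired difference is recomputed, giving a
#' null distribution per term. The z-score of the observed difference against
#' the null is converted to a two-tailed normal p-value and
#' Benjamini-Hochberg adjusted across terms. Terms whose null has zero
#' spread get p = 1; terms with fewer than two annotated proteins present in
#' the networks are skipped (returned in attribute \code{"skipped"}).
#'
#' @param netStim,netUnstim [InteractionNetwork-class] objects on a shared id
#'   space.
#' @param sets named list of protein id vectors (gene sets).
#' @param nPerm number of paired rewiring permutations (default 1000).
#' @param nIterFactor attempted swaps per edge for each rewiring.
#' @param seed integer seed.
#' @return data.frame with one row per tested term: term, nPPIStim,
#'   nPPIUnstim, delta, nullMean, nullSd, z, p, q.
#' @export
deltaNppiTest <- function(netStim, netUnstim, sets, nPerm = 1000L,
                          nIterFactor = 6.9, seed = 1L) {
  nodes <- sort(union(proteins(netStim), proteins(netUnstim)))
  present <- lapply(sets, intersect, nodes)
  keep <- lengths(present) >= 2L
  skipped <- names(sets)[!keep]
  sets <- sets[keep]
  if (!length(sets))
    return(structure(data.frame(), skipped = skipped))
  memb <- membershipMatrix(sets, nodes)
  elS <- networkEdgeIndex(netStim, nodes)
  elU <- networkEdgeIndex(netUnstim, nodes)
  nS <- countSetEdges(elS, memb)
  nU <- countSetEdges(elU, memb)
  dObs <- nS - nU
  gS <- asIgraph(netStim)
  gU <- asIgraph(netUnstim)
  set.seed(seed)
  dPerm <- matrix(0L, nPerm, length(sets))
  for (b in seq_len(nPerm)) {
    dPerm[b, ] <- countSetEdges(rewiredEdgeIndex(gS, nIterFactor, nodes), memb) -
      countSetEdges(rewiredEdgeIndex(gU, nIterFactor, nodes), memb)
  }
  nullMean <- colMeans(dPerm)
  nullSd <- apply(dPerm, 2L, stats::sd)
  z <- ifelse(nullSd > 0, (dObs - nullMean) / nullSd, NA_real_)
  p <- ifelse(is.na(z), 1, 2 * stats::pnorm(-abs(z)))
  res <- data.frame(term = names(sets), nPPIStim = nS, nPPIUnstim = nU,
                    delta = dObs, nullMean = nullMean, nullSd = nullSd,
                    z = z, p = p, q = stats::p.adjust(p, method = "BH"),
                    row.names = NULL)
  structure(res[order(res$p), ], skipped = skipped)
}

#' Shared-annotation enrichment of interacting pairs
#'
#' Observed statistic: the proportion of network edges whose endpoints share
#' at least one gene-set annotation. The null distribution comes from
#' degree-preserving rewirings of the network; the empirical p-value is
#' \eqn{(1 + \#\{null \ge observed\}) / (1 + nPerm)}.
#'
#' @param network an [InteractionNetwork-class].
#' @param sets named list of protein id vectors.
#' @param nPerm number of rewiring permutations (default 1000).
#' @param nIterFactor attempted swaps per edge.
#' @param seed integer seed.
#' @return list with \code{observed}, \code{null} (numeric vector) and
#'   \code{p}.
#' @export
pairAnnotationSharingEnrichment <- function(network, sets, nPerm = 1000L,
                                            nIterFactor = 6.9, seed = 1L) {
  nodes <- proteins(network)
  memb <- membershipMatrix(sets, nodes)
  shareFrac <- function(el) {
    if (!nrow(el)) return(0)
    mean(rowSums(memb[el[, 1L], , drop = FALSE] &
                 memb[el[, 2L], , drop = FALSE]) > 0)
  }
  observed <- shareFrac(networkEdgeIndex(network, nodes))
  g <- asIgraph(network)
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(b)
    shareFrac(rewiredEdgeIndex(g, nIterFactor, nodes)), numeric(1L))
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + nPerm))
}

#' Stouffer combination of z-scores
#' @param z numeric vector of z-scores (NA allowed).
#' @return combined z \eqn{\sum z_i / \sqrt{k}} over the k non-missing values.
#' @export
stoufferZ <- function(z) {
  z <- z[!is.na(z)]
  if (!length(z)) return(NA_real_)
  sum(z) / sqrt(length(z))
}

#' Cross-condition chromatogram autocorrelation per protein
#'
#' For each protein and replicate, the Pearson correlation between its
#' stimulated and unstimulated chromatograms over jointly observed fractions
#' (at least \code{minPairObs}, else that replicate contributes nothing).
#' Within each replicate the correlations are normalized to z-scores by a
#' rank-based inverse-normal transform across proteins, and the per-replicate
#' z-scores are aggregated with Stouffer's method. Low combined z marks
#' proteins whose elution behavior rewires upon stimulation.
#'
#' @param stimList,unstimList named lists of [ChromatogramMatrix-class], one
#'   per replicate (matching names).
#' @param minPairObs minimum jointly observed fractions (default 5).
#' @return data.frame with protein, one r and z column per replicate, the
#'   number of contributing replicates, and \code{combinedZ}; proteins absent
#'   from every replicate of either condition are omitted.
#' @export
proteinAutocorrelation <- function(stimList, unstimList, minPairObs = 5L) {
  reps <- intersect(names(stimList), names(unstimList))
  stopifnot(length(reps) >= 1L)
  allProt <- sort(unique(unlist(c(
    lapply(stimList[reps], proteins), lapply(unstimList[reps], proteins)))))
  rMat <- matrix(NA_real_, length(allProt), length(reps),
                 dimnames = list(allProt, reps))
  for (rep in reps) {
    ms <- intensities(stimList[[rep]])
    mu <- intensities(unstimList[[rep]])
    common <- intersect(rownames(ms), rownames(mu))
    for (p in common)
      rMat[p, rep] <- pairwisePearson(ms[p, ], mu[p, ],
                                      minOverlap = minPairObs)
  }
  zMat <- rMat
  for (j in seq_len(ncol(zMat))) {
    r <- rMat[, j]
    obs <- !is.na(r)
    z <- rep(NA_real_, length(r))
    if (sum(obs) >= 2L)
      z[obs] <- stats::qnorm((rank(r[obs]) - 0.5) / sum(obs))
    zMat[, j] <- z
  }
  combined <- apply(zMat, 1L, stoufferZ)
  keep <- rowSums(!is.na(rMat)) >= 1L
  out <- data.frame(protein = allProt,
                    rMat, zMat,
                    nReplicates = rowSums(!is.na(zMat)),
                    combinedZ = combined, row.names = NULL,
                    check.names = FALSE)
  names(out)[1L + seq_along(reps)] <- paste0("r_", reps)
  names(out)[1L + length(reps) + seq_along(reps)] <- paste0("z_", reps)
  out[keep, , drop = FALSE]
}

#' Brunner-Munzel test of stochastic dominance
#'
#' Nonparametric two-sample test of \eqn{H_0: P(X < Y) + 0.5 P(X = Y) = 0.5},
#' robust to unequal variances and ties (midranks), with Satterthwaite
#' degrees of freedom and a t reference distribution.
#'
#' @param x,y numeric samples.
#' @return list with \code{statistic}, \code{df}, \code{pValue} (two-sided)
#'   and \code{estimate} (the relative effect \eqn{\hat p = P(X<Y)+0.5P(X=Y)}).
#' @examples
#' brunnerMunzelTest(rnorm(20), rnorm(20, 1))
#' @export
brunnerMunzelTest <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 >= 2L, n2 >= 2L)
  r <- rank(c(x, y))
  r1 <- r[seq_len(n1)]
  r2 <- r[n1 + seq_len(n2)]
  m1 <- mean(r1)
  m2 <- mean(r2)
  v1 <- sum((r1 - rank(x) - m1 + (n1 + 1) / 2)^2) / (n1 - 1)
  v2 <- sum((r2 - rank(y) - m2 + (n2 + 1) / 2)^2) / (n2 - 1)
  est <- (m2 - (n2 + 1) / 2) / n1
  denom <- sqrt(n1 * v1 + n2 * v2)
  if (denom == 0) {
    stat <- if (m1 == m2) 0 else sign(m2 - m1) * Inf
    df <- Inf
  } else {
    stat <- n1 * n2 * (m2 - m1) / ((n1 + n2) * denom)
    df <- (n1 * v1 + n2 * v2)^2 /
      ((n1 * v1)^2 / (n1 - 1) + (n2 * v2)^2 / (n2 - 1))
  }
  p <- if (is.infinite(stat)) 0 else 2 * stats::pt(-abs(stat), df)
  list(statistic = stat, df = df, pValue = min(p, 1), estimate = est)
}

withinSetCorrelations <- function(matrix, members, minPairObs = 5L) {
  m <- intensities(matrix)
  members <- intersect(members, rownames(m))
  if (length(members) < 2L) return(numeric())
  cmb <- utils::combn(members, 2L)
  r <- vapply(seq_len(ncol(cmb)), function(k)
    pairwisePearson(m[cmb[1L, k], ], m[cmb[2L, k], ],
                    minOverlap = minPairObs), numeric(1L))
  r[!is.na(r)]
}

#' Gene-set correlation shift between conditions
#'
#' Computes the Pearson correlation of every within-set protein pair in each
#' condition (correlations based on fewer than \code{minPairObs} pairwise
#' observations are excluded) and compares the stimulated against the
#' unstimulated correlation distribution with a Brunner-Munzel test. A
#' positive median shift means the set's members co-elute more tightly after
#' stimulation.
#'
#' @param stim,unstim a [ChromatogramMatrix-class] each, or lists of them
#'   (replicates; pair correlations are pooled across replicates).
#' @param geneSet character vector of member protein ids (>= 2 present in
#'   both conditions).
#' @param minPairObs minimum pairwise observations per correlation
#'   (default 5).
#' @return list with \code{medianShift} (median stimulated minus median
#'   unstimulated correlation), \code{statistic}, \code{pValue},
#'   \code{nStim}, \code{nUnstim}; all NA with a \code{reason} when fewer
#'   than 3 valid correlations exist in either condition.
#' @export
correlationShiftTest <- function(stim, unstim, geneSet, minPairObs = 5L) {
  asList <- function(x) if (is(x, "ChromatogramMatrix")) list(x) else x
  rs <- unlist(lapply(asList(stim), withinSetCorrelations,
                      members = geneSet, minPairObs = minPairObs))
  ru <- unlist(lapply(asList(unstim), withinSetCorrelations,
                      members = geneSet, minPairObs = minPairObs))
  if (length(rs) < 3L || length(ru) < 3L)
    return(list(medianShift = NA_real_, statistic = NA_real_,
                pValue = NA_real_, nStim = length(rs), nUnstim = length(ru),
                reason = "fewer than 3 valid pair correlations in a condition"))
  bm <- brunnerMunzelTest(ru, rs)
  list(medianShift = stats::median(rs) - stats::median(ru),
       statistic = bm$statistic, pValue = bm$pValue,
       nStim = length(rs), nUnstim = length(ru), reason = NULL)
}

#' z-test of the log-odds ratio of a 2x2 table
#'
#' Haldane-Anscombe continuity correction (+0.5 to every cell) is applied
#' when any cell is zero.
#'
#' @param a,b,c,d counts of the 2x2 contingency table (a,b / c,d).
#' @return list with \code{logOdds}, \code{se}, \code{z} and two-sided
#'   \code{pValue}.
#' @examples
#' logOddsEnrichment(20, 5, 5, 20)
#' @export
logOddsEnrichment <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0))
  if (any(cells == 0)) cells <- cells + 0.5
  lo <- log(cells[1L] * cells[4L] / (cells[2L] * cells[3L]))
  se <- sqrt(sum(1 / cells))
  z <- lo / se
  list(logOdds = lo, se = se, z = z, pValue = 2 * stats::pnorm(-abs(z)))
}

#' Jaccard edges between gene sets (enrichment map)
#'
#' @param sets named list of protein id vectors.
#' @param jaccardMin inclusive minimum Jaccard index
#'   \eqn{|A \cap B| / |A \cup B|} for an edge (default 0.33).
#' @return data.frame with columns termA, termB, jaccard.
#' @export
enrichmentMapEdges <- function(sets, jaccardMin = 0.33) {
  stopifnot(length(sets) >= 1L, all(lengths(sets) > 0L))
  out <- data.frame(termA = character(), termB = character(),
                    jaccard = numeric())
  if (length(sets) < 2L) return(out)
  nm <- names(sets)
  cmb <- utils::combn(length(sets), 2L)
  jac <- vapply(seq_len(ncol(cmb)), function(k) {
    A <- sets[[cmb[1L, k]]]
    B <- sets[[cmb[2L, k]]]
    length(intersect(A, B)) / length(union(A, B))
  }, numeric(1L))
  keep <- jac >= jaccardMin
  data.frame(termA = nm[cmb[1L, keep]], termB = nm[cmb[2L, keep]],
             jaccard = jac[keep], row.names = NULL)
}

#' Annotate network edges with the maximum endpoint fold change
#'
#' @param network an [InteractionNetwork-class] (or a bare edge data.frame
#'   with proteinA/proteinB columns).
#' @param foldChanges named numeric vector of per-protein log2 fold changes
#'   (missing proteins allowed).
#' @return the edge data.frame with an added \code{maxAbsLog2FC} column: the
#'   maximum absolute log2 fold change over the endpoints (a missing endpoint
#'   is ignored; both missing gives NA).
#' @export
annotateEdgesWithAbundance <- function(network, foldChanges) {
  ed <- if (is(network, "InteractionNetwork")) edges(network) else
    as.data.frame(network)
  fa <- abs(foldChanges[ed$proteinA])
  fb <- abs(foldChanges[ed$proteinB])
  ed$maxAbsLog2FC <- pmax(fa, fb, na.rm = TRUE)
  ed$maxAbsLog2FC[is.na(fa) & is.na(fb)] <- NA_real_
  ed
}

#' Class-wise abundance summary of a network comparison
#'
#' @param comparison result of [compareNetworks()].
#' @param foldChanges named numeric vector of per-protein log2 fold changes.
#' @return data.frame with one row per edge class (shared, aOnly, bOnly):
#'   edge count, annotated count and median max |log2FC|.
#' @export
summarizeAbundanceByClass <- function(comparison, foldChanges) {
  do.call(rbind, lapply(c("shared", "aOnly", "bOnly"), function(cl) {
    ann <- annotateEdgesWithAbundance(comparison[[cl]], foldChanges)
    data.frame(class = cl, nEdges = nrow(ann),
               nAnnotated = sum(!is.na(ann$maxAbsLog2FC)),
               medianMaxAbsLog2FC = stats::median(ann$maxAbsLog2FC,
                                                  na.rm = TRUE))
  }))
}

#' Read gene sets from a GMT file
#' @param path GMT file path.
#' @return named list of member id vectors.
#' @export
readGeneSets <- function(path) fgsea::gmtPathways(path)

#' Write gene sets as GMT
#' @param sets named list of member id vectors.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGeneSets <- function(sets, path) {
  lines <- vapply(names(sets), function(tt)
    paste(c(tt, tt, sets[[tt]]), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Filter gene sets by size
#'
#' Very broad terms (more than \code{maxSize} annotated proteins) and
#' near-empty terms are removed before any differential-network statistic.
#'
#' @param sets named list of member id vectors.
#' @param minSize,maxSize inclusive size bounds (defaults 2 and 100).
#' @return filtered named list.
#' @export
filterGeneSets <- function(sets, minSize = 2L, maxSize = 100L) {
  sets <- lapply(sets, unique)
  sets[lengths(sets) >= minSize & lengths(sets) <= maxSize]
}

#' Build gene sets from an annotation table, GO-style
#'
#' Optional ingestion step producing a gene-set list from a per-protein
#' annotation table: annotations with evidence codes IPI, IEA, NAS or ND, or
#' the qualifier NOT, are removed, and annotations are propagated up the term
#' hierarchy through the supplied parent map before being grouped into sets.
#'
#' @param annotations data.frame with columns \code{protein}, \code{term} and
#'   optionally \code{evidence} and \code{qualifier}.
#' @param parents optional named list mapping a term to its direct parent
#'   terms; propagation is transitive.
#' @param excludeEvidence evidence codes to drop.
#' @param excludeQualifier qualifier values to drop.
#' @return named list of member id vectors (unfiltered; apply
#'   [filterGeneSets()] before testing).
#' @export
buildGeneSetsFromAnnotations <- function(annotations, parents = NULL,
                                         excludeEvidence = c("IPI", "IEA",
                                                             "NAS", "ND"),
                                         excludeQualifier = "NOT") {
  df <- as.data.frame(annotations)
  stopifnot(all(c("protein", "term") %in% names(df)))
  if ("evidence" %in% names(df))
    df <- df[!df$evidence %in% excludeEvidence, , drop = FALSE]
  if ("qualifier" %in% names(df))
    df <- df[!df$qualifier %in% excludeQualifier, , drop = FALSE]
  ancestors <- function(term) {
    seen <- character()
    frontier <- term
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(parents[frontier])), c(seen, term))
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  if (!is.null(parents) && nrow(df)) {
    extra <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      anc <- ancestors(df$term[i])
      if (!length(anc)) return(NULL)
      data.frame(protein = df$protein[i], term = anc)
    }))
    df <- rbind(df[, c("protein", "term")], extra)
  }
  lapply(split(df$protein, df$term), unique)
}
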