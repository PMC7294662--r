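randomNetwork <- function(nNodes, nEdges, ids = sprintf("P%03d", seq_len(nNodes))) {
  g <- igraph::sample_gnm(nNodes, nEdges)
  el <- igraph::as_edgelist(g)
  InteractionNetwork(data.frame(proteinA = ids[el[, 1L]],
                                proteinB = ids[el[, 2L]]))
}

degreeTable <- function(net) {
  sort(table(c(edges(net)$proteinA, edges(net)$proteinB)))
}

test_that("degree-preserving rewiring keeps degrees and edge counts", {
  set.seed(91)
  net <- randomNetwork(60, 150)
  for (s in 1:5) {
    rw <- rewireDegreePreserving(net, seed = s)
    expect_identical(edgeCount(rw), edgeCount(net))
    expect_identical(degreeTable(rw), degreeTable(net))
  }
  # graphs with a unique realization come back unchanged
  tri <- InteractionNetwork(data.frame(proteinA = c("A", "B", "C"),
                                       proteinB = c("B", "C", "A")))
  rwTri <- rewireDegreePreserving(tri, seed = 1)
  expect_setequal(pkey(edges(rwTri)$proteinA, edges(rwTri)$proteinB),
                  pkey(edges(tri)$proteinA, edges(tri)$proteinB))
  star <- InteractionNetwork(data.frame(proteinA = "HUB",
                                        proteinB = paste0("L", 1:4)))
  rwStar <- rewireDegreePreserving(star, seed = 1)
  expect_setequal(pkey(edges(rwStar)$proteinA, edges(rwStar)$proteinB),
                  pkey(edges(star)$proteinA, edges(star)$proteinB))
})

test_that("self-comparison yields no significant rewiring", {
  set.seed(92)
  ids <- sprintf("P%03d", 1:80)
  net <- randomNetwork(80, 200, ids)
  sets <- lapply(1:30, function(i) sample(ids, 10))
  names(sets) <- paste0("T", 1:30)
  res <- deltaNppiTest(net, net, sets, nPerm = 100, seed = 92)
  expect_true(all(res$delta == 0))
  expect_true(all(res$nPPIStim == res$nPPIUnstim))
  expect_false(any(res$q <= 0.2))
})

test_that("terms too small to test are skipped and reported", {
  net <- randomNetwork(20, 40)
  sets <- list(ok = proteins(net)[1:5], tiny = proteins(net)[1],
               absent = c("X1", "X2", "X3"))
  res <- deltaNppiTest(net, net, sets, nPerm = 50, seed = 1)
  expect_identical(res$term, "ok")
  expect_setequal(attr(res, "skipped"), c("tiny", "absent"))
  # all-singleton collections test nothing
  singles <- lapply(seq_along(proteins(net)), function(i) proteins(net)[i])
  names(singles) <- paste0("S", seq_along(singles))
  empty <- deltaNppiTest(net, net, singles, nPerm = 10, seed = 1)
  expect_identical(nrow(empty), 0L)
  expect_length(attr(empty, "skipped"), length(singles))
})

test_that("a planted fully-rewired module dominates the rewiring test", {
  set.seed(93)
  ids <- sprintf("P%03d", 1:120)
  term <- sample(ids, 10)
  bg <- randomNetwork(120, 250, ids)
  clique <- t(utils::combn(term, 2L))
  stimEdges <- rbind(edges(bg)[, c("proteinA", "proteinB")],
                     data.frame(proteinA = pmin(clique[, 1L], clique[, 2L]),
                                proteinB = pmax(clique[, 1L], clique[, 2L])))
  stimEdges <- stimEdges[!duplicated(pkey(stimEdges$proteinA,
                                          stimEdges$proteinB)), ]
  stim <- InteractionNetwork(stimEdges)
  sets <- lapply(1:20, function(i) sample(ids, 10))
  names(sets) <- paste0("T", 1:20)
  sets$planted <- term
  res <- deltaNppiTest(stim, bg, sets, nPerm = 200, seed = 93)
  expect_identical(res$term[which.max(abs(res$z))], "planted")
  expect_lt(res$q[res$term == "planted"], 0.2)
  expect_gt(res$delta[res$term == "planted"], 30)
})

test_that("permutation p-values respect their attainable bounds", {
  set.seed(94)
  ids <- sprintf("P%03d", 1:40)
  net <- randomNetwork(40, 90, ids)
  sets <- list(t1 = sample(ids, 8), t2 = sample(ids, 12))
  out <- pairAnnotationSharingEnrichment(net, sets, nPerm = 40, seed = 94)
  expect_gte(out$p, 1 / 41)
  expect_lte(out$p, 1)
})

test_that("annotation sharing enrichment handles degenerate annotations", {
  net <- InteractionNetwork(data.frame(proteinA = c("A", "B"),
                                       proteinB = c("B", "C")))
  universal <- list(all = c("A", "B", "C"))
  out <- pairAnnotationSharingEnrichment(net, universal, nPerm = 20, seed = 1)
  expect_equal(out$observed, 1)
  expect_true(all(out$null == 1))
  expect_equal(out$p, 1)
  none <- pairAnnotationSharingEnrichment(net, list(), nPerm = 20, seed = 1)
  expect_equal(none$observed, 0)
  expect_equal(none$p, 1)
})

test_that("module-aligned annotations are detected as enrichment", {
  set.seed(95)
  ids <- sprintf("P%03d", 1:60)
  modules <- split(ids, rep(1:6, each = 10))
  withinEdges <- do.call(rbind, lapply(modules, function(mod) {
    cmb <- utils::combn(mod, 2L)
    picks <- sample(ncol(cmb), 12)
    data.frame(proteinA = cmb[1L, picks], proteinB = cmb[2L, picks])
  }))
  net <- InteractionNetwork(withinEdges)
  sets <- setNames(modules, paste0("M", 1:6))
  out <- pairAnnotationSharingEnrichment(net, sets, nPerm = 1000, seed = 95)
  expect_equal(out$observed, 1)
  expect_lte(out$p, 0.01)
})

test_that("Stouffer combination matches its closed form", {
  expect_equal(stoufferZ(c(1, 1, 1)), sqrt(3))
  expect_equal(stoufferZ(c(2, NA, 2)), 4 / sqrt(2))
  expect_equal(stoufferZ(1.7), 1.7)
  expect_true(is.na(stoufferZ(NA_real_)))
})

test_that("cross-condition autocorrelation ranks preserved proteins highest", {
  set.seed(96)
  nF <- 30
  ids <- sprintf("P%02d", 1:20)
  mkMat <- function(m) ChromatogramMatrix(m, replicate = "r1")
  base <- t(sapply(seq_along(ids), function(i)
    exp(-((1:nF) - (5 + i))^2 / 4) + runif(nF, 0, 0.02)))
  rownames(base) <- ids
  shuffled <- base[, sample(nF)]
  colnames(shuffled) <- colnames(base)
  stim <- base
  stim[2:20, ] <- shuffled[2:20, ]  # protein 1 keeps its profile
  res <- proteinAutocorrelation(list(r1 = mkMat(stim)),
                                list(r1 = mkMat(base)))
  expect_identical(res$protein[which.max(res$combinedZ)], "P01")

  # per-replicate z of (1,1,1) combines to sqrt(3) by construction
  expect_equal(res$combinedZ, res$z_r1, tolerance = 1e-12)
})

test_that("replicate aggregation uses Stouffer over available replicates", {
  set.seed(97)
  nF <- 20
  m <- matrix(runif(5 * nF), 5, nF, dimnames = list(paste0("P", 1:5), NULL))
  mk <- function(mm, r) ChromatogramMatrix(mm, replicate = r)
  stim <- list(r1 = mk(m, "r1"), r2 = mk(m + runif(5 * nF, 0, 0.1), "r2"),
               r3 = mk(m, "r3"))
  unstim <- list(r1 = mk(m, "r1"), r2 = mk(m, "r2"), r3 = mk(m, "r3"))
  res <- proteinAutocorrelation(stim, unstim)
  zc <- rowSums(res[, c("z_r1", "z_r2", "z_r3")], na.rm = TRUE) /
    sqrt(res$nReplicates)
  expect_equal(res$combinedZ, unname(zc), tolerance = 1e-12)
})

test_that("members of a dissolved complex lose cross-condition correlation", {
  drops <- sapply(1:10, function(seed) {
    truth <- generateComplexTruth(40, 8, c(3L, 4L), 0.25, seed = seed)
    # fully observed profiles so every protein has a defined correlation
    sim <- simulateChromatograms(truth, simulationConfig(
      missingRate = 0.1, detectionLimit = 0, seed = seed))
    stim <- sim$matrices[grep("heavy", names(sim$matrices))]
    unstim <- sim$matrices[grep("medium", names(sim$matrices))]
    names(stim) <- names(unstim) <- paste0("r", 1:3)
    res <- proteinAutocorrelation(stim, unstim)
    rewired <- unlist(truth@complexes[rewiredComplexes(truth)])
    mean(res$combinedZ[res$protein %in% rewired], na.rm = TRUE) -
      mean(res$combinedZ[!res$protein %in% rewired], na.rm = TRUE)
  })
  expect_lt(mean(drops), 0)
  expect_gt(mean(drops < 0), 0.8)
})

test_that("the Brunner-Munzel test matches its reference implementation", {
  # frozen from scipy.stats.brunnermunzel on the same samples
  x <- c(1.1, 2.3, 3.2, 4.8, 5.5, 6.1, 2.2, 3.3)
  y <- c(2.0, 3.1, 4.5, 5.2, 6.8, 7.1, 8.3)
  bm <- brunnerMunzelTest(x, y)
  expect_equal(bm$statistic, 1.311632245303321, tolerance = 1e-12)
  expect_equal(bm$pValue, 0.22014815298550688, tolerance = 1e-12)

  ident <- brunnerMunzelTest(1:10, 1:10)
  expect_equal(ident$statistic, 0)
  expect_gte(ident$pValue, 0.99)

  shifted <- brunnerMunzelTest(rnorm(40), rnorm(40, 3))
  expect_lt(shifted$pValue, 1e-4)
  expect_gt(shifted$estimate, 0.9)
})

test_that("correlation shifts are detected only for truly rewired sets", {
  truth <- generateComplexTruth(40, 8, c(4L, 4L), 0.25, seed = 98)
  # broad observation so pair correlations are not restricted to peak overlaps
  sim <- simulateChromatograms(truth, simulationConfig(
    missingRate = 0.1, detectionLimit = 0, seed = 98))
  stim <- sim$matrices[grep("heavy", names(sim$matrices))]
  unstim <- sim$matrices[grep("medium", names(sim$matrices))]
  rewired <- unlist(truth@complexes[rewiredComplexes(truth)],
                    use.names = FALSE)
  stable <- unlist(truth@complexes[setdiff(names(truth@complexes),
                                           rewiredComplexes(truth))],
                   use.names = FALSE)
  # dissolved-complex members co-elute only without stimulation
  shift <- correlationShiftTest(stim, unstim, rewired)
  expect_lt(shift$pValue, 0.01)
  expect_lt(shift$medianShift, 0)
  stableShift <- correlationShiftTest(stim, unstim, stable)
  expect_gt(stableShift$pValue, 0.05)

  # identical conditions cannot shift
  null <- correlationShiftTest(unstim, unstim, stable)
  expect_equal(null$medianShift, 0)
  expect_gt(null$pValue, 0.99)

  tooFew <- correlationShiftTest(stim[[1L]], unstim[[1L]],
                                 truth@proteins[1:2])
  expect_true(is.na(tooFew$pValue))
  expect_match(tooFew$reason, "fewer than 3")
})

test_that("log-odds enrichment matches hand computation", {
  flat <- logOddsEnrichment(10, 10, 10, 10)
  expect_equal(flat$logOdds, 0)
  expect_equal(flat$z, 0)
  expect_equal(flat$pValue, 1)

  enr <- logOddsEnrichment(20, 5, 5, 20)
  expect_equal(enr$logOdds, log(16))
  expect_equal(enr$se, sqrt(1 / 20 + 1 / 5 + 1 / 5 + 1 / 20))
  expect_equal(enr$z, log(16) / sqrt(0.5))
  expect_equal(enr$pValue, 2 * pnorm(-abs(enr$z)))

  # Haldane-Anscombe correction engages on zero cells
  zero <- logOddsEnrichment(10, 0, 5, 20)
  expect_true(is.finite(zero$logOdds))
  expect_equal(zero$logOdds, log(10.5 * 20.5 / (0.5 * 5.5)))
})

test_that("enrichment-map edges honor the inclusive Jaccard boundary", {
  sets <- list(a = c("X", "Y"), b = c("X", "Z"), c = c("P", "Q"),
               d = c("X", "Y"))
  em <- enrichmentMapEdges(sets, jaccardMin = 0.33)
  keys <- paste(em$termA, em$termB)
  expect_true("a d" %in% keys)          # identical sets, Jaccard 1
  expect_true("a b" %in% keys)          # |A n B| = 1 of 3, 1/3 >= 0.33
  expect_false(any(grepl("c", keys)))   # disjoint sets never connect
  expect_equal(em$jaccard[em$termA == "a" & em$termB == "b"], 1 / 3)
})

test_that("edge abundance annotation takes the maximum absolute change", {
  fc <- c(A = 0.5, B = -2, C = NA, E = 1)
  net <- InteractionNetwork(data.frame(proteinA = c("A", "C", "C"),
                                       proteinB = c("B", "D", "E")))
  ann <- annotateEdgesWithAbundance(net, fc)
  expect_equal(ann$maxAbsLog2FC[1L], 2)
  expect_true(is.na(ann$maxAbsLog2FC[2L]))   # both endpoints unknown
  expect_equal(ann$maxAbsLog2FC[3L], 1)      # missing endpoint ignored

  cmp <- list(shared = edges(net)[1, ], aOnly = edges(net)[2, ],
              bOnly = edges(net)[3, ])
  sm <- summarizeAbundanceByClass(cmp, fc)
  expect_equal(sm$medianMaxAbsLog2FC[sm$class == "shared"], 2)
  expect_equal(sm$nAnnotated[sm$class == "aOnly"], 0)
})

test_that("gene sets round-trip through GMT and filter by size", {
  sets <- list(small = c("A", "B"), big = sprintf("G%03d", 1:120),
               mid = c("A", "B", "C"), lone = "A")
  path <- withr::local_tempfile(fileext = ".gmt")
  writeGeneSets(sets, path)
  back <- readGeneSets(path)
  expect_identical(back, sets)
  kept <- filterGeneSets(sets)
  expect_setequal(names(kept), c("small", "mid"))
})

test_that("annotation ingestion filters evidence and propagates upward", {
  ann <- data.frame(
    protein = c("P1", "P2", "P3", "P4", "P5"),
    term = c("leaf", "leaf", "mid", "leaf", "leaf"),
    evidence = c("EXP", "IEA", "EXP", "IDA", "EXP"),
    qualifier = c("", "", "", "NOT", ""))
  parents <- list(leaf = "mid", mid = "root")
  sets <- buildGeneSetsFromAnnotations(ann, parents)
  # IEA (P2) and NOT (P4) dropped; leaf annotations propagate to mid and root
  expect_setequal(sets$leaf, c("P1", "P5"))
  expect_setequal(sets$mid, c("P1", "P3", "P5"))
  expect_setequal(sets$root, c("P1", "P3", "P5"))
})
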