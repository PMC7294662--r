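makeFit <- function(mu, A, sigma = rep(2, length(mu))) {
  new("GaussianMixtureFit",
      components = data.frame(A = A, mu = mu, sigma = sigma),
      aicc = 0, nObs = 10L, converged = TRUE)
}

test_that("pair features match hand computation", {
  m <- rbind(a = c(1, 2, 1), b = c(1, 2, 3), c = c(1, 2, 1))
  mat <- ChromatogramMatrix(m)
  fits <- list(a = makeFit(10, 1), b = makeFit(13, 1), c = NULL)
  ft <- computePairFeatures(mat, mat, fits)
  ab <- ft[ft$proteinA == "a" & ft$proteinB == "b", ]
  expect_equal(ab$dRaw, 2)
  expect_equal(ab$dPeak, 1)
  expect_equal(ab$dGauss, 3)
  ac <- ft[ft$proteinA == "a" & ft$proteinB == "c", ]
  expect_equal(ac$rRaw, 1)
  expect_equal(ac$dRaw, 0)
  expect_equal(ac$dPeak, 0)
  expect_true(is.na(ac$dGauss))
})

test_that("correlation p-values match the t transform and cor.test", {
  set.seed(51)
  m <- matrix(runif(40), 4, 10, dimnames = list(letters[1:4], NULL))
  m[1, 3] <- NA
  mat <- ChromatogramMatrix(m)
  ft <- computePairFeatures(mat, mat, setNames(vector("list", 4),
                                               letters[1:4]))
  for (i in seq_len(nrow(ft))) {
    x <- m[ft$proteinA[i], ]
    y <- m[ft$proteinB[i], ]
    ok <- !is.na(x) & !is.na(y)
    ct <- cor.test(x[ok], y[ok])
    expect_equal(ft$rRaw[i], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(ft$pRaw[i], ct$p.value, tolerance = 1e-10)
    expect_equal(ft$dRaw[i], sqrt(sum((x[ok] - y[ok])^2)), tolerance = 1e-10)
  }
})

test_that("features with too little pairwise overlap are missing", {
  m <- rbind(a = c(1, 2, NA, NA, NA, 3),
             b = c(1, NA, 2, 3, 4, NA))
  mat <- ChromatogramMatrix(m)
  ft <- computePairFeatures(mat, mat, list(a = NULL, b = NULL))
  expect_true(is.na(ft$rRaw))
  expect_true(is.na(ft$dRaw))
})

test_that("gold standards enumerate co-membership correctly", {
  gs <- buildGoldStandard(list(c1 = c("A", "B", "C"), c2 = c("D", "E")),
                          universe = LETTERS[1:5])
  expect_setequal(pkey(gs$positives$proteinA, gs$positives$proteinB),
                  c("A B", "A C", "B C", "D E"))
  expect_setequal(pkey(gs$negatives$proteinA, gs$negatives$proteinB),
                  c("A D", "A E", "B D", "B E", "C D", "C E"))

  single <- buildGoldStandard(list(c1 = c("A", "B")), universe = c("A", "B"))
  expect_identical(nrow(single$positives), 1L)
  expect_identical(nrow(single$negatives), 0L)

  shared <- buildGoldStandard(list(c1 = c("A", "B"), c2 = c("B", "C")),
                              universe = c("A", "B", "C"))
  expect_setequal(pkey(shared$positives$proteinA, shared$positives$proteinB),
                  c("A B", "B C"))
  expect_setequal(pkey(shared$negatives$proteinA, shared$negatives$proteinB),
                  "A C")

  # members absent from the profiled universe are dropped first
  restricted <- buildGoldStandard(list(c1 = c("A", "B", "Z")),
                                  universe = c("A", "B"))
  expect_identical(nrow(restricted$positives), 1L)
})

test_that("uninformative features score near the class prior", {
  set.seed(61)
  n <- 1000
  # identical class-conditional feature distributions by construction
  # (quantile grids), so only the class prior carries information
  qgrid <- function(k) qnorm((seq_len(k) - 0.5) / k)
  feats <- data.frame(proteinA = sprintf("L%04d", 1:n),
                      proteinB = sprintf("R%04d", 1:n),
                      f1 = c(qgrid(150), qgrid(350), qgrid(500)),
                      f2 = c(rev(qgrid(150)), rev(qgrid(350)),
                             rev(qgrid(500))))
  # label 150 pairs positive, 350 negative, rest unlabeled
  gold <- list(positives = data.frame(proteinA = sprintf("L%04d", 1:150),
                                      proteinB = sprintf("R%04d", 1:150)),
               negatives = data.frame(proteinA = sprintf("L%04d", 151:500),
                                      proteinB = sprintf("R%04d", 151:500)))
  class(gold) <- "GoldStandard"
  sc <- scorePairs(feats, gold, seed = 61)
  prior <- 150 / 500
  expect_lt(max(abs(sc$score - prior)), 0.05)
})

test_that("a single informative Gaussian feature gives the closed-form posterior", {
  set.seed(62)
  n <- 1300
  qgrid <- function(k) qnorm((seq_len(k) - 0.5) / k)
  feats <- data.frame(proteinA = sprintf("L%04d", 1:n),
                      proteinB = sprintf("R%04d", 1:n),
                      f1 = c(1 + 0.1 * qgrid(600), -1 + 0.1 * qgrid(600),
                             0, 1, rnorm(98)))
  gold <- list(positives = data.frame(proteinA = sprintf("L%04d", 1:600),
                                      proteinB = sprintf("R%04d", 1:600)),
               negatives = data.frame(proteinA = sprintf("L%04d", 601:1200),
                                      proteinB = sprintf("R%04d", 601:1200)))
  class(gold) <- "GoldStandard"
  sc <- scorePairs(feats, gold, seed = 62)
  at0 <- sc$score[sc$proteinA == "L1201"]
  at1 <- sc$score[sc$proteinA == "L1202"]
  expect_lt(abs(at0 - 0.5), 0.05)
  expect_gt(at1, 0.99)
})

test_that("the classifier agrees with an independent naive Bayes on complete data", {
  skip_if_not_installed("e1071")
  set.seed(63)
  n <- 300
  X <- data.frame(f1 = c(rnorm(150, 1), rnorm(150, -1)),
                  f2 = c(rnorm(150, -0.5), rnorm(150, 0.5)))
  lab <- rep(c("positive", "negative"), each = 150)
  model <- CoFracNet:::trainNaiveBayes(as.matrix(X), lab)
  mine <- CoFracNet:::predictNaiveBayes(model, as.matrix(X))
  ref <- e1071::naiveBayes(X, factor(lab))
  theirs <- predict(ref, X, type = "raw")[, "positive"]
  expect_equal(mine, unname(theirs), tolerance = 1e-6)
})

test_that("missing features drop out of the likelihood product", {
  model <- CoFracNet:::trainNaiveBayes(
    matrix(c(1, 1.1, -1, -0.9, 0, 10, 0.1, 9.9), ncol = 2,
           dimnames = list(NULL, c("f1", "f2"))),
    c("positive", "positive", "negative", "negative"))
  full <- CoFracNet:::predictNaiveBayes(
    model, matrix(c(1, NA), nrow = 1, dimnames = list(NULL, c("f1", "f2"))))
  onlyF1 <- CoFracNet:::predictNaiveBayes(
    CoFracNet:::trainNaiveBayes(
      matrix(c(1, 1.1, -1, -0.9), ncol = 1,
             dimnames = list(NULL, "f1")),
      c("positive", "positive", "negative", "negative")),
    matrix(1, nrow = 1, dimnames = list(NULL, "f1")))
  expect_equal(full, onlyF1, tolerance = 1e-12)
})

test_that("zero-noise simulations are perfectly separable", {
  truth <- generateComplexTruth(36, 9, c(4L, 4L), 0, seed = 71)
  sim <- simulateChromatograms(truth, simulationConfig(
    noiseSd = 0, missingRate = 0, spikeRate = 0, seed = 71))
  sc <- scoreChannel(sim, "medium", seed = 71, modern = FALSE)
  lab <- sc[!is.na(sc$label), ]
  auc <- rankAUC(lab$score[lab$label == "positive"],
                 lab$score[lab$label == "negative"])
  expect_equal(auc, 1.0)
})

test_that("precision thresholding follows the ranked-list rules", {
  mk <- function(labels, scores = rev(seq_along(labels))) {
    data.frame(proteinA = paste0("A", seq_along(labels)),
               proteinB = paste0("B", seq_along(labels)),
               score = scores, label = labels)
  }
  net <- precisionThreshold(mk(c("positive", "positive", "negative",
                                 "positive")), 0.70)
  expect_identical(edgeCount(net), 4L)
  expect_equal(networkPrecision(net), 3 / 4)

  allPos <- precisionThreshold(mk(rep("positive", 5)), 0.70)
  expect_identical(edgeCount(allPos), 5L)
  expect_equal(networkPrecision(allPos), 1)

  expect_warning(
    empty <- precisionThreshold(mk(c("negative", "positive"))),
    "unreachable")
  expect_identical(edgeCount(empty), 0L)

  # unlabeled pairs ride along inside the retained prefix
  withUnlabeled <- precisionThreshold(mk(c("positive", NA, "positive",
                                           "negative")), 0.70)
  expect_identical(edgeCount(withUnlabeled), 3L)

  # equal-score blocks are atomic: a tied block enters only as a whole
  tied <- mk(c("positive", "positive", "negative", "negative"),
             scores = c(1, 0.5, 0.5, 0.2))
  netTied <- precisionThreshold(tied, 0.70)
  expect_identical(edgeCount(netTied), 1L)
})

test_that("cumulative precision matches brute force on random ranked lists", {
  set.seed(81)
  for (i in 1:100) {
    n <- 20
    labels <- sample(c("positive", "negative", NA), n, replace = TRUE,
                     prob = c(0.4, 0.3, 0.3))
    if (!any(!is.na(labels))) labels[1] <- "positive"
    scores <- round(runif(n), sample(c(1, 2), 1))  # induces ties
    scored <- data.frame(proteinA = paste0("A", 1:n),
                         proteinB = paste0("B", 1:n),
                         score = scores, label = labels)
    scored <- scored[order(-scored$score), ]
    target <- runif(1, 0.3, 0.95)
    got <- suppressWarnings(precisionThreshold(scored, target))

    # brute force: scan every prefix whose boundary does not split a tie
    lab <- !is.na(scored$label)
    cumPos <- cumsum(lab & scored$label == "positive")
    cumLab <- cumsum(lab)
    best <- 0L
    for (k in seq_len(n)) {
      if (k < n && scored$score[k + 1L] == scored$score[k]) next
      if (cumLab[k] > 0 && cumPos[k] / cumLab[k] >= target) best <- k
    }
    expect_identical(edgeCount(got), best)
  }
})

test_that("network comparison performs exact set algebra", {
  netA <- InteractionNetwork(data.frame(proteinA = c("A", "B"),
                                        proteinB = c("B", "C")))
  netB <- InteractionNetwork(data.frame(proteinA = c("A", "C"),
                                        proteinB = c("B", "D")))
  cmp <- compareNetworks(netA, netB)
  expect_identical(pkey(cmp$shared$proteinA, cmp$shared$proteinB), "A B")
  expect_identical(pkey(cmp$aOnly$proteinA, cmp$aOnly$proteinB), "B C")
  expect_identical(pkey(cmp$bOnly$proteinA, cmp$bOnly$proteinB), "C D")
  expect_setequal(cmp$sharedNodes, c("A", "B", "C"))
  expect_identical(cmp$bOnlyNodes, "D")
  expect_equal(sum(cmp$proportions), 1)

  same <- compareNetworks(netA, netA)
  expect_equal(unname(same$proportions["shared"]), 1)
  disjoint <- compareNetworks(
    netA, InteractionNetwork(data.frame(proteinA = "X", proteinB = "Y")))
  expect_equal(unname(disjoint$proportions["shared"]), 0)
})

test_that("networks round-trip as TSV and export as GraphML", {
  net <- InteractionNetwork(
    data.frame(proteinA = c("A", "B"), proteinB = c("B", "C"),
               score = c(0.9, 0.8), label = c("positive", NA)),
    condition = "unstimulated", precision = 0.9)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeNetwork(net, tsv)
  back <- utils::read.delim(tsv)
  expect_identical(nrow(back), 2L)
  expect_identical(back$condition, rep("unstimulated", 2L))
  gml <- withr::local_tempfile(fileext = ".graphml")
  writeNetworkGraphML(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 2)
})
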