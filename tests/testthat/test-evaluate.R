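test_that("adaptive bins close at the count target and conserve reads", {
  # 1000 reads spread uniformly over one chromosome -> two bins of ~500
  major <- matrix(rep(1, 1000), ncol = 1)
  minor <- matrix(rep(0, 1000), ncol = 1)
  ae <- aeFromMajorMinor(major, minor, pos = seq(1e5, 9e7, length.out = 1000))
  bins <- adaptiveBins(ae, minCount = 500)
  expect_length(bins, 2)
  expect_false(any(mcols(bins)$undersized))
  expect_equal(sum(mcols(bins)$totalMajor) + sum(mcols(bins)$totalMinor),
               1000)
  # 499 reads: one flagged undersized bin
  ae2 <- aeFromMajorMinor(matrix(rep(1, 499), ncol = 1),
                          matrix(0, 499, 1),
                          pos = seq(1e5, 9e7, length.out = 499))
  bins2 <- adaptiveBins(ae2, minCount = 500)
  expect_length(bins2, 1)
  expect_true(mcols(bins2)$undersized)
})

test_that("bin ratios concentrate near 0.5 on diploid data", {
  set.seed(61)
  nS <- 2000
  depth <- rpois(nS, 2)
  m <- rbinom(nS, depth, 0.5)
  ae <- aeFromMajorMinor(matrix(m, ncol = 1), matrix(depth - m, ncol = 1),
                         pos = sort(sample.int(9e7, nS)))
  bins <- adaptiveBins(ae, minCount = 500)
  expect_true(all(!mcols(bins)$undersized))
  expect_lt(mean(abs(mcols(bins)$ratio - 0.5)), 0.05)
})

test_that("window scores tile the genome and reflect allelic imbalance", {
  reg <- toyRegistry(1, 100e6)
  # deep counts: half the chromosome LoH-like, half balanced
  pos <- seq(1e6, 99e6, by = 1e6)
  loh <- pos <= 50e6
  major <- matrix(ifelse(loh, 100, 50), ncol = 1)
  minor <- matrix(ifelse(loh, 0, 50), ncol = 1)
  ae <- aeFromMajorMinor(major, minor, pos = pos)
  truth <- CopyNumberSegments("1", 1, 50e6, nMajor = 2, nMinor = 0)
  ws <- windowScores(ae, reg, truthSegs = truth)
  expect_length(ws, 20)  # 100 Mb / 5 Mb
  sc <- mcols(ws)
  expect_equal(unname(sc$score[sc$truth == "altered"]),
               rep(0.5, sum(sc$truth == "altered")))
  expect_true(all(sc$score[sc$truth == "neutral"] < 0.1))
  expect_equal(sum(sc$truth == "altered"), 10)
})

test_that("ROC analysis separates scores and matches a hand-rolled AUC", {
  r <- rocAuc(c(0.9, 0.8, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  # monotone transform invariance
  r2 <- rocAuc(log(c(0.9, 0.8, 0.1, 0.2)), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r2$auc, 1)
  # agreement with an independent trapezoid on overlapping scores
  set.seed(71)
  sc <- c(rnorm(50, 1), rnorm(50, 0))
  lab <- rep(c(TRUE, FALSE), each = 50)
  expect_equal(rocAuc(sc, lab)$auc, trapezoidAuc(sc, lab), tolerance = 1e-9)
  # label-independent scores give AUC ~ 0.5
  perm <- sample(lab)
  expect_lt(abs(rocAuc(sc, perm)$auc - 0.5), 0.12)
  expect_error(rocAuc(c(1, 2), c(TRUE, TRUE)), "both")
})

test_that("coverage histograms count cells per read total including zero", {
  h <- coverageHistogram(c(0, 0, 3))
  expect_equal(h$N, c(0, 3))
  expect_equal(h$cells, c(2, 1))
  expect_equal(nrow(coverageHistogram(numeric(0))), 0)
  set.seed(81)
  tot <- rpois(200, 3)
  expect_equal(sum(coverageHistogram(tot)$cells), 200)
})

test_that("classification summaries exclude unassigned cells from fractions", {
  calls <- S4Vectors::DataFrame(
    cellId = sprintf("c%03d", 1:150),
    posteriorCancer = 0.5,
    label = c(rep("cancer", 90), rep("normal", 10), rep("unassigned", 50)))
  s <- classificationSummary(calls, groups = "tumour")
  expect_equal(s$byGroup$fracCancer, 0.9)
  expect_equal(s$byGroup$nUnassigned, 50)
  s2 <- classificationSummary(calls[calls$label == "unassigned", ])
  expect_true(is.na(s2$byGroup$fracCancer))
  truth <- c(rep("cancer", 90), rep("normal", 10), rep("cancer", 50))
  s3 <- classificationSummary(calls, truth = truth)
  expect_equal(unname(s3$confusion["cancer", "cancer"]), 90)
  expect_equal(unname(s3$confusion["normal", "normal"]), 10)
  expect_equal(sum(s3$confusion) , 100)
})
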