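smallCfg <- function(seed = 7, ...) {
  simConfig(seed = seed, nCancer = 40, nNormal = 40, snpDensity = 3,
            genesPerMb = 3, meanInformativeReads = 300, ...)
}

test_that("the simulator is deterministic under its seed", {
  cfg <- smallCfg()
  r1 <- simulateReference(cfg); r2 <- simulateReference(cfg)
  expect_identical(as.data.frame(r1$snps), as.data.frame(r2$snps))
  c1 <- simulateCells(cfg, r1); c2 <- simulateCells(cfg, r2)
  expect_true(all(refCounts(c1$ae) == refCounts(c2$ae)))
  expect_true(all(altCounts(c1$ae) == altCounts(c2$ae)))
  expect_identical(c1$truth$rho, c2$truth$rho)
  # a different seed changes the data
  c3 <- simulateCells(simConfig(seed = 8, nCancer = 40, nNormal = 40,
                                snpDensity = 3, genesPerMb = 3,
                                meanInformativeReads = 300),
                      simulateReference(simConfig(seed = 8, snpDensity = 3,
                                                  genesPerMb = 3)))
  expect_false(sum(altCounts(c1$ae)) == sum(altCounts(c3$ae)) &&
                 all(dim(c1$ae) == dim(c3$ae)) &&
                 all(altCounts(c1$ae) == altCounts(c3$ae)))
})

test_that("simulated SNPs live inside genes at the configured density", {
  cfg <- smallCfg()
  ref <- simulateReference(cfg)
  # ~3 SNPs/Mb over 300 Mb
  expect_equal(length(ref$snps), 900, tolerance = 0.02)
  expect_true(all(mcols(ref$snps)$siteClass %in% c("exonic", "intronic")))
  expect_true(any(mcols(ref$snps)$siteClass == "exonic"))
  # no genes means no genic SNPs
  expect_warning(empty <- simulateReference(simConfig(seed = 1,
                                                      genesPerMb = 0)),
                 "no genes")
  expect_length(empty$snps, 0)
})

test_that("normal cells have balanced aggregate allele fractions", {
  cfg <- simConfig(seed = 13, nCancer = 0, nNormal = 120, snpDensity = 3,
                   genesPerMb = 3, meanInformativeReads = 1000)
  ref <- simulateReference(cfg)
  cells <- simulateCells(cfg, ref)
  tot <- sum(totalCounts(cells$ae))
  expect_gt(tot, 1e5)
  aggBaf <- sum(altCounts(cells$ae)) / tot
  expect_equal(aggBaf, 0.5, tolerance = 0.01)
})

test_that("cancer cells are fully imbalanced in LoH regions without errors", {
  cfg <- simConfig(seed = 17, nCancer = 50, nNormal = 0, snpDensity = 3,
                   genesPerMb = 3, meanInformativeReads = 500,
                   epsilon = c(exonic = 1e-9, intronic = 1e-9))
  ref <- simulateReference(cfg)
  cells <- simulateCells(cfg, ref)
  loh <- ref$segments[mcols(ref$segments)$nMinor == 0]
  inLoh <- IRanges::overlapsAny(rowRanges(cells$ae), loh)
  aom <- mcols(rowRanges(cells$ae))$truthAltOnMajor
  A <- altCounts(cells$ae); R <- refCounts(cells$ae)
  majorReads <- sum(A[inLoh & aom, ]) + sum(R[inLoh & !aom, ])
  allReads <- sum(A[inLoh, ]) + sum(R[inLoh, ])
  expect_gt(allReads, 1000)
  expect_equal(majorReads / allReads, 1)
})

test_that("bulk DNA counts track segment state, purity and haplotype", {
  cfg <- simConfig(seed = 19, snpDensity = 12, genesPerMb = 3,
                   dnaDepth = 1000)
  ref <- simulateReference(cfg)
  bulk <- simulateBulkDNA(cfg, ref, purity = 1)
  b <- baf(bulk$tumour)
  inSeg <- IRanges::overlapsAny(ref$snps, ref$segments)
  # diploid regions: BAF near 0.5
  expect_equal(mean(b[!inSeg]), 0.5, tolerance = 0.01)
  # LoH at purity 1, depth 1000: nearly all SNPs pushed to the extremes
  loh <- IRanges::overlapsAny(ref$snps,
                              ref$segments[mcols(ref$segments)$nMinor == 0])
  extreme <- b[loh] >= 0.95 | b[loh] <= 0.05
  expect_gte(mean(extreme), 0.99)
  # normal DNA stays balanced everywhere
  expect_equal(mean(baf(bulk$normal)), 0.5, tolerance = 0.01)
  # purity 0.5 cnLOH: per-haplotype expectation 0.75 / 0.25
  half <- simulateBulkDNA(cfg, ref, purity = 0.5)
  bh <- baf(half$tumour)
  aom <- mcols(ref$snps)$truthAltOnMajor
  expect_lt(abs(mean(bh[loh & aom]) - 0.75), 0.01)
  expect_lt(abs(mean(bh[loh & !aom]) - 0.25), 0.01)
  expect_error(simulateBulkDNA(cfg, ref, purity = 1.2), "purity")
})

test_that("parameter recovery from simulated normal cells", {
  cfg <- simConfig(seed = 23, nCancer = 0, nNormal = 150, snpDensity = 5,
                   genesPerMb = 5, meanInformativeReads = 800, phi = 0.1)
  ref <- simulateReference(cfg)
  cells <- simulateCells(cfg, ref)
  ae <- addPhase(cells$ae, phaseFromTruth(ref))
  mcols(rowRanges(ae))$majorIsAlt <- mcols(rowRanges(ae))$truthAltOnMajor
  ae <- orientCounts(ae)
  model <- fitASE(ae, normalCells = seq_len(ncol(ae)), spread = "fit")
  model <- fitOverdispersion(ae, normalCells = seq_len(ncol(ae)),
                             model = model)
  expect_lt(abs(overdispersion(model) - cfg$phi) / cfg$phi, 0.3)
})
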