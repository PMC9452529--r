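test_that("major-allele fraction matches copy-number arithmetic", {
  segs <- CopyNumberSegments("1", c(1, 2e7, 4e7), c(1e7, 3e7, 5e7),
                             nMajor = c(1, 2, 2), nMinor = c(1, 1, 0))
  expect_equal(majorAlleleFraction(segs), c(0.5, 2 / 3, 1))
  degenerate <- CopyNumberSegments("1", 1, 1e6, nMajor = 0, nMinor = 0)
  expect_error(majorAlleleFraction(degenerate), "zero total copies")
})

test_that("major-allele fraction is 0.5 exactly when copies balance", {
  for (k in 1:4) {
    seg <- CopyNumberSegments("1", 1, 1e6, nMajor = k, nMinor = k)
    expect_equal(majorAlleleFraction(seg), 0.5)
  }
  seg <- CopyNumberSegments("1", 1, 1e6, nMajor = 3, nMinor = 2)
  expect_gt(majorAlleleFraction(seg), 0.5)
})

test_that("segment cleaning removes artifacts, fills gaps, collapses chromosomes", {
  reg <- toyRegistry(1, 100e6)
  # 0.5 Mb segment removed outright
  short <- CopyNumberSegments("1", 1e6 + 1, 1.5e6, 2, 1)
  expect_length(cleanSegments(short, reg), 0)
  # 5 Mb segment exceeds 1 Mb but fails the 10%-of-chromosome rule
  tenpc <- CopyNumberSegments("1", 1, 5e6, 2, 1)
  expect_length(cleanSegments(tenpc, reg), 0)
  # two same-state segments 0.4 Mb apart merge into one
  gap <- CopyNumberSegments("1", c(1, 30.4e6 + 1), c(30e6, 70e6),
                            nMajor = 2, nMinor = 1)
  merged <- cleanSegments(gap, reg)
  expect_length(merged, 1)
  expect_equal(start(merged), 1)
  expect_equal(end(merged), 70e6)
  # >= 90% of covered length in one state sets the whole chromosome
  mixed <- CopyNumberSegments("1", c(1, 92e6 + 1), c(90e6, 97e6),
                              nMajor = c(2, 1), nMinor = c(1, 1))
  whole <- cleanSegments(mixed, reg)
  expect_length(whole, 1)
  expect_equal(mcols(whole)$nMajor, 2L)
  expect_equal(mcols(whole)$nMinor, 1L)
  expect_error(cleanSegments(CopyNumberSegments("99", 1, 5e7, 2, 1), reg),
               "unknown chromosome")
})

test_that("segment cleaning is idempotent and never grows the segment list", {
  reg <- toyRegistry(2, 100e6)
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(2:8, 1)
    st <- sort(sample.int(90e6, n))
    en <- pmin(st + sample(c(5e5, 2e6, 12e6, 30e6), n, replace = TRUE), 100e6)
    en <- pmax(en, st)
    # trim overlaps so input satisfies the non-overlap precondition
    for (i in seq_len(n - 1)) en[i] <- min(en[i], st[i + 1] - 1)
    ok <- en > st
    segs <- CopyNumberSegments(sample(c("1", "2"), 1), st[ok], en[ok],
                               nMajor = sample(1:3, sum(ok), TRUE),
                               nMinor = sample(0:1, sum(ok), TRUE))
    once <- cleanSegments(segs, reg)
    twice <- cleanSegments(once, reg)
    expect_lte(length(once), length(segs))
    expect_identical(as.data.frame(once), as.data.frame(twice))
  }
})

test_that("subclonal flagging applies the cell-fraction and length bounds", {
  segs <- CopyNumberSegments("1", c(1, 40e6, 60e6), c(30e6, 55e6, 76e6) + 1,
                             nMajor = 2, nMinor = 0,
                             cellFraction = c(0.30, 0.30, 0.95))
  part <- flagSubclonal(segs)
  expect_equal(start(part$subclonal), 1)        # 30 Mb at 30%
  expect_length(part$subclonal, 1)
  expect_equal(start(part$clonal), 60e6)        # 95% is clonal
  expect_length(part$clonal, 1)                 # 15 Mb at 30% dropped
  noCf <- segs
  mcols(noCf)$cellFraction <- NULL
  expect_error(flagSubclonal(noCf), "cellFraction")
})

test_that("segments round-trip through the TSV interface", {
  segs <- CopyNumberSegments(c("chr1", "2"), c(101, 1), c(5e6, 7e6),
                             nMajor = c(2, 3), nMinor = c(0, 1),
                             cellFraction = c(1, 0.4))
  f <- tempfile(fileext = ".tsv")
  writeSegments(segs, f)
  back <- readSegments(f)
  expect_identical(as.data.frame(back), as.data.frame(segs))
  # "chr1" normalized to "1"
  expect_setequal(as.character(seqnames(back)), c("1", "2"))
  bad <- tempfile()
  writeLines(c("x\ty", "1\t2"), bad)
  expect_error(readSegments(bad), "lacks column")
})
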