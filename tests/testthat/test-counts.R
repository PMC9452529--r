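geneModelFixture <- function() {
  genes <- GRanges("1", IRanges::IRanges(c(1000, 50000), width = c(10000, 8000)),
                   gene = c("geneA", "HLA-A"))
  exons <- GRanges("1", IRanges::IRanges(c(1000, 9000, 50000),
                                         width = c(2000, 2001, 8000)),
                   gene = c("geneA", "geneA", "HLA-A"))
  list(genes = genes, exons = exons)
}

test_that("SNP annotation distinguishes exonic, intronic and intergenic", {
  gm <- geneModelFixture()
  snps <- GRanges("1", IRanges::IRanges(c(1500, 5000, 30000, 51000), width = 1),
                  ref = "A", alt = "G")
  ann <- annotateSNPs(snps, gm, imprintedGenes = "geneA")
  expect_equal(mcols(ann)$siteClass,
               c("exonic", "intronic", "intergenic", "exonic"))
  expect_equal(mcols(ann)$gene, c("geneA", "geneA", NA, "HLA-A"))
  expect_equal(mcols(ann)$imprinted, c(TRUE, TRUE, FALSE, FALSE))
  expect_warning(annotateSNPs(snps, NULL), "intergenic")
})

test_that("site filtering removes imprinted, intergenic, uncovered and excluded genes", {
  gm <- geneModelFixture()
  snps <- GRanges("1", IRanges::IRanges(c(1500, 5000, 30000, 51000, 9500),
                                        width = 1),
                  ref = "A", alt = "G")
  snps <- annotateSNPs(snps, gm, imprintedGenes = character())
  # rows: geneA exon, geneA intron, intergenic, HLA-A exon, geneA exon
  ref <- matrix(c(1, 3, 100, 20, 0), ncol = 1)
  alt <- matrix(0, 5, 1)
  ae <- AlleleExperiment(ref, alt, snps)
  kept <- filterSNPs(ae)
  # intergenic removed despite 100 reads; HLA removed; zero-coverage removed
  expect_equal(start(rowRanges(kept)), c(1500, 5000))
  # an imprinted gene removes its sites too
  snps2 <- annotateSNPs(snps, gm, imprintedGenes = "geneA")
  ae2 <- AlleleExperiment(ref, alt, snps2)
  kept2 <- filterSNPs(ae2)
  expect_false(any(mcols(rowRanges(kept2))$gene %in% "geneA"))
  expect_equal(nrow(kept2), 0)
})

test_that("orientation relabels ref/alt to major/minor by phase", {
  snps <- GRanges("1", IRanges::IRanges(c(100, 200, 300), width = 1),
                  ref = "A", alt = "G")
  mcols(snps)$majorIsAlt <- c(TRUE, FALSE, NA)
  ref <- matrix(c(3, 3, 5), ncol = 1); alt <- matrix(c(1, 1, 2), ncol = 1)
  ae <- AlleleExperiment(ref, alt, snps)
  expect_message(oriented <- orientCounts(ae), "1 unphased")
  expect_equal(nrow(oriented), 2)
  expect_equal(as.numeric(majorCounts(oriented)[, 1]), c(1, 3))
  expect_equal(as.numeric(minorCounts(oriented)[, 1]), c(3, 1))
  # zero-count records survive orientation
  z <- AlleleExperiment(matrix(0, 1, 1), matrix(0, 1, 1), snps[1])
  expect_equal(sum(totalCounts(orientCounts(z))), 0)
})

test_that("segment aggregation sums member SNPs and conserves reads", {
  segs <- CopyNumberSegments("1", c(1, 1e6 + 1), c(1e6, 2e6),
                             nMajor = c(2, 2), nMinor = c(0, 1))
  major <- rbind(c(2, 0), c(3, 0), c(0, 4))
  minor <- rbind(c(0, 1), c(1, 0), c(0, 2))
  ae <- aeFromMajorMinor(major, minor, pos = c(100, 500, 1e6 + 100))
  agg <- aggregateBySegment(ae, segs)
  expect_equal(as.numeric(assay(agg, "majorTotal")[1, ]), c(5, 0))
  expect_equal(as.numeric(assay(agg, "minorTotal")[1, ]), c(1, 1))
  expect_equal(as.numeric(assay(agg, "majorTotal")[2, ]), c(0, 4))
  # conservation: aggregated totals equal retained SNP totals
  expect_equal(sum(assay(agg, "majorTotal")) + sum(assay(agg, "minorTotal")),
               sum(totalCounts(ae)))
  overlapping <- CopyNumberSegments("1", c(1, 50), c(1e6, 2e6),
                                    nMajor = 2, nMinor = 0)
  expect_error(aggregateBySegment(ae, overlapping), "disjoint")
})
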