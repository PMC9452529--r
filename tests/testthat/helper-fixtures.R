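suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
  library(SummarizedExperiment)
  library(Matrix)
})

# oriented AlleleExperiment straight from major/minor matrices, for model
# tests that do not exercise phasing
aeFromMajorMinor <- function(major, minor, gene = NULL,
                             siteClass = "exonic", segId = "seg1",
                             chrom = "1", pos = NULL) {
  major <- as.matrix(major); minor <- as.matrix(minor)
  nS <- nrow(major)
  if (is.null(pos)) pos <- seq_len(nS) * 1000
  snps <- GRanges(chrom, IRanges::IRanges(pos, width = 1),
                  ref = "A", alt = "G")
  mcols(snps)$gene <- if (is.null(gene)) sprintf("g%03d", seq_len(nS))
                      else rep_len(gene, nS)
  mcols(snps)$siteClass <- rep_len(siteClass, nS)
  mcols(snps)$imprinted <- FALSE
  mcols(snps)$segId <- rep_len(segId, nS)
  mcols(snps)$majorIsAlt <- TRUE
  ae <- AlleleExperiment(ref = minor, alt = major, snps = snps)
  orientCounts(ae)
}

# phase simulated SNPs from the simulator's haplotype truth (bypasses the
# bulk-DNA phasing stage where a test targets downstream operations)
phaseFromTruth <- function(ref, segs = NULL) {
  if (is.null(segs)) {
    segs <- ref$segments
    if (!is.null(ref$subcloneSegments))
      segs <- suppressWarnings(c(segs, ref$subcloneSegments))
  }
  snps <- ref$snps
  hit <- findOverlaps(snps, segs, select = "first", ignore.strand = TRUE)
  keep <- !is.na(hit)
  out <- snps[keep]
  mcols(out)$segId <- segmentIds(segs)[hit[keep]]
  mcols(out)$majorIsAlt <- mcols(out)$truthAltOnMajor
  out
}

# independent minlike two-sided exact binomial p-value by full enumeration
enumBinomP <- function(x, n, p = 0.5) {
  probs <- dbinom(0:n, n, p)
  sum(probs[probs <= dbinom(x, n, p) * (1 + 1e-7)])
}

# hand-rolled trapezoidal AUC over all thresholds, independent of pROC
trapezoidAuc <- function(score, altered) {
  th <- sort(unique(score))
  sens <- vapply(th, function(t) mean(score[altered] >= t), 0)
  fpr <- vapply(th, function(t) mean(score[!altered] >= t), 0)
  sens <- c(1, sens, 0); fpr <- c(1, fpr, 0)
  o <- order(fpr, sens)
  sum(diff(fpr[o]) * (head(sens[o], -1) + tail(sens[o], -1)) / 2)
}
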