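#' Site allele counts
#'
#' Bulk DNA allele counts at candidate SNP sites, represented as a width-1
#' \code{GRanges} with mcols \code{ref}, \code{alt} (allele characters) and
#' \code{refCount}, \code{altCount}.
#'
#' @param chrom,pos site coordinates (1-based).
#' @param ref,alt reference / alternate allele characters.
#' @param refCount,altCount supporting read counts.
#' @return a \code{GRanges} of site counts.
#' @examples
#' siteCounts("1", c(100, 200), ref = "A", alt = "G",
#'            refCount = c(10, 30), altCount = c(12, 70))
#' @export
siteCounts <- function(chrom, pos, ref, alt, refCount, altCount) {
  if (any(refCount < 0 | altCount < 0)) stop("counts must be non-negative")
  n <- length(pos)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  if (any(ref == alt)) stop("ref and alt alleles must differ")
  GRanges(normalizeChrom(chrom), IRanges(pos, width = 1),
          ref = ref, alt = alt,
          refCount = as.integer(refCount), altCount = as.integer(altCount))
}

#' B-allele frequency of site counts
#'
#' Fraction of reads supporting the alternate (non-reference) allele,
#' \code{altCount / (refCount + altCount)}; \code{NaN} at zero coverage.
#'
#' @param sites site-count \code{GRanges} (see \code{\link{siteCounts}}).
#' @return numeric vector in [0, 1].
#' @export
baf <- function(sites) {
  mcols(sites)$altCount / (mcols(sites)$refCount + mcols(sites)$altCount)
}

# Two-sided exact binomial p-values against p = 0.5 for alt counts x of
# totals n (minlike convention: sum of outcome probabilities <= that of the
# observed outcome). Delegates to stats::binom.test, which implements
# exactly this convention.
.binomP <- function(x, n) {
  vapply(seq_along(x), function(i) {
    if (n[i] == 0L) return(1)
    stats::binom.test(x[i], n[i], p = 0.5)$p.value
  }, numeric(1))
}

#' Call usable heterozygous SNPs from bulk DNA
#'
#' Retains sites compatible with germline heterozygosity: reads supporting
#' both alleles (at least \code{minReadsPerAllele} each), a B-allele
#' frequency within [\code{bafLow}, \code{bafHigh}], and not rejected by a
#' two-sided exact binomial test against BAF 0.5 after Benjamini-Hochberg
#' correction at \code{fdr} across all candidate sites. Counts should come
#' from normal (or matched) DNA so the test is against the germline 0.5.
#'
#' @param sites site-count \code{GRanges} (see \code{\link{siteCounts}}).
#' @param bafLow,bafHigh BAF window for candidate het sites.
#' @param fdr Benjamini-Hochberg false-discovery rate for the
#'   heterozygosity-inconsistency test.
#' @param minReadsPerAllele minimum reads supporting each allele.
#' @return the retained subset of \code{sites}.
#' @examples
#' s <- siteCounts("1", c(1, 2, 3) * 100, "A", "G",
#'                 refCount = c(50, 10, 30), altCount = c(50, 90, 70))
#' callHetSNPs(s)  # keeps only the balanced 50/50 site
#' @export
callHetSNPs <- function(sites, bafLow = 0.2, bafHigh = 0.8, fdr = 0.05,
                        minReadsPerAllele = 1) {
  if (!length(sites)) return(sites)
  rc <- mcols(sites)$refCount; ac <- mcols(sites)$altCount
  b <- baf(sites)
  cand <- rc >= minReadsPerAllele & ac >= minReadsPerAllele &
    !is.na(b) & b >= bafLow & b <= bafHigh
  sites <- sites[cand]
  if (!length(sites)) return(sites)
  p <- .binomP(mcols(sites)$altCount,
               mcols(sites)$refCount + mcols(sites)$altCount)
  sites[stats::p.adjust(p, "BH") > fdr]
}

# candidate phasing table for one uneven segment: raw p-values, no BH yet
.phaseCandidates <- function(tumourSites, seg) {
  if (mcols(seg)$nMajor == mcols(seg)$nMinor)
    stop("cannot phase a segment with equal major/minor copy number (",
         segmentIds(seg), "): tumour BAF carries no haplotype signal there")
  hits <- findOverlaps(tumourSites, seg)
  s <- tumourSites[S4Vectors::queryHits(hits)]
  tot <- mcols(s)$refCount + mcols(s)$altCount
  s <- s[tot > 0]
  if (!length(s)) return(s)
  mcols(s)$segId <- segmentIds(seg)
  mcols(s)$majorIsAlt <- baf(s) > 0.5
  mcols(s)$p <- .binomP(mcols(s)$altCount,
                        mcols(s)$refCount + mcols(s)$altCount)
  s
}

#' Phase heterozygous SNPs using tumour DNA BAF
#'
#' Within a copy-number segment whose major and minor haplotypes are present
#' at different copy numbers, the tumour-DNA BAF of a heterozygous SNP is
#' pushed away from 0.5 in the direction of the haplotype carrying its
#' alternate allele. \code{phaseSegment} assigns, for each site whose BAF
#' differs significantly from 0.5 (two-sided exact binomial test,
#' Benjamini-Hochberg at \code{fdr}), the alternate allele to the major
#' haplotype when BAF > 0.5 (\code{majorIsAlt = TRUE}) and to the minor
#' haplotype otherwise; non-significant sites are excluded.
#'
#' \code{phaseSNPs} applies this across a set of segments, skipping balanced
#' segments with a warning, with a single joint Benjamini-Hochberg family
#' across all sites in all uneven segments.
#'
#' @param tumourSites tumour-DNA site counts (\code{\link{siteCounts}}),
#'   typically restricted to called het SNPs.
#' @param seg one copy-number segment with \code{nMajor != nMinor}.
#' @param segs segment \code{GRanges}.
#' @param fdr Benjamini-Hochberg false-discovery rate.
#' @return a phased-SNP \code{GRanges}: the significant sites with added
#'   mcols \code{segId} and \code{majorIsAlt}.
#' @examples
#' seg <- CopyNumberSegments("1", 1, 1e6, nMajor = 2, nMinor = 1)
#' s <- siteCounts("1", c(100, 200), "A", "G",
#'                 refCount = c(10, 19), altCount = c(30, 21))
#' phaseSegment(s, seg)  # only the 10/30 site is phased
#' @export
phaseSegment <- function(tumourSites, seg, fdr = 0.05) {
  stopifnot(length(seg) == 1L)
  s <- .phaseCandidates(tumourSites, seg)
  .finishPhase(s, fdr)
}

#' @rdname phaseSegment
#' @export
phaseSNPs <- function(tumourSites, segs, fdr = 0.05) {
  uneven <- mcols(segs)$nMajor != mcols(segs)$nMinor
  if (any(!uneven))
    warning(sum(!uneven), " balanced segment(s) skipped: phasing needs ",
            "uneven copy number")
  segs <- segs[uneven]
  parts <- lapply(seq_along(segs),
                  function(i) .phaseCandidates(tumourSites, segs[i]))
  parts <- parts[vapply(parts, length, 1L) > 0]
  if (!length(parts)) {
    g <- GRanges()
    mcols(g) <- DataFrame(ref = character(0), alt = character(0),
                          refCount = integer(0), altCount = integer(0),
                          segId = character(0), majorIsAlt = logical(0))
    return(g)
  }
  s <- sort(unlist(GenomicRanges::GRangesList(parts), use.names = FALSE))
  .finishPhase(s, fdr)
}

.finishPhase <- function(s, fdr) {
  if (!length(s)) return(s)
  keep <- stats::p.adjust(mcols(s)$p, "BH") <= fdr
  s <- s[keep]
  mcols(s)$p <- NULL
  s
}
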