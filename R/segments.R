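#' Copy-number segments
#'
#' Segments are represented as a \code{GRanges} with integer columns
#' \code{nMajor} and \code{nMinor} (copies of the major/minor haplotype,
#' \code{nMajor >= nMinor}), an optional \code{cellFraction} column (fraction
#' of tumour cells carrying the state, 1 = clonal) and a \code{segId}.
#' This is the shape produced by post-processing the output of allele-specific
#' DNA copy-number callers (Battenberg, ASCAT).
#'
#' @param chrom,start,end segment coordinates (1-based inclusive).
#' @param nMajor,nMinor copies of the major / minor haplotype.
#' @param cellFraction fraction of tumour cells with this state, in (0, 1].
#' @param segId segment identifiers; autogenerated when missing.
#' @param registry optional \code{Seqinfo}; when given, segments must lie on
#'   known chromosomes and within their lengths.
#' @return a \code{GRanges} of segments.
#' @examples
#' CopyNumberSegments(chrom = "1", start = 1, end = 3e7, nMajor = 2, nMinor = 0)
#' @export
CopyNumberSegments <- function(chrom, start, end, nMajor, nMinor,
                               cellFraction = 1, segId = NULL,
                               registry = NULL) {
  chrom <- normalizeChrom(chrom)
  if (any(end < start)) stop("segment end must be >= start")
  nSeg <- max(length(chrom), length(start))
  chrom <- rep_len(chrom, nSeg)
  nMajor <- rep_len(as.integer(nMajor), nSeg)
  nMinor <- rep_len(as.integer(nMinor), nSeg)
  if (any(nMajor < 0 | nMinor < 0)) stop("copy numbers must be non-negative")
  if (any(nMajor < nMinor))
    stop("nMajor must be >= nMinor (swap the haplotype labels)")
  cellFraction <- rep_len(cellFraction, nSeg)
  if (any(cellFraction <= 0 | cellFraction > 1))
    stop("cellFraction must lie in (0, 1]")
  gr <- GRanges(chrom, IRanges(start, end), nMajor = nMajor, nMinor = nMinor,
                cellFraction = cellFraction)
  if (!is.null(registry)) {
    bad <- setdiff(unique(chrom), seqnames(registry))
    if (length(bad))
      stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- seqlevels(registry)
    GenomeInfoDb::seqinfo(gr) <- registry
  }
  mcols(gr)$segId <- if (is.null(segId)) .makeSegIds(gr) else segId
  sort(gr)
}

.makeSegIds <- function(gr) {
  sprintf("%s:%d-%d_%d+%d", seqnames(gr), start(gr), end(gr),
          mcols(gr)$nMajor, mcols(gr)$nMinor)
}

#' @rdname CopyNumberSegments
#' @param segs a segment \code{GRanges}.
#' @export
segmentIds <- function(segs) {
  id <- mcols(segs)$segId
  if (is.null(id)) .makeSegIds(segs) else as.character(id)
}

#' Major-allele fraction of a segment
#'
#' The fraction of a segment's copies carried by the major haplotype:
#' \code{nMajor / (nMajor + nMinor)}. This is the expected B-allele-like
#' fraction a pure cancer cell presents within the segment: 0.5 for a
#' balanced (e.g. diploid) state, 2/3 for a single-copy gain, 1 for loss of
#' heterozygosity.
#'
#' @param segs a segment \code{GRanges} (vectorized).
#' @return numeric vector in (0, 1].
#' @examples
#' segs <- CopyNumberSegments("1", c(1, 2e7, 4e7), c(1e7, 3e7, 5e7),
#'                            nMajor = c(1, 2, 2), nMinor = c(1, 1, 0))
#' majorAlleleFraction(segs)  # 0.5, 2/3, 1
#' @export
majorAlleleFraction <- function(segs) {
  nMaj <- mcols(segs)$nMajor; nMin <- mcols(segs)$nMinor
  tot <- nMaj + nMin
  if (any(tot < 1))
    stop("segment with zero total copies (homozygous deletion); ",
         "exclude such segments upstream")
  nMaj / tot
}

#' Post-process copy-number caller output
#'
#' Applies the standard artifact-removal rules to raw allele-specific
#' copy-number segments: (1) segments shorter than \code{minSegLength} or
#' shorter than \code{minChromFraction} of their chromosome are removed as
#' likely artifacts; (2) gaps shorter than \code{maxGap} between consecutive
#' segments with an identical (nMajor, nMinor) state are filled by merging;
#' (3) a chromosome on which at least \code{wholeChromFraction} of the
#' segment-covered length shares one state is set entirely to that state
#' (one segment spanning the covered extent).
#'
#' The operation is idempotent and never increases the segment count.
#'
#' @param segs segment \code{GRanges}.
#' @param registry \code{Seqinfo} giving chromosome lengths (required for the
#'   fraction-of-chromosome rules).
#' @param minSegLength minimum retained segment length in bases.
#' @param minChromFraction minimum segment length as a fraction of the
#'   chromosome length.
#' @param maxGap largest gap (bases) merged between same-state neighbours.
#' @param wholeChromFraction covered-length fraction above which a chromosome
#'   is collapsed to a single state.
#' @return cleaned segment \code{GRanges}.
#' @export
cleanSegments <- function(segs, registry, minSegLength = 1e6,
                          minChromFraction = 0.1, maxGap = 1e6,
                          wholeChromFraction = 0.9) {
  chroms <- normalizeChrom(seqnames(segs))
  known <- as.character(seqnames(registry))
  bad <- setdiff(unique(chroms), known)
  if (length(bad))
    stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
  if (!length(segs)) return(segs)
  chromLen <- seqlengths(registry)[chroms]
  # (1) drop short segments
  keep <- width(segs) >= minSegLength &
    width(segs) >= minChromFraction * chromLen
  segs <- sort(segs[keep])
  if (!length(segs)) return(segs)
  # (2) fill small gaps between same-state neighbours, (3) collapse
  # chromosomes dominated by one state; both per chromosome
  df <- data.frame(chrom = normalizeChrom(seqnames(segs)),
                   start = start(segs), end = end(segs),
                   nMajor = mcols(segs)$nMajor, nMinor = mcols(segs)$nMinor,
                   cellFraction = mcols(segs)$cellFraction,
                   stringsAsFactors = FALSE)
  pieces <- lapply(split(df, df$chrom), function(s) {
    s <- .mergeSameState(s, maxGap)
    .collapseChromState(s, wholeChromFraction)
  })
  df <- do.call(rbind, pieces)
  CopyNumberSegments(df$chrom, df$start, df$end, df$nMajor, df$nMinor,
                     df$cellFraction)
}

.mergeSameState <- function(s, maxGap) {
  n <- nrow(s)
  if (n < 2) return(s)
  s <- s[order(s$start), , drop = FALSE]
  keep <- rep(TRUE, n)
  i <- 1L
  for (j in 2:n) {
    gap <- s$start[j] - s$end[i] - 1L
    same <- s$nMajor[j] == s$nMajor[i] && s$nMinor[j] == s$nMinor[i]
    if (same && gap >= 0 && gap < maxGap) {
      w <- c(s$end[i] - s$start[i] + 1, s$end[j] - s$start[j] + 1)
      s$cellFraction[i] <-
        sum(w * c(s$cellFraction[i], s$cellFraction[j])) / sum(w)
      s$end[i] <- s$end[j]
      keep[j] <- FALSE
    } else {
      i <- j
    }
  }
  s[keep, , drop = FALSE]
}

.collapseChromState <- function(s, wholeChromFraction) {
  if (nrow(s) < 2) return(s)
  wid <- s$end - s$start + 1
  state <- paste(s$nMajor, s$nMinor, sep = "+")
  frac <- tapply(wid, state, sum) / sum(wid)
  if (max(frac) < wholeChromFraction) return(s)
  sel <- state == names(frac)[which.max(frac)]
  data.frame(chrom = s$chrom[1], start = min(s$start), end = max(s$end),
             nMajor = s$nMajor[sel][1], nMinor = s$nMinor[sel][1],
             cellFraction = sum(wid[sel] * s$cellFraction[sel]) / sum(wid[sel]),
             stringsAsFactors = FALSE)
}

#' Partition segments into clonal and subclonal sets
#'
#' Clonal segments are those carried by at least half of tumour cells
#' (\code{cellFraction >= 0.5}). A segment state seen in a minority of
#' tumour cells counts as subclonal only when it is common enough and large
#' enough to be credible: \code{cellFraction} in [\code{minFraction},
#' 0.5) and length > \code{minLength}. Minority states failing those bounds
#' are dropped.
#'
#' @param segs segment \code{GRanges} with \code{cellFraction} populated.
#' @param minFraction minimum subclonal cell fraction (default 0.10).
#' @param minLength minimum subclonal segment length in bases (default 20 Mb).
#' @return list with \code{GRanges} elements \code{clonal} and
#'   \code{subclonal}.
#' @examples
#' segs <- CopyNumberSegments("1", c(1, 4e7), c(3e7, 9e7), nMajor = 2,
#'                            nMinor = 0, cellFraction = c(0.3, 0.95))
#' flagSubclonal(segs)
#' @export
flagSubclonal <- function(segs, minFraction = 0.10, minLength = 20e6) {
  cf <- mcols(segs)$cellFraction
  if (is.null(cf)) stop("cellFraction must be populated")
  clonal <- cf >= 0.5
  subclonal <- cf >= minFraction & cf < 0.5 & width(segs) > minLength
  list(clonal = segs[clonal], subclonal = segs[subclonal])
}

#' Read / write segment tables
#'
#' Battenberg-like TSV with header columns \code{chrom, start, end, nMajor,
#' nMinor, cellFraction} (start/end 1-based inclusive on disk). Extra columns
#' are ignored on read.
#'
#' @param path file path.
#' @param registry optional \code{Seqinfo} for validation.
#' @return \code{readSegments}: a segment \code{GRanges}.
#' @export
readSegments <- function(path, registry = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "nMajor", "nMinor")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("segments file lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(df$cellFraction)) df$cellFraction <- 1
  CopyNumberSegments(df$chrom, df$start, df$end, df$nMajor, df$nMinor,
                     df$cellFraction, registry = registry)
}

#' @rdname readSegments
#' @param segs segment \code{GRanges} to write.
#' @export
writeSegments <- function(segs, path) {
  df <- data.frame(chrom = as.character(seqnames(segs)),
                   start = start(segs), end = end(segs),
                   nMajor = mcols(segs)$nMajor, nMinor = mcols(segs)$nMinor,
                   cellFraction = mcols(segs)$cellFraction)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
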