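#' Adaptive allelic-ratio bins
#'
#' Aggregates oriented allele counts along each chromosome, per cell group,
#' into bins chosen greedily left-to-right so that every bin holds at least
#' \code{minCount} reads (the resolution at which an allelic ratio is
#' stable enough to plot). A final undersized remainder is merged into the
#' preceding bin; a chromosome whose group total is below \code{minCount}
#' yields a single bin flagged \code{undersized}.
#'
#' @param ae oriented \code{\link{AlleleExperiment}}.
#' @param groups per-cell group labels (e.g. cell types), recycled if scalar.
#' @param minCount minimum reads per emitted bin.
#' @return a \code{GRanges} of bins with mcols \code{group},
#'   \code{totalMajor}, \code{totalMinor}, \code{ratio}
#'   (major/(major+minor)) and \code{undersized}.
#' @export
adaptiveBins <- function(ae, groups = "all", minCount = 500) {
  groups <- rep_len(as.character(groups), ncol(ae))
  rr <- rowRanges(ae)
  ord <- order(as.character(seqnames(rr)), start(rr))
  out <- list()
  for (g in unique(groups)) {
    M <- Matrix::rowSums(majorCounts(ae)[, groups == g, drop = FALSE])
    N <- Matrix::rowSums(minorCounts(ae)[, groups == g, drop = FALSE])
    for (chr in unique(as.character(seqnames(rr)))) {
      i <- ord[as.character(seqnames(rr))[ord] == chr]
      if (!length(i)) next
      tot <- M[i] + N[i]
      bin <- integer(length(i))
      b <- 1L; acc <- 0
      for (k in seq_along(i)) {
        bin[k] <- b
        acc <- acc + tot[k]
        if (acc >= minCount && k < length(i)) { b <- b + 1L; acc <- 0 }
      }
      if (b > 1L && acc < minCount && acc > 0)  # merge short tail
        bin[bin == b] <- b - 1L
      bM <- tapply(M[i], bin, sum); bN <- tapply(N[i], bin, sum)
      st <- tapply(start(rr)[i], bin, min); en <- tapply(start(rr)[i], bin, max)
      gr <- GRanges(chr, IRanges(as.integer(st), as.integer(en)),
                    group = g, totalMajor = as.numeric(bM),
                    totalMinor = as.numeric(bN),
                    ratio = as.numeric(bM) / (as.numeric(bM) + as.numeric(bN)),
                    undersized = as.numeric(bM + bN) < minCount)
      out[[length(out) + 1L]] <- gr
    }
  }
  sort(unlist(GenomicRanges::GRangesList(out), use.names = FALSE))
}

#' Fixed-width genome window scores
#'
#' Tiles the genome into non-overlapping windows of \code{width} bases and
#' computes, per cell group, the allelic imbalance score |aggregate major
#' fraction - 0.5| from all reads falling in the window. Windows without
#' reads get \code{NA} scores. When truth segments are supplied, each
#' window is labelled \code{altered} when at least \code{truthOverlap} of it
#' overlaps a copy-number-changed segment (any state other than 1+1), else
#' \code{neutral}.
#'
#' @param ae oriented \code{\link{AlleleExperiment}}.
#' @param registry genome registry (\code{Seqinfo}).
#' @param groups per-cell group labels.
#' @param width window width in bases (default 5 Mb).
#' @param truthSegs optional truth segment \code{GRanges}.
#' @param truthOverlap minimum overlapping fraction for the altered label.
#' @return a \code{GRanges} of windows with mcols \code{group},
#'   \code{score}, \code{nReads} and (when truth given) \code{truth}.
#' @export
windowScores <- function(ae, registry, groups = "all", width = 5e6,
                         truthSegs = NULL, truthOverlap = 0.5) {
  groups <- rep_len(as.character(groups), ncol(ae))
  tiles <- unlist(GenomicRanges::tileGenome(seqlengths(registry),
                                            tilewidth = width))
  hits <- findOverlaps(rowRanges(ae), tiles, ignore.strand = TRUE)
  out <- list()
  for (g in unique(groups)) {
    M <- Matrix::rowSums(majorCounts(ae)[, groups == g, drop = FALSE])
    N <- Matrix::rowSums(minorCounts(ae)[, groups == g, drop = FALSE])
    wM <- wN <- numeric(length(tiles))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    addM <- tapply(M[q], s, sum); addN <- tapply(N[q], s, sum)
    wM[as.integer(names(addM))] <- addM
    wN[as.integer(names(addN))] <- addN
    t2 <- tiles
    mcols(t2)$group <- g
    tot <- wM + wN
    mcols(t2)$score <- ifelse(tot > 0, abs(wM / tot - 0.5), NA_real_)
    mcols(t2)$nReads <- tot
    out[[g]] <- t2
  }
  res <- unlist(GenomicRanges::GRangesList(out), use.names = FALSE)
  if (!is.null(truthSegs)) {
    altered <- truthSegs[mcols(truthSegs)$nMajor != 1L |
                           mcols(truthSegs)$nMinor != 1L]
    cov <- numeric(length(res))
    if (length(altered)) {
      h <- findOverlaps(res, altered, ignore.strand = TRUE)
      ov <- width(IRanges::pintersect(
        IRanges::ranges(res)[S4Vectors::queryHits(h)],
        IRanges::ranges(altered)[S4Vectors::subjectHits(h)]))
      acc <- tapply(ov, S4Vectors::queryHits(h), sum)
      cov[as.integer(names(acc))] <- acc
    }
    mcols(res)$truth <- ifelse(cov / width(res) >= truthOverlap,
                               "altered", "neutral")
  }
  res
}

#' ROC curve and area for window scores against a truth profile
#'
#' Sweeps all score thresholds to build a receiver operating characteristic
#' for separating altered from neutral windows, with trapezoidal area under
#' the curve (via \pkg{pROC}). Windows with missing scores are excluded.
#'
#' @param scores numeric scores, or a \code{GRanges} from
#'   \code{\link{windowScores}} carrying \code{score} and \code{truth}.
#' @param truth labels ("altered"/"neutral" or logical) when \code{scores}
#'   is numeric.
#' @return list with \code{auc} and a \code{points} data.frame of
#'   sensitivity/specificity over thresholds.
#' @export
rocAuc <- function(scores, truth = NULL) {
  if (methods::is(scores, "GRanges")) {
    truth <- mcols(scores)$truth
    scores <- mcols(scores)$score
  }
  if (is.logical(truth)) truth <- ifelse(truth, "altered", "neutral")
  keep <- !is.na(scores) & !is.na(truth)
  scores <- scores[keep]; truth <- truth[keep]
  if (length(unique(truth)) < 2)
    stop("both altered and neutral windows are required for a ROC curve")
  r <- pROC::roc(response = factor(truth, levels = c("neutral", "altered")),
                 predictor = scores, direction = "<", quiet = TRUE)
  list(auc = as.numeric(pROC::auc(r)),
       points = data.frame(threshold = r$thresholds,
                           sensitivity = r$sensitivities,
                           specificity = r$specificities))
}

#' Histogram of per-cell covering-read totals
#'
#' Counts how many cells have exactly N reads over a site list (N = 0
#' included), the standard depth diagnostic for deciding whether point
#' mutations or heterozygous SNPs can genotype single transcriptomes.
#'
#' @param totals per-cell read totals (e.g.
#'   \code{Matrix::colSums(totalCounts(ae))}).
#' @return data.frame with columns \code{N} and \code{cells}; total cell
#'   mass equals \code{length(totals)}.
#' @examples
#' coverageHistogram(c(0, 0, 3))
#' @export
coverageHistogram <- function(totals) {
  if (!length(totals)) return(data.frame(N = integer(0), cells = integer(0)))
  tab <- table(factor(totals, levels = sort(unique(as.integer(totals)))))
  data.frame(N = as.integer(names(tab)), cells = as.integer(tab))
}

#' Per-group classification summary
#'
#' Fractions of cancer and normal calls per cell group, computed over
#' assigned cells only (unassigned excluded, as in standard reporting);
#' groups with no assigned cells get \code{NA} fractions. When truth labels
#' are given, a confusion matrix over assigned cells is included.
#'
#' @param calls a calls \code{DataFrame} from \code{\link{cancerPosterior}}.
#' @param groups per-cell group labels aligned with \code{calls}.
#' @param truth optional per-cell truth labels ("cancer"/"normal").
#' @return list with \code{byGroup} (data.frame) and, when truth is given,
#'   \code{confusion} (table over assigned cells).
#' @export
classificationSummary <- function(calls, groups = "all", truth = NULL) {
  groups <- rep_len(as.character(groups), nrow(calls))
  lab <- calls$label
  byGroup <- do.call(rbind, lapply(unique(groups), function(g) {
    l <- lab[groups == g]
    nAssigned <- sum(l != "unassigned")
    data.frame(group = g, nCells = length(l),
               nCancer = sum(l == "cancer"), nNormal = sum(l == "normal"),
               nUnassigned = sum(l == "unassigned"),
               fracCancer = if (nAssigned) sum(l == "cancer") / nAssigned
                            else NA_real_,
               fracNormal = if (nAssigned) sum(l == "normal") / nAssigned
                            else NA_real_)
  }))
  out <- list(byGroup = byGroup)
  if (!is.null(truth)) {
    assigned <- lab != "unassigned"
    out$confusion <- table(truth = truth[assigned], call = lab[assigned])
  }
  out
}

#' Plot allelic-ratio bins along the genome
#'
#' Simple genome-track view of \code{\link{adaptiveBins}} output: one panel
#' per group, bin major-allele ratio against genome position, chromosome
#' boundaries dashed, the heterozygous expectation 0.5 dotted.
#'
#' @param bins \code{GRanges} from \code{\link{adaptiveBins}}.
#' @param registry genome registry used for chromosome offsets.
#' @return invisibly, the per-bin plotting coordinates.
#' @export
plotAllelicRatio <- function(bins, registry) {
  len <- as.numeric(seqlengths(registry))
  offs <- stats::setNames(cumsum(c(0, len[-length(len)])),
                          as.character(seqnames(registry)))
  x <- offs[as.character(seqnames(bins))] + (start(bins) + end(bins)) / 2
  gs <- unique(mcols(bins)$group)
  op <- graphics::par(mfrow = c(length(gs), 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(op))
  for (g in gs) {
    sel <- mcols(bins)$group == g
    plot(x[sel], mcols(bins)$ratio[sel], pch = 16, cex = 0.6,
         ylim = c(0, 1), xlab = "", ylab = "major-allele ratio", main = g)
    graphics::abline(v = offs[-1], lty = 2, col = "grey")
    graphics::abline(h = 0.5, lty = 3)
  }
  invisible(data.frame(x = x, ratio = mcols(bins)$ratio,
                       group = mcols(bins)$group))
}
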