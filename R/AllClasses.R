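#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb Seqinfo seqlengths seqnames seqlevels
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges rowRanges<-
#'   assay assays assays<- assayNames colData colData<-
NULL

#' AlleleExperiment: per-cell allele counts at heterozygous SNPs
#'
#' An \code{AlleleExperiment} holds single-cell allele counts at heterozygous
#' SNP positions: rows are SNPs (a width-1 \code{GRanges} carrying at least
#' \code{ref} and \code{alt} allele columns), columns are cells. Counts are
#' stored as sparse matrices in assays \code{"ref"}/\code{"alt"}
#' (reference/alternate orientation, as counted from reads) and, once
#' \code{\link{orientCounts}} has been applied, \code{"major"}/\code{"minor"}
#' (haplotype orientation: the allele at higher copy number in the tumour
#' first).
#'
#' @slot ... inherits all slots from
#'   \code{\link[SummarizedExperiment]{RangedSummarizedExperiment}}.
#' @export
setClass("AlleleExperiment",
         contains = "RangedSummarizedExperiment")

setValidity("AlleleExperiment", function(object) {
  msg <- NULL
  an <- assayNames(object)
  if (!(all(c("ref", "alt") %in% an) || all(c("major", "minor") %in% an)))
    msg <- c(msg, "assays must contain 'ref'+'alt' and/or 'major'+'minor'")
  rr <- rowRanges(object)
  if (length(rr) && !all(width(rr) == 1L))
    msg <- c(msg, "rowRanges must be width-1 SNP positions")
  if (length(rr) && !all(c("ref", "alt") %in% colnames(mcols(rr))))
    msg <- c(msg, "rowRanges must carry 'ref' and 'alt' allele columns")
  for (a in intersect(an, c("ref", "alt", "major", "minor"))) {
    x <- assay(object, a)
    if (any(x@x < 0)) msg <- c(msg, sprintf("assay '%s' has negative counts", a))
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct an AlleleExperiment
#'
#' @param ref,alt matrices (dense or sparse) of reference / alternate allele
#'   counts, SNPs x cells. Coerced to \code{dgCMatrix}.
#' @param snps width-1 \code{GRanges} of SNP positions with mcols \code{ref}
#'   and \code{alt} (allele characters); one range per row of the matrices.
#' @param colData optional \code{DataFrame} of per-cell annotation; row names
#'   are cell barcodes.
#' @return an \code{AlleleExperiment}.
#' @examples
#' snps <- GenomicRanges::GRanges("1", IRanges::IRanges(c(100, 200), width = 1),
#'                                ref = c("A", "C"), alt = c("G", "T"))
#' ae <- AlleleExperiment(ref = matrix(0:3, 2), alt = matrix(c(1, 0, 2, 0), 2),
#'                        snps = snps)
#' ae
#' @export
AlleleExperiment <- function(ref, alt, snps, colData = NULL) {
  ref <- methods::as(methods::as(ref, "CsparseMatrix"), "generalMatrix")
  alt <- methods::as(methods::as(alt, "CsparseMatrix"), "generalMatrix")
  stopifnot(identical(dim(ref), dim(alt)), length(snps) == nrow(ref))
  if (is.null(colData)) {
    cn <- colnames(ref)
    if (is.null(cn)) cn <- sprintf("cell%d", seq_len(ncol(ref)))
    colData <- DataFrame(row.names = cn)
  }
  colnames(ref) <- colnames(alt) <- rownames(colData)
  methods::new("AlleleExperiment",
               SummarizedExperiment(assays = list(ref = ref, alt = alt),
                                    rowRanges = snps, colData = colData))
}

#' @describeIn AlleleExperiment-accessors reference-allele count matrix
#' @export
refCounts <- function(x) assay(x, "ref")

#' @describeIn AlleleExperiment-accessors alternate-allele count matrix
#' @export
altCounts <- function(x) assay(x, "alt")

#' Accessors for AlleleExperiment assays
#'
#' \code{majorCounts}/\code{minorCounts} are only available after
#' \code{\link{orientCounts}}; \code{totalCounts} works in either
#' orientation; \code{isOriented} reports whether haplotype orientation has
#' been applied.
#'
#' @param x an \code{AlleleExperiment}.
#' @name AlleleExperiment-accessors
#' @return a sparse count matrix (or logical for \code{isOriented}).
NULL

#' @describeIn AlleleExperiment-accessors major-allele count matrix
#' @export
majorCounts <- function(x) {
  if (!isOriented(x)) stop("counts not oriented; run orientCounts() first")
  assay(x, "major")
}

#' @describeIn AlleleExperiment-accessors minor-allele count matrix
#' @export
minorCounts <- function(x) {
  if (!isOriented(x)) stop("counts not oriented; run orientCounts() first")
  assay(x, "minor")
}

#' @describeIn AlleleExperiment-accessors total counts per SNP x cell
#' @export
totalCounts <- function(x) {
  if (isOriented(x)) assay(x, "major") + assay(x, "minor")
  else assay(x, "ref") + assay(x, "alt")
}

#' @describeIn AlleleExperiment-accessors has haplotype orientation been applied?
#' @export
isOriented <- function(x) all(c("major", "minor") %in% assayNames(x))

setMethod("show", "AlleleExperiment", function(object) {
  cat(sprintf("AlleleExperiment: %d SNPs x %d cells\n",
              nrow(object), ncol(object)))
  cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
  tot <- sum(totalCounts(object))
  cat(sprintf("  total allele counts: %.0f (mean %.1f per cell)\n",
              tot, if (ncol(object)) tot / ncol(object) else 0))
  ann <- intersect(c("gene", "siteClass", "segId", "majorIsAlt"),
                   colnames(mcols(rowRanges(object))))
  if (length(ann)) cat("  SNP annotation:", paste(ann, collapse = ", "), "\n")
})

#' AlleleModel: calibrated parameters of the allelic-imbalance model
#'
#' Bundles the three calibrated parameter sets used by the posterior
#' classifier: per-site-class sequencing/alignment error rates
#' \eqn{\epsilon}, per-gene allele-specific expression (ASE) ratios
#' \eqn{\rho} with the spread of their beta prior, and the global
#' beta-binomial overdispersion \eqn{\phi}.
#'
#' @slot epsilon named numeric, error rate per site class, each in [0, 0.5).
#' @slot rho named numeric, posterior-mean ASE ratio per gene, each in (0,1).
#'   Genes absent from the map are treated as \eqn{\rho = 0.5} (no ASE).
#' @slot priorSpread positive numeric, concentration of the mean-0.5 beta
#'   prior on \eqn{\rho}.
#' @slot phi numeric in (0,1), beta-binomial overdispersion; the beta
#'   concentration is \eqn{\theta = (1-\phi)/\phi}.
#' @export
setClass("AlleleModel",
         representation(epsilon = "numeric", rho = "numeric",
                        priorSpread = "numeric", phi = "numeric"))

setValidity("AlleleModel", function(object) {
  msg <- NULL
  if (is.null(names(object@epsilon)) || any(!nzchar(names(object@epsilon))))
    msg <- c(msg, "epsilon must be named by site class")
  if (any(object@epsilon < 0 | object@epsilon >= 0.5))
    msg <- c(msg, "epsilon must lie in [0, 0.5)")
  if (length(object@rho) &&
      (is.null(names(object@rho)) || any(object@rho <= 0 | object@rho >= 1)))
    msg <- c(msg, "rho must be named by gene with values in (0,1)")
  if (length(object@priorSpread) != 1L || object@priorSpread <= 0)
    msg <- c(msg, "priorSpread must be a positive scalar")
  if (length(object@phi) != 1L || object@phi <= 0 || object@phi >= 1)
    msg <- c(msg, "phi must lie in (0,1)")
  if (is.null(msg)) TRUE else msg
})

#' @rdname AlleleModel-class
#' @param epsilon,rho,priorSpread,phi see slot documentation. Defaults are the
#'   uncalibrated model: error rates 0.01 (exonic) and 0.05 (intronic), no
#'   gene-specific ASE, prior spread 10, overdispersion 0.05.
#' @return an \code{AlleleModel}.
#' @examples
#' AlleleModel()
#' @export
AlleleModel <- function(epsilon = c(exonic = 0.01, intronic = 0.05),
                        rho = stats::setNames(numeric(0), character(0)),
                        priorSpread = 10, phi = 0.05) {
  methods::new("AlleleModel", epsilon = epsilon, rho = rho,
               priorSpread = priorSpread, phi = phi)
}

#' @describeIn AlleleModel-class error rate per site class
#' @param x an \code{AlleleModel}.
#' @export
errorRates <- function(x) x@epsilon

#' @describeIn AlleleModel-class posterior-mean ASE ratio per gene
#' @export
aseRatios <- function(x) x@rho

#' @describeIn AlleleModel-class beta-binomial overdispersion
#' @export
overdispersion <- function(x) x@phi

#' @describeIn AlleleModel-class concentration of the beta prior on rho
#' @export
asePriorSpread <- function(x) x@priorSpread

setMethod("show", "AlleleModel", function(object) {
  cat("AlleleModel\n")
  cat("  error rates:",
      paste(sprintf("%s=%.4g", names(object@epsilon), object@epsilon),
            collapse = ", "), "\n")
  cat(sprintf("  ASE: %d gene(s) with fitted rho (prior spread %.3g)\n",
              length(object@rho), object@priorSpread))
  cat(sprintf("  overdispersion phi = %.4g\n", object@phi))
})

#' GenotypeHypothesis: a major-allele fraction per copy-number segment
#'
#' A genotype hypothesis assigns to each copy-number segment the fraction
#' \eqn{f} of copies carried by the major haplotype (1 for loss of
#' heterozygosity, 2/3 for a single-copy gain, 0.5 for a balanced/diploid
#' state). The cancer hypothesis sets \eqn{f} to the fraction implied by the
#' tumour DNA copy number in each segment; the normal hypothesis sets
#' \eqn{f = 0.5} everywhere.
#'
#' @slot name label for the hypothesis (e.g. "cancer", "normal").
#' @slot f named numeric: major-allele fraction per segment id, each in (0,1].
#' @export
setClass("GenotypeHypothesis",
         representation(name = "character", f = "numeric"))

setValidity("GenotypeHypothesis", function(object) {
  msg <- NULL
  if (length(object@f) && is.null(names(object@f)))
    msg <- c(msg, "f must be named by segment id")
  if (any(object@f <= 0 | object@f > 1))
    msg <- c(msg, "major-allele fractions must lie in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Build genotype hypotheses from copy-number segments
#'
#' \code{genotypeHypothesis} derives the cancer hypothesis from segments:
#' each segment contributes \eqn{f =} \code{\link{majorAlleleFraction}};
#' balanced segments (\eqn{f = 0.5}, e.g. diploid or 2+2) carry no allelic
#' signal and are excluded, as are homozygous deletions (zero copies), for
#' which the expected allelic ratio is undefined. \code{normalHypothesis}
#' returns the matched hypothesis with \eqn{f = 0.5} on the same segments.
#'
#' @param segments a segment \code{GRanges} (see
#'   \code{\link{CopyNumberSegments}}).
#' @param name hypothesis label.
#' @return a \code{GenotypeHypothesis}.
#' @examples
#' segs <- CopyNumberSegments(chrom = c("1", "2"), start = c(1, 1),
#'                            end = c(3e7, 5e7), nMajor = c(2, 2),
#'                            nMinor = c(0, 1))
#' hyp <- genotypeHypothesis(segs)
#' normalHypothesis(hyp)
#' @export
genotypeHypothesis <- function(segments, name = "cancer") {
  tot <- mcols(segments)$nMajor + mcols(segments)$nMinor
  keep <- tot >= 1L
  segments <- segments[keep]
  f <- majorAlleleFraction(segments)
  inf <- f != 0.5
  f <- f[inf]
  names(f) <- segmentIds(segments[inf])
  methods::new("GenotypeHypothesis", name = name, f = f)
}

#' @rdname genotypeHypothesis
#' @param hyp a \code{GenotypeHypothesis}.
#' @export
normalHypothesis <- function(hyp) {
  methods::new("GenotypeHypothesis", name = "normal",
               f = stats::setNames(rep(0.5, length(hyp@f)), names(hyp@f)))
}

#' @describeIn genotypeHypothesis major-allele fraction map (named by segment)
#' @export
hypothesisFractions <- function(hyp) hyp@f

setMethod("show", "GenotypeHypothesis", function(object) {
  cat(sprintf("GenotypeHypothesis '%s': %d segment(s)\n",
              object@name, length(object@f)))
  if (length(object@f))
    cat(" ", paste(sprintf("%s: f=%.3g", names(object@f), object@f),
                   collapse = "; "), "\n")
})
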