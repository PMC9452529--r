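#' Annotate SNPs against a gene model
#'
#' Labels each SNP \code{exonic} when it falls inside any exon,
#' \code{intronic} when inside a gene body but no exon, and
#' \code{intergenic} otherwise. Where genes overlap, exonic wins over
#' intronic and the first overlapping gene in sorted order provides the gene
#' symbol. The \code{imprinted} flag is set for SNPs whose gene is on the
#' supplied imprinted-gene list.
#'
#' @param snps a width-1 \code{GRanges} of SNPs.
#' @param geneModel a list with \code{GRanges} elements \code{genes} and
#'   \code{exons}, each carrying a \code{gene} mcol (see
#'   \code{\link{readGeneModel}}); \code{NULL} marks every site intergenic
#'   with a warning.
#' @param imprintedGenes character vector of imprinted gene symbols.
#' @return \code{snps} with added mcols \code{gene}, \code{siteClass},
#'   \code{imprinted}.
#' @export
annotateSNPs <- function(snps, geneModel, imprintedGenes = character()) {
  n <- length(snps)
  gene <- rep(NA_character_, n)
  cls <- rep("intergenic", n)
  if (is.null(geneModel)) {
    warning("no gene model supplied: all sites marked intergenic")
  } else {
    genes <- sort(geneModel$genes)
    exons <- geneModel$exons
    gh <- findOverlaps(snps, genes, select = "first", ignore.strand = TRUE)
    inGene <- !is.na(gh)
    gene[inGene] <- mcols(genes)$gene[gh[inGene]]
    cls[inGene] <- "intronic"
    inExon <- IRanges::overlapsAny(snps, exons, ignore.strand = TRUE) & inGene
    cls[inExon] <- "exonic"
  }
  mcols(snps)$gene <- gene
  mcols(snps)$siteClass <- cls
  mcols(snps)$imprinted <- !is.na(gene) & gene %in% imprintedGenes
  snps
}

#' Genes excluded from allelic-imbalance genotyping
#'
#' All HLA genes (matched by the \code{HLA-} prefix) and the hemoglobin
#' genes, both known for complex allele-specific expression that would mimic
#' copy-number-driven imbalance.
#'
#' @return character vector of literal gene symbols; HLA genes are handled
#'   by prefix in \code{\link{filterSNPs}}.
#' @export
defaultExcludedGenes <- function() {
  c("HBA1", "HBA2", "HBB", "HBD", "HBE1", "HBG1", "HBG2", "HBM", "HBQ1",
    "HBZ")
}

#' Filter SNPs before model fitting and cell calling
#'
#' A pure site-level filter (no cell dependence): removes SNPs that are
#' imprinted, not inside a gene (intergenic), have zero coverage summed over
#' all cells, or fall in excluded genes (HLA genes by prefix plus the
#' hemoglobin list by default, see \code{\link{defaultExcludedGenes}}).
#'
#' @param ae an \code{\link{AlleleExperiment}} whose \code{rowRanges} carry
#'   \code{gene}, \code{siteClass} and \code{imprinted} annotation
#'   (see \code{\link{annotateSNPs}}).
#' @param excludeGenes literal gene symbols to exclude.
#' @param excludePrefixes gene-symbol prefixes to exclude (default
#'   \code{"HLA-"}).
#' @return the filtered \code{AlleleExperiment}.
#' @export
filterSNPs <- function(ae, excludeGenes = defaultExcludedGenes(),
                       excludePrefixes = "HLA-") {
  rr <- rowRanges(ae)
  ann <- mcols(rr)
  if (is.null(ann$siteClass))
    stop("SNPs are not annotated; run annotateSNPs() first")
  covered <- Matrix::rowSums(totalCounts(ae)) > 0
  genic <- ann$siteClass %in% c("exonic", "intronic")
  imprinted <- ann$imprinted
  if (is.null(imprinted)) imprinted <- rep(FALSE, length(rr))
  imprinted[is.na(imprinted)] <- FALSE
  excluded <- !is.na(ann$gene) &
    (ann$gene %in% excludeGenes |
       Reduce(`|`, lapply(excludePrefixes, function(p) startsWith(ann$gene, p)),
              rep(FALSE, length(rr))))
  keep <- covered & genic & !imprinted & !excluded
  ae[keep, ]
}

#' Orient per-cell ref/alt counts to the major/minor haplotype
#'
#' Relabels each phased SNP's reference/alternate counts as major/minor
#' using the segment phase: where the alternate allele sits on the major
#' haplotype (\code{majorIsAlt}), the major count is the alt count, and vice
#' versa. SNPs without a phase assignment are dropped (with a message giving
#' the count).
#'
#' @param ae an \code{\link{AlleleExperiment}} with \code{ref}/\code{alt}
#'   assays whose \code{rowRanges} carry \code{majorIsAlt} (e.g. transferred
#'   from \code{\link{phaseSNPs}} output).
#' @return the \code{AlleleExperiment} restricted to phased SNPs, with added
#'   \code{major}/\code{minor} assays.
#' @export
orientCounts <- function(ae) {
  mia <- mcols(rowRanges(ae))$majorIsAlt
  if (is.null(mia)) stop("rowRanges lack majorIsAlt; phase SNPs first")
  drop <- is.na(mia)
  if (any(drop)) {
    message("dropping ", sum(drop), " unphased SNP(s)")
    ae <- ae[!drop, ]
    mia <- mia[!drop]
  }
  ref <- assay(ae, "ref"); alt <- assay(ae, "alt")
  major <- ref; minor <- alt
  major[mia, ] <- alt[mia, ]
  minor[mia, ] <- ref[mia, ]
  assays(ae, withDimnames = FALSE)$major <- major
  assays(ae, withDimnames = FALSE)$minor <- minor
  ae
}

#' Aggregate oriented counts by copy-number segment
#'
#' Sums major and minor counts over the SNPs of each segment, producing per
#' (cell, segment) totals; cells with no reads in a segment get zeros. Each
#' SNP must be assignable to at most one segment (segments disjoint); SNPs
#' outside all segments do not contribute.
#'
#' @param ae an oriented \code{\link{AlleleExperiment}}.
#' @param segs segment \code{GRanges}.
#' @return a \code{SummarizedExperiment} (segments x cells) with assays
#'   \code{majorTotal} and \code{minorTotal} and \code{rowRanges = segs}.
#' @export
aggregateBySegment <- function(ae, segs) {
  hits <- findOverlaps(rowRanges(ae), segs, ignore.strand = TRUE)
  if (anyDuplicated(S4Vectors::queryHits(hits)))
    stop("SNP overlapping two segments: segments must be disjoint")
  ind <- Matrix::sparseMatrix(i = S4Vectors::queryHits(hits),
                              j = S4Vectors::subjectHits(hits), x = 1,
                              dims = c(nrow(ae), length(segs)))
  majorTotal <- methods::as(Matrix::t(ind) %*% majorCounts(ae), "CsparseMatrix")
  minorTotal <- methods::as(Matrix::t(ind) %*% minorCounts(ae), "CsparseMatrix")
  rownames(majorTotal) <- rownames(minorTotal) <- segmentIds(segs)
  SummarizedExperiment(assays = list(majorTotal = majorTotal,
                                     minorTotal = minorTotal),
                       rowRanges = segs, colData = colData(ae))
}

#' Transfer phase and annotation from phased SNPs onto an AlleleExperiment
#'
#' Matches the experiment's SNPs to a phased-SNP set by position and allele
#' pair and copies \code{segId} and \code{majorIsAlt} across (NA where
#' unmatched, i.e. unphased).
#'
#' @param ae an \code{\link{AlleleExperiment}}.
#' @param phased phased-SNP \code{GRanges} from \code{\link{phaseSNPs}}.
#' @return the annotated \code{AlleleExperiment}.
#' @export
addPhase <- function(ae, phased) {
  key <- function(g) paste(seqnames(g), start(g), mcols(g)$ref,
                           mcols(g)$alt, sep = ":")
  m <- match(key(rowRanges(ae)), key(phased))
  mcols(rowRanges(ae))$segId <- ifelse(is.na(m), NA_character_,
                                       as.character(mcols(phased)$segId[m]))
  mcols(rowRanges(ae))$majorIsAlt <- mcols(phased)$majorIsAlt[m]
  ae
}
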