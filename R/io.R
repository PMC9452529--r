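#' Read / write bulk site counts
#'
#' Long TSV with header \code{chrom, pos, ref, alt, refCount, altCount};
#' positions 1-based. Chromosome names are normalized on read.
#'
#' @param path file path.
#' @return \code{readSiteCounts}: a site-count \code{GRanges}.
#' @export
readSiteCounts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "refCount", "altCount")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("site-counts file lacks column(s): ", paste(miss, collapse = ", "))
  siteCounts(df$chrom, df$pos, df$ref, df$alt, df$refCount, df$altCount)
}

#' @rdname readSiteCounts
#' @param sites site-count \code{GRanges} to write.
#' @export
writeSiteCounts <- function(sites, path) {
  utils::write.table(
    data.frame(chrom = as.character(seqnames(sites)), pos = start(sites),
               ref = mcols(sites)$ref, alt = mcols(sites)$alt,
               refCount = mcols(sites)$refCount,
               altCount = mcols(sites)$altCount),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write per-cell allele counts
#'
#' Long-format TSV with header \code{cellId, chrom, pos, ref, alt,
#' refCount, altCount}, one row per cell x SNP with any coverage. On read,
#' SNPs default to the distinct sites present in the file; pass \code{snps}
#' to align the experiment to a known SNP panel (cells are taken from the
#' file, sites with no reads anywhere get zero rows).
#'
#' @param path file path.
#' @param snps optional \code{GRanges} of SNPs defining the row space.
#' @return \code{readCellCounts}: an \code{\link{AlleleExperiment}}.
#' @export
readCellCounts <- function(path, snps = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("cellId", "chrom", "pos", "ref", "alt", "refCount", "altCount")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("cell-counts file lacks column(s): ", paste(miss, collapse = ", "))
  df$chrom <- normalizeChrom(df$chrom)
  key <- paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
  if (is.null(snps)) {
    u <- !duplicated(key)
    snps <- sort(GRanges(df$chrom[u], IRanges(df$pos[u], width = 1),
                         ref = df$ref[u], alt = df$alt[u]))
  }
  snpKey <- paste(seqnames(snps), start(snps), mcols(snps)$ref,
                  mcols(snps)$alt, sep = ":")
  ri <- match(key, snpKey)
  if (anyNA(ri))
    stop(sum(is.na(ri)), " count row(s) at sites absent from the SNP panel")
  cells <- sort(unique(df$cellId))
  ci <- match(df$cellId, cells)
  mk <- function(x) Matrix::sparseMatrix(i = ri, j = ci, x = x,
                                         dims = c(length(snps),
                                                  length(cells)))
  AlleleExperiment(ref = mk(df$refCount), alt = mk(df$altCount),
                   snps = snps, colData = DataFrame(row.names = cells))
}

#' @rdname readCellCounts
#' @param ae \code{AlleleExperiment} to write (ref/alt orientation).
#' @export
writeCellCounts <- function(ae, path) {
  R <- methods::as(refCounts(ae), "TsparseMatrix")
  A <- methods::as(altCounts(ae), "TsparseMatrix")
  tot <- methods::as(refCounts(ae) + altCounts(ae), "TsparseMatrix")
  su <- Matrix::summary(tot)
  su <- su[su$x > 0, , drop = FALSE]
  idx <- cbind(su$i, su$j)
  rr <- rowRanges(ae)
  df <- data.frame(cellId = colnames(ae)[su$j],
                   chrom = as.character(seqnames(rr))[su$i],
                   pos = start(rr)[su$i],
                   ref = mcols(rr)$ref[su$i], alt = mcols(rr)$alt[su$i],
                   refCount = as.integer(refCounts(ae)[idx]),
                   altCount = as.integer(altCounts(ae)[idx]))
  df <- df[order(df$cellId, df$chrom, df$pos), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write SNPs as VCF
#'
#' Het SNPs are exchanged as VCF 4.x records. Allele counts travel in INFO
#' fields \code{RC}/\code{AC} (reference/alternate read counts) and the
#' phase, when present, in \code{SEGID} (owning segment) and \code{MAJOR}
#' (\code{REF} or \code{ALT}: which allele is the major one). Reading
#' recovers whatever subset of those fields the file carries.
#'
#' @param path file path.
#' @return \code{readSNPVcf}: a \code{GRanges} with \code{ref}, \code{alt}
#'   and any of \code{refCount}, \code{altCount}, \code{segId},
#'   \code{majorIsAlt}.
#' @export
readSNPVcf <- function(path) {
  v <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- VariantAnnotation::alt(v)
  altChar <- vapply(seq_along(alt),
                    function(i) as.character(alt[[i]][1]), character(1))
  g <- GRanges(normalizeChrom(seqnames(rr)), IRanges::ranges(rr),
               ref = as.character(VariantAnnotation::ref(v)), alt = altChar)
  info <- VariantAnnotation::info(v)
  if ("RC" %in% colnames(info)) mcols(g)$refCount <- as.integer(info$RC)
  if ("AC" %in% colnames(info)) mcols(g)$altCount <- as.integer(info$AC)
  if ("SEGID" %in% colnames(info)) {
    segId <- as.character(info$SEGID)
    segId[segId %in% c("NA", ".")] <- NA_character_
    mcols(g)$segId <- segId
  }
  if ("MAJOR" %in% colnames(info)) {
    mj <- as.character(info$MAJOR)
    mcols(g)$majorIsAlt <- ifelse(mj %in% c("REF", "ALT"), mj == "ALT", NA)
  }
  names(g) <- NULL
  g
}

#' @rdname readSNPVcf
#' @param snps SNP \code{GRanges} to write.
#' @export
writeSNPVcf <- function(snps, path) {
  rr <- GenomicRanges::granges(snps)
  names(rr) <- sprintf("snp%06d", seq_along(rr))
  fixed <- DataFrame(
    REF = Biostrings::DNAStringSet(mcols(snps)$ref),
    ALT = Biostrings::DNAStringSetList(as.list(mcols(snps)$alt)),
    QUAL = rep(NA_real_, length(snps)),
    FILTER = rep("PASS", length(snps)))
  infoCols <- list()
  hdrRows <- list()
  addInfo <- function(name, values, type, desc) {
    infoCols[[name]] <<- values
    hdrRows[[name]] <<- data.frame(Number = "1", Type = type,
                                   Description = desc,
                                   row.names = name)
  }
  if (!is.null(mcols(snps)$refCount))
    addInfo("RC", as.integer(mcols(snps)$refCount), "Integer",
            "Reference allele read count")
  if (!is.null(mcols(snps)$altCount))
    addInfo("AC", as.integer(mcols(snps)$altCount), "Integer",
            "Alternate allele read count")
  if (!is.null(mcols(snps)$segId))
    addInfo("SEGID", as.character(mcols(snps)$segId), "String",
            "Owning copy-number segment")
  if (!is.null(mcols(snps)$majorIsAlt))
    addInfo("MAJOR", ifelse(is.na(mcols(snps)$majorIsAlt), ".",
                            ifelse(mcols(snps)$majorIsAlt, "ALT", "REF")),
            "String", "Which allele is on the major haplotype")
  info <- if (length(infoCols)) DataFrame(infoCols)
          else DataFrame(row.names = names(rr))
  vcf <- VariantAnnotation::VCF(rowRanges = rr, fixed = fixed, info = info,
                                collapsed = TRUE)
  hdr <- VariantAnnotation::header(vcf)
  # htslib requires ##fileformat as the first header line
  VariantAnnotation::meta(hdr) <- IRanges::DataFrameList(
    META = DataFrame(Value = "VCFv4.2", row.names = "fileformat"))
  if (length(hdrRows))
    VariantAnnotation::info(hdr) <-
      methods::as(do.call(rbind, unname(hdrRows)), "DataFrame")
  VariantAnnotation::header(vcf) <- hdr
  VariantAnnotation::writeVcf(vcf, path)
  # writeVcf can emit meta lines before ##fileformat; htslib-based readers
  # require it on line 1, so reorder and deduplicate the meta block
  lines <- readLines(path)
  metaIdx <- grep("^##", lines)
  meta <- unique(lines[metaIdx])
  ff <- grepl("^##fileformat=", meta)
  lines <- c(meta[ff], meta[!ff], lines[-metaIdx])
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a gene model
#'
#' \code{writeGeneModel} writes gene and exon features as GTF;
#' \code{readGeneModel} reads GTF (gene/exon features with \code{gene_id})
#' or BED12 (blocks become exons) via \pkg{rtracklayer} into the
#' \code{list(genes, exons)} shape used by \code{\link{annotateSNPs}}.
#'
#' @param path file path (.gtf/.gff or .bed).
#' @return \code{readGeneModel}: list of \code{genes}/\code{exons}
#'   \code{GRanges} with a \code{gene} mcol.
#' @export
readGeneModel <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading gene models requires the rtracklayer package")
  g <- rtracklayer::import(path)
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    genes <- GRanges(normalizeChrom(seqnames(g)), IRanges::ranges(g),
                     gene = mcols(g)$name)
    bl <- rtracklayer::blocks(g)
    exons <- unlist(bl, use.names = FALSE)
    exons <- GRanges(normalizeChrom(seqnames(exons)),
                     IRanges::ranges(exons),
                     gene = rep(mcols(g)$name, lengths(bl)))
    return(list(genes = sort(genes), exons = sort(exons)))
  }
  type <- as.character(mcols(g)$type)
  gid <- mcols(g)$gene_id
  mk <- function(sel) {
    GRanges(normalizeChrom(seqnames(g)[sel]), IRanges::ranges(g)[sel],
            gene = gid[sel])
  }
  list(genes = sort(mk(type == "gene")), exons = sort(mk(type == "exon")))
}

#' @rdname readGeneModel
#' @param geneModel list with \code{genes} and \code{exons} \code{GRanges}.
#' @export
writeGeneModel <- function(geneModel, path) {
  line <- function(gr, feat) {
    sprintf("%s\tallelicCall\t%s\t%d\t%d\t.\t+\t.\tgene_id \"%s\";",
            as.character(seqnames(gr)), feat, start(gr), end(gr),
            mcols(gr)$gene)
  }
  writeLines(c(line(geneModel$genes, "gene"),
               line(geneModel$exons, "exon")), path)
  invisible(path)
}

#' Read / write cell calls
#'
#' TSV mirror of the calls \code{DataFrame} produced by
#' \code{\link{cancerPosterior}}.
#'
#' @param path file path.
#' @return \code{readCalls}: a \code{DataFrame}.
#' @export
readCalls <- function(path) {
  DataFrame(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname readCalls
#' @param calls calls \code{DataFrame} to write.
#' @export
writeCalls <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
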