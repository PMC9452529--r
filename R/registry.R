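#' Genome registries
#'
#' A genome registry is a \code{\link[GenomeInfoDb]{Seqinfo}}: an ordered set
#' of chromosome names with lengths. Chromosome names are normalized
#' internally to the prefix-free style ("1", not "chr1"); see
#' \code{\link{normalizeChrom}}.
#'
#' \code{genomeRegistry} builds one from a named length vector;
#' \code{readGenomeRegistry} reads a two-column \code{chrom<TAB>length} TSV or
#' a FASTA index (\code{.fai}, first two columns used);
#' \code{grch37Registry} returns the GRCh37 autosomes + X/Y;
#' \code{toyRegistry} returns a small synthetic genome used by the simulator.
#'
#' @param lengths named numeric vector of chromosome lengths in bases.
#' @return a \code{Seqinfo}.
#' @examples
#' toyRegistry()
#' sum(GenomeInfoDb::seqlengths(grch37Registry())) / 1e6  # ~3096 Mb
#' @export
genomeRegistry <- function(lengths) {
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("chromosome lengths must be named")
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  Seqinfo(seqnames = normalizeChrom(names(lengths)),
          seqlengths = as.integer(lengths))
}

#' @rdname genomeRegistry
#' @param path path to a registry TSV or FASTA .fai file.
#' @export
readGenomeRegistry <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("registry file needs at least two columns")
  # tolerate an optional header line
  if (is.character(df[[2]])) {
    df <- df[-1, , drop = FALSE]
    df[[2]] <- as.numeric(df[[2]])
  }
  genomeRegistry(stats::setNames(df[[2]], df[[1]]))
}

#' @rdname genomeRegistry
#' @export
writeGenomeRegistry <- function(registry, path) {
  utils::write.table(
    data.frame(chrom = seqnames(registry),
               length = unname(seqlengths(registry))),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# GRCh37/hg19 chromosome lengths (bases)
.grch37 <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566)

#' @rdname genomeRegistry
#' @export
grch37Registry <- function() genomeRegistry(.grch37)

#' @rdname genomeRegistry
#' @param nChrom,chromLength number and common length of toy chromosomes.
#' @export
toyRegistry <- function(nChrom = 3, chromLength = 100e6) {
  genomeRegistry(stats::setNames(rep(chromLength, nChrom),
                                 as.character(seq_len(nChrom))))
}

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix so that mixed "chr1"/"1" inputs meet on a
#' single internal dialect. \code{denormalizeChrom} re-applies the prefix for
#' UCSC-style output.
#'
#' @param x character vector of chromosome names.
#' @return character vector.
#' @examples
#' normalizeChrom(c("chr1", "1", "chrX"))
#' @export
normalizeChrom <- function(x) sub("^chr", "", as.character(x))

#' @rdname normalizeChrom
#' @export
denormalizeChrom <- function(x) paste0("chr", normalizeChrom(x))

#' Informative-read density over a genome
#'
#' Converts a mean per-cell count of reads covering heterozygous SNPs into
#' reads per megabase of genome: the quantity that sets how large a
#' copy-number change must be before a single transcriptome can reveal it.
#' At the typical droplet-based depth of ~1522 SNP-covering reads per cell,
#' the density over the human genome is ~0.5 reads/Mb.
#'
#' @param readsPerCell mean number of SNP-covering reads per cell.
#' @param registry genome registry (default GRCh37).
#' @return reads per megabase (numeric scalar).
#' @examples
#' informativeReadDensity(1522)  # ~0.49, i.e. 0.5 reads/Mb
#' @export
informativeReadDensity <- function(readsPerCell, registry = grch37Registry()) {
  readsPerCell / (sum(as.numeric(seqlengths(registry))) / 1e6)
}
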