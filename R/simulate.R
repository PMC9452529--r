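#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults define
#' a study-scale scenario: a 3 x 100 Mb toy genome, a clonal cancer genotype
#' with a 30 Mb copy-neutral LoH on chromosome 1 plus a 50 Mb single-copy
#' arm gain on chromosome 2, and droplet-scale depth of on average 1522
#' SNP-covering reads per cell with negative-binomial spread. Allele counts
#' follow the generative assumptions of the classifier: per-gene ASE ratios
#' drawn from a mean-0.5 beta, site-class read errors, and beta-binomial
#' (transcriptional-burst) overdispersion.
#'
#' @param seed integer seed; fully determines all outputs.
#' @param registry genome registry (\code{Seqinfo}).
#' @param segments clonal cancer-genotype segments.
#' @param subcloneSegments extra segments carried only by subclone cells.
#' @param snpDensity het SNPs per Mb of genome (placed within gene bodies).
#' @param genesPerMb gene density per Mb.
#' @param meanGeneLength mean generated gene length (bases, log-normal).
#' @param exonFraction fraction of each gene body that is exonic.
#' @param imprintedFraction fraction of genes flagged imprinted.
#' @param nCancer,nNormal,nSubclone cell counts per clone.
#' @param meanInformativeReads mean SNP-covering reads per cell.
#' @param depthDispersion negative-binomial size of per-cell read totals.
#' @param epsilon named error rates by site class.
#' @param aseSpread beta concentration for true per-gene ASE ratios.
#' @param phi true beta-binomial overdispersion.
#' @param tumourPurity tumour DNA purity in (0, 1].
#' @param dnaDepth mean bulk DNA depth per site.
#' @return a list of class \code{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 7, nCancer = 50, nNormal = 50)
#' @export
simConfig <- function(seed = 1,
                      registry = toyRegistry(),
                      segments = CopyNumberSegments(
                        chrom = c("1", "2"), start = c(10e6 + 1, 1),
                        end = c(40e6, 50e6), nMajor = c(2L, 2L),
                        nMinor = c(0L, 1L)),
                      subcloneSegments = NULL,
                      snpDensity = 10, genesPerMb = 7,
                      meanGeneLength = 2e4, exonFraction = 0.3,
                      imprintedFraction = 0.01,
                      nCancer = 300, nNormal = 300, nSubclone = 0,
                      meanInformativeReads = 1522, depthDispersion = 2,
                      epsilon = c(exonic = 0.01, intronic = 0.05),
                      aseSpread = 30, phi = 0.05,
                      tumourPurity = 1, dnaDepth = 40) {
  stopifnot(nCancer >= 0, nNormal >= 0, nSubclone >= 0,
            snpDensity >= 0, genesPerMb >= 0,
            exonFraction > 0, exonFraction <= 1,
            phi > 0, phi < 1, aseSpread > 0,
            tumourPurity > 0, tumourPurity <= 1)
  structure(list(seed = as.integer(seed), registry = registry,
                 segments = segments, subcloneSegments = subcloneSegments,
                 snpDensity = snpDensity, genesPerMb = genesPerMb,
                 meanGeneLength = meanGeneLength,
                 exonFraction = exonFraction,
                 imprintedFraction = imprintedFraction,
                 nCancer = nCancer, nNormal = nNormal,
                 nSubclone = nSubclone,
                 meanInformativeReads = meanInformativeReads,
                 depthDispersion = depthDispersion, epsilon = epsilon,
                 aseSpread = aseSpread, phi = phi,
                 tumourPurity = tumourPurity, dnaDepth = dnaDepth),
            class = "SimConfig")
}

#' Simulate the genomic reference of a study
#'
#' Generates, deterministically under the config seed: a gene model (genes
#' with exon blocks), heterozygous SNP positions placed uniformly within
#' gene bodies at the configured density, per-SNP ref/alt alleles, the
#' haplotype truth (whether the alternate allele lies on the haplotype that
#' is major in altered segments), and the imprinted-gene list. SNPs come
#' annotated (gene, site class, imprinted).
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{registry}, \code{geneModel} (list of
#'   \code{genes}/\code{exons} \code{GRanges}), \code{snps} (annotated
#'   \code{GRanges} with \code{truthAltOnMajor}), \code{segments},
#'   \code{subcloneSegments}, \code{imprintedGenes}.
#' @export
simulateReference <- function(cfg) {
  set.seed(cfg$seed)
  reg <- cfg$registry
  chroms <- as.character(seqnames(reg))
  lens <- seqlengths(reg)
  genes <- list(); exons <- list()
  gid <- 0L
  for (chr in chroms) {
    nG <- round(cfg$genesPerMb * lens[[chr]] / 1e6)
    if (nG < 1) next
    gl <- pmax(2000, round(stats::rlnorm(nG, log(cfg$meanGeneLength), 0.5)))
    gs <- sort(sample.int(lens[[chr]] - max(gl), nG))
    nm <- sprintf("gene%05d", gid + seq_len(nG))
    gid <- gid + nG
    genes[[chr]] <- GRanges(chr, IRanges(gs, width = gl), gene = nm)
    # exons: exonFraction of the gene body split into a few blocks
    ex <- lapply(seq_len(nG), function(i) {
      nEx <- 1L + stats::rpois(1, 3)
      w <- max(50, round(gl[i] * cfg$exonFraction / nEx))
      st <- sort(sample.int(max(1L, gl[i] - w), nEx, replace = TRUE))
      es <- gs[i] + st - 1L
      ee <- pmin(es + w - 1L, gs[i] + gl[i] - 1L)
      IRanges::reduce(IRanges(es, ee))
    })
    exons[[chr]] <- GRanges(chr, unlist(IRanges::IRangesList(ex)),
                            gene = rep(nm, vapply(ex, length, 1L)))
  }
  geneModel <- if (gid > 0)
    list(genes = sort(unlist(GenomicRanges::GRangesList(genes),
                             use.names = FALSE)),
         exons = sort(unlist(GenomicRanges::GRangesList(exons),
                             use.names = FALSE)))
  else NULL
  imprinted <- character(0)
  if (!is.null(geneModel) && cfg$imprintedFraction > 0) {
    gn <- mcols(geneModel$genes)$gene
    imprinted <- sample(gn, max(0, round(length(gn) * cfg$imprintedFraction)))
  }
  # SNPs uniform within gene bodies
  snps <- GRanges()
  if (!is.null(geneModel)) {
    parts <- list()
    for (chr in chroms) {
      nS <- round(cfg$snpDensity * lens[[chr]] / 1e6)
      g <- geneModel$genes[seqnames(geneModel$genes) == chr]
      if (nS < 1 || !length(g)) next
      gi <- sample(length(g), nS, replace = TRUE,
                   prob = as.numeric(width(g)))
      pos <- start(g)[gi] +
        floor(stats::runif(nS) * as.numeric(width(g)[gi]))
      pos <- sort(unique(pmin(pos, lens[[chr]])))
      parts[[chr]] <- GRanges(chr, IRanges(pos, width = 1))
    }
    if (length(parts)) {
      snps <- unlist(GenomicRanges::GRangesList(parts), use.names = FALSE)
      bases <- c("A", "C", "G", "T")
      refIdx <- sample.int(4, length(snps), replace = TRUE)
      altOff <- sample.int(3, length(snps), replace = TRUE)
      mcols(snps)$ref <- bases[refIdx]
      mcols(snps)$alt <- bases[(refIdx + altOff - 1L) %% 4L + 1L]
      snps <- annotateSNPs(snps, geneModel, imprinted)
      mcols(snps)$truthAltOnMajor <-
        stats::rbinom(length(snps), 1, 0.5) == 1
    }
  } else {
    warning("no genes generated: zero genic SNPs")
  }
  # warn when an altered segment captured no SNPs
  if (length(snps) && length(cfg$segments)) {
    nPer <- GenomicRanges::countOverlaps(cfg$segments, snps)
    if (any(nPer == 0))
      warning(sum(nPer == 0), " segment(s) contain no SNPs at this density")
  }
  list(registry = reg, geneModel = geneModel, snps = snps,
       segments = cfg$segments, subcloneSegments = cfg$subcloneSegments,
       imprintedGenes = imprinted)
}

# effective tumour-DNA major-allele fraction per SNP, mixing purity and
# (for subclonal states) the cell fraction carrying the state
.tumourMajorFraction <- function(snps, segments, purity) {
  f <- rep(0.5, length(snps))
  if (!length(segments)) return(f)
  hits <- findOverlaps(snps, segments, select = "first",
                       ignore.strand = TRUE)
  hit <- !is.na(hits)
  seg <- segments[hits[hit]]
  cf <- mcols(seg)$cellFraction
  nMaj <- mcols(seg)$nMajor; nMin <- mcols(seg)$nMinor
  effMajor <- purity * (cf * nMaj + (1 - cf) * 1) + (1 - purity) * 1
  effTotal <- purity * (cf * (nMaj + nMin) + (1 - cf) * 2) + (1 - purity) * 2
  f[hit] <- effMajor / effTotal
  f
}

#' Simulate bulk DNA allele counts
#'
#' Produces normal-DNA and tumour-DNA site counts at the reference's SNPs:
#' normal counts are binomial around BAF 0.5; tumour counts are binomial
#' around the purity-adjusted major-allele fraction of the containing
#' segment, directed by the per-SNP haplotype truth. Deterministic under
#' the config seed.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param ref output of \code{\link{simulateReference}}.
#' @param purity tumour purity (defaults to the config value).
#' @param depth mean site depth (defaults to the config value).
#' @return list of site-count \code{GRanges}: \code{normal}, \code{tumour}.
#' @export
simulateBulkDNA <- function(cfg, ref, purity = cfg$tumourPurity,
                            depth = cfg$dnaDepth) {
  if (purity <= 0 || purity > 1) stop("purity must lie in (0, 1]")
  set.seed(cfg$seed + 1L)
  snps <- ref$snps
  nS <- length(snps)
  dN <- stats::rpois(nS, depth)
  dT <- stats::rpois(nS, depth)
  altN <- stats::rbinom(nS, dN, 0.5)
  segs <- ref$segments
  if (!is.null(ref$subcloneSegments))  # disjoint seqlevels are expected here
    segs <- suppressWarnings(c(segs, ref$subcloneSegments))
  fMaj <- .tumourMajorFraction(snps, segs, purity)
  pAlt <- ifelse(mcols(snps)$truthAltOnMajor, fMaj, 1 - fMaj)
  altT <- stats::rbinom(nS, dT, pAlt)
  mk <- function(d, alt) {
    s <- snps
    mcols(s) <- DataFrame(ref = mcols(snps)$ref, alt = mcols(snps)$alt,
                          refCount = as.integer(d - alt),
                          altCount = as.integer(alt))
    s
  }
  list(normal = mk(dN, altN), tumour = mk(dT, altT))
}

#' Simulate single-cell allele counts
#'
#' Generates per-cell ref/alt counts mirroring the classifier's generative
#' model: per-cell totals are negative-binomial around the configured mean;
#' reads scatter over SNPs proportionally to a log-normal per-gene
#' expression weight; per SNP, major-allele counts are beta-binomial with
#' mean given by the cell clone's segment fraction, the gene's true ASE
#' ratio and the site-class error rate, at the true overdispersion.
#' Orientation back to ref/alt follows the haplotype truth. Deterministic
#' under the config seed.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param ref output of \code{\link{simulateReference}}.
#' @return list with \code{ae} (an unoriented \code{\link{AlleleExperiment}}
#'   whose \code{colData} carries the true \code{clone}) and \code{truth}
#'   (list: per-cell \code{clone}, per-gene \code{rho} and \code{weight},
#'   \code{phi}).
#' @export
simulateCells <- function(cfg, ref) {
  set.seed(cfg$seed + 2L)
  snps <- ref$snps
  nS <- length(snps)
  if (!nS) stop("reference contains no SNPs")
  genes <- unique(mcols(snps)$gene)
  w <- stats::setNames(stats::rlnorm(length(genes), 0, 1), genes)
  a <- cfg$aseSpread / 2
  rho <- stats::setNames(
    pmin(pmax(stats::rbeta(length(genes), a, a), 1e-4), 1 - 1e-4), genes)
  wSnp <- unname(w[mcols(snps)$gene])
  eps <- cfg$epsilon[mcols(snps)$siteClass]
  eps[is.na(eps)] <- max(cfg$epsilon)
  rhoSnp <- unname(rho[mcols(snps)$gene])

  clones <- c(rep("cancer", cfg$nCancer), rep("subclone", cfg$nSubclone),
              rep("normal", cfg$nNormal))
  nC <- length(clones)
  if (!nC) stop("no cells configured")
  cellIds <- sprintf("cell%05d", seq_len(nC))

  fBy <- function(segs) {
    f <- rep(0.5, nS)
    if (is.null(segs) || !length(segs)) return(f)
    hits <- findOverlaps(snps, segs, select = "first", ignore.strand = TRUE)
    hit <- !is.na(hits)
    f[hit] <- majorAlleleFraction(segs)[hits[hit]]
    f
  }
  fClonal <- fBy(ref$segments)
  fSub <- fClonal
  if (!is.null(ref$subcloneSegments)) {
    fExtra <- fBy(ref$subcloneSegments)
    fSub[fExtra != 0.5] <- fExtra[fExtra != 0.5]
  }
  rList <- list(
    normal = expectedAllelicRatio(0.5, rhoSnp, unname(eps)),
    cancer = expectedAllelicRatio(fClonal, rhoSnp, unname(eps)),
    subclone = expectedAllelicRatio(fSub, rhoSnp, unname(eps)))

  totals <- stats::rnbinom(nC, mu = cfg$meanInformativeReads,
                           size = cfg$depthDispersion)
  ti <- tj <- tc <- vector("list", nC)
  for (c_ in seq_len(nC)) {
    if (totals[c_] == 0) next
    tab <- tabulate(sample.int(nS, totals[c_], replace = TRUE, prob = wSnp),
                    nbins = nS)
    nz <- which(tab > 0)
    ti[[c_]] <- nz
    tj[[c_]] <- rep.int(c_, length(nz))
    tc[[c_]] <- tab[nz]
  }
  i <- unlist(ti); j <- unlist(tj); cnt <- unlist(tc)
  r <- rList[["normal"]][i]
  for (cl in c("cancer", "subclone")) {
    sel <- clones[j] == cl
    r[sel] <- rList[[cl]][i[sel]]
  }
  theta <- (1 - cfg$phi) / cfg$phi
  p <- if (cfg$phi < 1e-8) r
       else stats::rbeta(length(cnt), r * theta, (1 - r) * theta)
  major <- stats::rbinom(length(cnt), cnt, pmin(pmax(p, 0), 1))
  aom <- mcols(snps)$truthAltOnMajor[i]
  altC <- ifelse(aom, major, cnt - major)
  refC <- cnt - altC
  mkMat <- function(x) Matrix::sparseMatrix(i = i, j = j, x = x,
                                            dims = c(nS, nC))
  ae <- AlleleExperiment(ref = mkMat(refC), alt = mkMat(altC), snps = snps,
                         colData = DataFrame(clone = clones,
                                             row.names = cellIds))
  list(ae = ae,
       truth = list(clone = stats::setNames(clones, cellIds),
                    rho = rho, weight = w, phi = cfg$phi))
}

#' Write a complete simulated input bundle to disk
#'
#' Runs \code{\link{simulateReference}}, \code{\link{simulateBulkDNA}} and
#' \code{\link{simulateCells}} and writes every pipeline input as plain
#' text: genome registry, segments, het-SNP VCF, bulk normal/tumour site
#' counts, long-format per-cell counts, the gene model (GTF), the imprinted
#' list, and the truth tables. Rerunning with the same config is
#' byte-identical.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of file paths.
#' @export
simulateDataset <- function(cfg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ref <- simulateReference(cfg)
  bulk <- simulateBulkDNA(cfg, ref)
  cells <- simulateCells(cfg, ref)
  p <- list(
    registry = file.path(dir, "registry.tsv"),
    segments = file.path(dir, "segments.tsv"),
    subcloneSegments = file.path(dir, "segments_subclone.tsv"),
    snps = file.path(dir, "snps.vcf"),
    bulkNormal = file.path(dir, "bulk_normal.tsv"),
    bulkTumour = file.path(dir, "bulk_tumour.tsv"),
    cellCounts = file.path(dir, "cell_counts.tsv"),
    geneModel = file.path(dir, "genes.gtf"),
    imprinted = file.path(dir, "imprinted.txt"),
    truthCells = file.path(dir, "truth_cells.tsv"),
    truthGenes = file.path(dir, "truth_genes.tsv"))
  writeGenomeRegistry(ref$registry, p$registry)
  writeSegments(ref$segments, p$segments)
  if (!is.null(ref$subcloneSegments))
    writeSegments(ref$subcloneSegments, p$subcloneSegments)
  else p$subcloneSegments <- NULL
  writeSNPVcf(ref$snps, p$snps)
  writeSiteCounts(bulk$normal, p$bulkNormal)
  writeSiteCounts(bulk$tumour, p$bulkTumour)
  writeCellCounts(cells$ae, p$cellCounts)
  writeGeneModel(ref$geneModel, p$geneModel)
  writeLines(ref$imprintedGenes, p$imprinted)
  utils::write.table(
    data.frame(cellId = names(cells$truth$clone),
               clone = unname(cells$truth$clone)),
    p$truthCells, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(cells$truth$rho),
               rho = unname(cells$truth$rho),
               weight = unname(cells$truth$weight)),
    p$truthGenes, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(p)
}
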