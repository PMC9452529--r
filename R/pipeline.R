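#' Run the allelic-imbalance genotyping workflow end to end
#'
#' The four-step workflow: (1) call usable heterozygous SNPs from normal
#' DNA; (2) phase them within copy-number-altered segments using tumour DNA
#' BAF; (3) annotate, filter and orient the per-cell counts to major/minor;
#' (4) calibrate the model (per-gene ASE and overdispersion from normal
#' cells when given) and compute each cell's posterior probability of
#' carrying the cancer genotype.
#'
#' Inputs may be in-memory objects or file paths (segments TSV, site-count
#' TSVs, long cell-count TSV, GTF/BED gene model, one-symbol-per-line
#' imprinted list).
#'
#' @param cellCounts \code{\link{AlleleExperiment}} or cell-counts TSV path.
#' @param segments segment \code{GRanges} or segments TSV path; used both
#'   for phasing (uneven segments) and as the cancer genotype hypothesis.
#' @param normalDNA,tumourDNA site-count \code{GRanges} or TSV paths of
#'   bulk allele counts at candidate SNPs.
#' @param geneModel \code{list(genes, exons)} or gene-model file path;
#'   \code{NULL} leaves sites unannotated (they are then all filtered out).
#' @param registry genome registry (\code{Seqinfo}) or registry TSV path;
#'   optional, used for validation only.
#' @param imprintedGenes character vector or file path.
#' @param normalCells barcodes of known normal cells for calibration
#'   (\code{NULL}: no ASE fit, configured \code{phi} used as-is).
#' @param excludeGenes genes excluded from genotyping (default HLA/HB).
#' @param bafLow,bafHigh,fdr het-calling and phasing parameters.
#' @param aseSpread ASE prior spread or \code{"fit"}.
#' @param highCountThreshold gene total for the spread fit.
#' @param epsilon site-class error rates.
#' @param phi fallback overdispersion when no normal cells are given.
#' @param threshHi,threshLo posterior thresholds for labels.
#' @param verbose print per-stage progress.
#' @return list with \code{calls} (DataFrame), \code{model}
#'   (\code{\link{AlleleModel}}), \code{hypothesis}, \code{phased}
#'   (phased-SNP \code{GRanges}), \code{ae} (the filtered, oriented
#'   experiment) and \code{summary} (label counts and read depth).
#' @export
runPipeline <- function(cellCounts, segments, normalDNA, tumourDNA,
                        geneModel = NULL, registry = NULL,
                        imprintedGenes = character(), normalCells = NULL,
                        excludeGenes = defaultExcludedGenes(),
                        bafLow = 0.2, bafHigh = 0.8, fdr = 0.05,
                        aseSpread = 10, highCountThreshold = 400,
                        epsilon = c(exonic = 0.01, intronic = 0.05),
                        phi = 0.05, threshHi = 0.99, threshLo = 0.01,
                        verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  if (is.character(registry) && length(registry) == 1)
    registry <- readGenomeRegistry(registry)
  if (is.character(segments)) segments <- readSegments(segments, registry)
  if (is.character(normalDNA)) normalDNA <- readSiteCounts(normalDNA)
  if (is.character(tumourDNA)) tumourDNA <- readSiteCounts(tumourDNA)
  if (is.character(geneModel)) geneModel <- readGeneModel(geneModel)
  if (is.character(imprintedGenes) && length(imprintedGenes) == 1 &&
      file.exists(imprintedGenes))
    imprintedGenes <- readLines(imprintedGenes)
  if (is.character(cellCounts)) cellCounts <- readCellCounts(cellCounts)
  if (!ncol(cellCounts))
    stop("stage counts: the cell-counts input contains no cells")

  say("stage hets: calling heterozygous SNPs from normal DNA")
  het <- callHetSNPs(normalDNA, bafLow = bafLow, bafHigh = bafHigh,
                     fdr = fdr)
  if (!length(het)) stop("stage hets: no usable heterozygous SNPs")
  say("  ", length(het), " het SNPs of ", length(normalDNA), " candidates")

  say("stage phase: phasing SNPs in uneven copy-number segments")
  key <- function(g) paste(seqnames(g), start(g), mcols(g)$ref,
                           mcols(g)$alt, sep = ":")
  tum <- tumourDNA[key(tumourDNA) %in% key(het)]
  uneven <- segments[mcols(segments)$nMajor != mcols(segments)$nMinor]
  if (!length(uneven))
    stop("stage phase: no segments with uneven copy number")
  phased <- phaseSNPs(tum, uneven, fdr = fdr)
  if (!length(phased)) stop("stage phase: no SNPs could be phased")
  say("  ", length(phased), " phased SNPs in ", length(uneven),
      " segment(s)")

  say("stage counts: annotating, filtering and orienting cell counts")
  ae <- cellCounts
  ae <- annotateSNPs2(ae, geneModel, imprintedGenes)
  ae <- filterSNPs(ae, excludeGenes = excludeGenes)
  if (!nrow(ae)) stop("stage counts: every SNP was filtered out")
  ae <- addPhase(ae, phased)
  ae <- orientCounts(ae)
  say("  ", nrow(ae), " SNPs x ", ncol(ae), " cells after filtering")

  say("stage calibrate: error / ASE / overdispersion")
  model <- AlleleModel(epsilon = epsilon, phi = phi)
  if (!is.null(normalCells)) {
    model <- fitASE(ae, normalCells, spread = aseSpread,
                    highCountThreshold = highCountThreshold, model = model)
    model <- fitOverdispersion(ae, normalCells, model = model)
    say("  phi = ", signif(overdispersion(model), 3), ", ",
        length(aseRatios(model)), " genes with fitted ASE")
  } else {
    say("  no normal cells given: rho = 0.5, phi = ", phi)
  }

  say("stage call: posterior probability of the cancer genotype")
  hyp <- genotypeHypothesis(segments)
  calls <- cancerPosterior(ae, hyp, model, threshHi = threshHi,
                           threshLo = threshLo)
  tab <- table(factor(calls$label,
                      levels = c("cancer", "normal", "unassigned")))
  summary <- list(
    labelCounts = tab,
    meanInformativeReads = mean(calls$nInformativeReads),
    nHetSNPs = length(het), nPhasedSNPs = length(phased))
  say("  ", paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                  collapse = ", "))
  list(calls = calls, model = model, hypothesis = hyp, phased = phased,
       ae = ae, summary = summary)
}

# annotate the experiment's rowRanges in place (helper around annotateSNPs)
annotateSNPs2 <- function(ae, geneModel, imprintedGenes) {
  rowRanges(ae) <- annotateSNPs(rowRanges(ae), geneModel, imprintedGenes)
  ae
}
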