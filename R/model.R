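#' Expected allelic ratio at a SNP
#'
#' The expected fraction of reads from the major allele at a SNP, given the
#' major-haplotype copy fraction \eqn{f} of its segment, the gene's
#' allele-specific expression ratio \eqn{\rho} (0.5 for no ASE) and the
#' site-class error rate \eqn{\epsilon}:
#' \deqn{r(f) = \frac{f\rho}{f\rho + (1-f)(1-\rho)} (1 - 2\epsilon) +
#'   \epsilon}
#' so that \eqn{r} is squeezed into \eqn{[\epsilon, 1-\epsilon]} by errors.
#'
#' @param f major-allele copy fraction in (0, 1].
#' @param rho ASE ratio in (0, 1).
#' @param eps error rate in [0, 0.5).
#' @return expected major-allele read fraction (vectorized over arguments).
#' @examples
#' expectedAllelicRatio(0.5, 0.5, 0)    # 0.5: diploid, no ASE, no error
#' expectedAllelicRatio(1, 0.5, 0.01)   # 0.99: LoH at error rate 1%
#' expectedAllelicRatio(2/3, 0.5, 0)    # 2/3: single-copy gain
#' @export
expectedAllelicRatio <- function(f, rho, eps) {
  if (any(f <= 0 | f > 1)) stop("f must lie in (0, 1]")
  if (any(rho <= 0 | rho >= 1)) stop("rho must lie in (0, 1)")
  if (any(eps < 0 | eps >= 0.5)) stop("eps must lie in [0, 0.5)")
  inner <- f * rho / (f * rho + (1 - f) * (1 - rho))
  inner * (1 - 2 * eps) + eps
}

#' Beta-binomial log-likelihood of a SNP's allele counts
#'
#' Log-probability of observing \code{m} major and \code{n} minor reads from
#' a beta-binomial with mean \code{r} and overdispersion \code{phi}
#' (concentration \eqn{\theta = (1-\phi)/\phi}):
#' \deqn{\log\binom{m+n}{m} + \log B(m + r\theta,\; n + (1-r)\theta) -
#'   \log B(r\theta,\; (1-r)\theta)}
#' computed in log space via log-gamma. Zero-coverage observations
#' (\code{m + n = 0}) contribute 0 (the empty-product convention). As
#' \eqn{\phi \to 0} the distribution approaches the binomial.
#'
#' @param m,n non-negative integer counts of major / minor reads
#'   (vectorized).
#' @param r expected major-allele fraction in (0, 1).
#' @param phi overdispersion in (0, 1).
#' @return log-likelihood (numeric, vectorized).
#' @examples
#' snpLogLikelihood(1, 0, 0.8, 0.3)            # log(0.8) for any phi
#' exp(snpLogLikelihood(1, 1, 0.5, 0.5))       # 0.25
#' @export
snpLogLikelihood <- function(m, n, r, phi) {
  if (any(r <= 0 | r >= 1)) stop("r must lie in (0, 1)")
  if (any(phi <= 0 | phi >= 1)) stop("phi must lie in (0, 1)")
  theta <- (1 - phi) / phi
  a <- r * theta
  b <- (1 - r) * theta
  lchoose(m + n, m) + lbeta(m + a, n + b) - lbeta(a, b)
}

#' Calibrate site-class error rates from homozygous-reference sites
#'
#' At sites homozygous for the reference allele, every non-reference read is
#' an error; the per-class error rate is the pooled non-reference read
#' fraction. Classes without data fall back to the supplied defaults (0.01
#' exonic, 0.05 intronic) with a warning.
#'
#' @param homRefSites \code{GRanges} of known homozygous-reference sites with
#'   mcols \code{siteClass}, \code{refCount} and \code{altCount} (non-reference
#'   reads); \code{NULL} returns the defaults.
#' @param defaults named fallback error rates.
#' @return named numeric vector of error rates per site class.
#' @export
calibrateError <- function(homRefSites = NULL,
                           defaults = c(exonic = 0.01, intronic = 0.05)) {
  eps <- defaults
  if (is.null(homRefSites) || !length(homRefSites)) return(eps)
  cls <- mcols(homRefSites)$siteClass
  nonref <- tapply(mcols(homRefSites)$altCount, cls, sum)
  tot <- tapply(mcols(homRefSites)$refCount + mcols(homRefSites)$altCount,
                cls, sum)
  for (k in names(defaults)) {
    if (!k %in% names(tot) || tot[[k]] == 0) {
      warning("no homozygous-reference reads for class '", k,
              "'; using default ", defaults[[k]])
    } else {
      e <- nonref[[k]] / tot[[k]]
      if (e >= 0.5) {
        warning("degenerate error estimate for class '", k,
                "' (", signif(e, 3), "); using default")
      } else eps[[k]] <- e
    }
  }
  eps
}

# expected ratio per SNP row of an AlleleExperiment for fraction f,
# looking up rho by gene and eps by site class
.rowRatios <- function(ae, f, model) {
  rr <- mcols(rowRanges(ae))
  eps <- errorRates(model)[rr$siteClass]
  eps[is.na(eps)] <- max(errorRates(model))  # unknown class: conservative
  rho <- aseRatios(model)[rr$gene]
  rho[is.na(rho)] <- 0.5
  expectedAllelicRatio(f, unname(rho), unname(eps))
}

# nonzero (snp, cell, m, n) observations of an oriented AlleleExperiment
.obs <- function(ae, cells = NULL) {
  if (!is.null(cells)) ae <- ae[, cells]
  M <- majorCounts(ae); N <- minorCounts(ae)
  su <- Matrix::summary(methods::as(M + N, "TsparseMatrix"))
  su <- su[su$x > 0, , drop = FALSE]
  idx <- cbind(su$i, su$j)
  list(snp = su$i, cell = su$j, m = as.vector(M[idx]), n = as.vector(N[idx]),
       nCells = ncol(ae))
}

#' Fit per-gene allele-specific expression from normal cells
#'
#' Aggregates major/minor counts per gene across normal cells and updates a
#' mean-0.5 beta prior on the gene's ASE ratio \eqn{\rho} by conjugacy: with
#' prior \eqn{Beta(c/2, c/2)} (spread \eqn{c}) and gene totals \eqn{(M, N)},
#' the stored point estimate is the posterior mean \eqn{(M + c/2)/(M + N +
#' c)}. Genes with no normal-cell reads keep \eqn{\rho = 0.5}. With
#' \code{spread = "fit"}, the prior concentration is set to its maximum
#' likelihood value on the observed allele fractions of highly expressed
#' genes (total counts > \code{highCountThreshold}).
#'
#' @param ae an oriented, annotated \code{\link{AlleleExperiment}}.
#' @param normalCells barcodes (or indices) of known normal cells; when
#'   \code{NULL}, every \eqn{\rho} stays 0.5 with a warning.
#' @param spread prior concentration (positive number) or \code{"fit"}.
#' @param highCountThreshold minimum gene total for the spread fit.
#' @param model \code{\link{AlleleModel}} to update.
#' @return the updated \code{AlleleModel}.
#' @export
fitASE <- function(ae, normalCells = NULL, spread = 10,
                   highCountThreshold = 400, model = AlleleModel()) {
  if (is.null(normalCells) || !length(normalCells)) {
    warning("no normal cells given: both alleles considered equally likely ",
            "(rho = 0.5 for every gene)")
    model@rho <- stats::setNames(numeric(0), character(0))
    return(model)
  }
  sub <- ae[, normalCells]
  gene <- mcols(rowRanges(sub))$gene
  if (is.null(gene)) stop("SNPs lack gene annotation; run annotateSNPs()")
  M <- Matrix::rowSums(majorCounts(sub))
  N <- Matrix::rowSums(minorCounts(sub))
  keep <- !is.na(gene)
  Mg <- tapply(M[keep], gene[keep], sum)
  Ng <- tapply(N[keep], gene[keep], sum)
  tot <- Mg + Ng
  if (identical(spread, "fit")) {
    hi <- tot > highCountThreshold
    if (sum(hi) < 2) {
      warning("too few high-count genes to fit the prior spread; ",
              "keeping spread ", model@priorSpread)
      spread <- model@priorSpread
    } else {
      # shrunken fractions avoid log(0) at fully imbalanced genes
      p <- (Mg[hi] + 0.5) / (tot[hi] + 1)
      nll <- function(logc) {
        c2 <- exp(logc) / 2
        -sum(stats::dbeta(p, c2, c2, log = TRUE))
      }
      spread <- exp(stats::optimize(nll, c(log(0.01), log(1e5)))$minimum)
    }
  }
  pos <- tot > 0
  rho <- (Mg[pos] + spread / 2) / (tot[pos] + spread)
  # clamp away from the open-interval bounds
  rho <- pmin(pmax(rho, 1e-9), 1 - 1e-9)
  model@rho <- stats::setNames(as.numeric(rho), names(Mg)[pos])
  model@priorSpread <- as.numeric(spread)
  methods::validObject(model)
  model
}

#' Fit the beta-binomial overdispersion from normal cells
#'
#' Maximizes, over \eqn{\phi}, the summed \code{\link{snpLogLikelihood}} of
#' all per-cell SNP observations in normal cells, with the diploid
#' expectation \eqn{f = 0.5} and the previously calibrated error and ASE
#' values. The search is bounded in \code{interval}. With
#' \code{marginalizeASE = TRUE} the per-gene likelihood is averaged over
#' draws from the ASE posterior instead of plugging in the posterior mean
#' (this typically changes nothing and is off by default).
#'
#' @param ae oriented, annotated \code{\link{AlleleExperiment}}.
#' @param normalCells barcodes/indices of normal cells; \code{NULL} returns
#'   the model unchanged with a warning (set \eqn{\phi} manually, or pass all
#'   cells explicitly — fitting across non-normal cells inflates the
#'   overdispersion and makes downstream calls more conservative).
#' @param model \code{\link{AlleleModel}} carrying error rates and ASE.
#' @param interval search bounds for \eqn{\phi}.
#' @param marginalizeASE average the likelihood over the ASE posterior.
#' @param nDraws posterior draws when marginalizing.
#' @return the updated \code{AlleleModel}.
#' @export
fitOverdispersion <- function(ae, normalCells = NULL, model = AlleleModel(),
                              interval = c(1e-6, 1 - 1e-6),
                              marginalizeASE = FALSE, nDraws = 20) {
  if (is.null(normalCells) || !length(normalCells)) {
    warning("no normal cells given: keeping overdispersion phi = ",
            model@phi, " (set manually or fit across all cells)")
    return(model)
  }
  obs <- .obs(ae, normalCells)
  if (!length(obs$m)) {
    warning("no informative reads in normal cells; keeping phi = ", model@phi)
    return(model)
  }
  if (all(obs$m + obs$n == 1)) {
    warning("all normal-cell observations are single reads: the likelihood ",
            "is flat in phi; keeping phi = ", model@phi)
    return(model)
  }
  r <- .rowRatios(ae, 0.5, model)[obs$snp]
  if (marginalizeASE) {
    gene <- mcols(rowRanges(ae))$gene[obs$snp]
    eps <- errorRates(model)[mcols(rowRanges(ae))$siteClass[obs$snp]]
    eps[is.na(eps)] <- max(errorRates(model))
    nll <- function(phi) {
      ll <- 0
      for (d in seq_len(nDraws)) {
        rho <- .drawRho(gene, model)
        rd <- expectedAllelicRatio(0.5, rho, unname(eps))
        ll <- ll + sum(snpLogLikelihood(obs$m, obs$n, rd, phi)) / nDraws
      }
      -ll
    }
  } else {
    nll <- function(phi) -sum(snpLogLikelihood(obs$m, obs$n, r, phi))
  }
  model@phi <- stats::optimize(nll, interval, tol = 1e-7)$minimum
  model
}

# one posterior draw of rho per observation, by gene
.drawRho <- function(gene, model) {
  c2 <- model@priorSpread / 2
  u <- unique(gene[!is.na(gene)])
  draw <- stats::setNames(stats::rbeta(length(u), c2, c2), u)
  known <- names(model@rho)
  # genes with data: draw around the posterior mean with posterior spread
  hit <- u[u %in% known]
  if (length(hit)) {
    mu <- model@rho[hit]
    draw[hit] <- stats::rbeta(length(hit), mu * model@priorSpread,
                              (1 - mu) * model@priorSpread)
  }
  out <- draw[gene]
  out[is.na(out)] <- 0.5
  pmin(pmax(out, 1e-9), 1 - 1e-9)
}

#' Log-likelihood of a genotype hypothesis for each cell
#'
#' Sums the per-SNP beta-binomial log-likelihood over all SNPs inside the
#' hypothesis' segments, with each SNP's expected ratio derived from the
#' segment's major-allele fraction, the gene's ASE ratio and the site-class
#' error rate. SNPs outside every hypothesis segment are ignored: only
#' copy-number-changed regions inform the call.
#'
#' @param ae oriented, annotated \code{\link{AlleleExperiment}} whose
#'   \code{rowRanges} carry \code{segId} (see \code{\link{addPhase}}).
#' @param hyp a \code{\link{GenotypeHypothesis}}.
#' @param model an \code{\link{AlleleModel}}.
#' @return numeric vector: one log-likelihood per cell.
#' @export
genotypeLogLikelihood <- function(ae, hyp, model) {
  f <- hypothesisFractions(hyp)
  segId <- mcols(rowRanges(ae))$segId
  if (is.null(segId)) stop("rowRanges lack segId; run addPhase() first")
  inHyp <- !is.na(segId) & segId %in% names(f)
  out <- stats::setNames(rep(0, ncol(ae)), colnames(ae))
  if (!any(inHyp)) return(out)
  sub <- ae[inHyp, ]
  r <- .rowRatios(sub, unname(f[mcols(rowRanges(sub))$segId]), model)
  obs <- .obs(sub)
  if (!length(obs$m)) return(out)
  ll <- snpLogLikelihood(obs$m, obs$n, r[obs$snp], overdispersion(model))
  agg <- rowsum(ll, obs$cell)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Posterior probability that each cell carries the cancer genotype
#'
#' Compares the cancer hypothesis (each segment at its copy-number-implied
#' major fraction) to the matched normal hypothesis (\eqn{f = 0.5}
#' everywhere) with a flat prior:
#' \deqn{P(cancer \mid data) = \frac{P(data \mid cancer)}{P(data \mid
#'   cancer) + P(data \mid normal)}}
#' evaluated stably from the log-likelihood difference. Cells are labelled
#' \code{cancer} above \code{threshHi}, \code{normal} below \code{threshLo}
#' and \code{unassigned} otherwise; cells with no informative reads have
#' posterior exactly 0.5.
#'
#' @inheritParams genotypeLogLikelihood
#' @param cancerHyp the cancer \code{\link{GenotypeHypothesis}}.
#' @param threshHi,threshLo posterior thresholds for the cancer / normal
#'   labels.
#' @return a \code{DataFrame} with columns \code{cellId},
#'   \code{posteriorCancer}, \code{label}, \code{nInformativeReads},
#'   \code{logLikCancer}, \code{logLikNormal}.
#' @export
cancerPosterior <- function(ae, cancerHyp, model, threshHi = 0.99,
                            threshLo = 0.01) {
  llC <- genotypeLogLikelihood(ae, cancerHyp, model)
  llN <- genotypeLogLikelihood(ae, normalHypothesis(cancerHyp), model)
  post <- stats::plogis(llC - llN)
  lab <- ifelse(post > threshHi, "cancer",
                ifelse(post < threshLo, "normal", "unassigned"))
  f <- hypothesisFractions(cancerHyp)
  segId <- mcols(rowRanges(ae))$segId
  inHyp <- !is.na(segId) & segId %in% names(f)
  nInf <- Matrix::colSums(totalCounts(ae)[inHyp, , drop = FALSE])
  DataFrame(cellId = colnames(ae), posteriorCancer = unname(post),
            label = unname(lab), nInformativeReads = unname(nInf),
            logLikCancer = unname(llC), logLikNormal = unname(llN))
}

#' Assign cells between two clones from their distinguishing segments
#'
#' Computes the two-hypothesis posterior restricted to the segments on which
#' the clones differ (a segment absent from one hypothesis is taken as
#' balanced there, \eqn{f = 0.5}). Cells exceeding \code{threshHi} are
#' assigned to the first clone (\code{subclone}), cells below
#' \code{threshLo} to the second (\code{major-clone}); everything else is
#' \code{ambiguous} — including cells with no reads on the distinguishing
#' segments.
#'
#' @inheritParams genotypeLogLikelihood
#' @param subcloneHyp,majorHyp the two clone hypotheses.
#' @param threshHi,threshLo posterior thresholds.
#' @return a \code{DataFrame} with \code{cellId}, \code{posteriorSubclone},
#'   \code{label}.
#' @export
assignSubclones <- function(ae, subcloneHyp, majorHyp, model,
                            threshHi = 0.99, threshLo = 0.01) {
  fA <- hypothesisFractions(subcloneHyp)
  fB <- hypothesisFractions(majorHyp)
  segs <- union(names(fA), names(fB))
  a <- ifelse(segs %in% names(fA), fA[segs], 0.5)
  b <- ifelse(segs %in% names(fB), fB[segs], 0.5)
  diff <- segs[a != b]
  if (!length(diff))
    stop("clone hypotheses are identical on all segments")
  hA <- methods::new("GenotypeHypothesis", name = "subclone",
                     f = stats::setNames(a[match(diff, segs)], diff))
  hB <- methods::new("GenotypeHypothesis", name = "major-clone",
                     f = stats::setNames(b[match(diff, segs)], diff))
  llA <- genotypeLogLikelihood(ae, hA, model)
  llB <- genotypeLogLikelihood(ae, hB, model)
  post <- stats::plogis(llA - llB)
  lab <- ifelse(post > threshHi, "subclone",
                ifelse(post < threshLo, "major-clone", "ambiguous"))
  DataFrame(cellId = colnames(ae), posteriorSubclone = unname(post),
            label = unname(lab))
}
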