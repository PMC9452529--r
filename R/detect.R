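#' Minimum detectable loss of heterozygosity in a single transcriptome
#'
#' How large must a region of loss of heterozygosity (LoH, major fraction
#' \eqn{f = 1}) be before a single cell's allele counts can distinguish it
#' from the heterozygous state (\eqn{f = 0.5}) at a stated accuracy, given a
#' density of informative reads per megabase? A region of length \eqn{L}
#' megabases yields \eqn{n = L \times} \code{readsPerMb} reads; the
#' calculator finds the smallest \eqn{n} meeting the accuracy requirement
#' under the chosen interpretation and converts back to megabases.
#'
#' "Accuracy" admits several formalizations, exposed as modes:
#' \describe{
#'   \item{\code{"balanced"} (default)}{a binomial read-allele model with
#'     major-read probability \eqn{1-\epsilon} for the LoH cell and 0.5 for
#'     the heterozygous cell, classified at the maximum-likelihood
#'     threshold; requires the mean of the two per-class error rates to be
#'     at most \eqn{1 - accuracy}. With the default exonic error rate
#'     \eqn{\epsilon = 0.01} this gives 10 reads, i.e. 20 Mb at 0.5
#'     reads/Mb.}
#'   \item{\code{"posterior"}}{requires that a cell whose reads all support
#'     the major allele reaches a flat-prior posterior of at least
#'     \code{accuracy} for the LoH hypothesis: smallest \eqn{n} with
#'     \eqn{((1-\epsilon)/0.5)^n > accuracy/(1-accuracy)}. With
#'     \eqn{\epsilon = 0} this is \eqn{2^n > 99} at 99\%, i.e. 7 reads /
#'     14 Mb: a lower bound for the other modes.}
#'   \item{\code{"betabinomial"}}{as \code{"balanced"} but with
#'     beta-binomial read counts at overdispersion \code{phi}, for
#'     sensitivity analysis of the binomial assumption.}
#' }
#'
#' @param readsPerMb informative reads per megabase per cell (default 0.5,
#'   the density implied by ~1522 SNP-covering reads over the human genome).
#' @param accuracy required accuracy in (0.5, 1).
#' @param mode interpretation of "accuracy"; see Details.
#' @param epsilon read error rate (default: the exonic rate 0.01).
#' @param phi overdispersion for \code{mode = "betabinomial"}.
#' @param integerReads require a whole number of reads (default); when
#'   \code{FALSE} the read requirement is interpolated continuously.
#' @param maxReads search bound.
#' @return region length in megabases, with attributes \code{reads} (the
#'   read requirement) and \code{mode}.
#' @examples
#' minDetectableLoH()                                     # 20 Mb
#' minDetectableLoH(mode = "posterior", epsilon = 0)      # 14 Mb
#' @export
minDetectableLoH <- function(readsPerMb = 0.5, accuracy = 0.99,
                             mode = c("balanced", "posterior",
                                      "betabinomial"),
                             epsilon = 0.01, phi = 0.05,
                             integerReads = TRUE, maxReads = 10000) {
  mode <- match.arg(mode)
  if (readsPerMb <= 0) stop("readsPerMb must be positive")
  if (accuracy <= 0.5 || accuracy >= 1)
    stop("accuracy must lie in (0.5, 1)")
  r <- 1 - epsilon
  if (r <= 0.5) stop("epsilon must be < 0.5")
  n <- if (mode == "posterior") {
    # all-major data: posterior odds (r/0.5)^n must exceed acc/(1-acc)
    nCont <- log(accuracy / (1 - accuracy)) / log(r / 0.5)
    if (integerReads) {
      nInt <- ceiling(nCont)
      if ((r / 0.5)^nInt <= accuracy / (1 - accuracy)) nInt <- nInt + 1
      nInt
    } else nCont
  } else {
    err <- function(k) {
      if (mode == "balanced") .balancedError(k, r)
      else .balancedErrorBB(k, r, phi)
    }
    nInt <- NA
    for (k in seq_len(maxReads)) {
      if (err(k) <= 1 - accuracy) { nInt <- k; break }
    }
    if (is.na(nInt)) stop("no read count up to ", maxReads,
                          " reaches the requested accuracy")
    if (integerReads || nInt == 1L) nInt
    else {
      e0 <- err(nInt - 1L); e1 <- err(nInt)
      (nInt - 1L) + (e0 - (1 - accuracy)) / (e0 - e1)
    }
  }
  structure(n / readsPerMb, reads = n, mode = mode)
}

# mean of the two error rates of the ML-threshold classifier for
# Binomial(n, r) vs Binomial(n, 0.5); r > 0.5 so the likelihood ratio is
# increasing in the major-read count and the ML rule is a cut-off
.balancedError <- function(n, r) {
  k <- 0:n
  cancer <- stats::dbinom(k, n, r)
  normal <- stats::dbinom(k, n, 0.5)
  t <- which(cancer > normal)[1]  # first k (1-based index) called cancer
  if (is.na(t)) return(0.5)
  0.5 * (sum(cancer[seq_len(t - 1)]) + sum(normal[t:(n + 1)]))
}

.balancedErrorBB <- function(n, r, phi) {
  k <- 0:n
  cancer <- exp(snpLogLikelihood(k, n - k, r, phi))
  normal <- exp(snpLogLikelihood(k, n - k, 0.5, phi))
  t <- which(cancer > normal)[1]
  if (is.na(t)) return(0.5)
  0.5 * (sum(cancer[seq_len(t - 1)]) + sum(normal[t:(n + 1)]))
}
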