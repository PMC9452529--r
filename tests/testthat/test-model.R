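test_that("expected allelic ratio evaluates the error/ASE-adjusted fraction", {
  expect_equal(expectedAllelicRatio(0.5, 0.5, 0), 0.5)
  expect_equal(expectedAllelicRatio(1, 0.5, 0.01), 0.99)
  expect_equal(expectedAllelicRatio(2 / 3, 0.5, 0), 2 / 3)
  # with rho = 0.5 the inner term reduces to f itself
  f <- runif(20, 0.01, 1)
  expect_equal(expectedAllelicRatio(f, 0.5, 0), f)
  expect_error(expectedAllelicRatio(0, 0.5, 0), "f must")
  expect_error(expectedAllelicRatio(0.5, 1, 0), "rho must")
  expect_error(expectedAllelicRatio(0.5, 0.5, 0.5), "eps must")
})

test_that("beta-binomial log-likelihood matches closed forms", {
  # a single read carries probability r regardless of overdispersion
  for (phi in c(0.01, 0.3, 0.9))
    expect_equal(snpLogLikelihood(1, 0, 0.8, phi), log(0.8))
  # m=1, n=1, r=0.5, phi=0.5: theta=1, 2 * B(1.5,1.5)/B(0.5,0.5) = 0.25
  expect_equal(exp(snpLogLikelihood(1, 1, 0.5, 0.5)), 0.25)
  # zero coverage contributes log(1) = 0
  expect_equal(snpLogLikelihood(0, 0, 0.3, 0.2), 0)
})

test_that("beta-binomial likelihood normalizes and has the binomial limit", {
  for (N in c(1, 5, 13, 30)) {
    for (r in c(0.1, 0.5, 0.9)) {
      for (phi in c(0.05, 0.5, 0.9)) {
        total <- sum(exp(snpLogLikelihood(0:N, N:0, r, phi)))
        expect_equal(total, 1, tolerance = 1e-8)
      }
    }
  }
  for (r in c(0.1, 0.5, 0.9)) {
    for (m in c(0, 3, 20)) {
      for (n in c(0, 2, 20)) {
        expect_equal(snpLogLikelihood(m, n, r, 1e-8),
                     dbinom(m, m + n, r, log = TRUE), tolerance = 1e-4)
      }
    }
  }
})

test_that("error calibration pools non-reference read fractions by class", {
  sites <- GRanges("1", IRanges::IRanges(c(100, 200), width = 1),
                   siteClass = c("exonic", "intronic"),
                   refCount = c(198L, 95L), altCount = c(2L, 5L))
  eps <- calibrateError(sites)
  expect_equal(unname(eps["exonic"]), 0.01)
  expect_equal(unname(eps["intronic"]), 0.05)
  expect_equal(calibrateError(NULL), c(exonic = 0.01, intronic = 0.05))
  onlyEx <- sites[1]
  expect_warning(eps2 <- calibrateError(onlyEx), "intronic")
  expect_equal(unname(eps2["intronic"]), 0.05)
})

test_that("ASE fitting is the conjugate beta update of gene totals", {
  major <- matrix(c(800, 500, 0), ncol = 1)
  minor <- matrix(c(200, 500, 0), ncol = 1)
  ae <- aeFromMajorMinor(major, minor, gene = c("gA", "gB", "gC"))
  m <- fitASE(ae, normalCells = 1, spread = 10)
  # prior Beta(5,5): posterior mean (800+5)/(1000+10)
  expect_equal(unname(aseRatios(m)["gA"]), 805 / 1010)
  expect_equal(unname(aseRatios(m)["gB"]), 0.5, tolerance = 0.01)
  # a gene with no reads keeps the prior mean implicitly
  expect_false("gC" %in% names(aseRatios(m)))
  expect_warning(m0 <- fitASE(ae, normalCells = NULL), "no normal cells")
  expect_length(aseRatios(m0), 0)
})

test_that("the fitted ASE prior spread tracks the dispersion of gene fractions", {
  set.seed(21)
  nG <- 200
  rho <- rbeta(nG, 15, 15)  # concentration 30
  tot <- rep(1000L, nG)
  maj <- rbinom(nG, tot, rho)
  ae <- aeFromMajorMinor(matrix(maj, ncol = 1), matrix(tot - maj, ncol = 1),
                         gene = sprintf("g%03d", seq_len(nG)))
  m <- fitASE(ae, normalCells = 1, spread = "fit")
  expect_gt(asePriorSpread(m), 15)
  expect_lt(asePriorSpread(m), 60)
})

test_that("overdispersion fitting recovers the truth and detects the binomial limit", {
  set.seed(31)
  # binomial data (phi -> 0): fitted phi must be near zero
  nObs <- 10000
  m <- rbinom(nObs, 10, 0.5)
  ae <- aeFromMajorMinor(matrix(m, ncol = 1), matrix(10 - m, ncol = 1),
                         gene = "g1")
  fit <- fitOverdispersion(ae, normalCells = 1)
  expect_lt(overdispersion(fit), 0.02)
  # beta-binomial at phi = 0.2, depth 20, 5000 observations
  phi <- 0.2; theta <- (1 - phi) / phi
  p <- rbeta(5000, 0.5 * theta, 0.5 * theta)
  m2 <- rbinom(5000, 20, p)
  ae2 <- aeFromMajorMinor(matrix(m2, ncol = 1), matrix(20 - m2, ncol = 1),
                          gene = "g1")
  fit2 <- fitOverdispersion(ae2, normalCells = 1)
  expect_gt(overdispersion(fit2), 0.15)
  expect_lt(overdispersion(fit2), 0.25)
  # a lone single-read observation is uninformative about phi
  ae3 <- aeFromMajorMinor(matrix(1), matrix(0), gene = "g1")
  expect_warning(fit3 <- fitOverdispersion(ae3, normalCells = 1), "flat")
  expect_equal(overdispersion(fit3), overdispersion(AlleleModel()))
})

test_that("cell posteriors match the closed-form binomial ratio", {
  segs <- CopyNumberSegments("1", 1, 1e6, nMajor = 2, nMinor = 0)
  hyp <- genotypeHypothesis(segs)
  model <- AlleleModel(epsilon = c(exonic = 0.01, intronic = 0.05),
                       phi = 1e-7)
  mkAE <- function(m, n) {
    aeFromMajorMinor(matrix(m), matrix(n), gene = "g1",
                     segId = segmentIds(segs), pos = 100)
  }
  # 20 major reads in an LoH segment: posterior 0.99^20/(0.99^20 + 0.5^20)
  calls <- cancerPosterior(mkAE(20, 0), hyp, model)
  expect_equal(calls$posteriorCancer, 0.99^20 / (0.99^20 + 0.5^20),
               tolerance = 1e-5)
  expect_equal(calls$label, "cancer")
  # 20 minor reads: posterior ~ (0.01/0.5)^20, label normal
  calls2 <- cancerPosterior(mkAE(0, 20), hyp, model)
  expect_equal(calls2$posteriorCancer, 0.01^20 / (0.01^20 + 0.5^20),
               tolerance = 1e-4)
  expect_equal(calls2$label, "normal")
  # no informative reads: posterior exactly 0.5, unassigned
  calls3 <- cancerPosterior(mkAE(0, 0), hyp, model)
  expect_equal(calls3$posteriorCancer, 0.5)
  expect_equal(calls3$label, "unassigned")
  expect_equal(calls3$nInformativeReads, 0)
})

test_that("the posterior is monotone in major and minor counts", {
  segs <- CopyNumberSegments("1", 1, 1e6, nMajor = 2, nMinor = 1)
  hyp <- genotypeHypothesis(segs)
  model <- AlleleModel(phi = 0.1)
  post <- function(m, n) {
    ae <- aeFromMajorMinor(matrix(m), matrix(n), gene = "g1",
                           segId = segmentIds(segs), pos = 100)
    cancerPosterior(ae, hyp, model)$posteriorCancer
  }
  p <- vapply(0:12, function(m) post(m, 4), 0)
  expect_true(all(diff(p) >= 0))
  q <- vapply(0:12, function(n) post(6, n), 0)
  expect_true(all(diff(q) <= 0))
})

test_that("two-hypothesis normalization holds exactly", {
  segs <- CopyNumberSegments("1", 1, 1e6, nMajor = 2, nMinor = 0)
  hyp <- genotypeHypothesis(segs)
  model <- AlleleModel(phi = 0.05)
  set.seed(41)
  for (rep in 1:10) {
    m <- rpois(1, 5); n <- rpois(1, 5)
    ae <- aeFromMajorMinor(matrix(m), matrix(n), gene = "g1",
                           segId = segmentIds(segs), pos = 100)
    llC <- genotypeLogLikelihood(ae, hyp, model)
    llN <- genotypeLogLikelihood(ae, normalHypothesis(hyp), model)
    pC <- plogis(llC - llN); pN <- plogis(llN - llC)
    expect_equal(unname(pC + pN), 1)
  }
})

test_that("subclone assignment uses only the distinguishing segments", {
  sub <- CopyNumberSegments("2", 1, 1e8, nMajor = 2, nMinor = 0)
  subHyp <- genotypeHypothesis(sub, "subclone")
  majHyp <- normalHypothesis(subHyp)
  model <- AlleleModel(epsilon = c(exonic = 1e-9, intronic = 1e-9),
                       phi = 1e-7)
  mkAE <- function(m, n) {
    aeFromMajorMinor(matrix(m), matrix(n), gene = "g1",
                     segId = segmentIds(sub), chrom = "2", pos = 100)
  }
  # 15 clean major reads: posterior 1/(1 + 0.5^15) > 0.99
  a <- assignSubclones(mkAE(15, 0), subHyp, majHyp, model)
  expect_equal(a$posteriorSubclone, 1 / (1 + 0.5^15), tolerance = 1e-5)
  expect_equal(a$label, "subclone")
  # 4 vs 3 reads at a realistic error rate: inside the ambiguous band
  noisier <- AlleleModel(epsilon = c(exonic = 0.05, intronic = 0.05),
                         phi = 1e-7)
  b <- assignSubclones(mkAE(4, 3), subHyp, majHyp, noisier)
  expect_equal(b$posteriorSubclone,
               (0.95^4 * 0.05^3) / (0.95^4 * 0.05^3 + 0.5^7),
               tolerance = 1e-4)
  expect_equal(b$label, "ambiguous")
  # no reads on the distinguishing chromosome: ambiguous
  d <- assignSubclones(mkAE(0, 0), subHyp, majHyp, model)
  expect_equal(d$posteriorSubclone, 0.5)
  expect_equal(d$label, "ambiguous")
  expect_error(assignSubclones(mkAE(1, 0), subHyp, subHyp, model),
               "identical")
})

test_that("the detectability calculator respects its modes and scaling", {
  # closed-form lower bound: minimal n with 2^n > 99 is 7, i.e. 14 Mb
  lo <- minDetectableLoH(mode = "posterior", epsilon = 0)
  expect_equal(as.numeric(lo), 14)
  expect_equal(attr(lo, "reads"), 7)
  # doubling the read density halves the length at fixed requirement
  expect_equal(as.numeric(minDetectableLoH(readsPerMb = 1)),
               as.numeric(minDetectableLoH(readsPerMb = 0.5)) / 2)
  # stricter accuracy demands a longer region
  expect_gt(as.numeric(minDetectableLoH(accuracy = 0.999)),
            as.numeric(minDetectableLoH(accuracy = 0.99)))
  # overdispersion can only make detection harder
  expect_gte(as.numeric(minDetectableLoH(mode = "betabinomial",
                                         phi = 0.05)),
             as.numeric(minDetectableLoH(mode = "balanced")))
  expect_error(minDetectableLoH(accuracy = 0.4), "accuracy")
  expect_error(minDetectableLoH(readsPerMb = 0), "readsPerMb")
})
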