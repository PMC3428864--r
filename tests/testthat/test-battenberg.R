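# Subclonal allele-specific copy number: haplotype-fraction equations,
# PCF segmentation, clonality testing and tau estimation.

test_that("clonalHf matches the closed form and its limits", {
  expect_equal(clonalHf(1, 1, 1), 0.5)
  expect_equal(clonalHf(0.7, 1, 0), 0.3 / 1.3)          # 0.2308 by hand
  expect_equal(clonalHf(0, 3, 1), 0.5)                  # pure normal
  expect_equal(clonalHf(0, 0, 0), 0.5)
})

test_that("clonalHf and alleleSpecificCN are exact inverses", {
  set.seed(8)
  for (i in 1:40) {
    rho <- runif(1, 0.05, 1)
    psi <- runif(1, 1.5, 4)
    nA <- sample(0:4, 1); nB <- sample(0:min(nA, 3), 1)
    if (nA + nB == 0) next
    hf <- clonalHf(rho, nA, nB)
    lR <- log2((rho * (nA + nB) + 2 * (1 - rho)) / psi)
    cn <- alleleSpecificCN(hf, lR, rho, psi)
    expect_equal(unname(cn["nA"]), nA, tolerance = 1e-9)
    expect_equal(unname(cn["nB"]), nB, tolerance = 1e-9)
  }
})

test_that("alleleSpecificCN handles pure-tumor and degenerate input", {
  expect_equal(unname(alleleSpecificCN(0.5, 0, 1, 2)), c(1, 1))
  expect_warning(cn <- alleleSpecificCN(0.5, -30, 0.7, 2), "clipped")
  expect_true(all(cn >= 0))
})

test_that("PCF returns one segment for a constant signal", {
  seg <- pcfSegment(rep(0.5, 100) + rnorm(100, 0, 1e-4))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$mean, 0.5, tolerance = 1e-3)
})

test_that("PCF finds a mid-signal step where exhaustive search does", {
  set.seed(3)
  x <- c(rnorm(60, 0.5, 0.01), rnorm(60, 0.34, 0.01))
  seg <- pcfSegment(x, penalty = 3)
  expect_equal(nrow(seg), 2L)
  # oracle: exhaustive single-breakpoint least squares
  sse <- vapply(2:(length(x) - 1), function(b)
    sum((x[1:b] - mean(x[1:b]))^2) +
      sum((x[(b + 1):length(x)] - mean(x[(b + 1):length(x)]))^2), numeric(1))
  expect_equal(seg$end[1], which.min(sse) + 1)
})

test_that("flipped haplotype blocks collapse onto one band after re-phasing", {
  # two blocks at 0.34 and 0.66 are the same state with switched labels
  set.seed(5)
  n <- 400
  block <- rep(c("b1", "b2"), each = n / 2)
  p <- ifelse(block == "b1", 0.34, 0.66)
  N <- rpois(n, 200)
  h1 <- rbinom(n, N, p)
  snps <- PhasedSNPSet("chr1", seq_len(n) * 1000L, h1, N - h1, block)
  segs <- phaseSwitchSegment(snps)
  expect_equal(length(segs), 1L)
  expect_lt(abs(segs[[1]]$hf - 0.34), 0.01)
})

test_that("clonality calls respect the t test and the minimum deviation", {
  rho <- 0.7; psi <- 2
  # exact clonal 1+0 state
  hfClonal <- clonalHf(rho, 1, 0)
  lR10 <- log2((rho * 1 + 2 * (1 - rho)) / psi)
  resExact <- testClonality(rep(hfClonal, 100), lR10, rho, psi)
  expect_equal(resExact$call, "clonal")
  expect_equal(unname(resExact$state), c(1, 0))
  # 0.05 away from every candidate with many tight SNPs: subclonal
  set.seed(2)
  frShift <- rnorm(500, hfClonal + 0.05, 0.005)
  lRmid <- log2((rho * 1.4 + 2 * (1 - rho)) / psi)
  resSub <- testClonality(frShift, lRmid, rho, psi)
  expect_equal(resSub$call, "subclonal")
  # oracle: the t statistic against the nearest state is overwhelming
  tstat <- abs(mean(frShift) - hfClonal) / (sd(frShift) / sqrt(500))
  expect_gt(tstat, 10)
  # below the minimum deviation: clonal regardless of p
  frTiny <- rnorm(500, hfClonal + 0.005, 0.001)
  expect_equal(testClonality(frTiny, lR10, rho, psi)$call, "clonal")
})

test_that("noise-free forward simulation inverts to the exact tau", {
  rho <- 0.8; psi <- 2
  # truth: 30% of tumor cells in (2,1), 70% in (1,1)
  tauTrue <- 0.3
  nAmix <- tauTrue * 2 + (1 - tauTrue) * 1
  nBmix <- 1
  hf <- clonalHf(rho, nAmix, nBmix)
  lR <- log2((rho * (nAmix + nBmix) + 2 * (1 - rho)) / psi)
  est <- estimateTau(rep(hf, 50), lR, rho, psi, nBoot = 10L)
  # state1 is reported as the lower-total state, so the (1,1) fraction is
  # 1 - tauTrue
  expect_equal(unname(est$state1), c(1, 1))
  expect_equal(unname(est$state2), c(2, 1))
  expect_equal(est$tau, 1 - tauTrue, tolerance = 1e-9)
})

test_that("a haplotype fraction at the clonal state gives tau at the boundary", {
  rho <- 0.7; psi <- 2
  hf <- clonalHf(rho, 1, 1)
  lR <- log2((rho * 2 + 2 * (1 - rho)) / psi) - 0.01  # barely below diploid
  est <- estimateTau(rep(hf, 50), lR, rho, psi, nBoot = 10L)
  expect_equal(unname(est$state2), c(1, 1))
  expect_equal(est$tau, 0, tolerance = 1e-6)
})

test_that("bootstrap CIs for tau achieve near-nominal coverage", {
  rho <- 0.7; psi <- 2; tauTrue <- 0.68
  hit <- vapply(1:20, function(s) {
    snps <- simulatePhasedChromosome(rho, tauTrue, c(1, 0), c(1, 1),
                                     nSnps = 1200L, depth = 100,
                                     seed = 100L + s)
    rp <- rephaseBlocks(snps)
    lR <- rp$logR[1]
    est <- estimateTau(rp$fraction, lR, rho, psi, nBoot = 250L, seed = s)
    est$ci[1] <= tauTrue && tauTrue <= est$ci[2]
  }, logical(1))
  expect_gte(mean(hit), 0.9)
})

test_that("purity fine-tuning recovers a perturbed estimate", {
  rhoTrue <- 0.712
  fractions <- rep(clonalHf(rhoTrue, 1, 0), 100)
  expect_equal(fineTunePurity(fractions, 1, 0, rho0 = 0.70), rhoTrue,
               tolerance = 5e-4)
})

test_that("the full pipeline recovers the chromosome-13-style deletion", {
  meta <- makeMeta(0.70, seed = 5L)
  snps <- simulatePhasedChromosome(rho = 0.70, tau = 0.68,
                                   state1 = c(1, 0), state2 = c(1, 1),
                                   nSnps = 5000L, depth = 188,
                                   blockLength = 3e5, seed = 5L)
  segs <- callSubclonalCN(snps, meta)
  expect_equal(length(segs), 1L)
  m <- S4Vectors::mcols(segs)
  expect_true(m$subclonal)
  expect_equal(c(m$nA1, m$nB1), c(1, 0))
  expect_equal(m$tau, 0.68, tolerance = 0.02 / 0.68)
  expect_lt(m$tauHi - m$tauLo, 0.05)
})

test_that("a balanced subclonal loss is flagged from depressed logR", {
  meta <- makeMeta(0.70, seed = 9L)
  # both parental copies lost in equal subclones: hf stays 0.5, logR drops
  snps <- simulatePhasedChromosome(rho = 0.70, tau = 1,
                                   state1 = c(0.8, 0.8), nSnps = 2000L,
                                   depth = 188, seed = 9L)
  segs <- callSubclonalCN(snps, meta)
  expect_false(any(S4Vectors::mcols(segs)$subclonal))
  expect_true(any(grepl("balanced subclonal loss",
                        S4Vectors::mcols(segs)$note)))
})
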