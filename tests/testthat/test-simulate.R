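# Synthetic-tumor generator: observation-model means, ground truth,
# reproducibility.

test_that("a single clone at 70% purity yields mean VAF near 0.35", {
  cfg <- simConfig(purity = 0.7, coverage = 210, cloneFractions = 1,
                   parents = 0L, mutationsPerClone = 2000L, seed = 3L)
  sim <- simulateTumor(cfg)
  mc <- S4Vectors::mcols(sim$mutations)
  expect_equal(mean(mc$altReads / mc$depth), 0.35, tolerance = 0.01 / 0.35)
})

test_that("zero mutations still produce valid segment and SNP tables", {
  cfg <- simConfig(mutationsPerClone = 0L, nSNPs = 200L, seed = 2L)
  sim <- simulateTumor(cfg)
  expect_equal(length(sim$mutations), 0L)
  expect_s4_class(sim$segments, "SegmentSet")
  expect_gt(length(sim$phasedSNPs), 0L)
})

test_that("VAF histogram modes sit at zeta * pi for each subclone", {
  # four components; mode locations have the closed form zeta * pi
  pis <- c(1, 0.6, 0.3, 0.2)
  cfg <- simConfig(purity = 0.7, coverage = 600,
                   cloneFractions = pis, parents = c(0L, 1L, 1L, 2L),
                   mutationsPerClone = 1500L, seed = 4L)
  sim <- simulateTumor(cfg)
  mc <- S4Vectors::mcols(sim$mutations)
  vaf <- mc$altReads / mc$depth
  d <- density(vaf, bw = 0.006)
  peaks <- d$x[which(diff(sign(diff(d$y))) == -2) + 1]
  expected <- 0.35 * pis
  for (e in expected)
    expect_lt(min(abs(peaks - e)), 0.01)
})

test_that("empirical VAF means converge to zeta * pi for every clone", {
  pis <- c(1, 0.5, 0.25)
  cfg <- simConfig(purity = 0.8, coverage = 150, cloneFractions = pis,
                   parents = c(0L, 1L, 2L), mutationsPerClone = 800L,
                   seed = 7L)
  sim <- simulateTumor(cfg)
  mc <- S4Vectors::mcols(sim$mutations)
  zeta <- expectedVAF(SampleMeta(0.8), 2)
  for (k in seq_along(pis)) {
    idx <- sim$truth$clone == k
    vaf <- mc$altReads[idx] / mc$depth[idx]
    se <- sd(vaf) / sqrt(sum(idx))
    expect_lt(abs(mean(vaf) - zeta * pis[k]), 3 * se + 1e-4)
  }
})

test_that("clone fractions violating the tree are rejected", {
  expect_error(
    simConfig(cloneFractions = c(1, 0.6, 0.5), parents = c(0L, 1L, 1L),
              mutationsPerClone = 10L),
    "tree inconsistent")
  expect_error(simConfig(cloneFractions = c(0.9)), "MRCA")
})

test_that("the simulation is reproducible from its seed", {
  cfg <- simConfig(cloneFractions = c(1, 0.5), parents = c(0L, 1L),
                   mutationsPerClone = 50L, seed = 11L)
  s1 <- simulateTumor(cfg)
  s2 <- simulateTumor(cfg)
  expect_identical(as.data.frame(s1$mutations), as.data.frame(s2$mutations))
  expect_identical(as.data.frame(s1$phasedSNPs), as.data.frame(s2$phasedSNPs))
  expect_identical(s1$truth, s2$truth)
})

test_that("phased chromosome: balanced diploid has mean fraction 0.5", {
  snps <- simulatePhasedChromosome(rho = 0.9, tau = 0, state1 = c(1, 0),
                                   state2 = c(1, 1), nSnps = 3000L,
                                   depth = 100, seed = 5L)
  m <- S4Vectors::mcols(snps)
  frac <- m$hap1Reads / (m$hap1Reads + m$hap2Reads)
  expect_equal(mean(frac), 0.5, tolerance = 0.01)
})

test_that("phased chromosome reproduces the mixture haplotype fraction", {
  # rho 0.7, tau 0.68 of 1+0 against 1+1: minor-band fraction 0.3438 by hand
  snps <- simulatePhasedChromosome(rho = 0.7, tau = 0.68, state1 = c(1, 0),
                                   state2 = c(1, 1), nSnps = 4000L,
                                   depth = 188, seed = 6L)
  m <- S4Vectors::mcols(snps)
  frac <- m$hap1Reads / (m$hap1Reads + m$hap2Reads)
  minor <- ifelse(frac > 0.5, 1 - frac, frac)
  expect_equal(mean(minor), 0.3438, tolerance = 0.01)
})

test_that("block length beyond the chromosome yields no switch-points", {
  snps <- simulatePhasedChromosome(rho = 0.7, tau = 1, state1 = c(2, 1),
                                   nSnps = 500L, depth = 100,
                                   blockLength = 1e10, seed = 8L)
  expect_equal(length(unique(S4Vectors::mcols(snps)$blockId)), 1L)
})

test_that("configured gain times shape the ploidy-2 fraction", {
  segs <- data.frame(chrom = "chr1", start = 1, end = 1e8, nA = 2, nB = 1,
                     gainClass = "trisomy_2+1", gainTime = 0.43)
  cfg <- simConfig(purity = 0.7, coverage = 150, cloneFractions = 1,
                   parents = 0L, mutationsPerClone = 3000L,
                   segments = segs, seed = 9L)
  sim <- simulateTumor(cfg)
  p2 <- mean(sim$truth$multiplicity == 2)
  expect_equal(p2, 0.43 / (3 - 0.43), tolerance = 0.1)
})
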