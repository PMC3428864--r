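# Gain timing in molecular time and spectrum comparison.

test_that("the trisomy worked example dates to 43% of molecular time", {
  t <- timeGain(n1 = 100, n2 = 20, gainClass = "trisomy_2+1")
  expect_equal(t, 20 / (20 + (100 - 20) / 3), tolerance = 1e-12)
  expect_equal(round(100 * t), 43)
})

test_that("timing limits behave as the formulas dictate", {
  expect_equal(timeGain(100, 0, "trisomy_2+1"), 0)   # gain before mutations
  expect_equal(timeGain(50, 50, "trisomy_2+1"), 1)   # all mutations pre-gain
  expect_equal(timeGain(100, 20, "UPD_2+0"), 20 / (20 + 50))
  expect_equal(timeGain(100, 20, "tetraploid_2+2"), 20 / (20 + 50))
  expect_error(timeGain(0, 0, "trisomy_2+1"), "undefined")
})

test_that("timeGain is scale-invariant", {
  for (g in c("trisomy_2+1", "UPD_2+0", "tetraploid_2+2"))
    expect_equal(timeGain(100, 20, g), timeGain(1000, 200, g))
})

test_that("multiplicity assignment follows the binomial likelihood", {
  meta <- makeMeta(0.70)
  # VAF exactly zeta: ploidy 1
  m1 <- MutationSet("chr1", 1L, "C", "T", depth = 200L, altReads = 70L,
                    tumorCN = 2)
  expect_equal(assignMultiplicity(m1, meta, maxMult = 2), "1")
  # trisomy 2+1 at rho 0.7: zeta = 0.7/(0.7*3+0.6) = 0.2593; VAF 0.52
  m2 <- MutationSet("chr1", 1L, "C", "T", depth = 200L, altReads = 104L,
                    tumorCN = 3)
  # oracle: explicit likelihood comparison at both multiplicities
  zeta <- 0.7 / (0.7 * 3 + 0.6)
  llm <- sapply(1:2, function(m) dbinom(104, 200, m * zeta, log = TRUE))
  expect_equal(which.max(llm), 2L)
  expect_equal(assignMultiplicity(m2, meta, maxMult = 2), "2")
  # VAF at half of zeta: below the 75% threshold, subclonal
  m3 <- MutationSet("chr1", 1L, "C", "T", depth = 200L, altReads = 35L,
                    tumorCN = 2)
  expect_equal(assignMultiplicity(m3, meta), "subclonal")
})

test_that("bootstrap timing brackets the point estimate", {
  labels <- rep(c("1", "2"), c(100, 20))
  bt <- bootstrapTiming(labels, "trisomy_2+1", nBoot = 2000L, seed = 3L)
  expect_equal(bt$t, 0.4285714, tolerance = 1e-6)
  expect_true(bt$ci[1] <= 0.43 && bt$ci[2] >= 0.43)
  expect_lt(diff(bt$ci), 0.35)
})

test_that("degenerate bootstrap cases collapse correctly", {
  all2 <- bootstrapTiming(rep("2", 30), "trisomy_2+1", nBoot = 100L)
  expect_equal(all2$ci, c(1, 1))
  one <- bootstrapTiming(rep(c("1", "2"), c(10, 5)), "trisomy_2+1",
                         nBoot = 1L, seed = 9L)
  expect_equal(one$ci[1], one$ci[2])
})

test_that("gain-time recovery from simulated tumors is nearly unbiased", {
  segs <- data.frame(chrom = "chr1", start = 1, end = 1e8, nA = 2, nB = 1,
                     gainClass = "trisomy_2+1", gainTime = 0.43)
  cfg <- simConfig(purity = 0.7, coverage = 200, cloneFractions = 1,
                   parents = 0L, mutationsPerClone = 500L, segments = segs,
                   seed = 31L)
  sim <- simulateTumor(cfg)
  meta <- makeMeta(0.7)
  plo <- assignMultiplicity(sim$mutations, meta, maxMult = 2)
  t <- timeGain(sum(plo == "1"), sum(plo == "2"), "trisomy_2+1")
  expect_lt(abs(t - 0.43), 0.05)
})

test_that("heterogeneity test separates synchronous from staggered gains", {
  expect_gt(heterogeneityTest(n1 = c(100, 100), n2 = c(20, 20)), 0.99)
  # oracle: chi-square on the 2x2 table by hand
  tab <- cbind(c(20, 100), c(100, 20))
  pHand <- suppressWarnings(chisq.test(tab))$p.value
  p <- heterogeneityTest(n1 = c(100, 20), n2 = c(20, 100))
  expect_equal(p, pHand)
  expect_lt(p, 0.001)
  expect_error(heterogeneityTest(100, 20), "single segment")
})

test_that("identical early and late spectra give chi2 0 and p 1", {
  early <- c(40, 10, 30, 5, 10, 5)
  cmp <- compareSpectra(early, early * 3)
  expect_equal(cmp$chi2, 0, tolerance = 1e-9)
  expect_equal(cmp$p, 1)
  expect_error(compareSpectra(rep(0, 6), early), "at least one")
})

test_that("a 40% vs 15% C>T shift is detected with high power", {
  pE <- c(0.12, 0.12, 0.40, 0.12, 0.12, 0.12)
  pL <- c(0.17, 0.17, 0.15, 0.17, 0.17, 0.17)
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    e <- as.vector(rmultinom(1, 500, pE))
    l <- as.vector(rmultinom(1, 500, pL))
    compareSpectra(e, l)$p < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("substitution classes are normalised to the pyrimidine strand", {
  muts <- MutationSet("chr1", 1:3, c("G", "A", "C"), c("A", "C", "T"),
                      depth = 10L, altReads = 5L, tumorCN = 2)
  expect_equal(as.character(substitutionClass(muts)),
               c("C>T", "T>G", "C>T"))
})

test_that("spectrumByTiming splits counts by ploidy class", {
  segs <- data.frame(chrom = "chr1", start = 1, end = 1e8, nA = 2, nB = 1,
                     gainClass = "trisomy_2+1", gainTime = 0.5)
  cfg <- simConfig(purity = 0.7, coverage = 200,
                   cloneFractions = c(1, 0.4), parents = c(0L, 1L),
                   mutationsPerClone = c(400L, 100L), segments = segs,
                   earlySpectrum = c(0.1, 0.1, 0.5, 0.1, 0.1, 0.1),
                   lateSpectrum = rep(1 / 6, 6), seed = 23L)
  sim <- simulateTumor(cfg)
  sp <- spectrumByTiming(sim$mutations, makeMeta(0.7), maxMult = 2)
  expect_gt(sum(sp$early), 0)
  expect_gt(sum(sp$late), 0)
  expect_gt(sum(sp$subclonal), 0)
  cmp <- compareSpectra(as.vector(sp$early), as.vector(sp$late))
  expect_lt(cmp$p, 0.05)
})
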