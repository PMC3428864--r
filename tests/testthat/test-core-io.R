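# Domain types and table I/O: field mapping, invariant enforcement,
# round-trip identity.

test_that("TSV mutation rows map directly onto MutationCall fields", {
  path <- writeTempTsv(c(
    "chrom\tpos\tref\talt\tdepth\talt_reads\ttumor_cn\tnormal_cn",
    "chr1\t1000\tA\tT\t210\t74\t2\t2"))
  muts <- readMutations(path)
  expect_s4_class(muts, "MutationSet")
  expect_equal(length(muts), 1L)
  expect_equal(S4Vectors::mcols(muts)$depth, 210L)
  expect_equal(S4Vectors::mcols(muts)$altReads, 74L)
  expect_equal(GenomicRanges::start(muts), 1000L)
})

test_that("VCF records with AD yield r and R by the AD convention", {
  path <- writeTempVcf("chr1\t1000\t.\tA\tT\t.\tPASS\t.\tGT:AD\t0/1:136,74")
  muts <- suppressWarnings(readMutations(path))
  expect_equal(S4Vectors::mcols(muts)$altReads, 74L)
  expect_equal(S4Vectors::mcols(muts)$depth, 210L)
})

test_that("records with more variant reads than depth are rejected", {
  path <- writeTempTsv(c(
    "chrom\tpos\tref\talt\tdepth\talt_reads",
    "chr1\t1000\tA\tT\t210\t300"))
  expect_error(readMutations(path), "exceed")
})

test_that("missing depth fields are an explicit error, never defaulted", {
  path <- writeTempTsv(c(
    "chrom\tpos\tref\talt\tdepth\talt_reads",
    "chr1\t1000\tA\tT\tNA\t10"))
  expect_error(readMutations(path), "missing depth")
  path2 <- writeTempTsv(c("chrom\tpos\tref\talt", "chr1\t1000\tA\tT"))
  expect_error(readMutations(path2), "missing required columns")
})

test_that("malformed numeric fields name the offending line", {
  path <- writeTempTsv(c(
    "chrom\tpos\tref\talt\tdepth\talt_reads",
    "chr1\t1000\tA\tT\t210\t74",
    "chr1\t2000\tA\tT\tbroken\t74"))
  expect_error(readMutations(path), "line 2")
})

test_that("mutation and segment tables round-trip identically", {
  segs <- SegmentSet(c("chr1", "chr13"), c(1L, 1L), c(5e7, 114e6),
                     logR = c(0, -0.39), nA = c(1, 1), nB = c(1, 0.32),
                     subclonal = c(FALSE, TRUE),
                     nA1 = c(NA, 1), nB1 = c(NA, 0),
                     nA2 = c(NA, 1), nB2 = c(NA, 1),
                     tau = c(NA, 0.68), tauLo = c(NA, 0.67),
                     tauHi = c(NA, 0.69))
  path <- tempfile(fileext = ".tsv")
  writeSegments(segs, path)
  back <- readSegments(path)
  expect_equal(as.data.frame(back), as.data.frame(segs))
  # 0-based half-open representation on disk
  onDisk <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(onDisk$start, c(0, 0))
  expect_equal(onDisk$end, c(5e7, 114e6))

  muts <- MutationSet("chr1", c(100L, 200L), c("C", "T"), c("A", "G"),
                      depth = c(50L, 60L), altReads = c(10L, 20L),
                      tumorCN = 2, context = c("ACA", "ATG"))
  mp <- tempfile(fileext = ".tsv")
  writeMutations(muts, mp)
  expect_equal(as.data.frame(readMutations(mp)), as.data.frame(muts))

  snps <- PhasedSNPSet("chr1", c(10L, 20L), c(30L, 40L), c(50L, 45L),
                       blockId = c("b0", "b1"), logR = 0.1)
  sp <- tempfile(fileext = ".tsv")
  writePhasedSNPs(snps, sp)
  expect_equal(as.data.frame(readPhasedSNPs(sp)), as.data.frame(snps))

  rp <- ReadPairEvidence(data.frame(chrom = "chr1", posA = 100L, posB = 400L,
                                    nBoth = 3L, nAOnly = 5L, nBOnly = 0L,
                                    nNeither = 40L))
  pp <- tempfile(fileext = ".tsv")
  writeReadPairs(rp, pp)
  expect_equal(as.data.frame(readReadPairs(pp)), as.data.frame(rp))
})

test_that("an empty segment table reads as an empty SegmentSet", {
  path <- writeTempTsv("chrom\tstart\tend\tlogr")
  expect_equal(length(readSegments(path)), 0L)
})

test_that("overlapping segments on one chromosome are an error", {
  expect_error(
    SegmentSet(c("chr1", "chr1"), c(1L, 100L), c(200L, 300L),
               nA = 1, nB = 1),
    "overlap")
})

test_that("annotateCopyNumber fills tumorCN and drops orphans with a count", {
  segs <- SegmentSet("chr1", 1L, 1000L, nA = 2, nB = 1)
  muts <- MutationSet("chr1", c(500L, 5000L), "C", "T",
                      depth = 100L, altReads = 30L)
  expect_message(ann <- annotateCopyNumber(muts, segs), "1 mutation")
  expect_equal(length(ann), 1L)
  expect_equal(S4Vectors::mcols(ann)$tumorCN, 3)
})

test_that("subclonal segments use the cell-fraction weighted copy number", {
  segs <- SegmentSet("chr13", 1L, 1000L, nA = 1, nB = 1, subclonal = TRUE,
                     nA1 = 1, nB1 = 0, nA2 = 1, nB2 = 1, tau = 0.68)
  expect_equal(segmentTotalCN(segs), 0.68 * 1 + 0.32 * 2)
})

test_that("SampleMeta enforces purity and ploidy ranges", {
  expect_error(SampleMeta(0), "purity")
  expect_error(SampleMeta(1.2), "purity")
  expect_error(SampleMeta(0.5, ploidy = -1), "ploidy")
  expect_equal(purity(SampleMeta(0.7)), 0.7)
})
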