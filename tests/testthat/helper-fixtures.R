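# Shared fixture builders: everything is generated in code at test time.

makeMeta <- function(purity = 0.70, ploidy = 2, seed = 1L) {
  SampleMeta(purity = purity, ploidy = ploidy, sampleId = "test", seed = seed)
}

# mutations drawn directly from the binomial observation model at fixed
# cluster fractions, bypassing the full simulator
makeClusteredMutations <- function(pis, counts, depth, meta,
                                   tumorCN = 2, seed = 1L) {
  set.seed(seed)
  pi <- rep(pis, counts)
  n <- length(pi)
  zeta <- expectedVAF(meta, tumorCN)
  N <- stats::rpois(n, depth)
  y <- stats::rbinom(n, N, zeta * pi)
  MutationSet("chr1", seq_len(n) * 1000L, "C", "T", N, y, tumorCN = tumorCN)
}

writeTempTsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# minimal single-sample VCF 4.2 with AD genotype field
writeTempVcf <- function(rows) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR",
    rows), path)
  path
}
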