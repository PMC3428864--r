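# Cancer-cell-fraction arithmetic.
#
# For a mutation with r variant reads out of R at a locus of tumor copy
# number etaT and normal copy number etaN, in a sample of purity rho, the
# fraction of tumor cells carrying the mutation (assuming one mutant copy
# per carrying cell) is
#     f = min(1, (r/R) * (rho*etaT + (1-rho)*etaN) / rho)
# and the expected variant read fraction of a fully clonal single-copy
# mutation is zeta = rho / (rho*etaT + (1-rho)*etaN).

#' Expected variant allele fraction
#'
#' Expected fraction of reads reporting a variant carried at multiplicity
#' \code{m} by a fraction \code{f} of tumor cells, at a locus of tumor copy
#' number \code{tumorCN} and normal copy number \code{normalCN} in a sample
#' of the given purity. With \code{m = 1}, \code{f = 1} this is \eqn{\zeta},
#' the clonal single-copy expectation.
#'
#' @param meta A \code{\link{SampleMeta}} (or a numeric purity).
#' @param tumorCN Locus total copy number in the tumor.
#' @param normalCN Locus copy number in the normal (default 2).
#' @param m Mutation multiplicity (copies per carrying cell), default 1.
#' @param f Fraction of tumor cells carrying the mutation, default 1.
#' @return Expected variant read fraction.
#' @examples
#' expectedVAF(SampleMeta(0.70), tumorCN = 2)   # 0.35, the clonal diploid VAF
#' @export
expectedVAF <- function(meta, tumorCN, normalCN = 2, m = 1, f = 1) {
  rho <- if (is(meta, "SampleMeta")) purity(meta) else as.numeric(meta)
  pmin(1, rho * m * f / (rho * tumorCN + (1 - rho) * normalCN))
}

#' Fraction of tumor cells carrying each mutation
#'
#' Computes, per mutation, the cancer cell fraction
#' \eqn{f = \min(1, (r/R)\,(\rho\eta_T + (1-\rho)\eta_N)/\rho)} and the
#' clonal single-copy read-fraction expectation
#' \eqn{\zeta = \rho/(\rho\eta_T + (1-\rho)\eta_N)}.
#'
#' @param muts A \code{\link{MutationSet}} with \code{tumorCN} filled (see
#'   \code{\link{annotateCopyNumber}}).
#' @param meta A \code{\link{SampleMeta}}.
#' @return data.frame with columns \code{f} and \code{zeta}, one row per
#'   mutation.
#' @examples
#' m <- MutationSet("chr1", 1000, "A", "T", depth = 210, altReads = 74,
#'                  tumorCN = 2)
#' cellFraction(m, SampleMeta(purity = 0.70))
#' @export
cellFraction <- function(muts, meta) {
  mc <- mcols(muts)
  if (any(mc$depth == 0))
    stop("cancer cell fraction is undefined for mutations with zero depth")
  if (anyNA(mc$tumorCN))
    stop("tumorCN is missing for some mutations; run annotateCopyNumber() first")
  rho <- purity(meta)
  denom <- rho * mc$tumorCN + (1 - rho) * mc$normalCN
  zeta <- rho / denom
  f <- pmin(1, (mc$altReads / mc$depth) / zeta)
  if (any(zeta <= 0 | zeta > 1))
    stop("zeta outside (0, 1]; check purity and copy numbers")
  data.frame(f = f, zeta = zeta)
}
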