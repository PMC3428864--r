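# Phasing of somatic mutations against nearby heterozygous germline SNPs,
# and classification of nearby subclonal mutation pairs from read-pair
# co-occurrence.

#' Phase a somatic mutation onto the deleted or retained parental copy
#'
#' Given the SNP allele linked to the mutation by spanning read pairs, tests
#' whether the fraction of tumor reads reporting that allele departs from the
#' baseline expectation (0.5 on a near-diploid chromosome) by a two-sided
#' binomial test. Significantly fewer reads places the mutation on the
#' subclonally deleted parental copy; significantly more on the retained
#' copy; otherwise the call defers to the block-level haplotype assignment if
#' one is supplied, else the mutation stays unphased.
#'
#' @param linkedReads Tumor reads reporting the SNP allele linked to the
#'   mutation.
#' @param otherReads Tumor reads reporting the other SNP allele.
#' @param baseline Expected linked-allele fraction under no deletion
#'   (default 0.5).
#' @param alpha Significance level of the binomial test (default 0.05).
#' @param blockAssignment Optional fallback from the wider imputed haplotype:
#'   \code{"deleted_copy"} or \code{"retained_copy"}.
#' @return List with \code{assignment} (\code{"deleted_copy"},
#'   \code{"retained_copy"} or \code{"unphased"}) and \code{p} (binomial
#'   test p value; NA with no spanning coverage).
#' @examples
#' phaseMutationToSNP(30, 170)   # 30/200 reads: deleted copy
#' @export
phaseMutationToSNP <- function(linkedReads, otherReads, baseline = 0.5,
                               alpha = 0.05, blockAssignment = NA_character_) {
  total <- linkedReads + otherReads
  if (total == 0) {
    assignment <- if (!is.na(blockAssignment)) blockAssignment else "unphased"
    return(list(assignment = assignment, p = NA_real_))
  }
  ht <- stats::binom.test(linkedReads, total, p = baseline,
                          alternative = "two.sided")
  frac <- linkedReads / total
  assignment <- if (ht$p.value < alpha) {
    if (frac < baseline) "deleted_copy" else "retained_copy"
  } else if (!is.na(blockAssignment)) {
    blockAssignment
  } else {
    "unphased"
  }
  list(assignment = assignment, p = ht$p.value)
}

#' Classify a nearby subclonal mutation pair from read-pair evidence
#'
#' Applies the existence rules for pairs of subclonal mutations spanned by
#' single read pairs. A pair is collinear (one mutation arose in a cell
#' already carrying the other) when at least \code{minSupport} read pairs
#' report both variants together AND at least \code{minSupport} pairs report
#' the earlier variant with the wild type of the other, with no pairs
#' reporting the reverse. A pair is mutually exclusive (the mutations sit in
#' completely independent subclones) when each variant is seen without the
#' other but never together — a verdict only valid where the tumor copy
#' number is 1, since at higher copy number the two variants could share a
#' subclone on different parental copies. Anything else is uninformative.
#'
#' @param ev One row of \code{\link{ReadPairEvidence}} (or a list with
#'   \code{nBoth}, \code{nAOnly}, \code{nBOnly}).
#' @param tumorCN Tumor total copy number at both loci.
#' @param minSupport Read pairs required to satisfy each existence rule
#'   (default 1, the literal "at least one example").
#' @return One of \code{"collinear_A_then_B"}, \code{"collinear_B_then_A"},
#'   \code{"mutually_exclusive"}, \code{"uninformative"}.
#' @export
classifyPair <- function(ev, tumorCN, minSupport = 1L) {
  nBoth <- ev$nBoth; nA <- ev$nAOnly; nB <- ev$nBOnly
  if (any(c(nBoth, nA, nB) < 0)) stop("read-pair counts must be non-negative")
  if (nBoth >= minSupport && nA >= minSupport && nB == 0)
    return("collinear_A_then_B")
  if (nBoth >= minSupport && nB >= minSupport && nA == 0)
    return("collinear_B_then_A")
  if (nBoth == 0 && nA >= minSupport && nB >= minSupport && tumorCN == 1)
    return("mutually_exclusive")
  "uninformative"
}

#' Classify every read-pair record against a segment table
#'
#' Vectorised driver for \code{\link{classifyPair}}: looks up the tumor copy
#' number of each pair's loci in the segment table and returns the verdicts.
#'
#' @param pairs A \code{\link{ReadPairEvidence}} data.frame.
#' @param segs A \code{\link{SegmentSet}} used to gate the mutually-exclusive
#'   rule on copy-number-1 regions (rounded total copy number).
#' @param minSupport As in \code{\link{classifyPair}}.
#' @return The data.frame with a \code{verdict} column appended.
#' @export
classifyPairs <- function(pairs, segs, minSupport = 1L) {
  gr <- GRanges(pairs$chrom, IRanges(pairs$posA, pairs$posB))
  ov <- findOverlaps(gr, granges(segs), select = "first")
  cn <- round(segmentTotalCN(segs))[ov]
  cn[is.na(cn)] <- 2
  pairs$verdict <- vapply(seq_len(nrow(pairs)), function(i)
    classifyPair(pairs[i, ], cn[i], minSupport), character(1))
  pairs
}
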