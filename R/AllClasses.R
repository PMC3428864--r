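#' @import methods
#' @importFrom GenomicRanges GRanges granges mcols mcols<- findOverlaps seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame queryHits subjectHits
NULL

#' Sample-level metadata for a sequenced tumor
#'
#' Holds the aberrant-cell fraction (purity) \eqn{\rho}, the tumor ploidy
#' \eqn{\psi}, a sample identifier and the seed used by every stochastic
#' operation in the package. Purity and ploidy are treated as given, e.g.
#' estimated upstream by ASCAT from SNP-array B-allele fractions.
#'
#' @slot purity Fraction of cells in the sample that are tumor cells, in (0, 1].
#' @slot ploidy Average tumor genome ploidy \eqn{\psi}, positive.
#' @slot sampleId Character label for the sample.
#' @slot seed Non-negative integer seed governing stochastic operations.
#'
#' @examples
#' meta <- SampleMeta(purity = 0.70, ploidy = 2, sampleId = "T1", seed = 1L)
#' purity(meta)
#' @export
setClass("SampleMeta",
  representation(purity = "numeric", ploidy = "numeric",
                 sampleId = "character", seed = "integer"),
  prototype(purity = 1, ploidy = 2, sampleId = "sample", seed = 1L))

setValidity("SampleMeta", function(object) {
  msg <- character()
  if (length(object@purity) != 1 || is.na(object@purity) ||
      object@purity <= 0 || object@purity > 1)
    msg <- c(msg, "purity must be a single value in (0, 1]")
  if (length(object@ploidy) != 1 || is.na(object@ploidy) || object@ploidy <= 0)
    msg <- c(msg, "ploidy must be a single positive value")
  if (length(object@seed) != 1 || is.na(object@seed) || object@seed < 0)
    msg <- c(msg, "seed must be a single non-negative integer")
  if (length(msg)) msg else TRUE
})

#' @rdname SampleMeta-class
#' @param purity,ploidy,sampleId,seed See slot descriptions.
#' @export
SampleMeta <- function(purity, ploidy = 2, sampleId = "sample", seed = 1L) {
  new("SampleMeta", purity = as.numeric(purity), ploidy = as.numeric(ploidy),
      sampleId = as.character(sampleId), seed = as.integer(seed))
}

.MUT_MCOLS <- c("ref", "alt", "depth", "altReads", "tumorCN", "normalCN")

#' Somatic substitution calls with read counts and copy-number context
#'
#' A \code{GRanges}-derived container, one row per somatic base substitution.
#' Metadata columns: \code{ref}/\code{alt} (single bases), \code{depth}
#' (total reads \eqn{R}), \code{altReads} (variant reads \eqn{r}),
#' \code{tumorCN} (\eqn{\eta_T}, locus total copy number in the tumor;
#' may be NA until annotated from a segment table), \code{normalCN}
#' (\eqn{\eta_N}, 1 or 2) and optionally \code{context}, the
#' pyrimidine-strand trinucleotide context.
#'
#' @export
setClass("MutationSet", contains = "GRanges")

setValidity("MutationSet", function(object) {
  msg <- character()
  miss <- setdiff(.MUT_MCOLS, colnames(mcols(object)))
  if (length(miss))
    return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
  m <- mcols(object)
  if (any(m$altReads < 0 | m$depth < 0, na.rm = TRUE))
    msg <- c(msg, "read counts must be non-negative")
  if (any(m$altReads > m$depth, na.rm = TRUE))
    msg <- c(msg, "altReads (r) must not exceed depth (R)")
  if (any(m$tumorCN < 0, na.rm = TRUE))
    msg <- c(msg, "tumorCN must be non-negative")
  if (any(!m$normalCN %in% c(1, 2), na.rm = TRUE))
    msg <- c(msg, "normalCN must be 1 or 2")
  if (length(msg)) msg else TRUE
})

#' Construct a MutationSet
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param ref,alt Reference and variant bases.
#' @param depth Total read depth \eqn{R} per site.
#' @param altReads Variant-supporting reads \eqn{r} per site.
#' @param tumorCN Total tumor copy number at the locus (NA to fill later from
#'   a segment table with \code{\link{annotateCopyNumber}}).
#' @param normalCN Normal copy number at the locus (2, or 1 on male sex
#'   chromosomes).
#' @param context Optional pyrimidine-strand trinucleotide context.
#' @return A \code{MutationSet}.
#' @examples
#' MutationSet("chr1", 1000, "A", "T", depth = 210, altReads = 74, tumorCN = 2)
#' @export
MutationSet <- function(chrom, pos, ref, alt, depth, altReads,
                        tumorCN = NA_real_, normalCN = 2, context = NA_character_) {
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
  n <- length(gr)
  mcols(gr) <- DataFrame(ref = as.character(ref), alt = as.character(alt),
                         depth = as.integer(depth), altReads = as.integer(altReads),
                         tumorCN = rep_len(as.numeric(tumorCN), n),
                         normalCN = rep_len(as.numeric(normalCN), n),
                         context = rep_len(as.character(context), n))
  new("MutationSet", gr)
}

.SEG_MCOLS <- c("logR", "nA", "nB", "subclonal",
                "nA1", "nB1", "nA2", "nB2", "tau", "tauLo", "tauHi")

#' Allele-specific copy-number segments, possibly subclonal mixtures
#'
#' A \code{GRanges}-derived container of copy-number segments. Metadata
#' columns: \code{logR} (log2 relative coverage \eqn{l_R}), \code{nA}/\code{nB}
#' (allele-specific copy numbers; real-valued before state calling), a
#' \code{subclonal} flag and, for subclonal segments, the two integer states
#' \code{nA1}/\code{nB1} (present in a fraction \code{tau} of tumor cells) and
#' \code{nA2}/\code{nB2} (the remaining \code{1 - tau}), with a bootstrap
#' confidence interval \code{tauLo}/\code{tauHi}.
#'
#' Subclonal segments assume the aberration gained or lost exactly one copy of
#' one allele, so the two states differ by one in total copy number.
#'
#' @export
setClass("SegmentSet", contains = "GRanges")

setValidity("SegmentSet", function(object) {
  msg <- character()
  miss <- setdiff(.SEG_MCOLS, colnames(mcols(object)))
  if (length(miss))
    return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
  m <- mcols(object)
  ov <- findOverlaps(object, drop.self = TRUE, drop.redundant = TRUE)
  if (length(ov))
    msg <- c(msg, "segments overlap on the same chromosome")
  if (any(m$tau < 0 | m$tau > 1, na.rm = TRUE))
    msg <- c(msg, "tau must lie in [0, 1]")
  sub <- which(m$subclonal %in% TRUE & !is.na(m$nA1))
  if (length(sub)) {
    d <- abs((m$nA1[sub] + m$nB1[sub]) - (m$nA2[sub] + m$nB2[sub]))
    if (any(d != 1))
      msg <- c(msg, "subclonal states must differ by exactly one copy in total")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SegmentSet
#'
#' @param chrom Chromosome names.
#' @param start,end 1-based closed interval bounds (as held in GRanges; the
#'   TSV representation written by \code{\link{writeSegments}} is 0-based
#'   half-open, BED-like).
#' @param logR log2 tumor/normal relative coverage.
#' @param nA,nB Allele-specific copy numbers (major, minor).
#' @param subclonal Logical flag; TRUE for two-state mixtures.
#' @param nA1,nB1,nA2,nB2 Integer states of the two cell populations.
#' @param tau Fraction of tumor cells in state 1.
#' @param tauLo,tauHi 95\% bootstrap interval for tau.
#' @return A \code{SegmentSet}.
#' @export
SegmentSet <- function(chrom, start, end, logR = NA_real_, nA = NA_real_,
                       nB = NA_real_, subclonal = FALSE,
                       nA1 = NA_real_, nB1 = NA_real_, nA2 = NA_real_,
                       nB2 = NA_real_, tau = NA_real_,
                       tauLo = NA_real_, tauHi = NA_real_) {
  gr <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)))
  n <- length(gr)
  mcols(gr) <- DataFrame(logR = rep_len(as.numeric(logR), n),
                         nA = rep_len(as.numeric(nA), n),
                         nB = rep_len(as.numeric(nB), n),
                         subclonal = rep_len(as.logical(subclonal), n),
                         nA1 = rep_len(as.numeric(nA1), n),
                         nB1 = rep_len(as.numeric(nB1), n),
                         nA2 = rep_len(as.numeric(nA2), n),
                         nB2 = rep_len(as.numeric(nB2), n),
                         tau = rep_len(as.numeric(tau), n),
                         tauLo = rep_len(as.numeric(tauLo), n),
                         tauHi = rep_len(as.numeric(tauHi), n))
  new("SegmentSet", gr)
}

.SNP_MCOLS <- c("hap1Reads", "hap2Reads", "blockId")

#' Phased heterozygous germline SNPs with per-haplotype read counts
#'
#' A \code{GRanges}-derived container of imputation-phased heterozygous SNPs.
#' Metadata columns: \code{hap1Reads}/\code{hap2Reads} (tumor reads supporting
#' each imputed parental haplotype), \code{blockId} (haplotype-block label;
#' haplotype assignment is only consistent within a block — blocks separated
#' by recombination hotspots may switch parental labels, producing the
#' checkered long-range pattern that segmentation re-phases) and optionally
#' \code{logR}, the local log2 relative coverage.
#'
#' @export
setClass("PhasedSNPSet", contains = "GRanges")

setValidity("PhasedSNPSet", function(object) {
  miss <- setdiff(.SNP_MCOLS, colnames(mcols(object)))
  if (length(miss))
    return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
  m <- mcols(object)
  if (any(m$hap1Reads < 0 | m$hap2Reads < 0, na.rm = TRUE))
    return("haplotype read counts must be non-negative")
  TRUE
})

#' Construct a PhasedSNPSet
#'
#' @param chrom Chromosome names.
#' @param pos 1-based positions.
#' @param hap1Reads,hap2Reads Reads supporting each imputed haplotype.
#' @param blockId Haplotype-block labels.
#' @param logR Optional per-SNP log2 relative coverage.
#' @return A \code{PhasedSNPSet}.
#' @export
PhasedSNPSet <- function(chrom, pos, hap1Reads, hap2Reads, blockId,
                         logR = NA_real_) {
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
  n <- length(gr)
  mcols(gr) <- DataFrame(hap1Reads = as.integer(hap1Reads),
                         hap2Reads = as.integer(hap2Reads),
                         blockId = rep_len(blockId, n),
                         logR = rep_len(as.numeric(logR), n))
  new("PhasedSNPSet", gr)
}

#' Read-pair co-occurrence evidence for a pair of nearby variant loci
#'
#' Validates and classes a data.frame of read-pair counts for pairs of loci
#' spanned by single sequencing fragments. Columns: \code{chrom}, \code{posA},
#' \code{posB} (1-based; A is the 5' locus), \code{nBoth} (pairs reporting both
#' variant alleles), \code{nAOnly} (variant at A, wild-type at B),
#' \code{nBOnly} (wild-type at A, variant at B) and \code{nNeither}.
#'
#' @param df A data.frame with the columns above.
#' @return The same data.frame, validated, with class
#'   \code{c("ReadPairEvidence", "data.frame")}.
#' @export
ReadPairEvidence <- function(df) {
  need <- c("chrom", "posA", "posB", "nBoth", "nAOnly", "nBOnly", "nNeither")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing read-pair columns: ", paste(miss, collapse = ", "))
  cnt <- as.matrix(df[, c("nBoth", "nAOnly", "nBOnly", "nNeither")])
  if (any(cnt < 0, na.rm = TRUE)) stop("read-pair counts must be non-negative")
  class(df) <- c("ReadPairEvidence", "data.frame")
  df
}

#' Detection-sensitivity curve for subclonal mutations
#'
#' Three-parameter logistic model of the probability of calling a mutation
#' present in a fraction \eqn{\theta} of tumor cells:
#' \deqn{S(\theta) = A / (1 + \exp((\chi - \log\theta)/\sigma)).}
#' \code{A} is the asymptotic sensitivity for fully clonal mutations,
#' \eqn{\chi} locates the half-maximum on the log-fraction scale and
#' \eqn{\sigma > 0} sets the steepness.
#'
#' @slot A Asymptote in (0, 1].
#' @slot chi Location on the log-fraction scale.
#' @slot sigma Scale, positive.
#' @slot rawPoints data.frame of (theta, detected) spike-in estimates the curve
#'   was fitted to (may be empty for analytic curves).
#' @export
setClass("SensitivityCurve",
  representation(A = "numeric", chi = "numeric", sigma = "numeric",
                 rawPoints = "data.frame"),
  prototype(A = 1, chi = -10, sigma = 0.5, rawPoints = data.frame()))

setValidity("SensitivityCurve", function(object) {
  msg <- character()
  if (object@A <= 0 || object@A > 1) msg <- c(msg, "A must be in (0, 1]")
  if (object@sigma <= 0) msg <- c(msg, "sigma must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname SensitivityCurve-class
#' @param A,chi,sigma Curve parameters.
#' @param rawPoints Optional data.frame of (theta, detected) pairs.
#' @export
SensitivityCurve <- function(A, chi, sigma, rawPoints = data.frame()) {
  new("SensitivityCurve", A = as.numeric(A), chi = as.numeric(chi),
      sigma = as.numeric(sigma), rawPoints = rawPoints)
}

#' Posterior of the Dirichlet-process mutation-cluster model
#'
#' Holds the monitored Gibbs draws and summaries of the truncated
#' stick-breaking Dirichlet-process fit: cluster locations \eqn{\pi_h}
#' (fractions of tumor cells), stick weights \eqn{\kappa_h}, per-cluster
#' allocation counts, the concentration \eqn{\alpha}, the sensitivity-corrected
#' weights \eqn{\omega_h = \kappa_h S(\pi_h) / \sum_i \kappa_i S(\pi_i)}, the
#' \eqn{\kappa}-weighted Gaussian-kernel posterior density over (0, 1] and a
#' split-chain convergence diagnostic.
#'
#' @slot locations Matrix of monitored \eqn{\pi_h} draws (draws x H).
#' @slot weights Matrix of monitored \eqn{\kappa_h} draws (draws x H).
#' @slot counts Matrix of per-cluster allocation counts (draws x H).
#' @slot alpha Numeric vector of monitored \eqn{\alpha} draws.
#' @slot correctedWeights Matrix of \eqn{\omega_h} draws (draws x H).
#' @slot density data.frame with columns x, y, lo, hi: posterior median and
#'   95\% band of the weighted kernel density over (0, 1].
#' @slot clusterSummary data.frame summarising occupied clusters (location,
#'   corrected weight, sensitivity-corrected mutation count with 95\%
#'   posterior interval).
#' @slot rhat Split-chain potential scale reduction of the total
#'   log-likelihood.
#' @slot converged Logical; FALSE records a convergence warning.
#' @slot meta The \code{SampleMeta} used for the fit.
#' @slot sensitivityCurve The \code{SensitivityCurve} used for weight
#'   correction, or NULL for flat sensitivity.
#' @export
setClass("ClusterFit",
  representation(locations = "matrix", weights = "matrix", counts = "matrix",
                 alpha = "numeric", correctedWeights = "matrix",
                 density = "data.frame", clusterSummary = "data.frame",
                 rhat = "numeric", converged = "logical", meta = "SampleMeta",
                 sensitivityCurve = "ANY"))

#' Phylogenetic tree of tumor subclones
#'
#' Nested clone tree built by \code{\link{buildTree}}. The root is the
#' most-recent common ancestor (cell fraction 1); each node carries a label,
#' the fraction of tumor cells in its lineage, a private mutation count,
#' attached copy-number events, an \code{ambiguous} flag for placements not
#' forced by the pigeonhole principle or phasing, and child nodes. Children
#' fractions never exceed the parent fraction by more than the tolerance
#' \code{epsilon}.
#'
#' @slot root Nested list of nodes (label, fraction, nMutations, events,
#'   ambiguous, children).
#' @slot constraints data.frame of pairwise constraints the tree honors.
#' @slot epsilon Fraction-sum tolerance.
#' @export
setClass("CloneTree",
  representation(root = "list", constraints = "data.frame",
                 epsilon = "numeric"))
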