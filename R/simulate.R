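# Synthetic-tumor generator with full ground truth.
#
# Read counts follow the observation model of the clustering stage: a
# mutation carried at multiplicity m by a fraction pi of tumor cells, at a
# locus of tumor copy number etaT, yields depth N ~ Poisson(coverage x
# relative copy number) and variant reads r ~ Bin(N, m * rho * pi /
# (rho*etaT + (1-rho)*etaN)). Phased-SNP counts are binomial around the
# haplotype-fraction mixture equation. The truth object records every
# latent value so downstream recovery can be scored.

#' Configuration of a synthetic tumor
#'
#' @slot purity Fraction of cells that are tumor cells.
#' @slot ploidy Tumor ploidy used for coverage normalisation.
#' @slot coverage Mean sequencing depth at a diploid locus.
#' @slot cloneFractions Cell fraction of each clone; the first clone is the
#'   most-recent common ancestor with fraction 1.
#' @slot parents Parent index of each clone (0 for the MRCA); children
#'   fractions must not exceed their parent's.
#' @slot mutationsPerClone Number of mutations private to each clone.
#' @slot segments data.frame of copy-number segments: \code{chrom},
#'   \code{start}, \code{end}, \code{nA}, \code{nB}; optional \code{nA2},
#'   \code{nB2}, \code{tau} for two-state subclonal segments (fraction tau
#'   of tumor cells in state nA/nB); optional \code{gainClass}
#'   (\code{"trisomy_2+1"}, \code{"UPD_2+0"}, \code{"tetraploid_2+2"}) and
#'   \code{gainTime} (molecular time of the gain) for gained segments.
#' @slot nSNPs Heterozygous SNPs simulated per chromosome.
#' @slot snpDepth Mean depth at SNPs (defaults to coverage).
#' @slot blockLength Haplotype-block length in bp (default 3e5).
#' @slot earlySpectrum,lateSpectrum Probability vectors over the six
#'   pyrimidine substitution classes for early (pre-gain) and late mutations.
#' @slot insertSize Maximum mutation-pair distance spanned by read pairs.
#' @slot errorRate Flat per-read sequencing error rate for read-pair
#'   simulation.
#' @slot sensitivityCurve Optional \code{\link{SensitivityCurve}}: simulated
#'   mutations are observed with probability S(pi), emulating caller
#'   sensitivity.
#' @slot seed Seed for all randomness.
#' @export
setClass("SimConfig",
  representation(purity = "numeric", ploidy = "numeric", coverage = "numeric",
                 cloneFractions = "numeric", parents = "integer",
                 mutationsPerClone = "integer", segments = "data.frame",
                 nSNPs = "integer", snpDepth = "numeric",
                 blockLength = "numeric", earlySpectrum = "numeric",
                 lateSpectrum = "numeric", insertSize = "numeric",
                 errorRate = "numeric", sensitivityCurve = "ANY",
                 seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  k <- length(object@cloneFractions)
  if (k < 1 || object@cloneFractions[1] != 1)
    msg <- c(msg, "the first clone (MRCA) must have fraction 1")
  if (length(object@parents) != k || length(object@mutationsPerClone) != k)
    msg <- c(msg, "parents and mutationsPerClone must match cloneFractions")
  if (any(object@cloneFractions <= 0 | object@cloneFractions > 1))
    msg <- c(msg, "clone fractions must lie in (0, 1]")
  for (c in seq_len(k)) {
    ch <- which(object@parents == c)
    if (length(ch) &&
        sum(object@cloneFractions[ch]) > object@cloneFractions[c] + 1e-9)
      msg <- c(msg, sprintf(
        "children of clone %d exceed its fraction: tree inconsistent", c))
  }
  if (abs(sum(object@earlySpectrum) - 1) > 1e-9 ||
      abs(sum(object@lateSpectrum) - 1) > 1e-9)
    msg <- c(msg, "spectra must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Build a SimConfig
#'
#' @param purity,ploidy,coverage Sample parameters.
#' @param cloneFractions,parents,mutationsPerClone Clone tree and mutation
#'   loads (see \code{\linkS4class{SimConfig}}).
#' @param segments Segment table; default one diploid chr1 of 100 Mb.
#' @param nSNPs,snpDepth,blockLength Phased-SNP simulation parameters.
#' @param earlySpectrum,lateSpectrum Substitution-class probabilities;
#'   default a typical breast-like spectrum for both.
#' @param insertSize,errorRate Read-pair simulation parameters.
#' @param sensitivityCurve Optional detection-sensitivity thinning.
#' @param seed Seed.
#' @return A \code{SimConfig}.
#' @export
simConfig <- function(purity = 0.7, ploidy = 2, coverage = 150,
                      cloneFractions = 1, parents = 0L,
                      mutationsPerClone = 100L,
                      segments = data.frame(chrom = "chr1", start = 1,
                                            end = 1e8, nA = 1, nB = 1),
                      nSNPs = 1000L, snpDepth = coverage,
                      blockLength = 3e5,
                      earlySpectrum = c(0.1, 0.1, 0.4, 0.1, 0.2, 0.1),
                      lateSpectrum = c(0.15, 0.2, 0.15, 0.15, 0.2, 0.15),
                      insertSize = 700, errorRate = 0,
                      sensitivityCurve = NULL, seed = 1L) {
  new("SimConfig", purity = purity, ploidy = ploidy, coverage = coverage,
      cloneFractions = as.numeric(cloneFractions),
      parents = as.integer(parents),
      mutationsPerClone = rep_len(as.integer(mutationsPerClone),
                                  length(cloneFractions)),
      segments = segments, nSNPs = as.integer(nSNPs),
      snpDepth = snpDepth, blockLength = blockLength,
      earlySpectrum = earlySpectrum, lateSpectrum = lateSpectrum,
      insertSize = insertSize, errorRate = errorRate,
      sensitivityCurve = sensitivityCurve, seed = as.integer(seed))
}

.segMixture <- function(seg) {
  # effective (nA, nB) of a segment row, averaging two-state mixtures
  if (!is.null(seg$tau) && !is.na(seg$tau)) {
    nA <- seg$tau * seg$nA + (1 - seg$tau) * seg$nA2
    nB <- seg$tau * seg$nB + (1 - seg$tau) * seg$nB2
  } else {
    nA <- seg$nA; nB <- seg$nB
  }
  c(nA = nA, nB = nB)
}

.drawClass <- function(n, spectrum) {
  cls <- substitutionClasses()
  sample(cls, n, replace = TRUE, prob = spectrum)
}

.classToBases <- function(cls) {
  ref <- substr(cls, 1, 1); alt <- substr(cls, 3, 3)
  ctx <- paste0(sample(c("A", "C", "G", "T"), length(cls), replace = TRUE),
                ref,
                sample(c("A", "C", "G", "T"), length(cls), replace = TRUE))
  list(ref = ref, alt = alt, context = ctx)
}

#' Simulate a full synthetic tumor
#'
#' Draws mutations for every clone, read counts under the binomial
#' observation model, phased heterozygous SNPs, read-pair co-occurrence
#' records for nearby mutation pairs, and a truth object holding every
#' latent value (clone assignments, multiplicities, ploidy classes,
#' haplotype-fraction expectations, the clone tree).
#'
#' @param cfg A \code{\link{simConfig}}.
#' @return List with elements \code{mutations} (\code{MutationSet}),
#'   \code{segments} (\code{SegmentSet}), \code{phasedSNPs}
#'   (\code{PhasedSNPSet}), \code{readPairs} (\code{ReadPairEvidence}) and
#'   \code{truth} (list).
#' @export
simulateTumor <- function(cfg) {
  methods::validObject(cfg)
  set.seed(cfg@seed)
  rho <- cfg@purity; psi <- cfg@ploidy
  segs <- cfg@segments
  nSeg <- nrow(segs)
  segW <- segs$end - segs$start + 1
  nClones <- length(cfg@cloneFractions)

  # --- mutations ---------------------------------------------------------
  nTot <- sum(cfg@mutationsPerClone)
  clone <- rep(seq_len(nClones), cfg@mutationsPerClone)
  pi <- cfg@cloneFractions[clone]
  segIdx <- sample.int(max(nSeg, 1), nTot, replace = TRUE,
                       prob = segW / sum(segW))
  pos <- floor(segs$start[segIdx] +
                 stats::runif(nTot) * (segW[segIdx] - 1))
  mix <- t(vapply(segIdx, function(i) .segMixture(segs[i, ]), numeric(2)))
  etaT <- mix[, 1] + mix[, 2]
  etaN <- 2

  # multiplicity: clonal mutations on gained segments may predate the gain
  mult <- rep(1L, nTot)
  ploidyClass <- rep("1", nTot)
  if (!is.null(segs$gainClass)) {
    for (i in which(!is.na(segs$gainClass) & nzchar(segs$gainClass))) {
      onSeg <- which(segIdx == i & clone == 1L)
      tStar <- segs$gainTime[i]
      p2 <- switch(segs$gainClass[i],
                   "trisomy_2+1" = tStar / (3 - tStar),
                   "UPD_2+0" = tStar / (2 - tStar),
                   "tetraploid_2+2" = tStar / (2 - tStar),
                   stop("unknown gainClass: ", segs$gainClass[i]))
      early <- onSeg[stats::runif(length(onSeg)) < p2]
      mult[early] <- 2L
      ploidyClass[early] <- "2"
    }
  }
  ploidyClass[clone != 1L] <- "subclonal"

  denom <- rho * etaT + (1 - rho) * etaN
  relCN <- denom / (rho * psi + (1 - rho) * 2)
  depth <- stats::rpois(nTot, cfg@coverage * relCN)
  pVar <- pmin(1, mult * rho * pi / denom)
  altReads <- stats::rbinom(nTot, depth, pVar)

  cls <- character(nTot)
  isEarly <- ploidyClass == "2"
  cls[isEarly] <- .drawClass(sum(isEarly), cfg@earlySpectrum)
  cls[!isEarly] <- .drawClass(sum(!isEarly), cfg@lateSpectrum)
  bases <- .classToBases(cls)

  detected <- rep(TRUE, nTot)
  if (!is.null(cfg@sensitivityCurve))
    detected <- stats::runif(nTot) < sensitivity(cfg@sensitivityCurve, pi)

  muts <- MutationSet(segs$chrom[segIdx], pos, bases$ref, bases$alt,
                      depth = depth, altReads = altReads, tumorCN = etaT,
                      normalCN = etaN, context = bases$context)
  ord <- order(as.integer(factor(segs$chrom[segIdx])), pos)

  # --- segment table ------------------------------------------------------
  sub <- if (is.null(segs$tau)) rep(FALSE, nSeg) else !is.na(segs$tau)
  etaTSeg <- vapply(seq_len(nSeg), function(i)
    sum(.segMixture(segs[i, ])), numeric(1))
  logRSeg <- log2((rho * etaTSeg + 2 * (1 - rho)) /
                    (rho * psi + 2 * (1 - rho)))
  segSet <- SegmentSet(segs$chrom, segs$start, segs$end, logR = logRSeg,
                       nA = segs$nA, nB = segs$nB,
                       subclonal = sub,
                       nA1 = ifelse(sub, segs$nA, NA_real_),
                       nB1 = ifelse(sub, segs$nB, NA_real_),
                       nA2 = ifelse(sub, if (!is.null(segs$nA2)) segs$nA2 else NA_real_, NA_real_),
                       nB2 = ifelse(sub, if (!is.null(segs$nB2)) segs$nB2 else NA_real_, NA_real_),
                       tau = ifelse(sub, if (!is.null(segs$tau)) segs$tau else NA_real_, NA_real_))

  # --- phased SNPs --------------------------------------------------------
  snpList <- list()
  for (i in seq_len(nSeg)) {
    nS <- max(1L, round(cfg@nSNPs * segW[i] / sum(segW)))
    st1 <- c(segs$nA[i], segs$nB[i])
    st2 <- if (sub[i]) c(segs$nA2[i], segs$nB2[i]) else st1
    tauI <- if (sub[i]) segs$tau[i] else 1
    snpList[[i]] <- simulatePhasedChromosome(
      rho = rho, tau = tauI, state1 = st1, state2 = st2, nSnps = nS,
      depth = cfg@snpDepth, blockLength = cfg@blockLength,
      seed = cfg@seed + i, chrom = segs$chrom[i], startPos = segs$start[i],
      endPos = segs$end[i], psi = psi)
  }
  snps <- do.call(c, lapply(snpList, function(x) methods::as(x, "GRanges")))
  snps <- new("PhasedSNPSet", snps)

  # --- read pairs for nearby mutation pairs -------------------------------
  readPairs <- .simulateReadPairs(muts[ord], clone[ord], cfg)

  truth <- list(
    cloneFractions = cfg@cloneFractions, parents = cfg@parents,
    clone = clone[ord], pi = pi[ord], multiplicity = mult[ord],
    ploidyClass = ploidyClass[ord], detected = detected[ord],
    class = cls[ord], segIdx = segIdx[ord], depthModel = "poisson",
    expectedVAF = pVar[ord], logR = logRSeg)

  list(mutations = muts[ord][detected[ord]], segments = segSet,
       phasedSNPs = snps, readPairs = readPairs, truth = truth)
}

# ancestor test on the configured clone tree
.isAncestor <- function(parents, a, b) {
  # TRUE if clone a is an ancestor of (or equal to) clone b
  while (b != 0) {
    if (b == a) return(TRUE)
    b <- parents[b]
  }
  FALSE
}

.simulateReadPairs <- function(muts, clone, cfg) {
  rho <- cfg@purity
  empty <- ReadPairEvidence(data.frame(
    chrom = character(), posA = integer(), posB = integer(),
    nBoth = integer(), nAOnly = integer(), nBOnly = integer(),
    nNeither = integer(), truthRelation = character(),
    stringsAsFactors = FALSE))
  if (length(muts) < 2) return(empty)
  pos <- start(muts); chrom <- as.character(seqnames(muts))
  mc <- mcols(muts)
  rows <- NULL
  for (i in seq_len(length(muts) - 1)) {
    j <- i + 1
    while (j <= length(muts) && chrom[j] == chrom[i] &&
           pos[j] - pos[i] <= cfg@insertSize) {
      ci <- clone[i]; cj <- clone[j]
      fi <- cfg@cloneFractions[ci]; fj <- cfg@cloneFractions[cj]
      if (.isAncestor(cfg@parents, ci, cj)) {
        fBoth <- fj; rel <- "nested_A_first"
      } else if (.isAncestor(cfg@parents, cj, ci)) {
        fBoth <- fi; rel <- "nested_B_first"
      } else {
        fBoth <- 0; rel <- "sibling"
      }
      # sample-cell fractions carrying A only / B only / both / neither
      pBoth <- rho * fBoth
      pA <- rho * (fi - fBoth); pB <- rho * (fj - fBoth)
      etaI <- mc$tumorCN[i]; etaJ <- mc$tumorCN[j]
      nPairs <- stats::rpois(1, cfg@coverage / 4)
      cat4 <- sample(c("both", "A", "B", "none"), nPairs, replace = TRUE,
                     prob = c(pBoth, pA, pB, max(1 - pBoth - pA - pB, 0)))
      # a pair from a carrying cell reports the variant if it samples the
      # mutated copy; flat error rate can flip wild-type calls
      showA <- (cat4 %in% c("both", "A") &
                  stats::runif(nPairs) < 1 / max(etaI, 1)) |
        stats::runif(nPairs) < cfg@errorRate
      showB <- (cat4 %in% c("both", "B") &
                  stats::runif(nPairs) < 1 / max(etaJ, 1)) |
        stats::runif(nPairs) < cfg@errorRate
      rows <- rbind(rows, data.frame(
        chrom = chrom[i], posA = pos[i], posB = pos[j],
        nBoth = sum(showA & showB), nAOnly = sum(showA & !showB),
        nBOnly = sum(!showA & showB), nNeither = sum(!showA & !showB),
        truthRelation = rel, stringsAsFactors = FALSE))
      j <- j + 1
    }
  }
  if (is.null(rows)) return(empty)
  ReadPairEvidence(rows)
}

#' Simulate phased heterozygous SNPs for one chromosome or segment
#'
#' SNP positions are uniform over the interval; imputation haplotype blocks
#' of the given length are randomly oriented (the parental label switches
#' between blocks, reproducing the checkered long-range pattern); per-SNP
#' depths are Poisson and haplotype-1 read counts binomial around the
#' mixture haplotype fraction of the two copy-number states.
#'
#' @param rho Purity.
#' @param tau Fraction of tumor cells in \code{state1} (1 for clonal).
#' @param state1,state2 Length-2 vectors (nA, nB) of the two states.
#' @param nSnps Number of SNPs.
#' @param depth Mean depth per SNP.
#' @param blockLength Haplotype-block length in bp.
#' @param seed Seed.
#' @param chrom Chromosome name.
#' @param startPos,endPos Interval simulated.
#' @param blockPrefix Prefix for haplotype-block labels (default the
#'   chromosome name; give distinct prefixes when concatenating simulated
#'   regions of one chromosome).
#' @param psi Tumor ploidy for the logR column.
#' @return A \code{\link{PhasedSNPSet}} with a \code{logR} column.
#' @export
simulatePhasedChromosome <- function(rho, tau, state1, state2 = state1,
                                     nSnps = 5000L, depth = 188,
                                     blockLength = 3e5, seed = 1L,
                                     chrom = "chr1", startPos = 1,
                                     endPos = startPos + 1e8 - 1, psi = 2,
                                     blockPrefix = chrom) {
  set.seed(seed)
  pos <- sort(floor(stats::runif(nSnps, startPos, endPos + 1)))
  nA <- tau * state1[1] + (1 - tau) * state2[1]
  nB <- tau * state1[2] + (1 - tau) * state2[2]
  hfMinor <- clonalHf(rho, nA, nB)
  block <- floor((pos - startPos) / blockLength)
  blockIds <- unique(block)
  flip <- stats::setNames(sample(c(TRUE, FALSE), length(blockIds),
                                 replace = TRUE), blockIds)
  p <- ifelse(flip[as.character(block)], 1 - hfMinor, hfMinor)
  N <- stats::rpois(nSnps, depth)
  hap1 <- stats::rbinom(nSnps, N, p)
  lR <- log2((rho * (nA + nB) + 2 * (1 - rho)) / (rho * psi + 2 * (1 - rho)))
  PhasedSNPSet(chrom, pos, hap1, N - hap1,
               blockId = paste0(blockPrefix, "_b", block), logR = lR)
}
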