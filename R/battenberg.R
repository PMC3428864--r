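# Subclonal allele-specific copy number from phased haplotype fractions and
# logR ("Battenberg"-style analysis).
#
# Within an imputation haplotype block the two parental alleles keep a fixed
# label, so for a region of allelic imbalance the per-SNP haplotype-1
# fraction sits in one of two bands, switching between blocks at
# recombination hotspots. Re-phasing flips each block onto the minor band;
# piecewise-constant-fitting segmentation of the re-phased fractions then
# recovers long-range segments whose haplotype fraction obeys, for a clonal
# state (nA, nB) at purity rho,
#     hf = (1 - rho + rho*nB) / (2(1 - rho) + rho*(nA + nB))
# and inverts jointly with logR to real-valued allele-specific copy numbers
#     nA = (rho - 1 + (1 - hf) * psi * 2^lR) / rho
#     nB = (rho - 1 + hf * psi * 2^lR) / rho.
# Segments whose haplotype fraction is inconsistent with every integer
# clonal state are subclonal mixtures of two states differing by one copy;
# the mixing fraction tau follows in closed form.

#' Expected haplotype fraction of a clonal copy-number state
#'
#' @param rho Purity (fraction of tumor cells), in [0, 1].
#' @param nA,nB Integer allele-specific copy numbers; \code{nB} is the
#'   allele whose fraction is reported.
#' @return Expected fraction of reads carrying the \code{nB} haplotype.
#' @examples
#' clonalHf(0.7, 1, 0)   # 0.2308: one-copy loss at 70% purity
#' @export
clonalHf <- function(rho, nA, nB) {
  (1 - rho + rho * nB) / (2 * (1 - rho) + rho * (nA + nB))
}

#' Allele-specific copy number from haplotype fraction and logR
#'
#' Deterministic inversion of the haplotype-fraction and total-coverage
#' equations. Negative values are clipped at zero with a warning.
#'
#' @param hf Segmented haplotype fraction.
#' @param logR log2 tumor/normal relative coverage of the segment.
#' @param rho Purity.
#' @param psi Tumor ploidy.
#' @return Named numeric vector \code{c(nA =, nB =)} (real-valued).
#' @export
alleleSpecificCN <- function(hf, logR, rho, psi) {
  tot <- psi * 2^logR
  nA <- (rho - 1 + (1 - hf) * tot) / rho
  nB <- (rho - 1 + hf * tot) / rho
  if (nA < -1e-9 || nB < -1e-9)
    warning("negative allele-specific copy number clipped at 0")
  nA <- max(nA, 0); nB <- max(nB, 0)
  c(nA = nA, nB = nB)
}

#' Re-phase haplotype blocks onto a common band
#'
#' Flips the haplotype labels of each imputation block whose aggregate
#' haplotype-1 read fraction is significantly above one half (z test on the
#' pooled block read counts at \code{zThresh} standard errors), so that in
#' regions of allelic imbalance all blocks report the same (minor) parental
#' band and segmentation can operate across block switch-points. Blocks with
#' no significant departure from 0.5 are left unflipped: in balanced regions
#' both labels are exchangeable and flipping on noise alone would fold the
#' fraction below one half, biasing the clonality test.
#'
#' @param snps A \code{\link{PhasedSNPSet}} (one chromosome).
#' @param zThresh z-score above which a block is deemed to sit on the upper
#'   band and is flipped (default 1.96).
#' @return data.frame with per-SNP \code{pos}, \code{fraction} (re-phased
#'   minor-band fraction), \code{flipped} (block flipped?), \code{blockId},
#'   and \code{logR}.
#' @export
rephaseBlocks <- function(snps, zThresh = 1.96) {
  m <- mcols(snps)
  tot <- m$hap1Reads + m$hap2Reads
  frac <- ifelse(tot > 0, m$hap1Reads / tot, 0.5)
  id <- as.character(m$blockId)
  h1 <- tapply(m$hap1Reads, id, sum)
  tt <- tapply(tot, id, sum)
  bf <- ifelse(tt > 0, h1 / pmax(tt, 1), 0.5)
  z <- (bf - 0.5) / sqrt(pmax(bf * (1 - bf), 1e-6) / pmax(tt, 1))
  flip <- (z > zThresh)[id]
  data.frame(pos = start(snps),
             fraction = ifelse(flip, 1 - frac, frac),
             flipped = unname(flip), blockId = m$blockId,
             logR = if ("logR" %in% colnames(m)) m$logR else NA_real_)
}

#' Piecewise-constant-fitting segmentation
#'
#' Exact least-squares segmentation by dynamic programming: minimises the
#' residual sum of squares (standardised by a robust difference-based noise
#' estimate) plus \code{penalty * log(n)} per breakpoint. The log(n) scaling
#' makes the penalty comparable across signal lengths (a BIC-like rate), so
#' the breakpoint penalty parameter stays O(1).
#'
#' @param x Numeric signal, ordered along the chromosome.
#' @param penalty Breakpoint penalty (default 3).
#' @param minLength Minimum segment length in points (default 5).
#' @return data.frame with one row per segment: \code{start}, \code{end}
#'   (indices into \code{x}) and \code{mean}.
#' @export
pcfSegment <- function(x, penalty = 3, minLength = 5L) {
  n <- length(x)
  if (n == 0) return(data.frame(start = integer(), end = integer(),
                                mean = numeric()))
  if (n <= minLength)
    return(data.frame(start = 1L, end = n, mean = mean(x)))
  s2 <- (stats::mad(diff(x)) / sqrt(2))^2
  if (s2 <= 0) s2 <- stats::var(x)
  if (is.na(s2) || s2 <= 0) s2 <- 1e-12
  cs <- c(0, cumsum(x)); css <- c(0, cumsum(x^2))
  best <- c(0, rep(Inf, n))   # best[j+1]: optimal cost of x[1..j]
  prev <- integer(n)
  for (j in seq_len(n)) {
    i <- seq_len(max(1L, j - minLength + 1L))   # candidate segment starts
    len <- j - i + 1
    sse <- (css[j + 1] - css[i]) - (cs[j + 1] - cs[i])^2 / len
    pen <- penalty * log(n)
    cost <- best[i] + sse / s2 + pen
    cost[1] <- cost[1] - pen                    # first segment: no breakpoint
    k <- which.min(cost)
    best[j + 1] <- cost[k]
    prev[j] <- i[k] - 1L
  }
  ends <- integer(); j <- n
  while (j > 0) { ends <- c(j, ends); j <- prev[j] }
  starts <- c(1L, utils::head(ends, -1) + 1L)
  data.frame(start = starts, end = ends,
             mean = vapply(seq_along(starts), function(k)
               mean(x[starts[k]:ends[k]]), numeric(1)))
}

#' Re-phase and segment a chromosome's haplotype fractions
#'
#' Re-phases imputation blocks onto the minor band
#' (\code{\link{rephaseBlocks}}), then segments the block-level mean
#' fractions by PCF with the given breakpoint penalty, so that switch-points
#' between haplotype blocks are absorbed and only genuine copy-number
#' boundaries remain. Per-SNP fractions are retained within each segment for
#' the clonality t test and the tau bootstrap.
#'
#' @param snps A \code{\link{PhasedSNPSet}} restricted to one chromosome.
#' @param penalty PCF breakpoint penalty (default 3).
#' @return List of segments, each a list with \code{startPos},
#'   \code{endPos}, \code{hf} (mean fraction), \code{nSnps},
#'   \code{fractions} (per-SNP), \code{logR} (mean of the logR column, NA if
#'   absent).
#' @export
phaseSwitchSegment <- function(snps, penalty = 3) {
  if (length(unique(as.character(seqnames(snps)))) > 1)
    stop("phaseSwitchSegment expects a single chromosome")
  rp <- rephaseBlocks(snps)
  rp <- rp[order(rp$pos), , drop = FALSE]
  blockOrder <- unique(rp$blockId)
  bi <- match(rp$blockId, blockOrder)
  blockMean <- vapply(seq_along(blockOrder), function(b)
    mean(rp$fraction[bi == b]), numeric(1))
  segB <- pcfSegment(blockMean, penalty = penalty, minLength = 1L)
  lapply(seq_len(nrow(segB)), function(k) {
    idx <- which(bi >= segB$start[k] & bi <= segB$end[k])
    list(startPos = min(rp$pos[idx]), endPos = max(rp$pos[idx]),
         hf = mean(rp$fraction[idx]), nSnps = length(idx),
         fractions = rp$fraction[idx],
         logR = mean(rp$logR[idx]))
  })
}

.candidateStates <- function(nA, nB) {
  fA <- unname(floor(nA)); fB <- unname(floor(nB))
  unique(rbind(c(fA, fB), c(fA + 1, fB), c(fA, fB + 1), c(fA + 1, fB + 1)))
}

#' Test whether a segment's copy number is clonal
#'
#' A segment is clonal if its haplotype fraction is consistent with one of
#' the four integer floor/ceiling states of its real-valued allele-specific
#' copy number: consistent means within \code{minDev} of the theoretical
#' clonal fraction, or not rejected by a two-sided one-sample t test on the
#' per-SNP fractions at level \code{alpha}. Otherwise it is subclonal.
#'
#' @param fractions Per-SNP re-phased haplotype fractions of the segment.
#' @param logR Segment log2 relative coverage.
#' @param rho Purity.
#' @param psi Tumor ploidy.
#' @param alpha t-test significance level (default 0.05).
#' @param minDev Minimum deviation of the segmented fraction from a clonal
#'   state required to call subclonality (default 0.01).
#' @return List with \code{call} (\code{"clonal"} or \code{"subclonal"}),
#'   \code{state} (clonal (nA, nB) if clonal), \code{hf} and the candidate
#'   table.
#' @export
testClonality <- function(fractions, logR, rho, psi, alpha = 0.05,
                          minDev = 0.01) {
  hf <- mean(fractions)
  cn <- suppressWarnings(alleleSpecificCN(hf, logR, rho, psi))
  cand <- .candidateStates(cn["nA"], cn["nB"])
  theo <- clonalHf(rho, cand[, 1], cand[, 2])
  dev <- abs(hf - theo)
  pvals <- vapply(theo, function(mu) {
    if (length(fractions) < 2 || stats::sd(fractions) == 0)
      return(as.numeric(abs(hf - mu) < 1e-12))
    stats::t.test(fractions, mu = mu)$p.value
  }, numeric(1))
  clonalIdx <- which(dev < minDev | pvals >= alpha)
  candidates <- data.frame(nA = cand[, 1], nB = cand[, 2], hf = theo,
                           dev = dev, p = pvals)
  if (length(clonalIdx)) {
    best <- clonalIdx[which.min(dev[clonalIdx])]
    list(call = "clonal", state = c(nA = cand[best, 1], nB = cand[best, 2]),
         hf = hf, candidates = candidates)
  } else {
    list(call = "subclonal", state = NULL, hf = hf, candidates = candidates)
  }
}

#' Estimate the subclonal fraction tau of a two-state segment
#'
#' Assuming the aberration gained or lost exactly one copy of one allele,
#' the segment is a mixture of two integer states drawn from the four
#' floor/ceiling combinations of its real-valued copy number; of the two
#' feasible combinations (mixing totals \eqn{\lfloor n \rfloor} with +1, or
#' +1 with +2), the one whose mixture total copy number matches the
#' logR-derived total is selected. The fraction of tumor cells in state 1 is
#' then
#' \deqn{\tau = \frac{1-\rho+\rho n_{B,2} - 2h_f(1-\rho) - h_f\rho(n_{A,2}+n_{B,2})}
#'   {h_f\rho(n_{A,1}+n_{B,1}) - h_f\rho(n_{A,2}+n_{B,2}) - \rho n_{B,1} + \rho n_{B,2}}}
#' with a percentile bootstrap confidence interval over per-SNP resampling.
#'
#' @param fractions Per-SNP re-phased haplotype fractions of the segment.
#' @param logR Segment log2 relative coverage.
#' @param rho Purity.
#' @param psi Tumor ploidy.
#' @param nBoot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @return List with \code{state1}, \code{state2} (named vectors),
#'   \code{tau}, \code{ci} (95\% percentile interval) and \code{hf}.
#' @export
estimateTau <- function(fractions, logR, rho, psi, nBoot = 1000L, seed = 1L) {
  hf <- mean(fractions)
  cn <- suppressWarnings(alleleSpecificCN(hf, logR, rho, psi))
  fA <- floor(cn["nA"]); fB <- floor(cn["nB"])
  combos <- list(list(s1 = c(fA, fB), s2 = c(fA + 1, fB)),
                 list(s1 = c(fA, fB), s2 = c(fA, fB + 1)),
                 list(s1 = c(fA + 1, fB), s2 = c(fA + 1, fB + 1)),
                 list(s1 = c(fA, fB + 1), s2 = c(fA + 1, fB + 1)))
  tauFor <- function(hf, s1, s2) {
    num <- 1 - rho + rho * s2[2] - 2 * hf * (1 - rho) -
      hf * rho * (s2[1] + s2[2])
    den <- hf * rho * (s1[1] + s1[2]) - hf * rho * (s2[1] + s2[2]) -
      rho * s1[2] + rho * s2[2]
    num / den
  }
  taus <- vapply(combos, function(cb) tauFor(hf, cb$s1, cb$s2), numeric(1))
  feas <- which(is.finite(taus) & taus > -1e-9 & taus < 1 + 1e-9)
  if (!length(feas))
    stop("no feasible two-state combination for this segment")
  totalFromLogR <- (2 * rho - 2 + psi * 2^logR) / rho
  mixTotal <- vapply(feas, function(i) {
    cb <- combos[[i]]; t <- min(max(taus[i], 0), 1)
    t * sum(cb$s1) + (1 - t) * sum(cb$s2)
  }, numeric(1))
  pick <- feas[which.min(abs(mixTotal - totalFromLogR))]
  cb <- combos[[pick]]
  tau <- taus[pick]
  if (tau < 0 || tau > 1) {
    warning("tau outside [0, 1] clipped (numeric noise)")
    tau <- min(max(tau, 0), 1)
  }
  set.seed(seed)
  n <- length(fractions)
  bt <- vapply(seq_len(nBoot), function(b) {
    hfB <- mean(fractions[sample.int(n, n, replace = TRUE)])
    min(max(tauFor(hfB, cb$s1, cb$s2), 0), 1)
  }, numeric(1))
  ci <- unname(stats::quantile(bt, c(0.025, 0.975)))
  list(state1 = c(nA = unname(cb$s1[1]), nB = unname(cb$s1[2])),
       state2 = c(nA = unname(cb$s2[1]), nB = unname(cb$s2[2])),
       tau = unname(tau), ci = ci, hf = hf)
}

#' Fine-tune the purity estimate on a clonal reference segment
#'
#' Refines a coarse (two-digit) purity estimate by a 1-D grid search over
#' +/- \code{window}, minimising the absolute difference between the
#' segment's observed haplotype fraction and the theoretical clonal fraction
#' of the given state.
#'
#' @param fractions Per-SNP re-phased haplotype fractions of a clonal
#'   reference segment with known state.
#' @param nA,nB The reference segment's clonal state.
#' @param rho0 Initial purity estimate.
#' @param window Half-width of the search grid (default 0.02).
#' @param stepSize Grid resolution (default 1e-4).
#' @return Refined purity estimate.
#' @export
fineTunePurity <- function(fractions, nA, nB, rho0, window = 0.02,
                           stepSize = 1e-4) {
  hf <- mean(fractions)
  grid <- seq(max(rho0 - window, 1e-3), min(rho0 + window, 1), by = stepSize)
  grid[which.min(abs(hf - clonalHf(grid, nA, nB)))]
}

#' Call clonal and subclonal copy number from phased SNPs
#'
#' Full pipeline per chromosome: re-phase haplotype blocks, segment the
#' re-phased fractions by PCF, test each segment for clonality against its
#' integer candidate states, and estimate the subclonal fraction tau (with
#' bootstrap CI) for subclonal segments. Segments with a balanced haplotype
#' fraction but logR clearly below the diploid baseline are flagged as
#' suspected balanced subclonal losses (both parental copies lost in equal
#' subclones), which haplotype fractions alone cannot reveal.
#'
#' @param snps A \code{\link{PhasedSNPSet}} with a \code{logR} column (or
#'   supply \code{logR}).
#' @param meta A \code{\link{SampleMeta}} (purity, ploidy, seed).
#' @param logR Optional constant log2 relative coverage overriding the
#'   per-SNP column.
#' @param penalty PCF breakpoint penalty (default 3).
#' @param alpha,minDev Clonality-test parameters (see
#'   \code{\link{testClonality}}).
#' @param nBoot Bootstrap resamples for tau (default 1000).
#' @param balancedLogRMargin logR deficit below 0 that triggers the
#'   balanced-loss flag on hf-balanced segments (default 0.05).
#' @return A \code{\link{SegmentSet}} with an extra \code{note} column
#'   (empty, or \code{"balanced subclonal loss suspected"}).
#' @export
callSubclonalCN <- function(snps, meta, logR = NULL, penalty = 3,
                            alpha = 0.05, minDev = 0.01, nBoot = 1000L,
                            balancedLogRMargin = 0.05) {
  rho <- purity(meta); psi <- ploidy(meta)
  out <- NULL
  for (chr in unique(as.character(seqnames(snps)))) {
    sc <- snps[seqnames(snps) == chr]
    segs <- phaseSwitchSegment(sc, penalty = penalty)
    for (k in seq_along(segs)) {
      fr <- segs[[k]]$fractions
      lR <- if (!is.null(logR)) logR else segs[[k]]$logR
      if (is.na(lR))
        stop("no logR available: supply a logR column or argument")
      clon <- testClonality(fr, lR, rho, psi, alpha = alpha, minDev = minDev)
      row <- data.frame(chrom = chr, start = segs[[k]]$startPos,
                        end = segs[[k]]$endPos, logR = lR,
                        subclonal = clon$call == "subclonal",
                        nA1 = NA_real_, nB1 = NA_real_, nA2 = NA_real_,
                        nB2 = NA_real_, tau = NA_real_, tauLo = NA_real_,
                        tauHi = NA_real_, note = "")
      cnReal <- suppressWarnings(alleleSpecificCN(clon$hf, lR, rho, psi))
      row$nA <- unname(cnReal["nA"]); row$nB <- unname(cnReal["nB"])
      if (clon$call == "clonal") {
        row$nA <- unname(clon$state["nA"]); row$nB <- unname(clon$state["nB"])
        if (abs(clon$hf - 0.5) < minDev && lR < -balancedLogRMargin)
          row$note <- "balanced subclonal loss suspected"
      } else {
        est <- estimateTau(fr, lR, rho, psi, nBoot = nBoot,
                           seed = randomSeed(meta))
        row$nA1 <- est$state1["nA"]; row$nB1 <- est$state1["nB"]
        row$nA2 <- est$state2["nA"]; row$nB2 <- est$state2["nB"]
        row$tau <- est$tau; row$tauLo <- est$ci[1]; row$tauHi <- est$ci[2]
      }
      out <- rbind(out, row)
    }
  }
  res <- SegmentSet(out$chrom, out$start, out$end, logR = out$logR,
                    nA = out$nA, nB = out$nB, subclonal = out$subclonal,
                    nA1 = out$nA1, nB1 = out$nB1, nA2 = out$nA2,
                    nB2 = out$nB2, tau = out$tau, tauLo = out$tauLo,
                    tauHi = out$tauHi)
  mcols(res)$note <- out$note
  res
}
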