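# Molecular-time dating of chromosomal gains and early/late mutation-spectrum
# comparison.
#
# On a gained segment, mutations acquired before the gain sit on every copy
# of the duplicated allele (ploidy 2), those acquired after on a single copy
# (ploidy 1). The ratio of the two, normalised by the number of copies at
# risk in each era, dates the gain as a fraction of point-mutation time:
#   trisomy 2+1:    t = n2 / (n2 + (n1 - n2)/3)
#   UPD 2+0:        t = n2 / (n2 + n1/2)
#   tetraploid 2+2: t = n2 / (n2 + n1/2)
# The trisomy form approximates the pre-gain per-copy mutation count by n2
# (the duplicated-allele mutations), so the post-gain per-copy count is
# (n1 - n2)/3 across the three copies.

.GAIN_CLASSES <- c("trisomy_2+1", "UPD_2+0", "tetraploid_2+2")

#' Substitution classes on the pyrimidine strand
#'
#' @return The six pyrimidine-strand substitution class labels.
#' @export
substitutionClasses <- function() {
  c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
}

.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Pyrimidine-strand substitution class of each mutation
#'
#' Substitutions with a purine reference base are complemented so every
#' mutation is expressed as C># or T># on the pyrimidine strand.
#'
#' @param muts A \code{\link{MutationSet}}.
#' @return Factor over \code{\link{substitutionClasses}()}.
#' @export
substitutionClass <- function(muts) {
  ref <- toupper(mcols(muts)$ref); alt <- toupper(mcols(muts)$alt)
  flip <- ref %in% c("A", "G")
  ref[flip] <- .COMP[ref[flip]]
  alt[flip] <- .COMP[alt[flip]]
  factor(paste0(ref, ">", alt), levels = substitutionClasses())
}

#' Mutation multiplicity (ploidy) classification
#'
#' Classifies each mutation on a gained segment as subclonal (variant allele
#' fraction below 75\% of the fully clonal single-copy expectation
#' \eqn{\zeta}) or, otherwise, assigns the maximum-likelihood multiplicity
#' under Binomial(R, m\eqn{\zeta}) across m = 1..\code{maxMult}.
#'
#' @param muts A \code{\link{MutationSet}} with \code{tumorCN} filled.
#' @param meta A \code{\link{SampleMeta}}.
#' @param maxMult Largest multiplicity considered (default the major-allele
#'   copy number; may be supplied per mutation).
#' @param subclonalThreshold VAF fraction of \eqn{\zeta} below which a
#'   mutation is called subclonal (default 0.75).
#' @return Character vector: \code{"subclonal"} or the multiplicity
#'   \code{"1"}, \code{"2"}, ...
#' @export
assignMultiplicity <- function(muts, meta, maxMult = 2,
                               subclonalThreshold = 0.75) {
  mc <- mcols(muts)
  cf <- cellFraction(muts, meta)
  vaf <- mc$altReads / mc$depth
  maxMult <- rep_len(as.integer(maxMult), length(muts))
  out <- character(length(muts))
  sub <- vaf < subclonalThreshold * cf$zeta
  out[sub] <- "subclonal"
  for (i in which(!sub)) {
    ms <- seq_len(max(1L, maxMult[i]))
    ll <- stats::dbinom(mc$altReads[i], mc$depth[i],
                        pmin(ms * cf$zeta[i], 1 - 1e-12), log = TRUE)
    out[i] <- as.character(ms[which.max(ll)])
  }
  out
}

#' Date a chromosomal gain in molecular time
#'
#' Point estimate of when a gain occurred, as a fraction of point-mutation
#' time, from the counts of mutations at ploidy 1 (\code{n1}) and ploidy 2
#' (\code{n2}) on the gained segment.
#'
#' @param n1 Mutations at ploidy 1.
#' @param n2 Mutations at ploidy 2.
#' @param gainClass One of \code{"trisomy_2+1"}, \code{"UPD_2+0"},
#'   \code{"tetraploid_2+2"}.
#' @return Molecular time t in [0, 1].
#' @examples
#' timeGain(n1 = 100, n2 = 20, gainClass = "trisomy_2+1")  # 0.4286
#' @export
timeGain <- function(n1, n2, gainClass = .GAIN_CLASSES) {
  gainClass <- match.arg(gainClass)
  if (n1 + n2 == 0)
    stop("timing is undefined with no mutations on the segment")
  t <- switch(gainClass,
    "trisomy_2+1" = n2 / (n2 + max(n1 - n2, 0) / 3),
    "UPD_2+0" = n2 / (n2 + n1 / 2),
    "tetraploid_2+2" = n2 / (n2 + n1 / 2))
  if (is.nan(t)) t <- 0   # n2 = 0 and no post-gain information
  min(max(t, 0), 1)
}

#' Bootstrap confidence interval for a gain time
#'
#' Resamples the per-mutation ploidy labels with replacement \code{nBoot}
#' times, recomputes the gain time for each resample, and returns the
#' percentile 95\% interval.
#'
#' @param ploidyLabels Vector of per-mutation ploidy classes (\code{"1"} /
#'   \code{"2"}; other labels are ignored).
#' @param gainClass As in \code{\link{timeGain}}.
#' @param nBoot Number of bootstrap resamples (default 10000).
#' @param seed Seed for the resampling.
#' @return List with \code{t} (point estimate), \code{ci} (length-2
#'   percentile interval) and \code{nBoot}.
#' @export
bootstrapTiming <- function(ploidyLabels, gainClass = .GAIN_CLASSES,
                            nBoot = 10000L, seed = 1L) {
  gainClass <- match.arg(gainClass)
  lab <- ploidyLabels[ploidyLabels %in% c("1", "2")]
  n <- length(lab)
  if (n == 0) stop("no ploidy-1 or ploidy-2 mutations to resample")
  set.seed(seed)
  point <- timeGain(sum(lab == "1"), sum(lab == "2"), gainClass)
  ts <- vapply(seq_len(nBoot), function(b) {
    rs <- lab[sample.int(n, n, replace = TRUE)]
    timeGain(sum(rs == "1"), sum(rs == "2"), gainClass)
  }, numeric(1))
  ci <- unname(stats::quantile(ts, c(0.025, 0.975)))
  list(t = point, ci = ci, nBoot = nBoot)
}

#' Test whether several gains are simultaneous
#'
#' Chi-square test of independence on the k x 2 table of (n2, n1) counts
#' across gained segments; a small p value indicates heterogeneous gain
#' times (the gains cannot all stem from a single event such as one
#' endoreduplication).
#'
#' @param n1 Vector of ploidy-1 counts per segment.
#' @param n2 Vector of ploidy-2 counts per segment.
#' @return p value.
#' @export
heterogeneityTest <- function(n1, n2) {
  if (length(n1) != length(n2)) stop("n1 and n2 must have equal length")
  if (length(n1) < 2)
    stop("heterogeneity is undefined for a single segment")
  tab <- cbind(n2 = n2, n1 = n1)
  suppressWarnings(stats::chisq.test(tab))$p.value
}

#' Compare early and late mutation spectra
#'
#' Aggregates mutations in gained regions (uniparental disomy, trisomy,
#' tetraploidy) into "early" (ploidy > 1) and "late" (ploidy 1) sets and
#' compares their substitution-class distributions by a chi-square test of
#' independence. An optional subclonal set is included as a third row.
#'
#' @param earlyCounts,lateCounts Integer vectors of counts over
#'   \code{\link{substitutionClasses}()}.
#' @param subclonalCounts Optional third count vector.
#' @return List with \code{table} (the class-count matrix), \code{chi2} and
#'   \code{p}.
#' @export
compareSpectra <- function(earlyCounts, lateCounts, subclonalCounts = NULL) {
  if (sum(earlyCounts) == 0 || sum(lateCounts) == 0)
    stop("early and late spectra must each contain at least one mutation")
  tab <- rbind(early = earlyCounts, late = lateCounts)
  if (!is.null(subclonalCounts)) tab <- rbind(tab, subclonal = subclonalCounts)
  keep <- colSums(tab) > 0
  ht <- suppressWarnings(stats::chisq.test(tab[, keep, drop = FALSE]))
  list(table = tab, chi2 = unname(ht$statistic), p = ht$p.value)
}

#' Spectrum counts by timing class for a mutation set
#'
#' Convenience wrapper: classifies multiplicities, restricts to the given
#' segments, and tabulates substitution classes for early (ploidy > 1), late
#' (ploidy 1) and subclonal mutations.
#'
#' @param muts A \code{\link{MutationSet}} with contexts/ref/alt filled.
#' @param meta A \code{\link{SampleMeta}}.
#' @param maxMult Largest multiplicity considered per mutation.
#' @return List of three count vectors: \code{early}, \code{late},
#'   \code{subclonal}.
#' @export
spectrumByTiming <- function(muts, meta, maxMult = 2) {
  cls <- substitutionClass(muts)
  plo <- assignMultiplicity(muts, meta, maxMult = maxMult)
  list(early = table(cls[plo %in% c("2", "3", "4")]),
       late = table(cls[plo == "1"]),
       subclonal = table(cls[plo == "subclonal"]))
}
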