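# Readers and writers for the tabular formats shared by every stage.
#
# Mutations: VCF 4.x (per-sample AD carries ref/alt depths) or a headered TSV.
# Segments: BED-like TSV, 0-based half-open start/end.
# Phased SNPs and read pairs: headered TSVs.
# Cluster posteriors and clone trees: JSON.

.readTsv <- function(path, need) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                      na.strings = "NA", colClasses = NA),
    error = function(e) stop("malformed table in ", path, ": ", conditionMessage(e)))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, " is missing required columns: ", paste(miss, collapse = ", "))
  df
}

.checkNumeric <- function(df, cols, path) {
  for (cl in cols) {
    v <- df[[cl]]
    if (!is.numeric(v) && !all(is.na(v))) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("non-numeric value in column '", cl, "' of ", path,
           " at data line ", if (length(bad)) bad[1] else "?")
    }
    df[[cl]] <- as.numeric(v)
  }
  df
}

#' Read somatic mutation calls
#'
#' Reads a somatic substitution table from a VCF 4.x file (read counts taken
#' from the per-sample \code{AD} genotype field, ref then alt depth) or from a
#' tab-separated file with header columns \code{chrom}, \code{pos},
#' \code{ref}, \code{alt}, \code{depth}, \code{alt_reads} and optionally
#' \code{tumor_cn}, \code{normal_cn}, \code{context}. Records with more
#' variant reads than total reads are rejected with an error; missing depth
#' information is an explicit error, never silently defaulted.
#'
#' @param path Path to the file.
#' @param format \code{"tsv"} or \code{"vcf"}; guessed from the extension by
#'   default.
#' @param sample For VCF input, which sample column holds the tumor (default
#'   the first).
#' @return A \code{\link{MutationSet}}.
#' @export
readMutations <- function(path, format = c("auto", "tsv", "vcf"), sample = 1L) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") {
    vcf <- VariantAnnotation::readVcf(path)
    ad <- VariantAnnotation::geno(vcf)$AD
    if (is.null(ad))
      stop("VCF has no AD genotype field; per-record read depths are required")
    adList <- ad[, sample]
    r <- vapply(adList, function(x) as.integer(x[2]), integer(1))
    R <- vapply(adList, function(x) as.integer(sum(x)), integer(1))
    rr <- SummarizedExperiment::rowRanges(vcf)
    alt <- vapply(as.list(VariantAnnotation::alt(vcf)),
                  function(a) as.character(a[1]), character(1))
    return(MutationSet(as.character(seqnames(rr)), start(rr),
                       as.character(VariantAnnotation::ref(vcf)), alt,
                       depth = R, altReads = r))
  }
  df <- .readTsv(path, c("chrom", "pos", "ref", "alt", "depth", "alt_reads"))
  df <- .checkNumeric(df, intersect(
    c("pos", "depth", "alt_reads", "tumor_cn", "normal_cn"), names(df)), path)
  if (anyNA(df$depth) || anyNA(df$alt_reads)) {
    bad <- which(is.na(df$depth) | is.na(df$alt_reads))[1]
    stop("missing depth/alt_reads at data line ", bad, " of ", path)
  }
  MutationSet(df$chrom, df$pos, df$ref, df$alt, df$depth, df$alt_reads,
              tumorCN = if ("tumor_cn" %in% names(df)) df$tumor_cn else NA_real_,
              normalCN = if ("normal_cn" %in% names(df)) df$normal_cn else 2,
              context = if ("context" %in% names(df)) df$context else NA_character_)
}

#' Write somatic mutation calls as TSV
#'
#' @param x A \code{\link{MutationSet}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeMutations <- function(x, path) {
  m <- mcols(x)
  df <- data.frame(chrom = as.character(seqnames(x)), pos = start(x),
                   ref = m$ref, alt = m$alt, depth = m$depth,
                   alt_reads = m$altReads, tumor_cn = m$tumorCN,
                   normal_cn = m$normalCN, context = m$context)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a copy-number segment table
#'
#' BED-like TSV with 0-based half-open \code{start}/\code{end} and header
#' columns matching \code{\link{writeSegments}} output. Overlapping segments
#' on one chromosome are an error.
#'
#' @param path Path to the TSV.
#' @return A \code{\link{SegmentSet}}.
#' @export
readSegments <- function(path) {
  df <- .readTsv(path, c("chrom", "start", "end"))
  if (nrow(df) == 0)
    return(SegmentSet(character(), integer(), integer()))
  df <- .checkNumeric(df, intersect(
    c("start", "end", "logr", "n_a", "n_b", "n_a1", "n_b1", "n_a2", "n_b2",
      "tau", "tau_lo", "tau_hi"), names(df)), path)
  gv <- function(cl) if (cl %in% names(df)) df[[cl]] else NA_real_
  SegmentSet(df$chrom, df$start + 1L, df$end,
             logR = gv("logr"), nA = gv("n_a"), nB = gv("n_b"),
             subclonal = if ("subclonal" %in% names(df)) as.logical(df$subclonal) else FALSE,
             nA1 = gv("n_a1"), nB1 = gv("n_b1"),
             nA2 = gv("n_a2"), nB2 = gv("n_b2"),
             tau = gv("tau"), tauLo = gv("tau_lo"), tauHi = gv("tau_hi"))
}

#' Write a copy-number segment table as BED-like TSV
#'
#' @param x A \code{\link{SegmentSet}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSegments <- function(x, path) {
  m <- mcols(x)
  df <- data.frame(chrom = as.character(seqnames(x)), start = start(x) - 1L,
                   end = end(x), logr = m$logR, n_a = m$nA, n_b = m$nB,
                   subclonal = m$subclonal, n_a1 = m$nA1, n_b1 = m$nB1,
                   n_a2 = m$nA2, n_b2 = m$nB2, tau = m$tau,
                   tau_lo = m$tauLo, tau_hi = m$tauHi)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phased heterozygous-SNP table
#'
#' TSV with header columns \code{chrom}, \code{pos}, \code{hap1_reads},
#' \code{hap2_reads}, \code{block_id} and optionally \code{logr}.
#'
#' @param path Path to the TSV.
#' @return A \code{\link{PhasedSNPSet}}.
#' @export
readPhasedSNPs <- function(path) {
  df <- .readTsv(path, c("chrom", "pos", "hap1_reads", "hap2_reads", "block_id"))
  if (nrow(df) == 0)
    return(PhasedSNPSet(character(), integer(), integer(), integer(), character()))
  df <- .checkNumeric(df, intersect(c("pos", "hap1_reads", "hap2_reads", "logr"),
                                    names(df)), path)
  PhasedSNPSet(df$chrom, df$pos, df$hap1_reads, df$hap2_reads, df$block_id,
               logR = if ("logr" %in% names(df)) df$logr else NA_real_)
}

#' Write a phased heterozygous-SNP table
#'
#' @param x A \code{\link{PhasedSNPSet}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePhasedSNPs <- function(x, path) {
  m <- mcols(x)
  df <- data.frame(chrom = as.character(seqnames(x)), pos = start(x),
                   hap1_reads = m$hap1Reads, hap2_reads = m$hap2Reads,
                   block_id = m$blockId, logr = m$logR)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read read-pair co-occurrence records
#'
#' TSV with header columns \code{chrom}, \code{posA}, \code{posB},
#' \code{nBoth}, \code{nAOnly}, \code{nBOnly}, \code{nNeither}.
#'
#' @param path Path to the TSV.
#' @return A \code{\link{ReadPairEvidence}} data.frame.
#' @export
readReadPairs <- function(path) {
  df <- .readTsv(path, c("chrom", "posA", "posB", "nBoth", "nAOnly",
                         "nBOnly", "nNeither"))
  ReadPairEvidence(df)
}

#' Write read-pair co-occurrence records
#'
#' @param x A \code{\link{ReadPairEvidence}} data.frame.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeReadPairs <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Fill locus copy number of mutations from a segment table
#'
#' Mutations with missing \code{tumorCN} take the total copy number of the
#' overlapping segment; on subclonal two-state segments the cell-fraction
#' weighted mean total copy number is used. Mutations falling in no segment
#' are dropped, with a message reporting how many.
#'
#' @param muts A \code{\link{MutationSet}}.
#' @param segs A \code{\link{SegmentSet}}.
#' @return The annotated (possibly shortened) \code{MutationSet}.
#' @export
annotateCopyNumber <- function(muts, segs) {
  ov <- findOverlaps(granges(muts), granges(segs))
  hit <- rep(NA_integer_, length(muts))
  hit[queryHits(ov)] <- subjectHits(ov)
  keep <- !is.na(hit) | !is.na(mcols(muts)$tumorCN)
  nDropped <- sum(!keep)
  if (nDropped > 0)
    message(nDropped, " mutation(s) outside all segments dropped")
  muts <- muts[keep]
  hit <- hit[keep]
  need <- is.na(mcols(muts)$tumorCN) & !is.na(hit)
  if (any(need)) {
    s <- mcols(segs)
    cn <- segmentTotalCN(segs)[hit[need]]
    mcols(muts)$tumorCN[need] <- cn
  }
  muts
}

#' Effective total tumor copy number of each segment
#'
#' Clonal segments return \code{nA + nB}; subclonal two-state segments return
#' the cell-fraction weighted mean of the two state totals.
#'
#' @param segs A \code{\link{SegmentSet}}.
#' @return Numeric vector of total copy numbers.
#' @export
segmentTotalCN <- function(segs) {
  s <- mcols(segs)
  tot <- s$nA + s$nB
  sub <- which(s$subclonal %in% TRUE & !is.na(s$tau) & !is.na(s$nA1))
  if (length(sub))
    tot[sub] <- s$tau[sub] * (s$nA1[sub] + s$nB1[sub]) +
      (1 - s$tau[sub]) * (s$nA2[sub] + s$nB2[sub])
  tot
}

#' Write a Dirichlet-process cluster posterior as JSON
#'
#' Serialises the cluster summary, posterior density grid and convergence
#' diagnostic of a \code{\link{ClusterFit}}.
#'
#' @param fit A \code{ClusterFit}.
#' @param path Output path.
#' @param draws Also include the monitored per-draw locations and weights
#'   (larger file); default FALSE.
#' @return \code{path}, invisibly.
#' @export
writeClusters <- function(fit, path, draws = FALSE) {
  out <- list(sample = sampleId(fit@meta), purity = purity(fit@meta),
              rhat = fit@rhat, converged = fit@converged,
              clusters = fit@clusterSummary, density = fit@density)
  if (draws)
    out$draws <- list(locations = fit@locations, weights = fit@weights)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.nodeToList <- function(node) {
  list(label = node$label, fraction = node$fraction,
       n_mutations = node$nMutations, events = as.list(node$events),
       ambiguous = isTRUE(node$ambiguous),
       children = lapply(node$children, .nodeToList))
}

.nodeFromList <- function(x) {
  list(label = x$label, fraction = as.numeric(x$fraction),
       nMutations = as.integer(x$n_mutations),
       events = as.character(unlist(x$events)),
       ambiguous = isTRUE(x$ambiguous),
       children = lapply(x$children, .nodeFromList))
}

#' Write a clone tree as JSON
#'
#' @param tree A \code{\link{CloneTree}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTree <- function(tree, path) {
  jsonlite::write_json(list(epsilon = tree@epsilon,
                            root = .nodeToList(tree@root)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a clone tree from JSON
#'
#' @param path Path written by \code{\link{writeTree}}.
#' @return A \code{\link{CloneTree}}.
#' @export
readTree <- function(path) {
  x <- jsonlite::read_json(path)
  new("CloneTree", root = .nodeFromList(x$root), constraints = data.frame(),
      epsilon = as.numeric(x$epsilon))
}
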