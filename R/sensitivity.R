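# Spike-in estimation of mutation-detection sensitivity, and the
# three-parameter logistic fit used to correct Dirichlet-process weights.
#
# At each level of subclonality theta, simulated variant reads are introduced
# at wild-type positions by the per-read uniform-draw scheme: a draw below
# zeta*theta flips a reference base call to the variant; a sequencing-error
# base is left unless it already shows the variant, in which case it is
# changed away. The caller predicate is then applied and the detected
# fraction recorded.

#' Default variant-caller predicate
#'
#' Calls a site if at least \code{minReads} reads report the variant and the
#' variant allele fraction is at least \code{minVAF}. Stands in for a
#' production somatic caller; any predicate on (variant reads, depth) can be
#' supplied to \code{\link{spikeInSensitivity}} instead.
#'
#' @param minReads Minimum variant-supporting reads (default 4).
#' @param minVAF Minimum variant allele fraction (default 0.05).
#' @return A function(varReads, depth) returning logical.
#' @export
defaultCaller <- function(minReads = 4, minVAF = 0.05) {
  function(varReads, depth) varReads >= minReads & varReads / depth >= minVAF
}

#' Estimate detection sensitivity by spike-in simulation
#'
#' For each level of subclonality \code{theta}, simulates \code{nPositions}
#' wild-type pileups (Poisson depths around \code{coverage}, base-call errors
#' at rate \code{errorRate}), introduces variant reads by the per-read
#' uniform-draw scheme at expected variant fraction \eqn{\zeta\theta}, runs
#' the caller predicate, and records the fraction of positions called.
#'
#' @param coverage Mean sequencing depth.
#' @param meta A \code{\link{SampleMeta}} giving purity and the seed.
#' @param levels Fractions of tumor cells to spike at (in (0, 1]).
#' @param nPositions Positions per level (default 10000).
#' @param caller Predicate function(varReads, depth) -> logical.
#' @param tumorCN,normalCN Copy numbers assumed at the spiked loci.
#' @param errorRate Per-read probability of a sequencing-error base call.
#' @return data.frame with columns \code{theta} and \code{detected}.
#' @export
spikeInSensitivity <- function(coverage, meta, levels,
                               nPositions = 10000L,
                               caller = defaultCaller(),
                               tumorCN = 2, normalCN = 2,
                               errorRate = 0.002) {
  if (!length(levels)) stop("at least one subclonality level is required")
  stopifnot(all(levels > 0 & levels <= 1))
  set.seed(randomSeed(meta))
  zeta <- expectedVAF(meta, tumorCN, normalCN)
  detected <- vapply(levels, function(theta) {
    depth <- stats::rpois(nPositions, coverage)
    p <- zeta * theta
    nErr <- stats::rbinom(nPositions, depth, errorRate)
    # a third of error base calls happen to show the chosen variant allele
    nErrVar <- stats::rbinom(nPositions, nErr, 1 / 3)
    # reference reads whose uniform draw falls below zeta*theta become variant
    flipped <- stats::rbinom(nPositions, depth - nErr, p)
    # error reads already showing the variant are flipped away when drawn
    keptErrVar <- nErrVar - stats::rbinom(nPositions, nErrVar, p)
    varReads <- flipped + keptErrVar
    mean(caller(varReads, pmax(depth, 1L)))
  }, numeric(1))
  data.frame(theta = levels, detected = detected)
}

#' Fit the three-parameter logistic sensitivity curve
#'
#' Nonlinear least-squares fit of
#' \eqn{S(\theta) = A/(1 + \exp((\chi - \log\theta)/\sigma))} to spike-in
#' detection fractions.
#'
#' @param rawPoints data.frame with columns \code{theta}, \code{detected}
#'   (at least 4 distinct levels).
#' @param start Optional named list of starting values \code{A}, \code{chi},
#'   \code{sigma}. Defaults: A = max response, chi = log of the level nearest
#'   half-max, sigma = 0.5.
#' @return A \code{\link{SensitivityCurve}} with the residuals attached as
#'   attribute \code{"residuals"}.
#' @export
fitLogistic <- function(rawPoints, start = NULL) {
  stopifnot(all(c("theta", "detected") %in% names(rawPoints)))
  if (length(unique(rawPoints$theta)) < 4)
    stop("at least 4 distinct subclonality levels are required")
  resp <- rawPoints$detected
  if (length(unique(round(resp, 10))) == 1)
    stop("degenerate detection fractions (all equal): no curve to fit")
  if (is.null(start)) {
    A0 <- min(max(resp), 1)
    half <- rawPoints$theta[which.min(abs(resp - A0 / 2))]
    start <- list(A = A0, chi = log(half), sigma = 0.5)
  }
  fit <- minpack.lm::nlsLM(
    detected ~ A / (1 + exp((chi - log(theta)) / sigma)),
    data = rawPoints, start = start,
    lower = c(A = 1e-6, chi = -20, sigma = 1e-4),
    upper = c(A = 1, chi = 20, sigma = 50),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  out <- SensitivityCurve(cf[["A"]], cf[["chi"]], cf[["sigma"]],
                          rawPoints = rawPoints)
  attr(out, "residuals") <- stats::residuals(fit)
  out
}

#' Default detection-sensitivity curve for 30--40x genomes
#'
#' A three-parameter logistic (A = 0.9, chi = -0.9, sigma = 0.2) giving
#' roughly 90\% sensitivity for fully clonal mutations, 60\% at half the
#' tumor cells and a few percent at a quarter — the regime typical of 30--40x
#' whole genomes with a stringent somatic caller.
#'
#' @return A \code{\link{SensitivityCurve}}.
#' @examples
#' round(sensitivity(defaultSensitivityCurve(), c(1, 0.5, 0.25)), 2)
#' @export
defaultSensitivityCurve <- function() {
  SensitivityCurve(A = 0.9, chi = -0.9, sigma = 0.2)
}
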