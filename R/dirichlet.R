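# Truncated stick-breaking Gibbs sampler for the Dirichlet-process mixture of
# binomial variant-read counts.
#
# Model: y_i ~ Bin(N_i, zeta_i * pi_i), pi_i ~ DP(alpha * P0), P0 = U(0, 1),
# alpha ~ Gamma(0.01, 0.01), truncated at H clusters via the stick-breaking
# construction kappa_h = V_h prod_{l<h} (1 - V_l), V_h ~ Beta(1, alpha),
# V_H = 1 so the weights sum to one at every iteration.
#
# The binomial likelihood is not conjugate in pi_h, so cluster locations are
# updated by a reflected random-walk Metropolis step (step size adapted during
# burn-in); empty clusters are refreshed from the uniform base measure.
# Reported cluster weights are corrected for the detection sensitivity S:
# omega_h = kappa_h S(pi_h) / sum_i kappa_i S(pi_i).

.PI_MIN <- 1e-4

.reflect01 <- function(x, lo = .PI_MIN, hi = 1) {
  # reflect a proposal into [lo, hi]; symmetric for step sizes << (hi - lo)
  span <- 2 * (hi - lo)
  x <- (x - lo) %% span
  x <- ifelse(x > (hi - lo), span - x, x)
  x + lo
}

.splitRhat <- function(x) {
  m <- length(x) %/% 2
  if (m < 5) return(NA_real_)
  a <- x[seq_len(m)]; b <- x[(m + 1):(2 * m)]
  W <- (stats::var(a) + stats::var(b)) / 2
  B <- m * (mean(a) - mean(b))^2 / 2  # two split chains of length m
  if (W <= 0) return(1)
  varPlus <- (m - 1) / m * W + B / m
  sqrt(varPlus / W)
}

#' Fit the sensitivity-corrected Dirichlet-process cluster model
#'
#' Clusters somatic mutations by the fraction of tumor cells carrying them,
#' using a truncated stick-breaking Gibbs sampler for the Dirichlet-process
#' mixture of binomial read counts. Cluster weights are corrected for the
#' probability of having detected a mutation at each subclonal fraction, so
#' that reported weights and mutation counts estimate the true underlying
#' numbers rather than the observed ones.
#'
#' @param muts A \code{\link{MutationSet}} with \code{tumorCN} filled.
#' @param meta A \code{\link{SampleMeta}}; its seed makes the fit
#'   reproducible.
#' @param sensitivityCurve A \code{\link{SensitivityCurve}}, or NULL for flat
#'   sensitivity (no correction).
#' @param iters Total Gibbs iterations (default 20000).
#' @param burn Burn-in iterations discarded (default 13000).
#' @param H Truncation level of the stick-breaking representation (default 30).
#' @param maxMonitor Cap on the number of monitored post-burn-in draws kept
#'   (thinning is derived from it).
#' @param densityGridN Number of grid points for the posterior density over
#'   (0, 1].
#' @return A \code{\link{ClusterFit}}.
#' @export
fitDirichlet <- function(muts, meta, sensitivityCurve = NULL,
                         iters = 20000L, burn = 13000L, H = 30L,
                         maxMonitor = 1000L, densityGridN = 256L) {
  mc <- mcols(muts)
  n <- length(muts)
  if (n < 20)
    stop("at least 20 mutations are required to fit the cluster model")
  if (burn >= iters) stop("burn must be smaller than iters")
  cf <- cellFraction(muts, meta)
  y <- mc$altReads; N <- mc$depth; zeta <- cf$zeta
  set.seed(randomSeed(meta))

  thin <- max(1L, as.integer(floor((iters - burn) / maxMonitor)))
  nMon <- length(seq.int(burn + 1L, iters, by = thin))
  piMon <- matrix(NA_real_, nMon, H)
  kapMon <- matrix(NA_real_, nMon, H)
  cntMon <- matrix(NA_integer_, nMon, H)
  alphaMon <- numeric(nMon)
  llMon <- numeric(nMon)

  # initial state: locations spread over the observed cell fractions
  pi <- stats::quantile(pmax(pmin(cf$f, 1), .PI_MIN),
                        probs = seq(0.02, 1, length.out = H), names = FALSE)
  pi <- pmin(pmax(pi + stats::runif(H, -0.01, 0.01), .PI_MIN), 1)
  V <- c(rep(0.5, H - 1), 1)
  alpha <- 1
  step <- rep(0.03, H)
  accTarget <- 0.44
  mon <- 0L

  for (it in seq_len(iters)) {
    # stick weights
    kappa <- V * cumprod(c(1, 1 - V[-H]))

    # allocation of mutations to clusters (Gumbel-max on log posteriors)
    P <- outer(zeta, pi)                       # n x H success probabilities
    P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
    logP <- sweep(y * log(P) + (N - y) * log1p(-P), 2, log(kappa + 1e-300), "+")
    g <- -log(-log(matrix(stats::runif(n * H), n, H)))
    z <- max.col(logP + g)
    nh <- tabulate(z, H)

    # stick-breaking beta updates; V_H = 1 keeps the weights summing to 1
    nGreater <- rev(cumsum(rev(nh)))  # counts in clusters >= h
    tail <- c(nGreater[-1], 0)
    V[-H] <- stats::rbeta(H - 1, 1 + nh[-H], alpha + tail[-H])
    V[-H] <- pmin(pmax(V[-H], 1e-9), 1 - 1e-9)
    V[H] <- 1

    # concentration parameter (conjugate gamma update)
    alpha <- stats::rgamma(1, shape = 0.01 + H - 1,
                           rate = 0.01 - sum(log1p(-V[-H])))

    # cluster locations: reflected random-walk Metropolis, uniform prior
    piProp <- .reflect01(pi + stats::rnorm(H, 0, step))
    pCur <- pmin(pmax(zeta * pi[z], 1e-12), 1 - 1e-12)
    pNew <- pmin(pmax(zeta * piProp[z], 1e-12), 1 - 1e-12)
    llCur <- y * log(pCur) + (N - y) * log1p(-pCur)
    llNew <- y * log(pNew) + (N - y) * log1p(-pNew)
    occ <- which(nh > 0)
    dSum <- rep(0, H)
    d <- rowsum(llNew - llCur, group = z)
    dSum[as.integer(rownames(d))] <- d[, 1]
    accept <- log(stats::runif(H)) < dSum
    accept[nh == 0] <- FALSE
    pi[accept] <- piProp[accept]
    # empty clusters: posterior equals the U(0,1) base measure
    if (any(nh == 0)) pi[nh == 0] <- stats::runif(sum(nh == 0), .PI_MIN, 1)
    if (it <= burn) {
      # Robbins-Monro adaptation toward the target acceptance rate
      step[occ] <- pmin(0.25, pmax(1e-3, step[occ] *
        exp((as.numeric(accept[occ]) - accTarget) / sqrt(it))))
    }

    if (it > burn && (it - burn - 1L) %% thin == 0L) {
      mon <- mon + 1L
      piMon[mon, ] <- pi
      kapMon[mon, ] <- kappa
      cntMon[mon, ] <- nh
      alphaMon[mon] <- alpha
      pz <- pmin(pmax(zeta * pi[z], 1e-12), 1 - 1e-12)
      llMon[mon] <- sum(stats::dbinom(y, N, pz, log = TRUE))
    }
  }
  piMon <- piMon[seq_len(mon), , drop = FALSE]
  kapMon <- kapMon[seq_len(mon), , drop = FALSE]
  cntMon <- cntMon[seq_len(mon), , drop = FALSE]
  alphaMon <- alphaMon[seq_len(mon)]
  llMon <- llMon[seq_len(mon)]

  rhat <- .splitRhat(llMon)
  converged <- is.na(rhat) || rhat < 1.1
  if (!converged)
    warning(sprintf("chain may not have converged (split Rhat = %.3f)", rhat))

  S <- matrix(sensitivity(sensitivityCurve, as.vector(piMon)), nrow(piMon))
  omegaRaw <- kapMon * S
  omega <- omegaRaw / rowSums(omegaRaw)

  dens <- .posteriorDensityGrid(piMon, kapMon, densityGridN)
  summ <- .summariseClusters(dens, piMon, kapMon, cntMon, omega, S)

  new("ClusterFit", locations = piMon, weights = kapMon, counts = cntMon,
      alpha = alphaMon, correctedWeights = omega, density = dens,
      clusterSummary = summ, rhat = if (is.na(rhat)) 1 else rhat,
      converged = converged, meta = meta, sensitivityCurve = sensitivityCurve)
}

# kappa-weighted Gaussian-kernel density of the monitored (pi, kappa) draws,
# renormalised to integrate to 1 over (0, 1]; Silverman's rule bandwidth on
# the weight-resampled pooled draws.
.posteriorDensityGrid <- function(piMon, kapMon, gridN) {
  x <- seq(1 / gridN, 1, length.out = gridN)
  w <- as.vector(kapMon); p <- as.vector(piMon)
  keep <- w > 1e-6
  w <- w[keep]; p <- p[keep]
  wm <- sum(w * p) / sum(w)
  wsd <- sqrt(sum(w * (p - wm)^2) / sum(w))
  nEff <- sum(w)^2 / sum(w^2)
  bw <- max(0.9 * wsd * nEff^(-1/5), 0.004)
  nd <- nrow(piMon)
  densMat <- matrix(0, nd, gridN)
  for (d in seq_len(nd)) {
    kd <- kapMon[d, ]
    yd <- stats::dnorm(outer(x, piMon[d, ], "-") / bw) %*% kd / bw
    tot <- sum(yd) * (x[2] - x[1])
    densMat[d, ] <- yd / tot
  }
  y <- apply(densMat, 2, stats::median)
  y <- y / (sum(y) * (x[2] - x[1]))   # pointwise median renormalised
  data.frame(x = x, y = y,
             lo = apply(densMat, 2, stats::quantile, 0.025),
             hi = apply(densMat, 2, stats::quantile, 0.975))
}

# identify modes of the posterior median density and aggregate draws to them
.summariseClusters <- function(dens, piMon, kapMon, cntMon, omega, S) {
  y <- dens$y; x <- dens$x; g <- length(x)
  isPeak <- c(FALSE, y[2:(g - 1)] > y[1:(g - 2)] & y[2:(g - 1)] >= y[3:g], FALSE)
  isPeak[g] <- y[g] > y[g - 1]   # boundary mode at pi = 1 (fully clonal)
  peaks <- x[isPeak & y > 0.01 * max(y)]
  if (!length(peaks)) peaks <- x[which.max(y)]
  nd <- nrow(piMon); K <- length(peaks)
  wSum <- matrix(0, nd, K); cSum <- matrix(0, nd, K)
  corrected <- cntMon / S
  for (d in seq_len(nd)) {
    idx <- apply(abs(outer(piMon[d, ], peaks, "-")), 1, which.min)
    wSum[d, ] <- vapply(seq_len(K), function(k)
      sum(omega[d, idx == k]), numeric(1))
    cSum[d, ] <- vapply(seq_len(K), function(k)
      sum(corrected[d, idx == k]), numeric(1))
  }
  summ <- data.frame(
    location = peaks,
    weight = apply(wSum, 2, stats::median),
    count = apply(cSum, 2, stats::median),
    countLo = apply(cSum, 2, stats::quantile, 0.025),
    countHi = apply(cSum, 2, stats::quantile, 0.975))
  summ <- summ[summ$weight >= 0.01, , drop = FALSE]
  summ[order(summ$location, decreasing = TRUE), , drop = FALSE]
}

#' Assign mutations to clusters and count mutations per subclonality band
#'
#' Assigns each mutation to the posterior cluster with the highest
#' probability (given the summarised cluster locations and corrected
#' weights), and reports sensitivity-corrected genome-wide mutation counts in
#' the bands fully clonal (>= 95\% of tumor cells), 50--95\%, 25--50\% and
#' < 25\%, as posterior medians with 95\% intervals.
#'
#' @param fit A \code{\link{ClusterFit}}.
#' @param muts The \code{\link{MutationSet}} that was fitted.
#' @param sensFloor Lower bound applied to S(pi) before dividing observed
#'   counts (default 0.05): below this sensitivity the correction factor is
#'   capped at 1/sensFloor, so counts in very low subclonality bands are
#'   conservative lower bounds rather than unstable amplifications.
#' @return A list with \code{assignments} (data.frame: cluster index,
#'   location per mutation) and \code{bands} (data.frame: band, count, lo,
#'   hi).
#' @export
classifyMutations <- function(fit, muts, sensFloor = 0.05) {
  mc <- mcols(muts)
  cf <- cellFraction(muts, fit@meta)
  summ <- fit@clusterSummary
  ll <- vapply(seq_len(nrow(summ)), function(k) {
    p <- pmin(pmax(cf$zeta * summ$location[k], 1e-12), 1 - 1e-12)
    log(summ$weight[k] + 1e-300) + stats::dbinom(mc$altReads, mc$depth, p, log = TRUE)
  }, numeric(length(muts)))
  ll <- matrix(ll, nrow = length(muts))
  k <- max.col(ll)
  assignments <- data.frame(cluster = k, location = summ$location[k])

  # per-draw sensitivity-corrected counts, aggregated into subclonality bands
  breaks <- c(-Inf, 0.25, 0.5, 0.95, Inf)
  labels <- c("below 25% cells", "25-50% cells", "50-95% cells", "clonal")
  S <- matrix(sensitivity(fit@sensitivityCurve,
                          pmin(pmax(as.vector(fit@locations), .PI_MIN), 1)),
              nrow(fit@locations))
  corr <- fit@counts / pmax(S, sensFloor)
  bandIdx <- matrix(cut(as.vector(fit@locations), breaks, labels = FALSE),
                    nrow(fit@locations))
  nd <- nrow(fit@locations)
  bandCounts <- matrix(0, nd, 4)
  for (d in seq_len(nd)) {
    occupied <- fit@counts[d, ] > 0
    bandCounts[d, ] <- vapply(1:4, function(b)
      sum(corr[d, occupied & bandIdx[d, ] == b]), numeric(1))
  }
  bands <- data.frame(
    band = labels,
    count = apply(bandCounts, 2, stats::median),
    lo = apply(bandCounts, 2, stats::quantile, 0.025),
    hi = apply(bandCounts, 2, stats::quantile, 0.975))
  list(assignments = assignments, bands = bands)
}
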