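# Dirichlet-process clustering: recovery, stick-breaking invariants,
# sensitivity correction.

# independent oracle: two-component binomial mixture EM on (y, N, zeta)
emTwoComponent <- function(y, N, zeta, iters = 300) {
  pi <- c(0.9, 0.4); w <- c(0.5, 0.5)
  for (it in seq_len(iters)) {
    ll <- vapply(1:2, function(k)
      log(w[k]) + dbinom(y, N, pmin(zeta * pi[k], 1 - 1e-12), log = TRUE),
      numeric(length(y)))
    r <- exp(ll - apply(ll, 1, max))
    r <- r / rowSums(r)
    w <- colMeans(r)
    for (k in 1:2)
      pi[k] <- min(1, sum(r[, k] * y) / sum(r[, k] * N) / zeta)
  }
  sort(pi, decreasing = TRUE)
}

test_that("two components are recovered within 0.02 of the EM oracle", {
  meta <- makeMeta(0.70, seed = 7L)
  muts <- makeClusteredMutations(c(1, 0.5), c(200, 200), depth = 500,
                                 meta, seed = 7L)
  mc <- S4Vectors::mcols(muts)
  oracle <- emTwoComponent(mc$altReads, mc$depth, 0.35)
  fit <- fitDirichlet(muts, meta, NULL, iters = 3000L, burn = 1000L)
  locs <- sort(clusterLocations(fit), decreasing = TRUE)[1:2]
  expect_equal(locs[1], oracle[1], tolerance = 0.02 / oracle[1])
  expect_equal(locs[2], oracle[2], tolerance = 0.02 / oracle[2])
})

test_that("identical deep mutations collapse to one clonal cluster", {
  meta <- makeMeta(0.70, seed = 3L)
  n <- 50L
  muts <- MutationSet("chr1", seq_len(n), "C", "T",
                      depth = rep(10000L, n), altReads = rep(3500L, n),
                      tumorCN = 2)
  fit <- fitDirichlet(muts, meta, NULL, iters = 1500L, burn = 500L)
  cs <- fit@clusterSummary
  expect_equal(nrow(cs), 1L)
  expect_gt(cs$location[1], 0.97)
  expect_gt(cs$weight[1], 0.95)
})

test_that("stick-breaking weights sum to 1 at every monitored iteration", {
  meta <- makeMeta(0.70, seed = 5L)
  muts <- makeClusteredMutations(c(1, 0.4), c(40, 40), depth = 100,
                                 meta, seed = 5L)
  fit <- fitDirichlet(muts, meta, NULL, iters = 800L, burn = 300L)
  expect_true(all(abs(rowSums(fit@weights) - 1) < 1e-12))
})

test_that("flat sensitivity leaves the corrected weights untouched", {
  meta <- makeMeta(0.70, seed = 5L)
  muts <- makeClusteredMutations(c(1, 0.4), c(40, 40), depth = 100,
                                 meta, seed = 5L)
  fit <- fitDirichlet(muts, meta, NULL, iters = 800L, burn = 300L)
  expect_equal(fit@correctedWeights, fit@weights, tolerance = 1e-12)
})

test_that("a sensitivity curve reweights clusters exactly as omega", {
  meta <- makeMeta(0.70, seed = 9L)
  muts <- makeClusteredMutations(c(1, 0.4), c(60, 60), depth = 150,
                                 meta, seed = 9L)
  curve <- defaultSensitivityCurve()
  fit <- suppressWarnings(
    fitDirichlet(muts, meta, curve, iters = 800L, burn = 300L))
  S <- matrix(sensitivity(curve, pmin(pmax(as.vector(fit@locations), 1e-4), 1)),
              nrow(fit@locations))
  omega <- fit@weights * S / rowSums(fit@weights * S)
  expect_equal(fit@correctedWeights, omega, tolerance = 1e-12)
})

test_that("the posterior density integrates to one over (0, 1]", {
  meta <- makeMeta(0.70, seed = 5L)
  muts <- makeClusteredMutations(c(1, 0.4), c(40, 40), depth = 100,
                                 meta, seed = 5L)
  fit <- fitDirichlet(muts, meta, NULL, iters = 800L, burn = 300L)
  d <- posteriorDensity(fit)
  expect_equal(sum(d$y) * (d$x[2] - d$x[1]), 1, tolerance = 1e-6)
})

test_that("a single clonal cluster puts all mutations in the clonal band", {
  meta <- makeMeta(0.70, seed = 3L)
  muts <- makeClusteredMutations(1, 120, depth = 800, meta, seed = 13L)
  fit <- fitDirichlet(muts, meta, NULL, iters = 1500L, burn = 500L)
  cls <- classifyMutations(fit, muts)
  clonal <- cls$bands$count[cls$bands$band == "clonal"]
  expect_equal(clonal, 120, tolerance = 0.05)
  expect_true(all(cls$assignments$location > 0.95))
})

test_that("forty uniform subclones yield a flat weight profile", {
  # many small clusters evenly spread through (0, 1], observed at deep
  # validation-grade coverage: no single cluster should dominate
  meta <- makeMeta(0.70, seed = 21L)
  pis <- seq(0.025, 1, by = 0.025)
  muts <- makeClusteredMutations(pis, rep(13L, 40), depth = 500,
                                 meta, seed = 21L)
  fit <- suppressWarnings(
    fitDirichlet(muts, meta, NULL, iters = 3000L, burn = 1000L))
  maxW <- apply(fit@correctedWeights, 1, max)
  expect_lt(median(maxW), 0.15)
})

test_that("the fit is reproducible from the SampleMeta seed", {
  meta <- makeMeta(0.70, seed = 17L)
  muts <- makeClusteredMutations(c(1, 0.5), c(30, 30), depth = 120,
                                 meta, seed = 17L)
  f1 <- fitDirichlet(muts, meta, NULL, iters = 500L, burn = 200L)
  f2 <- fitDirichlet(muts, meta, NULL, iters = 500L, burn = 200L)
  expect_identical(f1@locations, f2@locations)
  expect_identical(f1@weights, f2@weights)
})

test_that("fewer than 20 mutations are refused", {
  meta <- makeMeta(0.70)
  muts <- makeClusteredMutations(1, 10, depth = 100, meta)
  expect_error(fitDirichlet(muts, meta), "at least 20")
})
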