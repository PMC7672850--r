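test_that("objective matches a term-by-term loop evaluation", {
  set.seed(21)
  n <- 8; k <- 2
  As <- list(randSymNonneg(n, 31), randSymNonneg(n, 32))
  Bs <- list(randPSD(n, 33), randPSD(n, 34))
  Hv <- list(randFactor(n, k, 35), randFactor(n, k, 36))
  qs <- lapply(Hv, columnScaling)
  Hstar <- randFactor(n, k, 37)
  alphas <- c(0.3, 0.7)
  got <- mhsnmfObjective(Hv, Hstar, qs, alphas, As, Bs,
                         gamma = 0.4, beta = 0.2, r = 2)
  want <- oracleObjective(Hv, Hstar, qs, alphas, As, Bs, 0.4, 0.2, 2)
  expect_equal(got, want, tolerance = 1e-10)
  ## exact-factorization single view with gamma = beta = 0 -> objective 0
  H0 <- randFactor(n, k, 38)
  expect_equal(mhsnmfObjective(list(H0), H0, list(columnScaling(H0)), 1,
                               list(tcrossprod(H0)), NULL, 0, 0), 0)
  ## coupling term vanishes when H* = H^v Q^v and beta = 0
  HQ <- sweep(H0, 2, columnScaling(H0), "*")
  base <- mhsnmfObjective(list(H0), HQ, list(columnScaling(H0)), 1,
                          list(As[[1]]), NULL, gamma = 5, beta = 0)
  noCoupling <- mhsnmfObjective(list(H0), HQ, list(columnScaling(H0)), 1,
                                list(As[[1]]), NULL, gamma = 0, beta = 0)
  expect_equal(base, noCoupling)
})

test_that("per-view update reduces to SNMF when gamma = 0 and holds fixed points", {
  set.seed(50)
  n <- 8; k <- 2
  A <- randSymNonneg(n, 51)
  H <- randFactor(n, k, 52)
  expect_identical(
    mhsnmf:::.updateViewFactor(H, A, NULL, NULL, 0),
    H * (0.5 + 2 * (A %*% H) / (2 * (H %*% (2 * crossprod(H))) + 1e-10)))
  ## fixed point: A = H H', H* = H, Q = I
  Hf <- randFactor(n, k, 53)
  Af <- tcrossprod(Hf)
  up <- mhsnmf:::.updateViewFactor(Hf, Af, Hf, rep(1, k), gamma = 0.7)
  expect_equal(up, Hf, tolerance = 1e-8)
})

test_that("one per-view update step matches the scalar-loop oracle", {
  for (s in 1:6) {
    set.seed(600 + s)
    n <- 8; k <- 2
    A <- randSymNonneg(n, 600 + s)
    H <- randFactor(n, k, 700 + s)
    Hstar <- randFactor(n, k, 800 + s)
    q <- columnScaling(H)
    got <- mhsnmf:::.updateViewFactor(H, A, Hstar, q, gamma = 0.3)
    want <- oracleViewUpdate(H, A, Hstar, q, gamma = 0.3)
    expect_lt(max(abs(got - want)), 1e-12)
    expect_true(all(got >= 0))
  }
})

test_that("consensus update matches the scalar-loop oracle and stays nonnegative", {
  for (s in 1:6) {
    set.seed(900 + s)
    n <- 8; k <- 2
    Hv <- list(randFactor(n, k, 900 + s), randFactor(n, k, 910 + s))
    qs <- lapply(Hv, columnScaling)
    Hstar <- randFactor(n, k, 920 + s)
    B <- matrix(rnorm(n * n), n, n); B <- (B + t(B)) / 2  # indefinite
    got <- mhsnmf:::.updateConsensus(Hstar, Hv, qs, gamma = 0.5,
                                     beta = 0.2, Bcomb = B)
    want <- oracleConsensusUpdate(Hstar, Hv, qs, 0.5, 0.2, B)
    expect_lt(max(abs(got - want)), 1e-12)
    expect_true(min(got) >= 0)
  }
  ## beta = 0, single view at the coupling optimum -> unchanged
  H <- randFactor(8, 2, 930)
  q <- columnScaling(H)
  HQ <- sweep(H, 2, q, "*")
  up <- mhsnmf:::.updateConsensus(HQ, list(H), list(q), gamma = 1,
                                  beta = 0, Bcomb = NULL)
  expect_equal(up, HQ, tolerance = 1e-8)
  ## diagonal nonnegative B with gamma = 0: entries nonincreasing
  Hstar <- randFactor(8, 2, 931)
  Bd <- diag(runif(8, 0.5, 2))
  up2 <- mhsnmf:::.updateConsensus(Hstar, list(H), list(q), gamma = 0,
                                   beta = 1, Bcomb = Bd)
  expect_true(all(up2 <= Hstar + 1e-15))
})

test_that("closed-form view weights minimize the smoothed objective", {
  H <- randFactor(10, 3, 60)
  ## equal traces -> equal weights
  B <- randPSD(10, 61)
  expect_equal(mhsnmf:::.updateViewWeights(list(B, B), H, r = 2),
               c(0.5, 0.5))
  ## r -> infinity limit: uniform weights
  B2 <- randPSD(10, 62)
  a <- mhsnmf:::.updateViewWeights(list(B, B2), H, r = 1e6)
  expect_equal(a, c(0.5, 0.5), tolerance = 1e-4)
  ## traces (1, 4), r = 2 -> (0.8, 0.2), the grid-search minimizer
  tv <- c(1, 4)
  aClosed <- (1 / tv)^(1 / (2 - 1)) / sum((1 / tv)^(1 / (2 - 1)))
  expect_equal(aClosed, c(0.8, 0.2))
  grid <- seq(0, 1, by = 1e-4)
  f <- grid^2 * tv[1] + (1 - grid)^2 * tv[2]
  expect_equal(grid[which.min(f)], 0.8, tolerance = 1e-4)
  ## zero-trace views take all the weight
  expect_warning(
    az <- mhsnmf:::.updateViewWeights(list(matrix(0, 10, 10), B2), H, 2),
    "zero")
  expect_equal(az, c(1, 0))
})

test_that("single view with gamma = beta = 0 reproduces the SNMF trajectory", {
  A <- adjacency(buildSimilarityGraph(
    makeMultiviewBlobs(nSamples = 40, seed = 5)$views[[1]],
    knn = 6, scaleIndex = 4))
  ref <- snmf(A, 3, maxIter = 50, tol = 0)
  fit <- mhsnmfCore(list(A), NULL, k = 3, gamma = 0, beta = 0,
                    maxIter = 50, tol = 0)
  expect_lt(max(abs(viewFactors(fit)[[1]] - ref$H)), 1e-10)
  expect_equal(objectiveTrace(fit), ref$objective, tolerance = 1e-12)
})

test_that("two identical views stay symmetric through the fit", {
  fx <- solverFixture(n = 60, seed = 8)
  g <- fx$graphs[[1]]
  b <- fx$hessians[[1]]
  ## H* is updated between the two views inside each sweep, so exact
  ## symmetry of the factors only holds at convergence: run tight
  fit <- mhsnmfCore(list(a = g, b = g), list(b, b), k = 3, gamma = 0.05,
                    beta = 0.01, maxIter = 3000, tol = 1e-13)
  expect_equal(unname(viewWeights(fit)), c(0.5, 0.5), tolerance = 1e-10)
  expect_lt(max(abs(viewFactors(fit)$a - viewFactors(fit)$b)), 1e-8)
})

test_that("view order permutes the weights but not the consensus partition", {
  fx <- solverFixture(n = 60, seed = 13)
  fit12 <- mhsnmfCore(fx$graphs, fx$hessians, k = 3, gamma = 0.05,
                      beta = 0.01, maxIter = 500, tol = 1e-10)
  fit21 <- mhsnmfCore(rev(fx$graphs), rev(fx$hessians), k = 3,
                      gamma = 0.05, beta = 0.01, maxIter = 500,
                      tol = 1e-10)
  expect_equal(unname(viewWeights(fit12)),
               unname(rev(viewWeights(fit21))), tolerance = 1e-4)
  ## consensus invariant up to the column permutation induced by the
  ## changed alignment reference
  l1 <- clusterLabels(fit12)
  l2 <- clusterLabels(fit21)
  expect_equal(clusteringAccuracy(l1, l2), 1)
  perm <- sapply(1:3, function(c) unique(l2[l1 == c]))
  expect_lt(max(abs(consensus(fit12) - consensus(fit21)[, perm])), 1e-6)
})

test_that("weights stay on the simplex and factors nonnegative across sweeps", {
  fx <- solverFixture(n = 60, seed = 17, noiseSd = 1)
  fit <- mhsnmfCore(fx$graphs, fx$hessians, k = 3, gamma = 0.1,
                    beta = 0.05, maxIter = 40, tol = 0)
  expect_true(all(viewWeights(fit) >= 0))
  expect_lt(abs(sum(viewWeights(fit)) - 1), 1e-10)
  expect_true(all(consensus(fit) >= 0))
  for (H in viewFactors(fit)) expect_true(all(H >= 0))
  ## simplex constraint holds after every weight update on random states
  for (s in 1:5) {
    a <- mhsnmf:::.updateViewWeights(
      list(randPSD(8, s), randPSD(8, 50 + s), randPSD(8, 90 + s)),
      randFactor(8, 2, s), r = 2)
    expect_true(all(a >= 0))
    expect_lt(abs(sum(a) - 1), 1e-10)
  }
})

test_that("the full pipeline recovers planted multi-view clusters", {
  sim <- makeMultiviewBlobs(nSamples = 90, nClusters = 3, seed = 23)
  fit <- mhsnmf(sim$views, k = 3, knnHessian = 15)
  lab <- clusterLabels(fit)
  expect_gte(clusteringAccuracy(lab, sim$labels), 0.95)
})
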