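test_that("local neighbourhoods are centered nearest neighbours", {
  set.seed(10)
  X <- rbind(matrix(runif(2 * 10, 0, 5), 2, 10), 0)
  for (i in c(1, 4, 10)) {
    nb <- mhsnmf:::.localNeighborhood(X, i, 5)
    ## exhaustive distance sort oracle
    d <- apply(X, 2, function(v) sqrt(sum((v - X[, i])^2)))
    d[i] <- Inf
    expect_identical(nb$neighbors, order(d)[1:5])
    expect_equal(nb$V, t(X[, nb$neighbors] - X[, i]), ignore_attr = TRUE)
  }
  ## nearest neighbour at v_i + e1 appears as the row e1
  Y <- cbind(c(0, 0), c(1, 0), c(5, 5), c(9, 0), c(0, 7))
  nb <- mhsnmf:::.localNeighborhood(Y, 1, 2)
  expect_equal(nb$V[1, ], c(1, 0))
  ## all neighbours identical to the center -> zero matrix
  Z <- matrix(1, 3, 5); Z[, 5] <- 2
  nbz <- mhsnmf:::.localNeighborhood(Z, 1, 3)
  expect_equal(nbz$V, matrix(0, 3, 3), ignore_attr = TRUE)
})

test_that("tangent coordinates are orthonormal and span the local plane", {
  set.seed(20)
  basis <- qr.Q(qr(matrix(rnorm(10), 5, 2)))
  V <- matrix(rnorm(16), 8, 2) %*% t(basis)   # rank-2 in 5-D
  U <- mhsnmf:::.tangentCoordinates(V, 2)
  expect_equal(crossprod(U), diag(2), tolerance = 1e-8)
  ## principal angles between span(U' V) plane and true plane
  P <- V %*% basis                            # tangent plane coordinates
  ## compare column spans of V-projections: U must reproduce V exactly
  expect_lt(max(abs(V - U %*% crossprod(U, V))), 1e-8)
  ## Gram-matrix oracle: eigenvectors of V V' span the same subspace
  G <- V %*% t(V)
  Ug <- eigen(G, symmetric = TRUE)$vectors[, 1:2]
  M <- crossprod(U, Ug)
  expect_equal(crossprod(M), diag(2), tolerance = 1e-8)
  ## rank-deficient neighbourhood warns and zero-pads
  V1 <- cbind(rnorm(6)) %*% rbind(rnorm(3))   # rank 1
  expect_warning(U1 <- mhsnmf:::.tangentCoordinates(V1, 2), "rank")
  expect_equal(U1[, 2], rep(0, 6))
})

test_that("local Hessian estimator annihilates constant and linear parts", {
  set.seed(30)
  U <- qr.Q(qr(matrix(rnorm(14), 7, 2)))
  Bl <- mhsnmf:::.localHessian(U)
  expect_equal(dim(Bl), c(3L, 7L))
  expect_lt(max(abs(Bl %*% rep(1, 7))), 1e-10)
  expect_lt(max(abs(Bl %*% U)), 1e-10)
  ## QR projector oracle: crossprod(Bl) equals the projector onto the
  ## quadratic span orthogonal to [1 | U], independent of Gram-Schmidt
  quad <- cbind(U[, 1]^2, U[, 1] * U[, 2], U[, 2]^2)
  M <- cbind(1, U, quad)
  Pfull <- qr.Q(qr(M))[, 1:6] %*% t(qr.Q(qr(M))[, 1:6])
  lin <- cbind(1, U)
  Plin <- qr.Q(qr(lin))[, 1:3] %*% t(qr.Q(qr(lin))[, 1:3])
  expect_lt(max(abs(crossprod(Bl) - (Pfull - Plin))), 1e-8)
})

test_that("Hessian energy is symmetric PSD and annihilates affine functions", {
  pm <- makePlanarManifold(120, ambientDim = 6, seed = 4)
  he <- hessianEnergy(pm$X, knnH = 12, d = 2)
  B <- energyMatrix(he)
  expect_lt(max(abs(B - t(B))), 1e-8)
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))
  F <- cbind(1, pm$coords)
  expect_lt(norm(B %*% F, "F") / norm(B, "F"), 1e-6)
  ## a quadratic function has strictly positive energy
  f <- pm$coords[, 1]^2
  expect_gt(drop(t(f) %*% B %*% f), 0)
  ## PSD on random (non-manifold) fixtures too
  for (s in 1:5) {
    set.seed(100 + s)
    X <- matrix(runif(5 * 40), 5, 40)
    Br <- energyMatrix(hessianEnergy(X, knnH = 10, d = 2))
    evr <- eigen(Br, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(evr), -1e-8 * max(evr))
  }
})

test_that("Hessian accumulation matches an index-level brute-force oracle", {
  pm <- makePlanarManifold(40, ambientDim = 5, seed = 9)
  X <- pm$X
  n <- ncol(X)
  knnH <- 8; d <- 2
  ## oracle: independent local pipeline (distance sort, Gram-matrix
  ## eigenvectors, QR projector) scattered entry by entry per Eq-style
  ## double loop over local indices
  Bo <- matrix(0, n, n)
  for (l in 1:n) {
    dist <- apply(X, 2, function(v) sqrt(sum((v - X[, l])^2)))
    dist[l] <- Inf
    nb <- order(dist)[1:knnH]
    V <- t(X[, nb] - X[, l])
    U <- eigen(V %*% t(V), symmetric = TRUE)$vectors[, 1:d]
    quad <- cbind(U[, 1]^2, U[, 1] * U[, 2], U[, 2]^2)
    Qf <- qr.Q(qr(cbind(1, U, quad)))
    Pfull <- Qf %*% t(Qf)
    Ql <- qr.Q(qr(cbind(1, U)))
    Plin <- Ql %*% t(Ql)
    Gl <- Pfull - Plin        # = t(B^l) %*% B^l
    for (a in 1:knnH) for (b in 1:knnH)
      Bo[nb[a], nb[b]] <- Bo[nb[a], nb[b]] + Gl[a, b]
  }
  B <- energyMatrix(hessianEnergy(X, knnH = knnH, d = d))
  expect_lt(max(abs(B - Bo)), 1e-10)
})

test_that("Hessian null space is preserved under global rescaling", {
  pm <- makePlanarManifold(80, ambientDim = 6, seed = 12)
  he1 <- hessianEnergy(pm$X, knnH = 10, d = 2)
  he2 <- hessianEnergy(3 * pm$X, knnH = 10, d = 2)
  F <- cbind(1, pm$coords)
  expect_lt(norm(energyMatrix(he2) %*% F, "F") /
              norm(energyMatrix(he2), "F"), 1e-6)
  ## neighbour structure unchanged: support patterns agree
  expect_identical(abs(energyMatrix(he1)) > 1e-12,
                   abs(energyMatrix(he2)) > 1e-12)
})

test_that("bottom eigenvectors on a swiss roll are affine in the intrinsic coordinates", {
  sr <- swissRoll(400, seed = 3)
  B <- energyMatrix(hessianEnergy(sr$X, knnH = 12, d = 2))
  ev <- eigen(B, symmetric = TRUE)
  n <- ncol(sr$X)
  bottom <- ev$vectors[, n - (0:2)]
  ## each intrinsic coordinate is reproduced by the bottom eigenspace
  ## (multiple correlation), i.e. the bottom eigenvectors are affine in
  ## (t, y)
  for (j in 1:2) {
    fit <- stats::lm(sr$coords[, j] ~ bottom)
    expect_gt(sqrt(summary(fit)$r.squared), 0.95)
  }
  ## the constant function is in the bottom eigenspace too
  ones <- rep(1, n) / sqrt(n)
  proj <- bottom %*% crossprod(bottom, ones)
  expect_gt(sqrt(sum(proj^2)), 0.95)
})

test_that("hessianEnergy validates its parameters", {
  X <- matrix(runif(4 * 20), 4, 20)
  expect_error(hessianEnergy(X, knnH = 4, d = 2), "d\\*\\(d\\+3\\)/2")
  expect_error(hessianEnergy(X, knnH = 20, d = 2), "n_samples")
})
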