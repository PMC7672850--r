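# Independent brute-force oracles used to freeze expected values.
# Each oracle implements the defining formula literally (scalar loops,
# explicit enumerations) and never calls the code path it checks.

EPS <- 1e-10  # denominator guard, mirrors the package constant

# Gaussian kernel with local scaling, literal double loop
oracleGaussianW <- function(X, scaleIndex) {
  n <- ncol(X)
  d <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) d[i, j] <- sqrt(sum((X[, i] - X[, j])^2))
  sigma <- numeric(n)
  for (i in 1:n) sigma[i] <- sort(d[i, -i])[scaleIndex]
  W <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    if (i != j) W[i, j] <- exp(-d[i, j]^2 / (sigma[i] * sigma[j]))
  W
}

oracleCosineW <- function(X) {
  n <- ncol(X)
  W <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    if (i != j)
      W[i, j] <- sum(X[, i] * X[, j]) /
        (sqrt(sum(X[, i]^2)) * sqrt(sum(X[, j]^2)))
  W
}

# explicit neighbour-list enumeration for the kNN union rule
oracleKnnKeep <- function(W, knn) {
  n <- nrow(W)
  N <- vector("list", n)
  for (i in 1:n) {
    w <- W[, i]
    w[i] <- -Inf
    N[[i]] <- order(-w, seq_len(n))[seq_len(knn)]
  }
  keep <- matrix(FALSE, n, n)
  for (i in 1:n) for (j in 1:n)
    if (i != j && (i %in% N[[j]] || j %in% N[[i]])) keep[i, j] <- TRUE
  keep
}

# scalar triple-loop version of the per-view multiplicative update
# (1/2-damped KKT ratio, mirroring the implemented rule)
oracleViewUpdate <- function(H, A, Hstar, q, gamma) {
  n <- nrow(H); k <- ncol(H)
  out <- matrix(0, n, k)
  for (i in 1:n) for (c in 1:k) {
    ah <- 0
    for (j in 1:n) ah <- ah + A[i, j] * H[j, c]
    hhh <- 0
    for (a in 1:k) for (j in 1:n)
      hhh <- hhh + H[i, a] * H[j, a] * H[j, c]
    num <- 2 * ah
    den <- 2 * hhh
    if (gamma > 0) {
      num <- num + gamma * Hstar[i, c] * q[c]
      den <- den + gamma * H[i, c] * q[c]^2
    }
    out[i, c] <- H[i, c] * (0.5 + num / (2 * den + EPS))
  }
  out
}

# scalar loop version of the consensus update with the B = B+ - B- split
oracleConsensusUpdate <- function(Hstar, Hviews, qs, gamma, beta, B) {
  n <- nrow(Hstar); k <- ncol(Hstar); nv <- length(Hviews)
  Bp <- matrix(0, n, n); Bn <- matrix(0, n, n)
  if (!is.null(B)) {
    for (i in 1:n) for (j in 1:n) {
      Bp[i, j] <- (abs(B[i, j]) + B[i, j]) / 2
      Bn[i, j] <- (abs(B[i, j]) - B[i, j]) / 2
    }
  }
  out <- matrix(0, n, k)
  for (i in 1:n) for (c in 1:k) {
    num <- 0; den <- gamma * nv * Hstar[i, c]
    for (v in 1:nv) num <- num + gamma * Hviews[[v]][i, c] * qs[[v]][c]
    if (beta > 0 && !is.null(B)) {
      for (j in 1:n) {
        num <- num + beta * Bn[i, j] * Hstar[j, c]
        den <- den + beta * Bp[i, j] * Hstar[j, c]
      }
    }
    out[i, c] <- Hstar[i, c] * num / (den + EPS)
  }
  out
}

# term-by-term loop evaluation of the full objective
oracleObjective <- function(Hviews, Hstar, qs, alphas, As, Bs, gamma,
                            beta, r) {
  obj <- 0
  for (v in seq_along(Hviews)) {
    H <- Hviews[[v]]; A <- As[[v]]
    n <- nrow(H); k <- ncol(H)
    for (i in 1:n) for (j in 1:n) {
      hh <- 0
      for (c in 1:k) hh <- hh + H[i, c] * H[j, c]
      obj <- obj + (A[i, j] - hh)^2
    }
    if (gamma > 0) {
      for (i in 1:n) for (c in 1:k)
        obj <- obj + gamma * (H[i, c] * qs[[v]][c] - Hstar[i, c])^2
    }
  }
  if (beta > 0 && !is.null(Bs)) {
    for (v in seq_along(Bs)) {
      B <- Bs[[v]]
      n <- nrow(Hstar); k <- ncol(Hstar)
      tv <- 0
      for (c in 1:k) for (i in 1:n) for (j in 1:n)
        tv <- tv + Hstar[i, c] * B[i, j] * Hstar[j, c]
      obj <- obj + beta * alphas[v]^r * tv
    }
  }
  obj
}

# projected gradient solver for min_{h>=0} ||y - C h||^2 (+ reg ||h||^2
# folded into C, y by the caller); independent of the active-set path
oraclePGNNLS <- function(C, y, tol = 1e-10, maxIter = 200000L) {
  k <- ncol(C)
  G <- crossprod(C)
  b <- crossprod(C, y)
  L <- 2 * max(abs(eigen(G, symmetric = TRUE, only.values = TRUE)$values))
  h <- numeric(k)
  for (it in seq_len(maxIter)) {
    g <- 2 * (G %*% h - b)
    hNew <- pmax(0, h - drop(g) / L)
    if (max(abs(hNew - h)) < tol) return(hNew)
    h <- hNew
  }
  h
}

nnlsObjective <- function(C, y, h) sum((y - C %*% h)^2)

# all permutations of 1..n (n <= 6)
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1L)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub)))
    out <- rbind(out, block)
  }
  out
}

# accuracy by exhaustive enumeration of cluster-to-class matchings
oraclePermAccuracy <- function(pred, truth) {
  pf <- as.integer(factor(pred)); tf <- as.integer(factor(truth))
  k <- max(max(pf), max(tf))
  best <- 0
  P <- allPerms(k)
  for (p in seq_len(nrow(P))) {
    acc <- mean(P[p, ][pf] == tf)
    best <- max(best, acc)
  }
  best
}

# NMI from hand-rolled entropy computation on the joint counts
oracleNMI <- function(pred, truth) {
  n <- length(pred)
  ps <- unique(pred); ts <- unique(truth)
  I <- 0
  for (a in ps) for (b in ts) {
    pab <- sum(pred == a & truth == b) / n
    pa <- sum(pred == a) / n
    pb <- sum(truth == b) / n
    if (pab > 0) I <- I + pab * log(pab / (pa * pb))
  }
  Hp <- 0
  for (a in ps) {
    pa <- sum(pred == a) / n
    if (pa > 0) Hp <- Hp - pa * log(pa)
  }
  Ht <- 0
  for (b in ts) {
    pb <- sum(truth == b) / n
    if (pb > 0) Ht <- Ht - pb * log(pb)
  }
  if (Hp == 0 || Ht == 0) return(0)
  I / sqrt(Hp * Ht)
}

# random symmetric nonnegative matrix with zero diagonal
randSymNonneg <- function(n, seed) {
  set.seed(seed)
  M <- matrix(runif(n * n), n, n)
  W <- (M + t(M)) / 2
  diag(W) <- 0
  W
}

# random nonnegative factor
randFactor <- function(n, k, seed) {
  set.seed(seed)
  matrix(runif(n * k, 0.05, 1), n, k)
}

# random PSD matrix
randPSD <- function(n, seed) {
  set.seed(seed)
  M <- matrix(rnorm(n * n), n, n)
  crossprod(M) / n
}

# swiss-roll-like 3-D manifold; intrinsic (isometric) coordinates are the
# arc length s(t) along the spiral and the height y; shifted nonnegative
swissRoll <- function(n, seed) {
  set.seed(seed)
  t <- runif(n, 1.5 * pi, 3 * pi)
  y <- runif(n, 0, 25)  # height comparable to the unrolled arc length
  P <- cbind(t * cos(t), y, t * sin(t))
  s <- (t * sqrt(1 + t^2) + asinh(t)) / 2
  X <- t(P) + max(abs(P)) + 1
  list(X = X, coords = cbind(s, y))
}

# two-view graph/hessian fixture over blob data, for solver tests
solverFixture <- function(n = 120, k = 3, seed = 1, noiseSd = 0.5) {
  sim <- makeMultiviewBlobs(nSamples = n, nClusters = k, nViews = 2,
                            noiseSd = noiseSd, seed = seed)
  graphs <- lapply(sim$views, buildSimilarityGraph)
  hessians <- lapply(sim$views, hessianEnergy, knnH = 15, d = 2)
  list(sim = sim, graphs = graphs, hessians = hessians)
}
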