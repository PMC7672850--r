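## Single-view symmetric NMF: A ~ H t(H), H >= 0, via the multiplicative
## update H <- H * (AH) / (H t(H) H). Used as a building block of the
## multi-view solver and as a baseline on its own.

#' NNDSVD initialization for symmetric NMF
#'
#' Deterministic nonnegative initialization from the leading `k` singular
#' pairs of `A`: for each pair the dominant sign block (positive or
#' negative parts of the singular vectors) is selected and rescaled by the
#' singular value; exact zeros are floored at `eps` so multiplicative
#' updates can escape them.
#'
#' @param A symmetric nonnegative matrix (or [SimilarityGraph-class]).
#' @param k factorization rank (number of clusters), `1 <= k <= n`.
#' @param eps floor replacing zeros (default `1e-6`).
#' @return nonnegative `n x k` matrix.
#' @export
nndsvdInit <- function(A, k, eps = 1e-6) {
  A <- .asMatrixLike(A)
  n <- nrow(A)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("k must satisfy 1 <= k <= n_samples")
  sv <- svd(A, nu = k, nv = k)
  smax <- max(sv$d)
  r <- if (smax > 0) sum(sv$d > smax * 1e-12) else 0L
  if (k > r)
    warning("k = ", k, " exceeds numerical rank ", r,
            " of A; padding extra columns with eps")
  H <- matrix(eps, n, k)
  kk <- min(k, r)
  if (kk >= 1L) {
    ## leading pair: Perron vector of the nonnegative A, take |u|
    H[, 1L] <- sqrt(sv$d[1L]) * abs(sv$u[, 1L])
  }
  if (kk >= 2L) {
    for (j in 2:kk) {
      x <- sv$u[, j]; y <- sv$v[, j]
      xp <- pmax(x, 0); xn <- pmax(-x, 0)
      yp <- pmax(y, 0); yn <- pmax(-y, 0)
      nxp <- sqrt(sum(xp^2)); nxn <- sqrt(sum(xn^2))
      nyp <- sqrt(sum(yp^2)); nyn <- sqrt(sum(yn^2))
      mp <- nxp * nyp; mn <- nxn * nyn
      if (mp >= mn && mp > 0) {
        H[, j] <- sqrt(sv$d[j] * mp) * xp / nxp
      } else if (mn > 0) {
        H[, j] <- sqrt(sv$d[j] * mn) * xn / nxn
      }
    }
  }
  H[H < .Machine$double.eps] <- eps
  rownames(H) <- rownames(A)
  H
}

#' Symmetric nonnegative matrix factorization
#'
#' Minimizes `||A - H t(H)||_F^2` over `H >= 0` by multiplicative updates
#' from an NNDSVD (or user-supplied) initialization, recording the
#' objective each iteration and stopping when its relative change drops
#' below `tol`.
#'
#' @param A symmetric nonnegative matrix (or [SimilarityGraph-class]).
#' @param k factorization rank.
#' @param init optional nonnegative `n x k` starting factor; default
#'   [nndsvdInit()].
#' @param maxIter maximum iterations (default 500).
#' @param tol relative objective-change stopping tolerance (default 1e-6).
#' @return list with components `H` (the factor), `objective` (trace,
#'   element 1 = value at init) and `nIter`.
#' @export
snmf <- function(A, k, init = NULL, maxIter = 500L, tol = 1e-6) {
  A <- .asMatrixLike(A)
  if (max(abs(A - t(A))) >= 1e-10) stop("A must be symmetric")
  if (any(A < 0)) stop("A must be nonnegative")
  H <- if (is.null(init)) nndsvdInit(A, k) else init
  if (any(H < 0)) stop("init must be nonnegative")
  if (!all(dim(H) == c(nrow(A), k))) stop("init must be n x k")
  obj <- .snmfObjective(A, H)
  trace <- numeric(maxIter + 1L)
  trace[1L] <- obj
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    H <- .updateViewFactor(H, A, Hstar = NULL, q = NULL, gamma = 0)
    if (any(!is.finite(H)))
      stop("non-finite factor entries at iteration ", it)
    newObj <- .snmfObjective(A, H)
    trace[it + 1L] <- newObj
    if (abs(obj - newObj) < tol * max(obj, .EPS)) {
      obj <- newObj
      break
    }
    obj <- newObj
  }
  list(H = H, objective = trace[seq_len(it + 1L)], nIter = it)
}

.snmfObjective <- function(A, H) {
  R <- A - tcrossprod(H)
  sum(R * R)
}

#' Column scaling factor
#'
#' Diagonal of the auxiliary matrix `Q = Diag(1/colSums(H))` that rescales
#' a factor so its columns sum to one, making clustering solutions from
#' different views comparable before consensus coupling.
#'
#' @param H nonnegative factor matrix.
#' @return numeric vector `q` of length `ncol(H)`; `sweep(H, 2, q, "*")`
#'   has unit column sums. A zero column sum (dead cluster) yields a 0
#'   entry with a warning.
#' @export
columnScaling <- function(H) {
  s <- colSums(H)
  q <- ifelse(s > 0, 1 / s, 0)
  if (any(s <= 0))
    warning("dead cluster: zero column sum in column(s) ",
            paste(which(s <= 0), collapse = ", "))
  q
}
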