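## Hessian energy estimation.
##
## For each sample, a local tangent frame is fit by SVD of the centered
## neighbourhood; a quadratic basis built on the tangent coordinates is
## orthonormalized against the constant and linear parts; the extracted
## quadratic block is the local Hessian estimator. Summing the local Gram
## matrices over all centers gives the global symmetric PSD operator B whose
## quadratic form t(f) B f measures the total curviness of f along the
## manifold. Its null space contains functions that are affine in the
## tangent coordinates.

# rows of the returned matrix are v_j - v_i for the knnH nearest neighbours
# of sample i (Euclidean, ties by ascending index); the center is excluded.
.localNeighborhood <- function(X, i, knnH) {
  n <- ncol(X)
  if (knnH >= n)
    stop("knnH must be < n_samples (got ", knnH, " for n = ", n, ")")
  d2 <- colSums((X - X[, i])^2)
  d2[i] <- Inf
  nb <- order(d2, seq_len(n))[seq_len(knnH)]
  list(neighbors = nb, V = t(X[, nb, drop = FALSE] - X[, i]))
}

# first d left singular vectors of the centered neighbourhood; if the local
# rank is below d, warn and zero-pad the missing directions.
.tangentCoordinates <- function(V, d) {
  if (d > min(dim(V)))
    stop("tangent dimension d = ", d, " exceeds min(dim(neighbourhood)) = ",
         min(dim(V)))
  sv <- svd(V, nu = min(dim(V)), nv = 0)
  smax <- if (length(sv$d)) max(sv$d) else 0
  r <- if (smax > 0) sum(sv$d > smax * 1e-12) else 0L
  if (r >= d) return(sv$u[, seq_len(d), drop = FALSE])
  warning("local neighbourhood has rank ", r, " < d = ", d,
          "; padding missing tangent directions with zeros")
  cbind(sv$u[, seq_len(r), drop = FALSE],
        matrix(0, nrow(V), d - r))
}

# modified Gram-Schmidt with one re-orthogonalization pass; columns whose
# residual norm falls below tol are zeroed (dropped) with a warning.
.gramSchmidt <- function(M, tol = 1e-10) {
  Q <- M
  dropped <- integer(0)
  for (j in seq_len(ncol(M))) {
    v <- Q[, j]
    for (pass in 1:2) {
      for (i in seq_len(j - 1L)) {
        qi <- Q[, i]
        v <- v - drop(crossprod(qi, v)) * qi
      }
    }
    nv <- sqrt(sum(v^2))
    if (nv < tol) {
      dropped <- c(dropped, j)
      Q[, j] <- 0
    } else {
      Q[, j] <- v / nv
    }
  }
  if (length(dropped))
    warning("degenerate quadratic basis: dropped column(s) ",
            paste(dropped, collapse = ", "), " during Gram-Schmidt")
  Q
}

# local Hessian estimator: design matrix [1 | U | squares & cross products in
# lexicographic pair order], orthonormalized; the transposed last d(d+1)/2
# columns extract the quadratic components orthogonal to constant + linear.
.localHessian <- function(U) {
  knnH <- nrow(U)
  d <- ncol(U)
  quad <- matrix(0, knnH, d * (d + 1L) / 2L)
  col <- 0L
  for (a in seq_len(d)) {
    for (b in a:d) {
      col <- col + 1L
      quad[, col] <- U[, a] * U[, b]
    }
  }
  M <- cbind(rep(1, knnH), U, quad)
  Mhat <- .gramSchmidt(M)
  nq <- ncol(quad)
  t(Mhat[, (ncol(M) - nq + 1L):ncol(M), drop = FALSE])
}

#' Total Hessian energy operator of one view
#'
#' Estimates the symmetric positive semidefinite matrix `B` whose quadratic
#' form `t(f) %*% B %*% f` approximates the integrated squared second
#' derivative of a function `f` sampled at the view's samples. For every
#' sample: find its `knnH` nearest neighbours, center them on the sample,
#' take the first `d` left singular vectors as tangent coordinates, build
#' the quadratic design matrix, orthonormalize it by Gram-Schmidt, extract
#' the quadratic block as the local estimator, and accumulate its Gram
#' matrix into the global `B` at the neighbours' indices.
#'
#' @param X numeric matrix, features x samples.
#' @param knnH neighbourhood size (default 30). Must satisfy
#'   `knnH >= d*(d+3)/2 + 1` so the local design matrix is solvable, and
#'   `knnH < n_samples`.
#' @param d tangent-space dimension (default 2, the smallest nontrivial
#'   manifold dimension).
#' @return a [HessianEnergy-class].
#' @export
hessianEnergy <- function(X, knnH = 30L, d = 2L) {
  .checkFeatureMatrix(X)
  knnH <- as.integer(knnH)
  d <- as.integer(d)
  if (d < 1L) stop("d must be >= 1")
  minK <- d * (d + 3L) / 2L + 1L
  if (knnH < minK)
    stop("knnH = ", knnH, " too small for d = ", d,
         "; need knnH >= d*(d+3)/2 + 1 = ", minK)
  n <- ncol(X)
  if (knnH >= n)
    stop("knnH must be < n_samples (got ", knnH, " for n = ", n, ")")
  B <- matrix(0, n, n)
  for (l in seq_len(n)) {
    res <- tryCatch({
      nb <- .localNeighborhood(X, l, knnH)
      U <- .tangentCoordinates(nb$V, d)
      Bl <- .localHessian(U)
      list(idx = nb$neighbors, G = crossprod(Bl))
    }, error = function(e) {
      stop("Hessian estimation failed at center ", l, ": ",
           conditionMessage(e), call. = FALSE)
    })
    B[res$idx, res$idx] <- B[res$idx, res$idx] + res$G
  }
  B <- (B + t(B)) / 2
  dimnames(B) <- list(colnames(X), colnames(X))
  new("HessianEnergy", energy = B, knnH = knnH, tangentDim = d)
}
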