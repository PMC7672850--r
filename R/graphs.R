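## Per-view sample-sample similarity graphs.
##
## The pipeline for one view is: kernel (Gaussian with local scaling, or
## cosine for text-like views) -> kNN sparsification with the union rule ->
## symmetric normalization A = D^{-1/2} W D^{-1/2}.

#' Gaussian similarity with local scaling
#'
#' Computes the locally scaled Gaussian affinity between all pairs of
#' samples (columns) of a feature matrix:
#' `W_ij = exp(-||V_i - V_j||^2 / (sigma_i * sigma_j))` for `i != j`, where
#' `sigma_i` is the Euclidean distance from sample `i` to its
#' `scaleIndex`-th nearest neighbour. Self-similarities are removed
#' (`W_ii = 0`).
#'
#' @param X numeric matrix, features x samples (nonnegative, finite).
#' @param scaleIndex positive integer: the neighbour rank used for the local
#'   bandwidth `sigma_i`. Default 7.
#' @return a [SimilarityGraph-class] (dense, unsparsified, unnormalized).
#' @seealso [sparsifyKnn()], [normalizeSymmetric()], [cosineSimilarity()]
#' @export
gaussianSimilarity <- function(X, scaleIndex = 7L) {
  .checkFeatureMatrix(X)
  n <- ncol(X)
  scaleIndex <- as.integer(scaleIndex)
  if (scaleIndex < 1L || scaleIndex >= n)
    stop("scaleIndex must satisfy 1 <= scaleIndex < n_samples (got ",
         scaleIndex, " for n = ", n, ")")
  D <- as.matrix(stats::dist(t(X)))
  ## sigma_i = distance to the scaleIndex-th neighbour (self excluded)
  sigma <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    sort(d, partial = scaleIndex)[scaleIndex]
  }, numeric(1))
  if (any(sigma == 0)) {
    bad <- which(sigma == 0)
    ids <- colnames(X)
    lab <- if (is.null(ids)) bad else ids[bad]
    stop("zero local scale sigma_i for sample(s) ",
         paste(lab, collapse = ", "),
         ": at least ", scaleIndex, " duplicates present")
  }
  W <- exp(-D^2 / outer(sigma, sigma))
  diag(W) <- 0
  W <- (W + t(W)) / 2  # remove float asymmetry from outer()
  dimnames(W) <- list(colnames(X), colnames(X))
  new("SimilarityGraph", adjacency = W, kind = "gaussian",
      knn = 0L, normalized = FALSE)
}

#' Cosine similarity graph
#'
#' `W_ij = <V_i, V_j> / (||V_i|| ||V_j||)` for `i != j`; the diagonal is
#' zeroed. Intended for text-like sparse nonnegative views.
#'
#' @inheritParams gaussianSimilarity
#' @return a [SimilarityGraph-class].
#' @export
cosineSimilarity <- function(X) {
  .checkFeatureMatrix(X)
  nrm <- sqrt(colSums(X^2))
  if (any(nrm == 0)) {
    bad <- which(nrm == 0)
    ids <- colnames(X)
    lab <- if (is.null(ids)) bad else ids[bad]
    stop("zero-norm sample column(s): ", paste(lab, collapse = ", "))
  }
  W <- crossprod(X) / outer(nrm, nrm)
  diag(W) <- 0
  W <- (W + t(W)) / 2
  W[W < 0] <- 0  # guard float noise; X >= 0 so true values are >= 0
  dimnames(W) <- list(colnames(X), colnames(X))
  new("SimilarityGraph", adjacency = W, kind = "cosine",
      knn = 0L, normalized = FALSE)
}

#' kNN sparsification (union rule)
#'
#' Keeps `W_ij` iff `i` is among the `knn` most similar neighbours of `j`
#' or vice versa, so the result stays symmetric; all other entries are set
#' to 0. Neighbour ties at the boundary are broken by ascending sample
#' index for reproducibility.
#'
#' @param graph a [SimilarityGraph-class].
#' @param knn positive integer neighbourhood size. Default 12.
#' @return a sparsified [SimilarityGraph-class].
#' @export
sparsifyKnn <- function(graph, knn = 12L) {
  stopifnot(is(graph, "SimilarityGraph"))
  if (graph@normalized)
    stop("sparsify before normalization, not after")
  knn <- as.integer(knn)
  if (knn < 1L) stop("knn must be >= 1")
  W <- graph@adjacency
  n <- nrow(W)
  if (knn >= n) {
    warning("knn >= n_samples; graph left unchanged")
    graph@knn <- knn
    return(graph)
  }
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    w <- W[, i]
    w[i] <- -Inf
    nb <- order(-w, seq_len(n))[seq_len(knn)]  # ties: ascending index
    keep[nb, i] <- TRUE
  }
  keep <- keep | t(keep)
  W[!keep] <- 0
  diag(W) <- 0
  new("SimilarityGraph", adjacency = W, kind = graph@kind,
      knn = knn, normalized = FALSE)
}

#' Symmetric normalization
#'
#' `A = D^{-1/2} W D^{-1/2}` with `D_ii = sum_j W_ij`. The spectral radius
#' of the result is at most 1.
#'
#' @param graph a [SimilarityGraph-class] with strictly positive row sums.
#' @return a normalized [SimilarityGraph-class].
#' @export
normalizeSymmetric <- function(graph) {
  stopifnot(is(graph, "SimilarityGraph"))
  W <- graph@adjacency
  rs <- rowSums(W)
  if (any(rs <= 0)) {
    bad <- which(rs <= 0)
    stop("isolated node(s) with zero row sum at index ",
         paste(bad, collapse = ", "),
         "; increase knn or check the input")
  }
  s <- 1 / sqrt(rs)
  A <- W * outer(s, s)
  A <- (A + t(A)) / 2
  new("SimilarityGraph", adjacency = A, kind = graph@kind,
      knn = graph@knn, normalized = TRUE)
}

#' Build the full affinity graph for one view
#'
#' Convenience wrapper running kernel -> [sparsifyKnn()] ->
#' [normalizeSymmetric()] with the defaults used throughout the package.
#'
#' @inheritParams gaussianSimilarity
#' @param kernel `"gaussian"` (default, with local scaling) or `"cosine"`.
#' @param knn neighbourhood size for sparsification (default 12).
#' @param scaleIndex local-scale neighbour rank for the Gaussian kernel
#'   (default 7; ignored for cosine).
#' @return a normalized [SimilarityGraph-class].
#' @export
buildSimilarityGraph <- function(X, kernel = c("gaussian", "cosine"),
                                 knn = 12L, scaleIndex = 7L) {
  kernel <- match.arg(kernel)
  g <- switch(kernel,
              gaussian = gaussianSimilarity(X, scaleIndex = scaleIndex),
              cosine = cosineSimilarity(X))
  normalizeSymmetric(sparsifyKnn(g, knn = knn))
}
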