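## Seeded synthetic multi-view generators.
##
## makeMultiviewBlobs emulates the shared-structure assumption behind the
## multi-view model: one latent cluster assignment drives every view, each
## view observing the latent cluster centers through its own random
## nonnegative linear map plus truncated Gaussian noise. It does NOT
## emulate compositionality, sparsity or overdispersion of real microbiome
## profiles.

#' Multi-view Gaussian blobs with planted clusters
#'
#' Draws `nClusters` latent centers in a `latentDim`-dimensional
#' nonnegative box (uniform on `[0, 2*separation]`, redrawn until all
#' pairwise distances are at least `separation`; error after 100
#' redraws), assigns samples to clusters in (near-)balanced blocks, and
#' produces each view as `M_v %*% center + noise`, where `M_v` has iid
#' Uniform(0,1) entries and the Gaussian noise (sd `noiseSd`) is clipped
#' at 0 to keep matrices nonnegative (this truncation slightly biases
#' means upward). Fully determined by `seed`.
#'
#' @param nSamples number of samples; default 150.
#' @param nClusters number of planted clusters (>= 2); default 3.
#' @param nViews number of views; default 2.
#' @param nFeatures integer vector of per-view feature counts (recycled);
#'   default `c(30, 40)`.
#' @param noiseSd noise standard deviation; default 0.5.
#' @param separation minimum pairwise latent center distance; default 10.
#' @param latentDim latent space dimension; default 6.
#' @param clusterSizes optional integer vector summing to `nSamples`;
#'   default near-balanced.
#' @param seed integer seed; default 1.
#' @return list with `views` (named list of features x samples matrices),
#'   `labels` (integer vector in `1..nClusters`) and `centers`.
#' @export
makeMultiviewBlobs <- function(nSamples = 150L, nClusters = 3L, nViews = 2L,
                               nFeatures = c(30L, 40L), noiseSd = 0.5,
                               separation = 10, latentDim = 6L,
                               clusterSizes = NULL, seed = 1L) {
  if (nClusters < 2L) stop("nClusters must be >= 2")
  if (is.null(clusterSizes)) {
    base <- nSamples %/% nClusters
    clusterSizes <- rep(base, nClusters)
    extra <- nSamples - sum(clusterSizes)
    if (extra > 0) clusterSizes[seq_len(extra)] <- clusterSizes[seq_len(extra)] + 1L
  }
  if (sum(clusterSizes) != nSamples)
    stop("clusterSizes must sum to nSamples")
  nFeatures <- rep(as.integer(nFeatures), length.out = nViews)
  set.seed(seed)
  centers <- NULL
  for (try in seq_len(100L)) {
    C <- matrix(stats::runif(nClusters * latentDim, 0, 2 * separation),
                nClusters, latentDim)
    if (min(stats::dist(C)) >= separation) {
      centers <- C
      break
    }
  }
  if (is.null(centers))
    stop("could not place ", nClusters, " centers with separation ",
         separation, " in 100 redraws; lower separation or raise latentDim")
  labels <- rep(seq_len(nClusters), times = clusterSizes)
  Z <- centers[labels, , drop = FALSE]          # samples x latentDim
  ids <- sprintf("s%03d", seq_len(nSamples))
  views <- vector("list", nViews)
  names(views) <- paste0("view", seq_len(nViews))
  for (v in seq_len(nViews)) {
    M <- matrix(stats::runif(nFeatures[v] * latentDim), nFeatures[v],
                latentDim)
    X <- M %*% t(Z)
    if (noiseSd > 0)
      X <- X + matrix(stats::rnorm(length(X), sd = noiseSd), nrow(X))
    X <- pmax(X, 0)
    dimnames(X) <- list(sprintf("%s_f%03d", names(views)[v],
                                seq_len(nFeatures[v])), ids)
    views[[v]] <- X
  }
  list(views = views, labels = labels, centers = centers)
}

#' Planar manifold fixture
#'
#' Samples `n` points uniformly from a random affine 2-flat embedded in
#' `ambientDim` dimensions, translated into the nonnegative orthant.
#' Returns the intrinsic plane coordinates per sample, the fixture used to
#' verify that the Hessian energy operator annihilates affine functions.
#'
#' @param n number of samples.
#' @param ambientDim ambient dimension (>= 2); default 6.
#' @param seed integer seed; default 1.
#' @return list with `X` (ambientDim x n feature matrix) and `coords`
#'   (n x 2 intrinsic coordinates).
#' @export
makePlanarManifold <- function(n, ambientDim = 6L, seed = 1L) {
  if (ambientDim < 2L) stop("ambientDim must be >= 2")
  set.seed(seed)
  basis <- qr.Q(qr(matrix(stats::rnorm(ambientDim * 2L), ambientDim, 2L)))
  coords <- cbind(stats::runif(n, 0, 10), stats::runif(n, 0, 10))
  P <- coords %*% t(basis)                      # n x ambientDim
  shift <- pmax(0, -apply(P, 2L, min)) + 1
  X <- t(P) + shift                             # ambientDim x n, nonnegative
  dimnames(X) <- list(sprintf("dim%d", seq_len(ambientDim)),
                      sprintf("s%04d", seq_len(n)))
  list(X = X, coords = coords)
}
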