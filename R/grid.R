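## Hyperparameter grid search over the consensus coupling gamma and the
## Hessian weight beta, scored against reference labels by accuracy and
## NMI. Default grids are the candidate sets used for tuning:
## beta in {1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 0.05, 0.1, 0.5, 1},
## gamma in {1e-3, 5e-3, 1e-2, 0.05, 0.1, 0.5, 1}.

#' Grid search over gamma and beta
#'
#' Fits [mhsnmf()] for every `(gamma, beta)` cell, scores the consensus
#' clustering against `labels` with [clusteringAccuracy()] and
#' [clusteringNMI()], and returns one row per cell. Graphs and Hessian
#' operators are precomputed once and shared across cells. A failing cell
#' records its error message instead of aborting the grid.
#'
#' @param views named list of feature matrices (features x samples).
#' @param labels reference labels.
#' @param k number of clusters; default = number of distinct labels.
#' @param gammaGrid,betaGrid numeric candidate vectors (defaults above).
#' @param r,kernel,knn,scaleIndex,knnHessian,tangentDim,maxIter,tol as in
#'   [mhsnmf()].
#' @return data.frame with columns `gamma`, `beta`, `accuracy`, `nmi`,
#'   `nIter`, `error`.
#' @export
gridSearch <- function(views, labels, k = NULL,
                       gammaGrid = c(1e-3, 5e-3, 1e-2, 0.05, 0.1, 0.5, 1),
                       betaGrid = c(1e-4, 5e-4, 1e-3, 5e-3, 1e-2, 0.05,
                                    0.1, 0.5, 1),
                       r = 2, kernel = "gaussian", knn = 12L,
                       scaleIndex = 7L, knnHessian = 30L, tangentDim = 2L,
                       maxIter = 500L, tol = 1e-6) {
  views <- .checkViews(views)
  if (length(labels) != ncol(views[[1L]]))
    stop("labels must have length n_samples")
  if (is.null(k)) k <- length(unique(labels))
  kernel <- rep(kernel, length.out = length(views))
  graphs <- mapply(function(X, kern)
    buildSimilarityGraph(X, kernel = kern, knn = knn,
                         scaleIndex = scaleIndex),
    views, kernel, SIMPLIFY = FALSE)
  hessians <- NULL
  if (any(betaGrid > 0))
    hessians <- lapply(views, hessianEnergy, knnH = knnHessian,
                       d = tangentDim)
  cells <- expand.grid(gamma = gammaGrid, beta = betaGrid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    g <- cells$gamma[i]
    b <- cells$beta[i]
    out <- tryCatch({
      fit <- mhsnmfCore(graphs, hessians, k = k, gamma = g, beta = b,
                        r = r, maxIter = maxIter, tol = tol)
      lab <- clusterLabels(fit)
      data.frame(gamma = g, beta = b,
                 accuracy = clusteringAccuracy(lab, labels),
                 nmi = clusteringNMI(lab, labels),
                 nIter = fit@nIter, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(gamma = g, beta = b, accuracy = NA_real_, nmi = NA_real_,
                 nIter = NA_integer_, error = conditionMessage(e),
                 stringsAsFactors = FALSE))
    out
  })
  do.call(rbind, res)
}
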