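## Out-of-sample embedding and classification.
##
## A new sample x_new from view i is summarized by its inner-product
## similarity S = t(V_tr) x_new to the training samples of that view; its
## consensus-space representation h solves the ridge-regularized
## nonnegative least squares min_{h>=0} ||S - H* h||^2 + reg ||h||^2, and
## the sample is classified by majority vote among the knn nearest
## training rows of H*.

#' Similarity of a new sample to the training cohort
#'
#' `S = t(V_tr) %*% x_new`: inner product of the new sample with each
#' training sample of one view.
#'
#' @param xNew numeric feature vector (length = number of features of the
#'   view).
#' @param Vtr training feature matrix of the view (features x n_train).
#' @return numeric vector of length `n_train`.
#' @export
similarityToTraining <- function(xNew, Vtr) {
  if (!is.numeric(xNew) || length(xNew) != nrow(Vtr))
    stop("xNew must have length nrow(Vtr) = ", nrow(Vtr),
         " (got ", length(xNew), ")")
  drop(crossprod(Vtr, xNew))
}

#' Kernel-matched similarity of a new sample to the training cohort
#'
#' Locally scaled Gaussian similarity of `xNew` to each training sample,
#' the out-of-sample analogue of [gaussianSimilarity()]:
#' `S_j = exp(-||x - v_j||^2 / (sigma_x sigma_j))` with `sigma_j` the
#' distance from training sample `j` to its `scaleIndex`-th training
#' neighbour and `sigma_x` the distance from `xNew` to its
#' `scaleIndex`-th nearest training sample. Puts `S` on the same scale
#' and geometry as the affinity graph the consensus was trained on; raw
#' inner products ([similarityToTraining()]) play that role only when the
#' training graph itself is inner-product (cosine) based.
#'
#' @inheritParams similarityToTraining
#' @param scaleIndex local-scale neighbour rank (default 7, matching
#'   [gaussianSimilarity()]).
#' @param sigmaTrain optional precomputed vector of training bandwidths
#'   `sigma_j` (saves the O(n^2) recomputation across many new samples).
#' @return numeric vector of length `n_train`.
#' @export
kernelSimilarityToTraining <- function(xNew, Vtr, scaleIndex = 7L,
                                       sigmaTrain = NULL) {
  if (!is.numeric(xNew) || length(xNew) != nrow(Vtr))
    stop("xNew must have length nrow(Vtr) = ", nrow(Vtr),
         " (got ", length(xNew), ")")
  n <- ncol(Vtr)
  if (scaleIndex >= n)
    stop("scaleIndex must be < n_train")
  if (is.null(sigmaTrain)) sigmaTrain <- .trainingBandwidths(Vtr, scaleIndex)
  d2 <- colSums((Vtr - xNew)^2)
  sigmaX <- sort(sqrt(d2), partial = scaleIndex)[scaleIndex]
  if (sigmaX == 0)
    stop("zero local scale for the new sample: it duplicates >= ",
         scaleIndex, " training samples")
  exp(-d2 / (sigmaX * sigmaTrain))
}

# sigma_j = distance from training sample j to its scaleIndex-th neighbour
.trainingBandwidths <- function(Vtr, scaleIndex = 7L) {
  D <- as.matrix(stats::dist(t(Vtr)))
  vapply(seq_len(ncol(Vtr)), function(i)
    sort(D[i, -i], partial = scaleIndex)[scaleIndex], numeric(1))
}

# Lawson-Hanson active-set nonnegative least squares: min_{x>=0} ||y - Cx||^2
.nnlsSolve <- function(C, y, tol = 1e-12, maxIter = NULL) {
  k <- ncol(C)
  if (is.null(maxIter)) maxIter <- 30L * max(k, 3L)
  x <- numeric(k)
  P <- logical(k)
  w <- drop(crossprod(C, y - C %*% x))
  scale <- max(1, abs(w))
  iter <- 0L
  while (any(!P) && any(w[!P] > tol * scale)) {
    cand <- which(!P)
    j <- cand[which.max(w[cand])]
    P[j] <- TRUE
    repeat {
      s <- numeric(k)
      co <- qr.coef(qr(C[, P, drop = FALSE]), y)
      co[is.na(co)] <- 0
      s[P] <- co
      if (all(s[P] > tol)) {
        x <- s
        break
      }
      Q <- P & (s <= tol)
      a <- min(x[Q] / (x[Q] - s[Q]))
      x <- x + a * (s - x)
      P <- P & (x > tol)
      x[!P] <- 0
      iter <- iter + 1L
      if (iter > maxIter) break
    }
    w <- drop(crossprod(C, y - C %*% x))
    iter <- iter + 1L
    if (iter > maxIter) break
  }
  pmax(x, 0)
}

#' Embed a new sample into the consensus space
#'
#' Solves `min_{h >= 0} ||S - H* h||^2 + reg * ||h||^2` as nonnegative
#' least squares on the augmented system `[H*; sqrt(reg) I]` vs `[S; 0]`
#' (Lawson-Hanson active set; deterministic).
#'
#' @param S similarity vector to the training samples (length `n_train`),
#'   from [similarityToTraining()].
#' @param Hstar trained consensus factor (`n_train x k`).
#' @param reg ridge weight `>= 0`; default 0.1.
#' @return nonnegative vector `h` of length `k`.
#' @export
embedNewSample <- function(S, Hstar, reg = 0.1) {
  Hstar <- .asMatrixLike(Hstar)
  k <- ncol(Hstar)
  if (k == 0L) stop("Hstar has zero columns")
  if (length(S) != nrow(Hstar))
    stop("S must have length nrow(Hstar)")
  if (reg < 0) stop("reg must be >= 0")
  C <- Hstar
  y <- S
  if (reg > 0) {
    C <- rbind(Hstar, sqrt(reg) * diag(k))
    y <- c(S, numeric(k))
  }
  .nnlsSolve(C, y)
}

#' Classify an embedded sample by nearest neighbours
#'
#' Majority vote among the `knnClassify` training rows of `H*` closest
#' (Euclidean) to `h`; vote ties go to the smallest label (sort order),
#' distance ties to the lowest sample index.
#'
#' @param h embedded sample (length `k`), from [embedNewSample()].
#' @param HstarTrain trained consensus factor (`n_train x k`).
#' @param trainLabels labels of the training samples (length `n_train`).
#' @param knnClassify number of neighbours; default 5.
#' @return the predicted label (same type as `trainLabels`).
#' @export
classifySample <- function(h, HstarTrain, trainLabels, knnClassify = 5L) {
  HstarTrain <- .asMatrixLike(HstarTrain)
  nTrain <- nrow(HstarTrain)
  if (nTrain == 0L) stop("empty training set")
  if (length(trainLabels) != nTrain)
    stop("trainLabels must have length nrow(HstarTrain)")
  if (knnClassify > nTrain)
    stop("knnClassify must be <= n_train")
  d2 <- rowSums(sweep(HstarTrain, 2L, h)^2)
  nb <- order(d2, seq_len(nTrain))[seq_len(knnClassify)]
  votes <- table(trainLabels[nb])
  winners <- names(votes)[votes == max(votes)]
  win <- sort(winners)[1L]
  trainLabels[match(win, as.character(trainLabels))]
}

#' Stratified holdout evaluation of the prediction pipeline
#'
#' Splits the cohort into training and test sets stratified by label
#' (classes with fewer than 2 samples are kept whole in training, with a
#' warning), fits [mhsnmf()] on the training views, then embeds and
#' classifies every test sample separately from each view and reports
#' per-view and average test accuracy.
#'
#' @param views named list of feature matrices (features x samples).
#' @param labels reference labels, length = number of samples.
#' @param trainFrac fraction of each class used for training, in (0, 1);
#'   default 0.7.
#' @param k number of clusters; default = number of distinct labels.
#' @param reg ridge weight for the embedding; default 0.1.
#' @param knnClassify neighbours for classification; default 5.
#' @param similarity `"auto"` (default): Gaussian kernel similarity
#'   ([kernelSimilarityToTraining()]) for views whose training graph used
#'   the Gaussian kernel, raw inner products for cosine views;
#'   `"linear"`/`"kernel"` force one form for all views.
#' @param seed integer seed controlling the split; default 1.
#' @param ... further arguments to [mhsnmf()] (gamma, beta, knnHessian, ...).
#' @return list with `perView` (named accuracy vector), `average`,
#'   `testIndex`, `predictions` (list per view) and the training `fit`.
#' @export
holdoutProtocol <- function(views, labels, trainFrac = 0.7, k = NULL,
                            reg = 0.1, knnClassify = 5L,
                            similarity = c("auto", "linear", "kernel"),
                            seed = 1L, ...) {
  similarity <- match.arg(similarity)
  views <- .checkViews(views)
  n <- ncol(views[[1L]])
  if (length(labels) != n) stop("labels must have length n_samples")
  if (trainFrac <= 0 || trainFrac >= 1) stop("trainFrac must be in (0, 1)")
  if (is.null(k)) k <- length(unique(labels))
  set.seed(seed)
  trainIdx <- integer(0)
  for (cl in sort(unique(as.character(labels)))) {
    idx <- which(as.character(labels) == cl)
    if (length(idx) < 2L) {
      warning("class '", cl, "' has < 2 samples; kept whole in training")
      trainIdx <- c(trainIdx, idx)
    } else {
      nTr <- max(1L, round(trainFrac * length(idx)))
      nTr <- min(nTr, length(idx) - 1L)
      trainIdx <- c(trainIdx, sample(idx, nTr))
    }
  }
  trainIdx <- sort(trainIdx)
  testIdx <- setdiff(seq_len(n), trainIdx)
  if (length(testIdx) == 0L) stop("empty test set; lower trainFrac")
  trainViews <- lapply(views, function(X) X[, trainIdx, drop = FALSE])
  fit <- mhsnmf(trainViews, k = k, ...)
  Hstar <- consensus(fit)
  trLab <- labels[trainIdx]
  perView <- numeric(length(views))
  names(perView) <- names(views)
  predictions <- vector("list", length(views))
  names(predictions) <- names(views)
  kernels <- rep(fit@config$kernel %||% "gaussian",
                 length.out = length(views))
  scaleIndex <- fit@config$scaleIndex %||% 7L
  for (v in seq_along(views)) {
    Vtr <- trainViews[[v]]
    useKernel <- switch(similarity,
                        auto = kernels[v] == "gaussian",
                        linear = FALSE, kernel = TRUE)
    sigmaTrain <- if (useKernel) .trainingBandwidths(Vtr, scaleIndex)
                  else NULL
    pred <- vapply(testIdx, function(j) {
      S <- if (useKernel)
        kernelSimilarityToTraining(views[[v]][, j], Vtr, scaleIndex,
                                   sigmaTrain)
      else similarityToTraining(views[[v]][, j], Vtr)
      h <- embedNewSample(S, Hstar, reg = reg)
      as.character(classifySample(h, Hstar, trLab, knnClassify))
    }, character(1))
    predictions[[v]] <- pred
    perView[v] <- mean(pred == as.character(labels[testIdx]))
  }
  list(perView = perView, average = mean(perView), testIndex = testIdx,
       predictions = predictions, fit = fit)
}
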