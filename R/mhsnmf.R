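## The multi-view Hessian-regularized symmetric NMF solver.
##
## Objective (implemented form; the Hessian term carries the smoothed
## weights alpha^r, r > 1, which makes the closed-form weight update the
## exact minimizer):
##
##   sum_v ||A^v - H^v t(H^v)||_F^2
##   + gamma * sum_v ||H^v Q^v - H*||_F^2
##   + beta * tr( t(H*) (sum_v (alpha^v)^r B^v) H* ),
##   H^v, H* >= 0, alpha on the simplex.
##
## Alternating scheme per sweep: for each view, multiplicative update of
## H^v then of H*; after all views, closed-form update of alpha.

## ---- update rules (internal; exercised directly by the test oracles) ----

# H <- H * (1/2 + (2 A H + gamma H* Q) / (2 (2 H t(H) H + gamma H Q^2) + eps))
# q is the diagonal of Q. The ratio is the KKT multiplicative step; the
# 1/2-damping (the standard symmetric-NMF stabilization) keeps the same
# fixed points but makes the objective nonincreasing — the undamped ratio
# oscillates on dense inputs. gamma = 0 reduces to damped single-view SNMF.
.updateViewFactor <- function(H, A, Hstar, q, gamma) {
  num <- 2 * (A %*% H)
  den <- H %*% (2 * crossprod(H))
  if (gamma > 0) {
    num <- num + gamma * sweep(Hstar, 2L, q, "*")
    den <- den + gamma * sweep(H, 2L, q^2, "*")
  }
  H * (0.5 + num / (2 * den + .EPS))
}

# H* <- H* * (gamma sum_v H^v Q^v + beta B^- H*) /
#            (gamma n_v H* + beta B^+ H* + eps)
# with B = Bcomb split as B^+ - B^- so nonnegativity is preserved.
.updateConsensus <- function(Hstar, Hviews, qs, gamma, beta, Bcomb = NULL) {
  nv <- length(Hviews)
  num <- matrix(0, nrow(Hstar), ncol(Hstar))
  if (gamma > 0) {
    for (v in seq_len(nv))
      num <- num + gamma * sweep(Hviews[[v]], 2L, qs[[v]], "*")
  }
  den <- gamma * nv * Hstar
  if (beta > 0 && !is.null(Bcomb)) {
    Bp <- (abs(Bcomb) + Bcomb) / 2
    Bn <- (abs(Bcomb) - Bcomb) / 2
    num <- num + beta * (Bn %*% Hstar)
    den <- den + beta * (Bp %*% Hstar)
  }
  Hstar * num / (den + .EPS)
}

# closed-form simplex weights: alpha^v propto (1/t_v)^(1/(r-1)) with
# t_v = tr(t(H*) B^v H*). Zero-trace views (already perfectly smooth)
# absorb all the weight uniformly, the limit behaviour of the formula.
.updateViewWeights <- function(Bs, Hstar, r) {
  t <- vapply(Bs, function(B) sum(Hstar * (.asMatrixLike(B) %*% Hstar)),
              numeric(1))
  t <- pmax(t, 0)  # B^v is PSD; clamp float noise
  if (any(t == 0)) {
    warning("zero Hessian trace for view(s) ",
            paste(which(t == 0), collapse = ", "),
            "; assigning them all the weight uniformly")
    alpha <- ifelse(t == 0, 1, 0)
    return(alpha / sum(alpha))
  }
  w <- (1 / t)^(1 / (r - 1))
  w / sum(w)
}

#' Objective value of the multi-view factorization
#'
#' Evaluates the implemented objective: per-view reconstruction errors
#' `||A^v - H^v t(H^v)||_F^2`, consensus coupling
#' `gamma * ||H^v Q^v - H*||_F^2`, and the Hessian smoothness penalty
#' `beta * tr(t(H*) (sum_v alpha_v^r B^v) H*)`.
#'
#' @param Hviews list of per-view factors.
#' @param Hstar consensus factor.
#' @param qs list of column-scaling vectors (diagonals of `Q^v`).
#' @param alphas simplex view weights.
#' @param graphs list of [SimilarityGraph-class] (or matrices) `A^v`.
#' @param hessians list of [HessianEnergy-class] (or matrices) `B^v`, or
#'   `NULL` when `beta = 0`.
#' @param gamma,beta,r hyperparameters (see [mhsnmf()]).
#' @return scalar objective value.
#' @export
mhsnmfObjective <- function(Hviews, Hstar, qs, alphas, graphs,
                            hessians = NULL, gamma, beta, r = 2) {
  obj <- 0
  for (v in seq_along(Hviews)) {
    A <- .asMatrixLike(graphs[[v]])
    H <- Hviews[[v]]
    if (!all(dim(A) == nrow(H)))
      stop("shape mismatch between graph and factor in view ", v)
    R <- A - tcrossprod(H)
    obj <- obj + sum(R * R)
    if (gamma > 0) {
      Dv <- sweep(H, 2L, qs[[v]], "*") - Hstar
      obj <- obj + gamma * sum(Dv * Dv)
    }
  }
  if (beta > 0 && !is.null(hessians)) {
    for (v in seq_along(hessians)) {
      B <- .asMatrixLike(hessians[[v]])
      obj <- obj + beta * alphas[v]^r * sum(Hstar * (B %*% Hstar))
    }
  }
  obj
}

#' Multi-view solver on precomputed graphs and Hessians
#'
#' The alternating MHSNMF engine. Initializes each `H^v` by [nndsvdInit()]
#' on its graph, the consensus `H*` as the mean of the column-rescaled
#' `H^v Q^v`, and uniform weights `alpha_v = 1/n_v`; then sweeps
#' (per view: update `H^v`, recompute `Q^v`, update `H*`; then update
#' `alpha`) until the relative objective change falls below `tol` or
#' `maxIter` sweeps.
#'
#' @param graphs list of normalized [SimilarityGraph-class] (or symmetric
#'   nonnegative matrices), one per view.
#' @param hessians list of [HessianEnergy-class] (or matrices), one per
#'   view; may be `NULL` when `beta = 0`.
#' @param k factorization rank (number of clusters).
#' @param gamma consensus coupling weight (>= 0), shared across views.
#' @param beta Hessian regularization weight (>= 0).
#' @param r weight-smoothing exponent (> 1), default 2.
#' @param maxIter maximum sweeps (default 500).
#' @param tol relative objective-change tolerance (default 1e-6).
#' @param learnWeights update `alpha` each sweep (default `TRUE`); set
#'   `FALSE` to keep the weights fixed at their initial value.
#' @param init optional list of initial per-view factors.
#' @return an [MHSNMFFit-class].
#' @export
mhsnmfCore <- function(graphs, hessians = NULL, k, gamma, beta, r = 2,
                       maxIter = 500L, tol = 1e-6, learnWeights = TRUE,
                       init = NULL) {
  if (!is.list(graphs) || length(graphs) == 0L)
    stop("graphs must be a non-empty list")
  if (gamma < 0 || beta < 0) stop("gamma and beta must be >= 0")
  if (r <= 1) stop("r must be > 1")
  nv <- length(graphs)
  As <- lapply(graphs, .asMatrixLike)
  n <- nrow(As[[1L]])
  for (A in As)
    if (!all(dim(A) == n)) stop("all graphs must be n x n over one cohort")
  Bs <- NULL
  if (beta > 0) {
    if (is.null(hessians) || length(hessians) != nv)
      stop("beta > 0 requires one Hessian energy per view")
    Bs <- lapply(hessians, .asMatrixLike)
    for (B in Bs)
      if (!all(dim(B) == n)) stop("Hessian matrices must be n x n")
  }
  vnames <- names(graphs)
  if (is.null(vnames) || any(!nzchar(vnames)))
    vnames <- paste0("view", seq_len(nv))

  userInit <- !is.null(init)
  Hv <- if (userInit) init else lapply(As, nndsvdInit, k = k)
  for (H in Hv)
    if (any(H < 0) || !all(dim(H) == c(n, k)))
      stop("init factors must be nonnegative n x k")
  qs <- lapply(Hv, columnScaling)
  ## Cluster columns of independently initialized views are in arbitrary
  ## order (for block-structured graphs the leading eigenvalues are
  ## degenerate), so the factors must be column-aligned before the mean
  ## defines the initial consensus; otherwise the coupling term pulls every
  ## view toward a scrambled average. Alignment is a one-off permutation of
  ## the initialization; the update rules are untouched. User-supplied
  ## inits are taken as given.
  if (!userInit && nv > 1L && k > 1L) {
    ref <- sweep(Hv[[1L]], 2L, qs[[1L]], "*")
    for (v in 2:nv) {
      M <- crossprod(ref, sweep(Hv[[v]], 2L, qs[[v]], "*"))
      perm <- .hungarian(max(M) - M)
      Hv[[v]] <- Hv[[v]][, perm, drop = FALSE]
      qs[[v]] <- qs[[v]][perm]
    }
  }
  alpha <- rep(1 / nv, nv)
  Hstar <- Reduce(`+`, mapply(function(H, q) sweep(H, 2L, q, "*"),
                              Hv, qs, SIMPLIFY = FALSE)) / nv

  combineB <- function(alpha) {
    if (is.null(Bs)) return(NULL)
    Bc <- matrix(0, n, n)
    for (v in seq_len(nv)) Bc <- Bc + alpha[v]^r * Bs[[v]]
    Bc
  }

  obj <- mhsnmfObjective(Hv, Hstar, qs, alpha, As, Bs, gamma, beta, r)
  trace <- numeric(maxIter + 1L)
  trace[1L] <- obj
  it <- 0L
  nIncrease <- 0L
  while (it < maxIter) {
    it <- it + 1L
    Bcomb <- combineB(alpha)
    for (v in seq_len(nv)) {
      Hv[[v]] <- .updateViewFactor(Hv[[v]], As[[v]], Hstar, qs[[v]], gamma)
      if (any(!is.finite(Hv[[v]])))
        stop("non-finite entries in view factor ", v, " at sweep ", it)
      qs[[v]] <- columnScaling(Hv[[v]])
      Hstar <- .updateConsensus(Hstar, Hv, qs, gamma, beta, Bcomb)
      if (any(!is.finite(Hstar)))
        stop("non-finite entries in consensus at sweep ", it)
    }
    if (learnWeights && !is.null(Bs))
      alpha <- .updateViewWeights(Bs, Hstar, r)
    newObj <- mhsnmfObjective(Hv, Hstar, qs, alpha, As, Bs, gamma, beta, r)
    trace[it + 1L] <- newObj
    if (newObj > obj * (1 + 1e-6)) {
      nIncrease <- nIncrease + 1L
      if (nIncrease >= 5L)
        stop("objective increased for 5 consecutive sweeps (sweep ", it,
             ": ", format(obj), " -> ", format(newObj),
             "); the solver is diverging")
    } else {
      nIncrease <- 0L
    }
    done <- abs(obj - newObj) < tol * max(obj, .EPS)
    obj <- newObj
    if (done) break
  }
  names(Hv) <- vnames
  names(qs) <- vnames
  names(alpha) <- vnames
  new("MHSNMFFit", viewFactors = Hv, consensus = Hstar, weights = alpha,
      scalings = qs, objective = trace[seq_len(it + 1L)], nIter = it,
      config = list(k = k, gamma = gamma, beta = beta, r = r,
                    maxIter = maxIter, tol = tol,
                    learnWeights = learnWeights))
}

#' Multi-view Hessian-regularized symmetric NMF
#'
#' High-level entry point: builds the per-view affinity graphs
#' ([buildSimilarityGraph()]) and Hessian energy operators
#' ([hessianEnergy()]) from raw feature matrices, then runs the
#' alternating solver [mhsnmfCore()].
#'
#' @param views named list of feature matrices (features x samples), one
#'   per view, sharing the sample cohort (matching column order; ids are
#'   checked when present).
#' @param k number of clusters.
#' @param gamma consensus coupling weight; default 0.05.
#' @param beta Hessian regularization weight; default 0.01.
#' @param r weight-smoothing exponent (> 1); default 2.
#' @param kernel affinity kernel, `"gaussian"` (default) or `"cosine"`;
#'   recycled over views.
#' @param knn affinity-graph neighbourhood size; default 12.
#' @param scaleIndex Gaussian local-scale neighbour rank; default 7.
#' @param knnHessian Hessian neighbourhood size; default 30.
#' @param tangentDim tangent-space dimension for the Hessian; default 2.
#' @param maxIter,tol solver controls, see [mhsnmfCore()].
#' @param learnWeights learn the view weights (default `TRUE`).
#' @return an [MHSNMFFit-class].
#' @examples
#' sim <- makeMultiviewBlobs(nSamples = 60, nClusters = 3, nViews = 2,
#'                           seed = 1)
#' fit <- mhsnmf(sim$views, k = 3, knnHessian = 15)
#' table(clusterLabels(fit), sim$labels)
#' @export
mhsnmf <- function(views, k, gamma = 0.05, beta = 0.01, r = 2,
                   kernel = "gaussian", knn = 12L, scaleIndex = 7L,
                   knnHessian = 30L, tangentDim = 2L,
                   maxIter = 500L, tol = 1e-6, learnWeights = TRUE) {
  views <- .checkViews(views)
  kernel <- rep(kernel, length.out = length(views))
  graphs <- mapply(function(X, kern)
    buildSimilarityGraph(X, kernel = kern, knn = knn,
                         scaleIndex = scaleIndex),
    views, kernel, SIMPLIFY = FALSE)
  hessians <- NULL
  if (beta > 0)
    hessians <- lapply(views, hessianEnergy, knnH = knnHessian,
                       d = tangentDim)
  fit <- mhsnmfCore(graphs, hessians, k = k, gamma = gamma, beta = beta,
                    r = r, maxIter = maxIter, tol = tol,
                    learnWeights = learnWeights)
  fit@config <- c(fit@config,
                  list(kernel = kernel, knn = knn, scaleIndex = scaleIndex,
                       knnHessian = knnHessian, tangentDim = tangentDim))
  fit
}
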