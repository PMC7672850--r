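#' @import methods
NULL

## denominator guard shared by every multiplicative update
.EPS <- 1e-10

#' SimilarityGraph: a sample-sample affinity matrix for one view
#'
#' Symmetric nonnegative affinity over the samples of a single view,
#' produced by [gaussianSimilarity()] or [cosineSimilarity()], optionally
#' kNN-sparsified ([sparsifyKnn()]) and symmetrically normalized
#' ([normalizeSymmetric()]).
#'
#' @slot adjacency numeric matrix, samples x samples; symmetric, entrywise
#'   nonnegative, zero diagonal before normalization.
#' @slot kind character, `"gaussian"` or `"cosine"`.
#' @slot knn integer, neighbourhood size used for sparsification
#'   (0 = unsparsified).
#' @slot normalized logical, whether `D^{-1/2} W D^{-1/2}` normalization has
#'   been applied.
#'
#' @exportClass SimilarityGraph
setClass("SimilarityGraph",
  representation(adjacency = "matrix", kind = "character",
                 knn = "integer", normalized = "logical"))

setValidity("SimilarityGraph", function(object) {
  W <- object@adjacency
  if (nrow(W) != ncol(W)) return("adjacency must be square")
  if (any(!is.finite(W))) return("adjacency contains non-finite entries")
  if (any(W < 0)) return("adjacency must be nonnegative")
  if (max(abs(W - t(W))) >= 1e-10) return("adjacency must be symmetric (tol 1e-10)")
  if (!object@normalized && any(abs(diag(W)) > 0))
    return("unnormalized adjacency must have a zero diagonal")
  if (!object@kind %in% c("gaussian", "cosine"))
    return("kind must be 'gaussian' or 'cosine'")
  TRUE
})

#' HessianEnergy: total Hessian energy operator of one view
#'
#' Symmetric positive semidefinite n x n matrix `B` such that `t(f) %*% B %*% f`
#' estimates the integrated squared second derivative (curviness) of a
#' function `f` sampled on the view's data manifold. Built by
#' [hessianEnergy()].
#'
#' @slot energy numeric matrix, samples x samples, symmetric PSD.
#' @slot knnH integer, local neighbourhood size used.
#' @slot tangentDim integer, tangent-space dimension `d` used.
#'
#' @exportClass HessianEnergy
setClass("HessianEnergy",
  representation(energy = "matrix", knnH = "integer", tangentDim = "integer"))

setValidity("HessianEnergy", function(object) {
  B <- object@energy
  if (nrow(B) != ncol(B)) return("energy must be square")
  if (any(!is.finite(B))) return("energy contains non-finite entries")
  if (max(abs(B - t(B))) >= 1e-8) return("energy must be symmetric (tol 1e-8)")
  TRUE
})

#' MHSNMFFit: state of a fitted multi-view factorization
#'
#' Holds the per-view factors `H^v`, the consensus factor `H*`, the learned
#' simplex view weights `alpha^v`, the diagonal column scalings `Q^v`
#' (stored as vectors), and the objective trace of the alternating solver.
#'
#' @slot viewFactors named list of nonnegative matrices (samples x k).
#' @slot consensus nonnegative matrix, samples x k.
#' @slot weights numeric vector on the simplex, one weight per view.
#' @slot scalings named list of numeric vectors; `Q^v` diagonals.
#' @slot objective numeric vector, objective value after each sweep
#'   (element 1 is the value at initialization).
#' @slot nIter integer, number of sweeps run.
#' @slot config list echoing the hyperparameters used.
#'
#' @exportClass MHSNMFFit
setClass("MHSNMFFit",
  representation(viewFactors = "list", consensus = "matrix",
                 weights = "numeric", scalings = "list",
                 objective = "numeric", nIter = "integer", config = "list"))

setValidity("MHSNMFFit", function(object) {
  if (any(object@consensus < 0)) return("consensus must be nonnegative")
  for (H in object@viewFactors)
    if (any(H < 0)) return("view factors must be nonnegative")
  a <- object@weights
  if (length(a) != length(object@viewFactors))
    return("one weight per view required")
  if (any(a < 0) || abs(sum(a) - 1) > 1e-10)
    return("weights must lie on the simplex (sum 1, tol 1e-10)")
  TRUE
})

## ---- generics ----

#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @export
setGeneric("graphKind", function(x) standardGeneric("graphKind"))
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))
#' @export
setGeneric("energyMatrix", function(x) standardGeneric("energyMatrix"))
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))
#' @export
setGeneric("viewFactors", function(x) standardGeneric("viewFactors"))
#' @export
setGeneric("viewWeights", function(x) standardGeneric("viewWeights"))
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @export
setGeneric("clusterLabels", function(x, ...) standardGeneric("clusterLabels"))

#' @describeIn SimilarityGraph the affinity matrix.
#' @param x a `SimilarityGraph`
#' @export
setMethod("adjacency", "SimilarityGraph", function(x) x@adjacency)

#' @describeIn SimilarityGraph the kernel used (`"gaussian"`/`"cosine"`).
#' @export
setMethod("graphKind", "SimilarityGraph", function(x) x@kind)

#' @describeIn SimilarityGraph whether symmetric normalization was applied.
#' @export
setMethod("isNormalized", "SimilarityGraph", function(x) x@normalized)

#' @describeIn HessianEnergy the n x n Hessian energy matrix `B`.
#' @param x a `HessianEnergy`
#' @export
setMethod("energyMatrix", "HessianEnergy", function(x) x@energy)

#' @describeIn MHSNMFFit the consensus factor `H*` (samples x k).
#' @param x an `MHSNMFFit`
#' @export
setMethod("consensus", "MHSNMFFit", function(x) x@consensus)

#' @describeIn MHSNMFFit named list of per-view factors `H^v`.
#' @export
setMethod("viewFactors", "MHSNMFFit", function(x) x@viewFactors)

#' @describeIn MHSNMFFit learned simplex view weights `alpha^v`.
#' @export
setMethod("viewWeights", "MHSNMFFit", function(x) x@weights)

#' @describeIn MHSNMFFit objective value per sweep (first element:
#'   initialization).
#' @export
setMethod("objectiveTrace", "MHSNMFFit", function(x) x@objective)

#' @describeIn MHSNMFFit hard cluster labels from the consensus factor
#'   (row argmax, see [assignClusters()]).
#' @param ... ignored
#' @export
setMethod("clusterLabels", "MHSNMFFit",
          function(x, ...) assignClusters(x@consensus))

## ---- show ----

setMethod("show", "SimilarityGraph", function(object) {
  cat(sprintf("SimilarityGraph: %d samples, %s kernel%s%s\n",
              nrow(object@adjacency), object@kind,
              if (object@knn > 0L) sprintf(", knn=%d", object@knn) else "",
              if (object@normalized) ", normalized" else ""))
})

setMethod("show", "HessianEnergy", function(object) {
  cat(sprintf("HessianEnergy: %d samples, knnH=%d, tangent dim d=%d\n",
              nrow(object@energy), object@knnH, object@tangentDim))
})

setMethod("show", "MHSNMFFit", function(object) {
  k <- ncol(object@consensus)
  cat(sprintf("MHSNMFFit: %d samples, k=%d, %d view(s)\n",
              nrow(object@consensus), k, length(object@viewFactors)))
  cat(sprintf("  sweeps run: %d; final objective: %.6g\n",
              object@nIter, utils::tail(object@objective, 1)))
  cat("  view weights:",
      paste(sprintf("%s=%.4f", names(object@viewFactors), object@weights),
            collapse = ", "), "\n")
})
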