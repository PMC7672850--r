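## shared input validation helpers (internal)

# A feature matrix is features x samples, nonnegative, finite, >= 2 samples,
# unique sample ids (if named).
.checkFeatureMatrix <- function(X, what = "X") {
  if (!is.matrix(X) || !is.numeric(X))
    stop(what, " must be a numeric matrix (features x samples)")
  if (any(!is.finite(X)))
    stop(what, " contains non-finite entries")
  if (any(X < 0))
    stop(what, " contains negative entries; feature matrices must be nonnegative")
  if (ncol(X) < 2L)
    stop(what, " must have at least 2 samples (columns)")
  ids <- colnames(X)
  if (!is.null(ids) && anyDuplicated(ids))
    stop(what, " has duplicated sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  invisible(TRUE)
}

# Views: a non-empty list of feature matrices over one shared sample cohort.
# Sample identity is enforced by id match when ids are present, else by count.
.checkViews <- function(views) {
  if (!is.list(views) || length(views) == 0L)
    stop("views must be a non-empty list of feature matrices")
  if (is.null(names(views)) || any(!nzchar(names(views))))
    names(views) <- paste0("view", seq_along(views))
  n <- ncol(views[[1L]])
  ref <- colnames(views[[1L]])
  for (v in seq_along(views)) {
    .checkFeatureMatrix(views[[v]], names(views)[v])
    if (ncol(views[[v]]) != n)
      stop("all views must share the sample cohort: ", names(views)[v],
           " has ", ncol(views[[v]]), " samples, expected ", n)
    ids <- colnames(views[[v]])
    if (!is.null(ref) && !is.null(ids) && !identical(ids, ref)) {
      d <- union(setdiff(ids, ref), setdiff(ref, ids))
      stop("sample ids of ", names(views)[v], " do not match view 1",
           if (length(d)) paste0("; symmetric difference: ",
                                 paste(d, collapse = ", ")) else
             " (same set, different order)")
    }
  }
  views
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# accept either a SimilarityGraph / HessianEnergy or a bare matrix
.asMatrixLike <- function(x) {
  if (is(x, "SimilarityGraph")) return(x@adjacency)
  if (is(x, "HessianEnergy")) return(x@energy)
  if (is.matrix(x)) return(x)
  stop("expected a matrix, SimilarityGraph or HessianEnergy")
}
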