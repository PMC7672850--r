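## Clustering readout and evaluation metrics.

#' Hard cluster assignment from a factor matrix
#'
#' `label_i = argmax_j H[i, j]`, ties broken by the lowest column index.
#' Note the readout is not invariant to rescaling columns of `H` by
#' different positive constants; with unit-column-sum factors (`H Q`) it
#' is scale-free.
#'
#' @param H nonnegative matrix, samples x k.
#' @return integer vector of labels in `1..k`.
#' @export
assignClusters <- function(H) {
  H <- .asMatrixLike(H)
  if (any(H < 0)) stop("H must be nonnegative")
  zero <- rowSums(H) == 0
  if (any(zero))
    warning("all-zero row(s) ", paste(which(zero), collapse = ", "),
            "; assigned to cluster 1")
  lab <- max.col(H, ties.method = "first")
  lab[zero] <- 1L
  lab
}

# O(k^3) Hungarian algorithm on a square cost matrix (minimization).
# Returns match[i] = column assigned to row i.
.hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1L)   # column potentials; index 1 = virtual column 0
  p <- integer(n + 1L)   # p[j+1] = row matched to column j (0 = free)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    way <- integer(n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- -1L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match <- integer(n)
  for (j in seq_len(n)) match[p[j + 1L]] <- j
  match
}

#' Clustering accuracy under optimal label matching
#'
#' The fraction of samples correctly clustered under the best one-to-one
#' matching between predicted clusters and reference classes, computed
#' exactly by optimal assignment (Hungarian algorithm) on the confusion
#' matrix. Invariant to renaming labels in either argument.
#'
#' @param pred,truth label vectors of equal length (any atomic type).
#' @return accuracy in `[0, 1]`.
#' @export
clusteringAccuracy <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  n <- length(pred)
  C <- unclass(table(factor(pred), factor(truth)))
  k <- max(dim(C))
  profit <- matrix(0, k, k)
  profit[seq_len(nrow(C)), seq_len(ncol(C))] <- C
  match <- .hungarian(max(profit) - profit)
  sum(profit[cbind(seq_len(k), match)]) / n
}

#' Normalized mutual information between two partitions
#'
#' `NMI = I(pred; truth) / sqrt(H(pred) * H(truth))` from the empirical
#' joint distribution, with the convention `0/0 = 0` (a constant partition
#' carries zero information). Invariant to label renaming.
#'
#' @inheritParams clusteringAccuracy
#' @return NMI in `[0, 1]`.
#' @export
clusteringNMI <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length")
  n <- length(pred)
  J <- unclass(table(factor(pred), factor(truth))) / n
  pi <- rowSums(J)
  pj <- colSums(J)
  I <- 0
  for (a in seq_along(pi)) {
    for (b in seq_along(pj)) {
      if (J[a, b] > 0)
        I <- I + J[a, b] * log(J[a, b] / (pi[a] * pj[b]))
    }
  }
  Hx <- -sum(pi[pi > 0] * log(pi[pi > 0]))
  Hy <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  if (Hx == 0 || Hy == 0) return(0)
  unname(I / sqrt(Hx * Hy))
}
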