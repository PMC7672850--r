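## Delimited-text I/O for view matrices and fitted states.
##
## View matrices are TSV/CSV with the first row = sample ids and the first
## column = feature ids, orientation features x samples (a transpose flag
## covers samples x features files).

#' Read a view matrix from delimited text
#'
#' @param path file path; tab- or comma-delimited, first row sample ids,
#'   first column feature ids.
#' @param transpose logical; set `TRUE` when the file is samples x
#'   features. Default `FALSE`.
#' @param sep field separator; default `"\t"` (use `","` for CSV).
#' @return numeric matrix, features x samples, with dimnames.
#' @export
readViewMatrix <- function(path, transpose = FALSE, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(df) < 2L) stop(path, ": expected an id column plus data columns")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop(path, ": duplicated row ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(colnames(df)[-1L]))
    stop(path, ": duplicated column ids: ",
         paste(unique(colnames(df)[-1L][duplicated(colnames(df)[-1L])]),
               collapse = ", "))
  M <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(M)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))
    stop(path, ": non-numeric cells in column(s) ",
         paste(colnames(df)[-1L][bad], collapse = ", "))
  }
  rownames(M) <- ids
  if (transpose) M <- t(M)
  if (any(!is.finite(M))) {
    bad <- which(!is.finite(M), arr.ind = TRUE)[1L, ]
    stop(path, ": non-finite value at row '", rownames(M)[bad[1L]],
         "', column '", colnames(M)[bad[2L]], "'")
  }
  if (any(M < 0)) {
    bad <- which(M < 0, arr.ind = TRUE)[1L, ]
    stop(path, ": negative value at row '", rownames(M)[bad[1L]],
         "', column '", colnames(M)[bad[2L]], "'")
  }
  M
}

#' Write a matrix as TSV
#'
#' Writes with row ids in the first column (header `id`) and column ids in
#' the first row, the layout [readViewMatrix()] reads back.
#'
#' @param x matrix (or vector, written as a one-column matrix).
#' @param path output file path.
#' @export
writeMatrixTSV <- function(x, path) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("r%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("c%d", seq_len(ncol(x)))
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Serialize a fitted state to a directory
#'
#' Writes `H_star.tsv`, one `H_view_<name>.tsv` per view, `alphas.tsv`,
#' `objective_trace.tsv`, `labels.tsv` (consensus row-argmax clusters) and
#' a `config.txt` echo. Optionally stores the training view matrices and
#' labels so the state supports out-of-sample prediction.
#'
#' @param fit an [MHSNMFFit-class].
#' @param dir output directory (created if absent).
#' @param views optional named list of the training view matrices.
#' @param labels optional training labels.
#' @return `dir`, invisibly.
#' @export
writeFitState <- function(fit, dir, views = NULL, labels = NULL) {
  stopifnot(is(fit, "MHSNMFFit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Hs <- consensus(fit)
  colnames(Hs) <- sprintf("k%d", seq_len(ncol(Hs)))
  if (is.null(rownames(Hs))) rownames(Hs) <- sprintf("s%d", seq_len(nrow(Hs)))
  writeMatrixTSV(Hs, file.path(dir, "H_star.tsv"))
  for (v in names(viewFactors(fit))) {
    H <- viewFactors(fit)[[v]]
    colnames(H) <- sprintf("k%d", seq_len(ncol(H)))
    rownames(H) <- rownames(Hs)
    writeMatrixTSV(H, file.path(dir, paste0("H_view_", v, ".tsv")))
  }
  a <- matrix(viewWeights(fit), ncol = 1L,
              dimnames = list(names(viewFactors(fit)), "alpha"))
  writeMatrixTSV(a, file.path(dir, "alphas.tsv"))
  tr <- matrix(objectiveTrace(fit), ncol = 1L,
               dimnames = list(sprintf("sweep%d",
                                       seq_along(objectiveTrace(fit)) - 1L),
                               "objective"))
  writeMatrixTSV(tr, file.path(dir, "objective_trace.tsv"))
  lab <- matrix(clusterLabels(fit), ncol = 1L,
                dimnames = list(rownames(Hs), "cluster"))
  writeMatrixTSV(lab, file.path(dir, "labels.tsv"))
  cfg <- fit@config
  keep <- vapply(cfg, function(x) is.atomic(x) && length(x) >= 1L,
                 logical(1))
  lines <- vapply(names(cfg)[keep], function(nm)
    paste0(nm, "=", paste(cfg[[nm]], collapse = ",")), character(1))
  writeLines(sort(lines), file.path(dir, "config.txt"))
  if (!is.null(views)) {
    for (v in names(views))
      writeMatrixTSV(views[[v]], file.path(dir, paste0("view_data_", v,
                                                       ".tsv")))
  }
  if (!is.null(labels)) {
    tl <- matrix(as.character(labels), ncol = 1L,
                 dimnames = list(rownames(Hs), "label"))
    writeMatrixTSV(tl, file.path(dir, "train_labels.tsv"))
  }
  invisible(dir)
}

#' Read back a serialized fitted state
#'
#' @param dir directory written by [writeFitState()].
#' @return list with `Hstar`, `viewFactors`, `alphas`, `config`, and, when
#'   stored, `views` (training matrices) and `trainLabels`.
#' @export
readFitState <- function(dir) {
  if (!dir.exists(dir)) stop("state directory not found: ", dir)
  Hstar <- readViewMatrix(file.path(dir, "H_star.tsv"))
  files <- list.files(dir, pattern = "^H_view_.*\\.tsv$")
  vnames <- sub("^H_view_(.*)\\.tsv$", "\\1", files)
  viewFactors <- lapply(file.path(dir, files), readViewMatrix)
  names(viewFactors) <- vnames
  alphas <- readViewMatrix(file.path(dir, "alphas.tsv"))[, 1L]
  cfgLines <- readLines(file.path(dir, "config.txt"))
  cfg <- strsplit(cfgLines, "=", fixed = TRUE)
  config <- stats::setNames(lapply(cfg, function(x)
    utils::type.convert(strsplit(x[2L], ",", fixed = TRUE)[[1L]],
                        as.is = TRUE)),
    vapply(cfg, `[`, "", 1L))
  out <- list(Hstar = Hstar, viewFactors = viewFactors, alphas = alphas,
              config = config)
  dataFiles <- list.files(dir, pattern = "^view_data_.*\\.tsv$")
  if (length(dataFiles)) {
    vd <- lapply(file.path(dir, dataFiles), readViewMatrix)
    names(vd) <- sub("^view_data_(.*)\\.tsv$", "\\1", dataFiles)
    out$views <- vd
  }
  tlPath <- file.path(dir, "train_labels.tsv")
  if (file.exists(tlPath)) {
    tl <- utils::read.table(tlPath, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    out$trainLabels <- as.character(tl[[2L]])
  }
  out
}
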