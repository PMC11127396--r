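# Readers and writers for the plain-text interchange formats: CSV/TSV label
# tables (one id column plus one column per partition) and count matrices as
# MatrixMarket MTX with genes.txt/cells.txt sidecars or dense CSV.

guess_sep <- function(path, format) {
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv"
              else "csv"
  }
  switch(format, csv = ",", tsv = "\t",
         stop("unknown format: ", format, call. = FALSE))
}

#' Read a label table into a partition set
#'
#' Expects a header row and a first column of unique observation ids; every
#' remaining column is one partition, named by its header.
#'
#' @param path CSV/TSV file path.
#' @param format `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @param unclustered_label sentinel label for unclustered observations.
#' @return a `partition_set` with `observation_ids` set.
#' @export
read_labels <- function(path, format = c("auto", "csv", "tsv"),
                        unclustered_label = "-1") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- guess_sep(path, format)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2) {
    stop("label table needs an id column plus at least one partition column",
         call. = FALSE)
  }
  if (anyNA(df) || any(df == "")) {
    stop("label table has missing entries (use the unclustered sentinel)",
         call. = FALSE)
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate observation id: ", dup, call. = FALSE)
  }
  partition_set(df[, -1, drop = FALSE], observation_ids = ids,
                unclustered_label = unclustered_label)
}

#' Write a partition set as a label table
#'
#' CSV/TSV with an `id` column followed by one column per partition, in
#' stable partition order. Round-trips with [read_labels()].
#'
#' @param ps a `partition_set`.
#' @param path output file path.
#' @param format `"auto"`, `"csv"` or `"tsv"`.
#' @export
write_labels <- function(ps, path, format = c("auto", "csv", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(ps, "partition_set"))
  sep <- guess_sep(path, format)
  df <- as.data.frame(ps)
  if (!"id" %in% names(df)) {
    df <- cbind(id = sprintf("obs%d", seq_len(ps$n)), df,
                stringsAsFactors = FALSE)
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genes x cells count matrix
#'
#' MatrixMarket files expect `genes.txt` and `cells.txt` sidecars (one id
#' per line) next to the matrix unless given explicitly; dense CSV expects a
#' header row of cell ids and a first column of gene ids.
#'
#' @param path `.mtx` or `.csv` file path.
#' @param format `"auto"` (by extension), `"mtx"` or `"csv"`.
#' @param genes,cells optional sidecar paths for MTX input.
#' @param orientation `"genes_by_cells"` (default) or `"cells_by_genes"`
#'   (transposed on read).
#' @return count matrix with gene/cell ids in dimnames (sparse for MTX).
#' @export
read_counts <- function(path, format = c("auto", "mtx", "csv"),
                        genes = NULL, cells = NULL,
                        orientation = c("genes_by_cells",
                                        "cells_by_genes")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "csv"
  }
  if (format == "mtx") {
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    if (is.null(genes)) genes <- file.path(dirname(path), "genes.txt")
    if (is.null(cells)) cells <- file.path(dirname(path), "cells.txt")
    gid <- if (file.exists(genes)) readLines(genes) else NULL
    cid <- if (file.exists(cells)) readLines(cells) else NULL
    if (orientation == "cells_by_genes") m <- Matrix::t(m)
    if (!is.null(gid) && length(gid) != nrow(m)) {
      stop("gene sidecar length does not match matrix rows", call. = FALSE)
    }
    if (!is.null(cid) && length(cid) != ncol(m)) {
      stop("cell sidecar length does not match matrix columns",
           call. = FALSE)
    }
    dimnames(m) <- list(gid, cid)
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    if (orientation == "cells_by_genes") m <- t(m)
  }
  if (anyNA(m) || min(m) < 0) {
    stop("count matrix must be complete and non-negative", call. = FALSE)
  }
  m
}

#' Write a genes x cells count matrix
#'
#' @param x count matrix with dimnames.
#' @param prefix output prefix: MTX writes `<prefix>.mtx`, `genes.txt` and
#'   `cells.txt` in the prefix's directory; CSV writes `<prefix>.csv`.
#' @param format `"mtx"` or `"csv"`.
#' @return paths of the files written, invisibly.
#' @export
write_counts <- function(x, prefix, format = c("mtx", "csv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    mtx <- paste0(prefix, ".mtx")
    Matrix::writeMM(methods::as(methods::as(x, "CsparseMatrix"),
                                "generalMatrix"), mtx)
    gpath <- file.path(dirname(mtx), "genes.txt")
    cpath <- file.path(dirname(mtx), "cells.txt")
    writeLines(rownames(x), gpath)
    writeLines(colnames(x), cpath)
    invisible(c(mtx, gpath, cpath))
  } else {
    csv <- paste0(prefix, ".csv")
    df <- data.frame(gene = rownames(x), as.matrix(x), check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("gene", colnames(x))
    utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
    invisible(csv)
  }
}
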