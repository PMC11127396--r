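#' Create a partition of observations
#'
#' A partition assigns every observation to exactly one cluster. Cluster
#' identifiers are treated as opaque tags; their canonical order is the order
#' of first appearance in `labels`, which makes every downstream operation
#' deterministic for a fixed input ordering. A designated sentinel label
#' (default `"-1"`) marks unclustered observations; sentinel observations are
#' excluded from all pairwise agreement measures and are never merged.
#'
#' @param labels vector of cluster identifiers, one per observation. Coerced
#'   to character.
#' @param name optional tag identifying the source clustering.
#' @param unclustered_label sentinel label for unclustered observations, or
#'   `NULL` if every observation is clustered.
#' @return an object of class `partition` with fields `labels`,
#'   `cluster_ids` (distinct non-sentinel labels in first-appearance order),
#'   `name` and `unclustered_label`.
#' @examples
#' p <- partition(c("a", "a", "b"), name = "toy")
#' n_clusters(p)
#' @export
partition <- function(labels, name = NULL, unclustered_label = "-1") {
  if (length(labels) < 1L) {
    stop("a partition needs at least one observation", call. = FALSE)
  }
  if (anyNA(labels)) {
    stop("labels must not contain NA; use the unclustered sentinel instead",
         call. = FALSE)
  }
  labels <- as.character(labels)
  ids <- unique(labels)
  if (!is.null(unclustered_label)) {
    ids <- setdiff(ids, unclustered_label)
  }
  if (length(ids) < 1L) {
    stop("partition contains no clustered observations", call. = FALSE)
  }
  structure(
    list(labels = labels, cluster_ids = ids,
         name = if (is.null(name)) "partition" else as.character(name),
         unclustered_label = unclustered_label),
    class = "partition"
  )
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition '%s': %d observations, %d clusters>\n",
              x$name, length(x$labels), length(x$cluster_ids)))
  invisible(x)
}

#' Number of clusters in a partition
#'
#' Counts distinct non-sentinel cluster identifiers.
#'
#' @param p a `partition`.
#' @return integer cluster count.
#' @export
n_clusters <- function(p) {
  stopifnot(inherits(p, "partition"))
  length(p$cluster_ids)
}

as_partition <- function(x, name = NULL, unclustered_label = "-1") {
  if (inherits(x, "partition")) x else
    partition(x, name = name, unclustered_label = unclustered_label)
}

#' Bundle aligned partitions of the same observations
#'
#' @param partitions a list of `partition` objects (or plain label vectors),
#'   or a data.frame/matrix with one column per partition. All partitions
#'   must cover the same observations in the same order.
#' @param observation_ids optional unique identifiers for the observations.
#' @param unclustered_label sentinel passed through to label vectors that are
#'   not yet `partition` objects.
#' @return an object of class `partition_set` with fields `partitions`, `n`
#'   and `observation_ids`.
#' @examples
#' ps <- partition_set(data.frame(km = c(1, 1, 2, 2), hc = c(1, 2, 1, 2)))
#' @export
partition_set <- function(partitions, observation_ids = NULL,
                          unclustered_label = "-1") {
  if (is.data.frame(partitions) || is.matrix(partitions)) {
    nms <- colnames(partitions)
    if (is.null(nms)) nms <- paste0("P", seq_len(ncol(partitions)))
    partitions <- lapply(seq_len(ncol(partitions)), function(j) {
      partition(partitions[, j], name = nms[j],
                unclustered_label = unclustered_label)
    })
  }
  if (!is.list(partitions) || length(partitions) < 1L) {
    stop("partitions must be a non-empty list", call. = FALSE)
  }
  partitions <- lapply(seq_along(partitions), function(r) {
    as_partition(partitions[[r]], name = paste0("P", r),
                 unclustered_label = unclustered_label)
  })
  n <- length(partitions[[1L]]$labels)
  lens <- vapply(partitions, function(p) length(p$labels), integer(1))
  if (any(lens != n)) {
    stop("all partitions must have the same number of observations",
         call. = FALSE)
  }
  if (!is.null(observation_ids)) {
    observation_ids <- as.character(observation_ids)
    if (length(observation_ids) != n) {
      stop("observation_ids length does not match partitions", call. = FALSE)
    }
    if (anyDuplicated(observation_ids)) {
      stop("observation_ids must be unique", call. = FALSE)
    }
  }
  nms <- vapply(partitions, function(p) p$name, character(1))
  if (anyDuplicated(nms)) {
    nms <- make.unique(nms)
    for (r in seq_along(partitions)) partitions[[r]]$name <- nms[r]
  }
  structure(list(partitions = partitions, n = n,
                 observation_ids = observation_ids),
            class = "partition_set")
}

#' @export
print.partition_set <- function(x, ...) {
  ks <- vapply(x$partitions, n_clusters, integer(1))
  cat(sprintf("<partition_set: %d observations, %d partitions (k = %s)>\n",
              x$n, length(x$partitions), paste(ks, collapse = ", ")))
  invisible(x)
}

#' @export
length.partition_set <- function(x) length(x$partitions)

#' Convert a partition set to a label data.frame
#'
#' @param x a `partition_set`.
#' @param ... unused.
#' @return data.frame with one character column per partition (plus an `id`
#'   column when observation identifiers are present).
#' @export
as.data.frame.partition_set <- function(x, ...) {
  out <- lapply(x$partitions, function(p) p$labels)
  names(out) <- vapply(x$partitions, function(p) p$name, character(1))
  out <- as.data.frame(out, optional = TRUE, stringsAsFactors = FALSE)
  if (!is.null(x$observation_ids)) {
    out <- cbind(id = x$observation_ids, out, stringsAsFactors = FALSE)
  }
  out
}
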