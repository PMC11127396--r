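# Baseline hierarchical mergers: "dist" merges bottom-up along an
# agglomerative tree built on Euclidean distances between cluster medoids of
# log1p counts; "de" merges cluster pairs whose fraction of differentially
# expressed genes (limma moderated t-test, BH-adjusted) falls below a
# threshold, as in RSEC-style workflows.

as_count_matrix <- function(x) {
  if (inherits(x, "sim_result")) x <- x$data
  if (!(is.matrix(x) || inherits(x, "Matrix"))) {
    stop("counts must be a genes x cells matrix", call. = FALSE)
  }
  if (min(x) < 0) stop("count matrix has negative entries", call. = FALSE)
  x
}

cells_of <- function(p, id) which(p$labels == id)

#' Cluster medoids on the log scale
#'
#' For each cluster, the gene-wise median of log(count + 1) over its cells
#' (1 is added to avoid taking the log of zero).
#'
#' @param x genes x cells count matrix (dense or sparse), columns aligned
#'   with `p`.
#' @param p a `partition` (or label vector) of the cells.
#' @return genes x k matrix of medoid profiles, columns named by cluster id.
#' @export
cluster_medoids <- function(x, p) {
  x <- as_count_matrix(x)
  p <- as_partition(p)
  if (ncol(x) != length(p$labels)) {
    stop("columns of x do not align with the partition", call. = FALSE)
  }
  meds <- vapply(p$cluster_ids, function(id) {
    sub <- log1p(as.matrix(x[, cells_of(p, id), drop = FALSE]))
    apply(sub, 1, stats::median)
  }, numeric(nrow(x)))
  meds <- matrix(meds, nrow = nrow(x),
                 dimnames = list(rownames(x), p$cluster_ids))
  meds
}

#' Hierarchical tree of clusters from their medoids
#'
#' Agglomerative clustering of the cluster medoids under Euclidean distance.
#'
#' @param medoids genes x k medoid matrix (columns named by cluster id), as
#'   from [cluster_medoids()].
#' @param linkage agglomeration rule: `"average"` (default), `"single"` or
#'   `"complete"`.
#' @return a `cluster_tree`: list with the underlying `hclust` object and
#'   `leaves` (cluster ids).
#' @export
build_tree <- function(medoids, linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (ncol(medoids) < 2) {
    stop("need at least two clusters to build a tree", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(t(medoids)), method = linkage)
  structure(list(hclust = hc, leaves = colnames(medoids), linkage = linkage),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("<cluster_tree: %d leaves, %s linkage>\n",
              length(x$leaves), x$linkage))
  invisible(x)
}

new_merge_path <- function(p, steps, states, method, companions_names = NULL) {
  best <- if ("mean_nmi" %in% names(steps) && nrow(steps) &&
              !all(is.na(steps$mean_nmi))) {
    which.max(steps$mean_nmi)
  } else NA_integer_
  structure(list(initial = p, steps = steps, states = states,
                 method = method, best_step = best,
                 companions = companions_names),
            class = "merge_path")
}

#' @export
print.merge_path <- function(x, ...) {
  cat(sprintf("<merge_path (%s): %d steps from k = %d>\n",
              x$method, nrow(x$steps), n_clusters(x$initial)))
  invisible(x)
}

#' Partition after part of a baseline merge path
#'
#' @param path a `merge_path`.
#' @param step number of merges to replay (0 = initial partition).
#' @return a `partition`.
#' @export
path_state_at <- function(path, step) {
  stopifnot(inherits(path, "merge_path"))
  if (step < 0 || step > nrow(path$steps)) {
    stop("step must be between 0 and ", nrow(path$steps), call. = FALSE)
  }
  if (step == 0) return(path$initial)
  partition(path$states[[step]], name = path$initial$name,
            unclustered_label = path$initial$unclustered_label)
}

companion_mean_nmi <- function(labels, p, companions) {
  if (is.null(companions)) return(NA_real_)
  q <- partition(labels, name = p$name, unclustered_label = p$unclustered_label)
  mean(vapply(companions$partitions,
              function(s) nmi_from_table(contingency(q, s)), numeric(1)))
}

#' Merge clusters bottom-up along the medoid tree
#'
#' Builds the agglomerative tree of cluster medoids and executes its joins in
#' height order; each join replaces two current clusters by their union (the
#' surviving label is the lexicographically first of the canonical pair).
#' With `n_merges = k - 1` the path ends in a single cluster. When
#' `companions` are supplied, the mean NMI against them is recorded at every
#' state and `best_step` marks the state that maximizes it — the
#' agreement-based stopping rule used when benchmarking against consensus
#' merging.
#'
#' @param x genes x cells count matrix.
#' @param p a `partition` of the cells.
#' @param n_merges number of joins to execute, between 0 and k - 1 (default
#'   k - 1, the full path).
#' @param companions optional `partition_set` against which mean NMI is
#'   tracked.
#' @param linkage linkage for the medoid tree.
#' @return a `merge_path` with columns `step, cluster_a, cluster_b, height,
#'   mean_nmi`.
#' @export
dist_merge <- function(x, p, n_merges = NULL, companions = NULL,
                       linkage = "average") {
  x <- as_count_matrix(x)
  p <- as_partition(p)
  k <- n_clusters(p)
  if (is.null(n_merges)) n_merges <- k - 1L
  if (n_merges < 0 || n_merges > k - 1) {
    stop("n_merges must be between 0 and k - 1 = ", k - 1, call. = FALSE)
  }
  tree <- build_tree(cluster_medoids(x, p), linkage = linkage)
  hc <- tree$hclust
  # hclust node -> current cluster id (merges are executed in join order, so
  # every internal node is a single current cluster when reached)
  node_id <- character(k - 1)
  labels <- p$labels
  steps <- list()
  states <- list()
  for (t in seq_len(n_merges)) {
    ab <- hc$merge[t, ]
    id_of <- function(v) if (v < 0) hc$labels[-v] else node_id[v]
    ia <- id_of(ab[1]); ib <- id_of(ab[2])
    # canonical-first id survives
    ord <- order(match(c(ia, ib), p$cluster_ids))
    keep <- c(ia, ib)[ord[1]]; gone <- c(ia, ib)[ord[2]]
    labels[labels == gone] <- keep
    node_id[t] <- keep
    states[[t]] <- labels
    steps[[t]] <- data.frame(
      step = t, cluster_a = keep, cluster_b = gone,
      height = hc$height[t],
      mean_nmi = companion_mean_nmi(labels, p, companions),
      stringsAsFactors = FALSE)
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(), cluster_a = character(),
               cluster_b = character(), height = numeric(),
               mean_nmi = numeric(), stringsAsFactors = FALSE)
  new_merge_path(p, steps, states, "dist",
                 if (!is.null(companions))
                   vapply(companions$partitions, function(q) q$name,
                          character(1)))
}

#' Fraction of differentially expressed genes between two cell groups
#'
#' Fits a two-group limma model to the log1p counts, applies empirical-Bayes
#' moderation, adjusts p-values by Benjamini--Hochberg, and returns the
#' fraction of genes significant at the `fdr` cutoff. Genes with no variance
#' anywhere are never DE.
#'
#' @param x genes x cells count matrix.
#' @param cells_a,cells_b integer or logical indices of the two cell groups.
#' @param fdr adjusted p-value cutoff (default 0.05).
#' @return fraction of DE genes in [0, 1].
#' @export
de_fraction <- function(x, cells_a, cells_b, fdr = 0.05) {
  x <- as_count_matrix(x)
  if (is.logical(cells_a)) cells_a <- which(cells_a)
  if (is.logical(cells_b)) cells_b <- which(cells_b)
  if (length(cells_a) < 2 || length(cells_b) < 2) {
    warning("a group has fewer than 2 cells; moderated variance is pooled ",
            "across all genes", call. = FALSE)
  }
  y <- log1p(as.matrix(x[, c(cells_a, cells_b), drop = FALSE]))
  grp <- factor(rep(c("a", "b"), c(length(cells_a), length(cells_b))))
  design <- stats::model.matrix(~grp)
  fit <- withCallingHandlers(
    limma::eBayes(limma::lmFit(y, design)),
    warning = function(w) {
      # genes constant in both groups are offset by limma and handled below
      if (grepl("Zero sample variances", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  pv <- fit$p.value[, 2]
  pv[is.na(pv)] <- 1
  padj <- stats::p.adjust(pv, method = "BH")
  mean(padj < fdr)
}

# cherries of the current medoid tree: pairs of cluster ids joined at an
# internal node whose children are both leaves
tree_cherries <- function(tree) {
  hc <- tree$hclust
  idx <- which(hc$merge[, 1] < 0 & hc$merge[, 2] < 0)
  lapply(idx, function(t) sort(hc$labels[-hc$merge[t, ]]))
}

all_pairs <- function(ids) {
  if (length(ids) < 2) return(list())
  cmb <- utils::combn(ids, 2, simplify = FALSE)
  lapply(cmb, sort)
}

#' Merge clusters by fraction of differentially expressed genes
#'
#' Iteratively merges the candidate cluster pair with the smallest fraction
#' of DE genes (per [de_fraction()]) while that fraction is below `alpha`.
#' Candidates default to pairs adjacent in the medoid tree (cherries),
#' rebuilt after each merge; `candidates = "all"` scores every pair. With
#' `exhaustive = TRUE` the threshold is ignored and merging continues to a
#' single cluster, recording the full path for curve evaluation.
#'
#' @param x genes x cells count matrix.
#' @param p a `partition` of the cells.
#' @param alpha DE-fraction threshold below which a pair is merged
#'   (default 0.05).
#' @param companions optional `partition_set` for mean-NMI tracking.
#' @param exhaustive continue to one cluster regardless of `alpha`.
#' @param candidates `"tree"` (medoid-tree cherries, default) or `"all"`.
#' @param fdr per-gene adjusted p-value cutoff inside [de_fraction()].
#' @param linkage linkage for the candidate tree.
#' @return a `merge_path` with columns `step, cluster_a, cluster_b,
#'   de_fraction, mean_nmi`.
#' @export
de_merge <- function(x, p, alpha = 0.05, companions = NULL,
                     exhaustive = FALSE, candidates = c("tree", "all"),
                     fdr = 0.05, linkage = "average") {
  candidates <- match.arg(candidates)
  x <- as_count_matrix(x)
  p <- as_partition(p)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must be in [0, 1]", call. = FALSE)
  }
  labels <- p$labels
  current <- partition(labels, name = p$name,
                       unclustered_label = p$unclustered_label)
  cache <- new.env(parent = emptyenv())
  steps <- list()
  states <- list()
  t <- 0L
  while (n_clusters(current) >= 2) {
    pairs <- if (candidates == "tree" && n_clusters(current) > 2) {
      tree_cherries(build_tree(cluster_medoids(x, current), linkage = linkage))
    } else {
      all_pairs(current$cluster_ids)
    }
    if (!length(pairs)) break
    fracs <- vapply(pairs, function(pr) {
      key <- paste(pr, collapse = "\r")
      if (!is.null(cache[[key]])) return(cache[[key]])
      v <- de_fraction(x, cells_of(current, pr[1]), cells_of(current, pr[2]),
                       fdr = fdr)
      cache[[key]] <- v
      v
    }, numeric(1))
    b <- which.min(fracs)
    if (!exhaustive && fracs[b] >= alpha) break
    pr <- pairs[[b]]
    ord <- order(match(pr, p$cluster_ids))
    keep <- pr[ord[1]]; gone <- pr[ord[2]]
    labels[labels == gone] <- keep
    t <- t + 1L
    states[[t]] <- labels
    steps[[t]] <- data.frame(
      step = t, cluster_a = keep, cluster_b = gone,
      de_fraction = fracs[b],
      mean_nmi = companion_mean_nmi(labels, p, companions),
      stringsAsFactors = FALSE)
    current <- partition(labels, name = p$name,
                         unclustered_label = p$unclustered_label)
    # cached fractions involving the merged cluster are stale
    for (key in ls(cache)) {
      if (keep %in% strsplit(key, "\r", fixed = TRUE)[[1]]) rm(list = key, envir = cache)
    }
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(), cluster_a = character(),
               cluster_b = character(), de_fraction = numeric(),
               mean_nmi = numeric(), stringsAsFactors = FALSE)
  new_merge_path(p, steps, states, "de",
                 if (!is.null(companions))
                   vapply(companions$partitions, function(q) q$name,
                          character(1)))
}

#' Write a baseline merge path to CSV
#'
#' Same layout as [write_history()] with the extra `height` /
#' `de_fraction` column.
#'
#' @param path_obj a `merge_path`.
#' @param path output file path.
#' @export
write_path <- function(path_obj, path) {
  stopifnot(inherits(path_obj, "merge_path"))
  utils::write.csv(path_obj$steps, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
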