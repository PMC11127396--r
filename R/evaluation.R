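# Benchmark utilities: agreement-with-truth curves along a merge path, their
# normalized area under the curve, and silhouette-based output selection.

#' Agreement-with-truth curve along a merge path
#'
#' Scores the evolving partition against a reference partition at every state
#' of a merge, from the initial partition (step 0) to the final one. For a
#' multi-partition `merge_history`, one input partition is tracked and a
#' point is recorded whenever its cluster count decreases; for a baseline
#' `merge_path` every step is a point.
#'
#' @param x a `merge_history` or `merge_path`.
#' @param truth reference `partition` (or label vector) aligned with the
#'   observations.
#' @param score_kind `"ari"` (default) or `"nmi"`.
#' @param partition for a `merge_history`: index or name of the tracked
#'   input partition (default 1).
#' @return a `merge_curve` data.frame with columns `clusters_remaining` and
#'   `score`, ordered by decreasing cluster count.
#' @export
truth_curve <- function(x, truth, score_kind = c("ari", "nmi"),
                        partition = 1L) {
  score_kind <- match.arg(score_kind)
  truth <- as_partition(truth, name = "truth")
  score <- function(labs, template) {
    q <- partition(labs, unclustered_label = template$unclustered_label)
    tab <- contingency(q, truth)
    if (score_kind == "ari") ari_from_table(tab) else nmi_from_table(tab)
  }
  if (inherits(x, "merge_history")) {
    nms <- vapply(x$initial$partitions, function(p) p$name, character(1))
    r <- if (is.character(partition)) match(partition, nms) else as.integer(partition)
    if (is.na(r) || r < 1 || r > length(nms)) {
      stop("unknown partition: ", partition, call. = FALSE)
    }
    p0 <- x$initial$partitions[[r]]
    if (length(p0$labels) != length(truth$labels)) {
      stop("truth is not aligned with the merged observations", call. = FALSE)
    }
    labs <- p0$labels
    pts <- data.frame(clusters_remaining = n_clusters(p0),
                      score = score(labs, p0))
    if (nrow(x$steps)) {
      for (t in seq_len(nrow(x$steps))) {
        if (x$steps$partition[t] != nms[r]) next
        labs[labs == x$steps$cluster_b[t]] <- x$steps$cluster_a[t]
        kept <- if (is.null(p0$unclustered_label)) labs else
          labs[labs != p0$unclustered_label]
        pts <- rbind(pts, data.frame(
          clusters_remaining = length(unique(kept)),
          score = score(labs, p0)))
      }
    }
  } else if (inherits(x, "merge_path")) {
    p0 <- x$initial
    if (length(p0$labels) != length(truth$labels)) {
      stop("truth is not aligned with the merged observations", call. = FALSE)
    }
    pts <- data.frame(clusters_remaining = n_clusters(p0),
                      score = score(p0$labels, p0))
    for (t in seq_len(nrow(x$steps))) {
      q <- path_state_at(x, t)
      pts <- rbind(pts, data.frame(clusters_remaining = n_clusters(q),
                                   score = score(q$labels, p0)))
    }
  } else {
    stop("x must be a merge_history or merge_path", call. = FALSE)
  }
  structure(pts, score_kind = score_kind, class = c("merge_curve",
                                                    "data.frame"))
}

#' Normalized area under a merge curve
#'
#' Trapezoidal area of the score over the cluster-count axis, with the axis
#' min-max normalized to [0, 1] so that a constant curve of value v has AUC
#' v and AUCs are comparable across paths of different lengths. A
#' single-point curve returns its score. To compare methods whose paths stop
#' at different resolutions, `extend_to` extends the curve horizontally (at
#' its final score) down to the given cluster count before integrating.
#'
#' @param curve a `merge_curve` (or data.frame with `clusters_remaining` and
#'   `score`).
#' @param extend_to optional cluster count (below the curve's minimum) to
#'   extend the final score to.
#' @return AUC in [-1, 1].
#' @export
curve_auc <- function(curve, extend_to = NULL) {
  if (!all(c("clusters_remaining", "score") %in% names(curve))) {
    stop("curve needs clusters_remaining and score columns", call. = FALSE)
  }
  k <- curve$clusters_remaining
  v <- curve$score
  o <- order(k)
  k <- k[o]; v <- v[o]
  if (!is.null(extend_to) && extend_to < min(k)) {
    k <- c(extend_to, k)
    v <- c(v[1], v)  # after sorting, v[1] is the final (smallest-k) score
  }
  if (length(k) == 1) return(v)
  x <- (k - min(k)) / (max(k) - min(k))
  sum(diff(x) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
}

#' Average silhouette width of a partition
#'
#' Mean over observations of the silhouette width
#' \eqn{s(i) = (b_i - a_i) / \max(a_i, b_i)} under Euclidean distance in the
#' given embedding.
#'
#' @param embedding numeric matrix of per-observation coordinates (rows =
#'   observations).
#' @param p a `partition` (or label vector) of the rows; needs at least two
#'   clusters.
#' @return average silhouette width in [-1, 1].
#' @export
avg_silhouette <- function(embedding, p) {
  p <- as_partition(p)
  embedding <- as.matrix(embedding)
  if (nrow(embedding) != length(p$labels)) {
    stop("embedding is not aligned with the partition", call. = FALSE)
  }
  keep <- rep(TRUE, length(p$labels))
  if (!is.null(p$unclustered_label)) keep <- p$labels != p$unclustered_label
  cl <- as.integer(factor(p$labels[keep], levels = p$cluster_ids))
  if (length(unique(cl)) < 2) {
    stop("average silhouette is undefined for a single cluster",
         call. = FALSE)
  }
  sil <- cluster::silhouette(cl, stats::dist(embedding[keep, , drop = FALSE]))
  mean(sil[, "sil_width"])
}

#' Select an output partition by average silhouette
#'
#' Scores every candidate partition by its average silhouette width in the
#' embedding and returns the index of the best one (ties go to the lower
#' index). Single-cluster partitions are excluded with a warning. This is the
#' selection heuristic used after merging; it usually — but not always —
#' picks the best candidate.
#'
#' @param merged a `partition_set` of candidate partitions.
#' @param embedding numeric matrix of per-observation coordinates.
#' @return index of the selected partition.
#' @export
select_output <- function(merged, embedding) {
  stopifnot(inherits(merged, "partition_set"))
  scores <- rep(NA_real_, length(merged$partitions))
  for (r in seq_along(merged$partitions)) {
    p <- merged$partitions[[r]]
    if (n_clusters(p) < 2) {
      warning("partition ", p$name,
              " has a single cluster and is excluded from selection",
              call. = FALSE)
      next
    }
    scores[r] <- avg_silhouette(embedding, p)
  }
  if (all(is.na(scores))) {
    stop("no candidate partition has at least two clusters", call. = FALSE)
  }
  which.max(scores)  # which.max takes the first (lowest index) on ties
}

#' Downsampling robustness experiment
#'
#' For each simulation seed, generates a count dataset, builds the standard
#' trio of over-clusterings, merges by consensus, and scores each merged
#' partition against the truth; then repeats at each downsampling fraction,
#' either re-clustering the subsampled cells (`mode = "before"`) or
#' subsetting the full-data cluster labels before merging
#' (`mode = "after"`). At `fraction = 1` both modes reproduce the baseline
#' run exactly.
#'
#' @param sim_config list of arguments for [simulate_counts()] (the `seed`
#'   element is overridden by `seeds`).
#' @param fractions numeric vector of cell fractions in (0, 1].
#' @param seeds integer vector of simulation seeds.
#' @param mode `"before"` (downsample before clustering) or `"after"`.
#' @param k over-clustering resolution passed to [benchmark_inputs()].
#' @return tidy data.frame with one row per (fraction, input, seed):
#'   columns `fraction, input, seed, mode, ari_after_merge`.
#' @export
run_downsampling_experiment <- function(sim_config = list(), fractions = 1,
                                        seeds = 1L,
                                        mode = c("before", "after"),
                                        k = 40L) {
  mode <- match.arg(mode)
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must be in (0, 1]", call. = FALSE)
  }
  rows <- list()
  for (seed in seeds) {
    cfg <- sim_config
    cfg$seed <- seed
    sim <- do.call(simulate_counts, cfg)
    full_inputs <- benchmark_inputs(sim, k = k, seed = seed)
    for (f in fractions) {
      if (f == 1) {
        sub <- sim
        inputs <- full_inputs
      } else if (mode == "before") {
        sub <- downsample_cells(sim, fraction = f, seed = seed,
                                stratified = TRUE)
        inputs <- benchmark_inputs(sub, k = k, seed = seed)
      } else {
        sub <- downsample_cells(sim, fraction = f, seed = seed,
                                stratified = TRUE)
        idx <- attr(sub, "cell_index")
        inputs <- partition_set(lapply(full_inputs$partitions, function(p) {
          partition(p$labels[idx], name = p$name,
                    unclustered_label = p$unclustered_label)
        }))
      }
      res <- consensus_merge(inputs)
      for (r in seq_along(res$merged$partitions)) {
        p <- res$merged$partitions[[r]]
        rows[[length(rows) + 1L]] <- data.frame(
          fraction = f, input = p$name, seed = seed, mode = mode,
          ari_after_merge = ari_from_table(contingency(p, sub$truth)),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
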