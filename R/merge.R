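# Greedy consensus merging. The engine keeps, for every ordered pair of
# partitions, the current contingency table; a candidate merge of clusters
# (i, j) within partition r collapses two rows of each table involving r, so
# its effect on NMI/ARI is computed from row sums alone, never by re-scanning
# the n observations. Results are contractually bit-identical to full
# recomputation from the raw labels (see tests).

# --- engine state -----------------------------------------------------------

# codes: list of integer label vectors (NA = unclustered sentinel)
# ids:   list of character vectors, code -> original cluster id
# tabs:  tabs[[r]][[s]] (r < s) contingency matrix of codes r x codes s
engine_init <- function(ps, metric) {
  R <- length(ps$partitions)
  codes <- vector("list", R)
  ids <- vector("list", R)
  for (r in seq_len(R)) {
    p <- ps$partitions[[r]]
    f <- factor(p$labels, levels = p$cluster_ids)  # sentinel -> NA
    codes[[r]] <- as.integer(f)
    ids[[r]] <- p$cluster_ids
  }
  tabs <- vector("list", R)
  for (r in seq_len(R)) tabs[[r]] <- vector("list", R)
  for (r in seq_len(R - 1)) {
    for (s in seq(r + 1, R)) {
      tabs[[r]][[s]] <- cross_tab(codes[[r]], length(ids[[r]]),
                                  codes[[s]], length(ids[[s]]))
    }
  }
  val_fun <- if (metric == "nmi") nmi_from_table else ari_from_table
  cur <- matrix(NA_real_, R, R)
  for (r in seq_len(R - 1)) {
    for (s in seq(r + 1, R)) {
      cur[r, s] <- val_fun(tabs[[r]][[s]])
    }
  }
  list(R = R, codes = codes, ids = ids, tabs = tabs, cur = cur,
       metric = metric)
}

cross_tab <- function(c1, k1, c2, k2) {
  keep <- !is.na(c1) & !is.na(c2)
  c1 <- c1[keep]
  c2 <- c2[keep]
  m <- matrix(tabulate((c2 - 1L) * k1 + c1, nbins = k1 * k2), nrow = k1)
  m
}

# get the table between r and s with rows indexed by clusters of r
row_tab <- function(st, r, s) {
  if (r < s) st$tabs[[r]][[s]] else t(st$tabs[[s]][[r]])
}

# Deltas of the pairwise metric for every within-partition candidate merge.
# Returns a k x k matrix (upper triangle filled): entry (i, j) is
# metric(P_r^{i u j}, P_s) - metric(P_r, P_s), where rows of `tab` are the
# clusters of P_r.
pair_deltas <- function(tab, metric, cur_val) {
  k <- nrow(tab)
  out <- matrix(NA_real_, k, k)
  if (k < 2) return(out)
  n <- sum(tab)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (metric == "nmi") {
    plogp <- function(x) ifelse(x > 0, (x / n) * log(x / n), 0)
    h1 <- entropy_counts(rs)
    h2 <- entropy_counts(cs)
    # per-row mutual information contributions
    mirow <- numeric(k)
    for (i in seq_len(k)) {
      row <- tab[i, ]
      nz <- row > 0
      if (rs[i] > 0 && any(nz)) {
        mirow[i] <- sum((row[nz] / n) * log(row[nz] * n / (rs[i] * cs[nz])))
      }
    }
    mi <- sum(mirow)
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        row <- tab[i, ] + tab[j, ]
        rsij <- rs[i] + rs[j]
        nz <- row > 0
        mij <- if (rsij > 0 && any(nz)) {
          sum((row[nz] / n) * log(row[nz] * n / (rsij * cs[nz])))
        } else 0
        mi2 <- mi - mirow[i] - mirow[j] + mij
        h1b <- h1 + plogp(rs[i]) + plogp(rs[j]) - plogp(rsij)
        if (h1b < 1e-12) h1b <- 0
        v <- if (h1b == 0 && h2 == 0) 1
             else if (h1b == 0 || h2 == 0) 0
             else 2 * mi2 / (h1b + h2)
        out[i, j] <- v - cur_val
      }
    }
  } else {
    tot <- n * (n - 1) / 2
    sj <- choose2(as.numeric(cs))
    si <- choose2(as.numeric(rs))
    sij <- choose2(as.numeric(tab))
    c2 <- function(x) x * (x - 1) / 2
    rowpairs <- vapply(seq_len(k), function(i) sum(c2(tab[i, ])), numeric(1))
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        row <- tab[i, ] + tab[j, ]
        sij2 <- sij - rowpairs[i] - rowpairs[j] + sum(c2(row))
        si2 <- si - c2(rs[i]) - c2(rs[j]) + c2(rs[i] + rs[j])
        expected <- si2 * sj / tot
        maximum <- (si2 + sj) / 2
        v <- if (maximum == expected) 1 else (sij2 - expected) / (maximum - expected)
        out[i, j] <- v - cur_val
      }
    }
  }
  out
}

# Sum the per-companion deltas for partition r: k_r x k_r matrix.
partition_deltas <- function(st, r) {
  k <- length(st$ids[[r]])
  total <- matrix(0, k, k)
  for (s in seq_len(st$R)) {
    if (s == r) next
    cur_val <- if (r < s) st$cur[r, s] else st$cur[s, r]
    total <- total + pair_deltas(row_tab(st, r, s), st$metric, cur_val)
  }
  total
}

# Pick the best candidate under the deterministic tie-break: largest delta,
# ties resolved by smallest partition index, then smallest canonical cluster
# pair. deltas is a list of per-partition delta matrices.
argmax_candidate <- function(deltas) {
  best <- NULL
  for (r in seq_along(deltas)) {
    d <- deltas[[r]]
    if (all(is.na(d))) next
    m <- max(d, na.rm = TRUE)
    if (is.null(best) || m > best$delta + 1e-15) {
      idx <- which(d >= m - 1e-15, arr.ind = TRUE)
      # within a partition ties go to the smallest (i, j) pair
      idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
      best <- list(partition = r, i = idx[1, 1], j = idx[1, 2], delta = m)
    }
  }
  best
}

# Apply the merge of codes (i, j), i < j, in partition r: code i survives.
engine_merge <- function(st, r, i, j) {
  val_fun <- if (st$metric == "nmi") nmi_from_table else ari_from_table
  cd <- st$codes[[r]]
  cd[which(cd == j)] <- i
  above <- which(cd > j)
  cd[above] <- cd[above] - 1L
  st$codes[[r]] <- cd
  st$ids[[r]] <- st$ids[[r]][-j]
  for (s in seq_len(st$R)) {
    if (s == r) next
    if (r < s) {
      tab <- st$tabs[[r]][[s]]
      tab[i, ] <- tab[i, ] + tab[j, ]
      tab <- tab[-j, , drop = FALSE]
      st$tabs[[r]][[s]] <- tab
      st$cur[r, s] <- val_fun(tab)
    } else {
      tab <- st$tabs[[s]][[r]]
      tab[, i] <- tab[, i] + tab[, j]
      tab <- tab[, -j, drop = FALSE]
      st$tabs[[s]][[r]] <- tab
      st$cur[s, r] <- val_fun(tab)
    }
  }
  st
}

engine_mean <- function(st) mean(st$cur[upper.tri(st$cur)], na.rm = FALSE)

engine_to_partition_set <- function(st, ps) {
  parts <- lapply(seq_len(st$R), function(r) {
    p <- ps$partitions[[r]]
    labs <- st$ids[[r]][st$codes[[r]]]
    if (!is.null(p$unclustered_label)) {
      labs[is.na(labs)] <- p$unclustered_label
    }
    partition(labs, name = p$name, unclustered_label = p$unclustered_label)
  })
  partition_set(parts, observation_ids = ps$observation_ids)
}

# --- public operations ------------------------------------------------------

#' Agreement change from merging one cluster pair
#'
#' Summed change, over all companion partitions s != r, in the pairwise
#' agreement metric when clusters `i` and `j` of partition `r` are merged:
#' \eqn{\sum_{s \ne r} [m(P_r^{i \cup j}, P_s) - m(P_r, P_s)]}.
#'
#' @param ps a `partition_set`.
#' @param r partition index (1..R).
#' @param i,j distinct cluster ids present in partition `r`.
#' @param metric `"nmi"` or `"ari"`.
#' @return the summed improvement (positive means the merge increases overall
#'   agreement).
#' @export
candidate_delta <- function(ps, r, i, j, metric = c("nmi", "ari")) {
  metric <- match.arg(metric)
  stopifnot(inherits(ps, "partition_set"))
  R <- length(ps$partitions)
  if (!(r %in% seq_len(R))) stop("unknown partition index: ", r, call. = FALSE)
  ids <- ps$partitions[[r]]$cluster_ids
  i <- as.character(i); j <- as.character(j)
  if (!i %in% ids || !j %in% ids) {
    stop("unknown cluster id in partition ", r, call. = FALSE)
  }
  if (i == j) stop("i and j must be distinct clusters", call. = FALSE)
  st <- engine_init(ps, metric)
  ci <- match(i, ids); cj <- match(j, ids)
  a <- min(ci, cj); b <- max(ci, cj)
  total <- 0
  for (s in seq_len(R)) {
    if (s == r) next
    cur_val <- if (r < s) st$cur[r, s] else st$cur[s, r]
    d <- pair_deltas(row_tab(st, r, s), metric, cur_val)
    total <- total + d[a, b]
  }
  total
}

#' Best within-partition merge across a partition set
#'
#' Exhaustively scores all candidate merges — every pair of clusters within
#' every partition — and returns the one with the largest summed improvement
#' in pairwise agreement, or `NULL` when no candidate improves it (the
#' natural stopping point). Ties are broken deterministically: smallest
#' partition index, then smallest cluster pair in canonical order.
#'
#' @inheritParams candidate_delta
#' @return a list with `partition` (index), `cluster_a`, `cluster_b`
#'   (canonical-first id survives as `cluster_a`) and `delta`, or `NULL`.
#' @export
best_merge <- function(ps, metric = c("nmi", "ari")) {
  metric <- match.arg(metric)
  stopifnot(inherits(ps, "partition_set"))
  if (length(ps$partitions) < 2) {
    stop("need at least two partitions", call. = FALSE)
  }
  st <- engine_init(ps, metric)
  deltas <- lapply(seq_len(st$R), function(r) partition_deltas(st, r))
  cand <- argmax_candidate(deltas)
  if (is.null(cand) || cand$delta <= 0) return(NULL)
  list(partition = cand$partition,
       cluster_a = st$ids[[cand$partition]][cand$i],
       cluster_b = st$ids[[cand$partition]][cand$j],
       delta = cand$delta)
}

#' Greedy consensus merging of several partitions
#'
#' Iteratively merges the single pair of clusters, within a single partition,
#' that most increases the mean pairwise agreement (NMI by default) between
#' all partitions, until no merge gives a strictly positive improvement.
#' Because each step is constrained to one pair in one partition, the
#' procedure does not collapse to the trivial all-in-one-cluster optimum; it
#' stops at the resolution where the input clusterings agree.
#'
#' @param ps a `partition_set` (R >= 2 aligned partitions). Label columns,
#'   data.frames, or lists of label vectors are accepted and converted.
#' @param metric merging criterion, `"nmi"` (default) or `"ari"`.
#' @param stop_fraction fraction in [0, 1] of the total achievable agreement
#'   gain at which to stop early; 1 (default) returns the natural stopping
#'   point. The full history is always recorded.
#' @param unclustered_label sentinel for unclustered observations when `ps`
#'   is not already a `partition_set`; sentinel observations never merge.
#' @param verbose print one line per merge step.
#' @return a list with `merged` (the final `partition_set`, possibly sliced
#'   at `stop_fraction`) and `history` (a `merge_history`).
#' @examples
#' ps <- partition_set(list(c("a", "a", "b", "c"), c("x", "x", "y", "y")))
#' res <- consensus_merge(ps)
#' res$history$steps
#' @export
consensus_merge <- function(ps, metric = c("nmi", "ari"), stop_fraction = 1,
                            unclustered_label = "-1", verbose = FALSE) {
  metric <- match.arg(metric)
  if (!inherits(ps, "partition_set")) {
    ps <- partition_set(ps, unclustered_label = unclustered_label)
  }
  if (length(ps$partitions) < 2) {
    stop("need at least two partitions", call. = FALSE)
  }
  if (!is.numeric(stop_fraction) || stop_fraction < 0 || stop_fraction > 1) {
    stop("stop_fraction must be in [0, 1]", call. = FALSE)
  }
  st <- engine_init(ps, metric)
  initial_mean <- engine_mean(st)
  nms <- vapply(ps$partitions, function(p) p$name, character(1))
  steps <- list()
  # per-partition delta matrices; only those involving the merged partition
  # change between steps, but with the summed-over-companions layout every
  # partition has a term involving r*, so all are refreshed from cached tables
  repeat {
    deltas <- lapply(seq_len(st$R), function(r) partition_deltas(st, r))
    cand <- argmax_candidate(deltas)
    if (is.null(cand) || cand$delta <= 0) break
    r <- cand$partition
    id_a <- st$ids[[r]][cand$i]
    id_b <- st$ids[[r]][cand$j]
    st <- engine_merge(st, r, cand$i, cand$j)
    m <- engine_mean(st)
    steps[[length(steps) + 1L]] <- data.frame(
      step = length(steps) + 1L, partition = nms[r],
      cluster_a = id_a, cluster_b = id_b,
      delta = cand$delta, mean_nmi_after = m,
      stringsAsFactors = FALSE)
    if (verbose) {
      message(sprintf("step %d: merge (%s, %s) in %s; mean %s = %.4f",
                      length(steps), id_a, id_b, nms[r], metric, m))
    }
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(step = integer(), partition = character(),
               cluster_a = character(), cluster_b = character(),
               delta = numeric(), mean_nmi_after = numeric(),
               stringsAsFactors = FALSE)
  history <- structure(
    list(initial = ps, steps = steps, metric = metric,
         initial_mean = initial_mean),
    class = "merge_history")
  merged <- if (stop_fraction < 1) slice_at_fraction(history, stop_fraction)
            else engine_to_partition_set(st, ps)
  list(merged = merged, history = history)
}

#' @export
print.merge_history <- function(x, ...) {
  cat(sprintf(
    "<merge_history: %d steps, metric %s, mean %.4f -> %.4f>\n",
    nrow(x$steps), x$metric, x$initial_mean,
    if (nrow(x$steps)) x$steps$mean_nmi_after[nrow(x$steps)] else x$initial_mean))
  invisible(x)
}

#' Partition set after replaying part of a merge history
#'
#' @param history a `merge_history`.
#' @param step number of merges to replay; 0 gives the initial partitions,
#'   `nrow(history$steps)` the final merged set.
#' @return a `partition_set`.
#' @export
state_at <- function(history, step) {
  stopifnot(inherits(history, "merge_history"))
  nsteps <- nrow(history$steps)
  if (!is.numeric(step) || step < 0 || step > nsteps) {
    stop("step must be between 0 and ", nsteps, call. = FALSE)
  }
  ps <- history$initial
  labs <- lapply(ps$partitions, function(p) p$labels)
  nms <- vapply(ps$partitions, function(p) p$name, character(1))
  if (step >= 1) {
    for (t in seq_len(step)) {
      r <- match(history$steps$partition[t], nms)
      b <- history$steps$cluster_b[t]
      a <- history$steps$cluster_a[t]
      labs[[r]][labs[[r]] == b] <- a
    }
  }
  parts <- lapply(seq_along(labs), function(r) {
    partition(labs[[r]], name = nms[r],
              unclustered_label = ps$partitions[[r]]$unclustered_label)
  })
  partition_set(parts, observation_ids = ps$observation_ids)
}

#' Partial merging at a fraction of the total agreement gain
#'
#' Returns the earliest recorded state whose cumulative gain in mean pairwise
#' agreement reaches at least `m` times the total gain at the natural
#' stopping point; `m = 0` gives the initial partitions, `m = 1` the final
#' ones.
#'
#' @param history a `merge_history`.
#' @param m fraction in [0, 1].
#' @return a `partition_set`.
#' @export
slice_at_fraction <- function(history, m) {
  stopifnot(inherits(history, "merge_history"))
  if (!is.numeric(m) || m < 0 || m > 1) {
    stop("m must be in [0, 1]", call. = FALSE)
  }
  nsteps <- nrow(history$steps)
  if (nsteps == 0 || m == 0) return(state_at(history, 0))
  total <- history$steps$mean_nmi_after[nsteps] - history$initial_mean
  if (total <= 0) return(state_at(history, 0))
  gain <- (history$steps$mean_nmi_after - history$initial_mean) / total
  step <- which(gain >= m - 1e-12)[1]
  state_at(history, step)
}

#' Write a merge history to CSV
#'
#' Columns `step, partition, cluster_a, cluster_b, delta, mean_nmi_after`
#' (contractual names).
#'
#' @param history a `merge_history`.
#' @param path output file path.
#' @export
write_history <- function(history, path) {
  stopifnot(inherits(history, "merge_history"))
  utils::write.csv(history$steps, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
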