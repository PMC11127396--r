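# Pairwise agreement measures between partitions. All measures exclude
# observations carrying the unclustered sentinel of either partition, and all
# entropies are in nats (the NMI, a ratio, is base-invariant).

entropy_counts <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  -sum(p * log(p))
}

nmi_from_table <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(NA_real_)
  rs <- rowSums(tab)
  cs <- colSums(tab)
  h1 <- entropy_counts(rs)
  h2 <- entropy_counts(cs)
  # degenerate denominators: two single-cluster partitions are identical (1);
  # a single-cluster partition carries no mutual information about any other (0)
  if (h1 == 0 && h2 == 0) return(1)
  if (h1 == 0 || h2 == 0) return(0)
  nz <- which(tab > 0)
  i <- ((nz - 1L) %% nrow(tab)) + 1L
  j <- ((nz - 1L) %/% nrow(tab)) + 1L
  mi <- sum((tab[nz] / n) * log(tab[nz] * n / (rs[i] * cs[j])))
  2 * mi / (h1 + h2)
}

choose2 <- function(x) sum(x * (x - 1)) / 2

ari_from_table <- function(tab) {
  n <- sum(tab)
  if (n < 2) return(NA_real_)
  sij <- choose2(as.numeric(tab))
  si <- choose2(as.numeric(rowSums(tab)))
  sj <- choose2(as.numeric(colSums(tab)))
  tot <- n * (n - 1) / 2
  expected <- si * sj / tot
  maximum <- (si + sj) / 2
  if (maximum == expected) return(1)  # both partitions degenerate and equal
  (sij - expected) / (maximum - expected)
}

# Indices of observations clustered (non-sentinel) in both partitions.
shared_clustered <- function(p1, p2) {
  keep <- rep(TRUE, length(p1$labels))
  if (!is.null(p1$unclustered_label)) {
    keep <- keep & p1$labels != p1$unclustered_label
  }
  if (!is.null(p2$unclustered_label)) {
    keep <- keep & p2$labels != p2$unclustered_label
  }
  keep
}

check_aligned <- function(p1, p2) {
  if (length(p1$labels) != length(p2$labels)) {
    stop("partitions have different numbers of observations", call. = FALSE)
  }
}

#' Contingency table of two partitions
#'
#' Cross-tabulates two aligned partitions: entry (i, j) counts the
#' observations in cluster i of `p1` and cluster j of `p2`. Observations
#' flagged as unclustered in either partition are excluded. Rows and columns
#' follow the canonical (first appearance) cluster order of each partition.
#'
#' @param p1,p2 `partition` objects (or label vectors) over the same
#'   observations.
#' @return an integer matrix with cluster ids as dimnames; row sums are the
#'   cluster sizes of `p1`, column sums those of `p2`, and the grand total is
#'   the number of jointly clustered observations.
#' @examples
#' contingency(c("a", "a", "b", "b"), c("x", "y", "x", "y"))
#' @export
contingency <- function(p1, p2) {
  p1 <- as_partition(p1)
  p2 <- as_partition(p2)
  check_aligned(p1, p2)
  keep <- shared_clustered(p1, p2)
  f1 <- factor(p1$labels[keep], levels = p1$cluster_ids)
  f2 <- factor(p2$labels[keep], levels = p2$cluster_ids)
  tab <- table(f1, f2, dnn = NULL)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(p1$cluster_ids, p2$cluster_ids))
  m
}

#' Entropy of a partition
#'
#' Shannon entropy, in nats, of the cluster-membership distribution:
#' \eqn{H(P) = -\sum_c (n_c/n) \log(n_c/n)}. Unclustered observations are
#' excluded. A single-cluster partition has entropy 0; for fixed k the
#' entropy is maximized, at \eqn{\log k}, by balanced clusters.
#'
#' @param p a `partition` or label vector.
#' @return non-negative entropy in nats.
#' @examples
#' partition_entropy(c("a", "a", "b", "b"))  # log(2)
#' @export
partition_entropy <- function(p) {
  p <- as_partition(p)
  labs <- p$labels
  if (!is.null(p$unclustered_label)) {
    labs <- labs[labs != p$unclustered_label]
  }
  entropy_counts(tabulate(factor(labs, levels = p$cluster_ids)))
}

#' Normalized mutual information between two partitions
#'
#' \deqn{NMI(P_1, P_2) = \frac{2 (H(P_2) - H(P_2 | P_1))}{H(P_1) + H(P_2)}}
#' where H is the entropy function and the conditional entropy comes from the
#' contingency table; the numerator equals twice the mutual information, so
#' the measure is symmetric. It is 1 iff the partitions are identical up to
#' relabeling and 0 when they are independent. By convention two
#' single-cluster partitions have NMI 1 (they are identical) and a
#' single-cluster partition has NMI 0 with any non-trivial partition (zero
#' mutual information).
#'
#' @param p1,p2 `partition` objects (or label vectors) over the same
#'   observations.
#' @return NMI in [0, 1].
#' @examples
#' nmi(c(1, 1, 2, 2), c(1, 1, 2, 2))  # 1
#' nmi(c("a", "a", "b", "b"), c("x", "y", "x", "y"))  # 0
#' @export
nmi <- function(p1, p2) {
  nmi_from_table(contingency(p1, p2))
}

#' Adjusted Rand index between two partitions
#'
#' The Hubert--Arabie chance-corrected pair-counting agreement, computed from
#' the contingency table. It is 1 iff the partitions are identical up to
#' relabeling and has expectation 0 under random, independent labelings.
#'
#' @param p1,p2 `partition` objects (or label vectors) over the same
#'   observations.
#' @return ARI in (-1, 1].
#' @examples
#' ari(c("a", "a", "b", "b"), c("x", "y", "x", "y"))  # -0.5
#' @export
ari <- function(p1, p2) {
  tab <- contingency(p1, p2)
  if (sum(tab) < 2) {
    stop("ARI needs at least two jointly clustered observations",
         call. = FALSE)
  }
  ari_from_table(tab)
}

#' Jaccard index of two clusters from two partitions
#'
#' Cardinality of the intersection of the two clusters over the cardinality
#' of their union.
#'
#' @param p1,p2 `partition` objects (or label vectors) over the same
#'   observations.
#' @param i cluster id in `p1`.
#' @param j cluster id in `p2`.
#' @return Jaccard index in [0, 1].
#' @examples
#' jaccard_index(c("a", "a", "a", "b"), c("x", "x", "y", "y"), "a", "x")
#' @export
jaccard_index <- function(p1, p2, i, j) {
  p1 <- as_partition(p1)
  p2 <- as_partition(p2)
  check_aligned(p1, p2)
  i <- as.character(i)
  j <- as.character(j)
  if (!i %in% p1$cluster_ids) stop("unknown cluster id: ", i, call. = FALSE)
  if (!j %in% p2$cluster_ids) stop("unknown cluster id: ", j, call. = FALSE)
  in_i <- p1$labels == i
  in_j <- p2$labels == j
  sum(in_i & in_j) / sum(in_i | in_j)
}

#' Mean pairwise NMI of a partition set
#'
#' Average NMI over all R(R-1)/2 unordered pairs of partitions — the
#' objective that consensus merging greedily maximizes.
#'
#' @param ps a `partition_set` with at least two partitions.
#' @param metric agreement measure, `"nmi"` (default) or `"ari"`.
#' @return mean pairwise agreement.
#' @export
mean_pairwise_nmi <- function(ps, metric = c("nmi", "ari")) {
  metric <- match.arg(metric)
  stopifnot(inherits(ps, "partition_set"))
  R <- length(ps$partitions)
  if (R < 2) stop("need at least two partitions", call. = FALSE)
  f <- if (metric == "nmi") nmi_from_table else ari_from_table
  vals <- c()
  for (r in seq_len(R - 1)) {
    for (s in seq(r + 1, R)) {
      vals <- c(vals, f(contingency(ps$partitions[[r]], ps$partitions[[s]])))
    }
  }
  mean(vals)
}
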