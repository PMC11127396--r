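# Small deterministic count fixture: three groups with controllable shifts.
make_counts <- function(n_per = c(10, 10, 10), n_genes = 60, shift_frac = 0,
                        fold = 1, seed = 1) {
  withr::with_seed(seed, {
    n <- sum(n_per)
    base <- rgamma(n_genes, shape = 2, rate = 0.5)
    groups <- rep(seq_along(n_per), n_per)
    mu <- matrix(base, n_genes, n)
    if (shift_frac > 0) {
      shifted <- seq_len(round(shift_frac * n_genes))
      mu[shifted, groups == length(n_per)] <-
        mu[shifted, groups == length(n_per)] * fold
    }
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 2), n_genes, n,
                     dimnames = list(sprintf("g%d", 1:n_genes),
                                     sprintf("c%d", 1:n)))
    list(counts = counts, labels = paste0("cl", groups))
  })
}

test_that("cluster medoids are gene-wise medians of log1p counts", {
  x <- matrix(c(0, exp(1) - 1, exp(2) - 1), nrow = 1,
              dimnames = list("g1", c("c1", "c2", "c3")))
  m <- cluster_medoids(x, c("a", "a", "a"))
  expect_equal(m["g1", "a"], 1)
  # a single-cell cluster is its own log1p profile
  x2 <- matrix(c(3, 8), nrow = 2, dimnames = list(c("g1", "g2"), "c1"))
  expect_equal(unname(cluster_medoids(x2, "solo")[, 1]), log1p(c(3, 8)))
  # random matrix against a naive sort-and-pick oracle
  set.seed(9)
  x3 <- matrix(rpois(20 * 30, 5), 20, 30)
  p <- random_labels(30, 3)
  m3 <- cluster_medoids(x3, p)
  for (id in unique(p)) {
    for (g in 1:20) {
      v <- sort(log1p(x3[g, p == id]))
      n <- length(v)
      naive <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
      expect_equal(unname(m3[g, id]), naive)
    }
  }
})

test_that("medoid trees join the closest clusters first", {
  med <- matrix(c(0, 1, 10), nrow = 1,
                dimnames = list("g1", c("a", "b", "c")))
  tree <- build_tree(med)
  first <- sort(tree$hclust$labels[-tree$hclust$merge[1, ]])
  expect_equal(first, c("a", "b"))
  expect_error(build_tree(med[, 1, drop = FALSE]), "at least two")
  # heights are non-decreasing on random medoid sets
  set.seed(13)
  for (rep in 1:20) {
    m <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(NULL, letters[1:6]))
    expect_true(all(diff(build_tree(m)$hclust$height) >= -1e-12))
  }
})

test_that("dist_merge walks the tree bottom-up and can reach one cluster", {
  fx <- make_counts(seed = 2)
  p <- partition(fx$labels, unclustered_label = NULL)
  path0 <- dist_merge(fx$counts, p, n_merges = 0)
  expect_equal(nrow(path0$steps), 0L)
  expect_equal(path_state_at(path0, 0)$labels, fx$labels)
  full <- dist_merge(fx$counts, p)
  expect_equal(nrow(full$steps), 2L)
  expect_equal(n_clusters(path_state_at(full, 2)), 1L)
  expect_error(dist_merge(fx$counts, p, n_merges = 5), "between 0 and")
  # 1-D toy: clusters with medoid profiles {0, 1, 10} merge {0,1} first
  x <- matrix(expm1(c(0, 0, 1, 1, 10, 10)), nrow = 1,
              dimnames = list("g1", sprintf("c%d", 1:6)))
  p2 <- partition(c("a", "a", "b", "b", "c", "c"), unclustered_label = NULL)
  toy <- dist_merge(x, p2, n_merges = 1)
  expect_equal(sort(c(toy$steps$cluster_a, toy$steps$cluster_b)),
               c("a", "b"))
})

test_that("dist_merge order is invariant to relabeling and cell order", {
  fx <- make_counts(n_per = c(8, 8, 8, 8), shift_frac = 0.3, fold = 4,
                    seed = 5)
  p <- partition(fx$labels, unclustered_label = NULL)
  path1 <- dist_merge(fx$counts, p)
  # permute cells
  perm <- withr::with_seed(8, sample(ncol(fx$counts)))
  path2 <- dist_merge(fx$counts[, perm], partition(fx$labels[perm],
                                                   unclustered_label = NULL))
  expect_equal(path1$steps$height, path2$steps$height)
  # same sequence of states up to cluster relabeling
  inv <- order(perm)
  for (t in seq_len(nrow(path1$steps))) {
    expect_equal(ari(path_state_at(path1, t)$labels,
                     path_state_at(path2, t)$labels[inv]), 1)
  }
})

test_that("DE fraction detects shifted genes and not exchangeable splits", {
  # half the genes shifted 8-fold in group 3
  fx <- make_counts(n_per = c(50, 50), n_genes = 500, shift_frac = 0.5,
                    fold = 8, seed = 21)
  frac <- de_fraction(fx$counts, fx$labels == "cl1", fx$labels == "cl2")
  expect_gt(frac, 0.4)
  expect_lt(frac, 0.6)
  # a cluster split at random against itself
  fx0 <- make_counts(n_per = c(60, 0), n_genes = 300, seed = 22)
  split <- withr::with_seed(23, sample(rep(c(TRUE, FALSE), 30)))
  expect_lt(de_fraction(fx0$counts, split, !split), 0.02)
})

test_that("de_merge joins indistinguishable groups first and honors alpha", {
  # groups 1 and 2 identical, group 3 with 30% strongly DE genes
  fx <- make_counts(n_per = c(25, 25, 25), n_genes = 400, shift_frac = 0.3,
                    fold = 8, seed = 31)
  p <- partition(fx$labels, unclustered_label = NULL)
  res <- de_merge(fx$counts, p, alpha = 0.05)
  expect_equal(nrow(res$steps), 1L)
  expect_equal(sort(c(res$steps$cluster_a, res$steps$cluster_b)),
               c("cl1", "cl2"))
  # alpha = 0: nothing can be below the threshold
  expect_equal(nrow(de_merge(fx$counts, p, alpha = 0)$steps), 0L)
  # exhaustive mode continues to a single cluster in exactly k - 1 steps
  exh <- de_merge(fx$counts, p, exhaustive = TRUE)
  expect_equal(nrow(exh$steps), 2L)
  expect_equal(n_clusters(path_state_at(exh, 2)), 1L)
  expect_error(de_merge(fx$counts, p, alpha = 2), "alpha")
})

test_that("baseline paths are coarsenings of the input partition", {
  fx <- make_counts(n_per = c(10, 10, 10, 10), shift_frac = 0.4, fold = 6,
                    seed = 41)
  p <- partition(fx$labels, unclustered_label = NULL)
  for (path in list(dist_merge(fx$counts, p),
                    de_merge(fx$counts, p, exhaustive = TRUE))) {
    for (t in seq_len(nrow(path$steps))) {
      tab <- table(fx$labels, path_state_at(path, t)$labels)
      expect_true(all(rowSums(tab > 0) == 1))
    }
  }
})

test_that("dist_merge records mean NMI against companions and its argmax", {
  fx <- make_counts(n_per = c(12, 12, 12), shift_frac = 0.4, fold = 6,
                    seed = 51)
  p <- partition(fx$labels, unclustered_label = NULL)
  comp <- partition_set(list(partition(fx$labels, name = "other",
                                       unclustered_label = NULL)))
  path <- dist_merge(fx$counts, p, companions = comp)
  expect_false(any(is.na(path$steps$mean_nmi)))
  expect_equal(path$best_step, which.max(path$steps$mean_nmi))
  for (t in seq_len(nrow(path$steps))) {
    expect_equal(path$steps$mean_nmi[t],
                 nmi(path_state_at(path, t), comp$partitions[[1]]),
                 tolerance = 1e-12)
  }
})
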