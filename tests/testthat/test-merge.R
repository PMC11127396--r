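toy_set <- function() {
  partition_set(list(c("a", "a", "b", "c"), c("x", "x", "y", "y")))
}

test_that("candidate_delta matches direct recomputation from raw labels", {
  ps <- toy_set()
  expected <- 1 - bf_nmi(c("a", "a", "b", "c"), c("x", "x", "y", "y"))
  expect_equal(candidate_delta(ps, 1, "b", "c"), expected, tolerance = 1e-12)
  expect_gt(expected, 0)
  # merging anything in identical partitions destroys perfect agreement
  same <- partition_set(list(c("a", "a", "b", "b", "c"),
                             c("x", "x", "y", "y", "z")))
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    expect_lt(candidate_delta(same, 1, pair[1], pair[2]), 0)
  }
  expect_error(candidate_delta(ps, 1, "b", "zzz"), "unknown cluster")
  expect_error(candidate_delta(ps, 7, "b", "c"), "unknown partition")
})

test_that("incremental deltas equal brute force on random instances", {
  set.seed(23)
  for (rep in 1:8) {
    labs <- random_partition_set(100, 3, 6)
    ps <- partition_set(labs)
    base <- bf_mean_metric(labs)
    for (cand in 1:25) {
      r <- sample(3, 1)
      ids <- unique(labs[[r]])
      pr <- sample(ids, 2)
      merged <- labs
      merged[[r]][merged[[r]] == pr[2]] <- pr[1]
      # summed pairwise delta = mean delta * number of pairs
      expected <- (bf_mean_metric(merged) - base) * 3
      expect_equal(candidate_delta(ps, r, pr[1], pr[2]), expected,
                   tolerance = 1e-12)
    }
  }
})

test_that("best_merge returns the exhaustive argmax or NULL at the stop", {
  expect_equal(best_merge(toy_set())[c("partition", "cluster_a", "cluster_b")],
               list(partition = 1L, cluster_a = "b", cluster_b = "c"))
  same <- partition_set(list(c("a", "a", "b"), c("x", "x", "y")))
  expect_null(best_merge(same))
  expect_error(best_merge(partition_set(list(c("a", "b")))), "at least two")
})

test_that("consensus merging on the toy instance stops after one step", {
  res <- consensus_merge(toy_set())
  expect_equal(nrow(res$history$steps), 1L)
  expect_equal(res$history$steps$mean_nmi_after, 1)
  expect_equal(vapply(res$merged$partitions, n_clusters, integer(1)),
               c(2L, 2L))
  # exhaustive check: no further merge has positive delta
  expect_null(best_merge(res$merged))
})

test_that("identical inputs are returned unchanged with an empty history", {
  labs <- c("a", "a", "b", "b", "c")
  res <- consensus_merge(partition_set(list(labs, labs, labs)))
  expect_equal(nrow(res$history$steps), 0L)
  expect_equal(res$merged$partitions[[1]]$labels, labs)
})

test_that("greedy sequence equals an independent brute-force implementation", {
  set.seed(31)
  for (rep in 1:20) {
    labs <- random_partition_set(sample(20:60, 1), 3, 6)
    ps <- partition_set(labs)
    res <- consensus_merge(ps)
    oracle <- bf_greedy(labs)
    expect_equal(nrow(res$history$steps), length(oracle$steps))
    if (length(oracle$steps)) {
      got <- res$history$steps
      for (t in seq_along(oracle$steps)) {
        expect_equal(match(got$partition[t], c("P1", "P2", "P3")),
                     as.integer(oracle$steps[[t]][1]))
        expect_equal(got$cluster_a[t], oracle$steps[[t]][2])
        expect_equal(got$cluster_b[t], oracle$steps[[t]][3])
      }
    }
    # final labelings identical
    for (r in 1:3) {
      expect_equal(res$merged$partitions[[r]]$labels, oracle$labels[[r]])
    }
    # never the naive all-in-one-cluster optimum
    expect_true(all(vapply(res$merged$partitions, n_clusters,
                           integer(1)) > 1))
  }
})

test_that("mean agreement increases strictly and one pair merges per step", {
  set.seed(41)
  labs <- random_partition_set(80, 3, 6)
  res <- consensus_merge(partition_set(labs))
  h <- res$history$steps
  if (nrow(h)) {
    expect_true(all(h$delta > 0))
    expect_true(all(diff(c(res$history$initial_mean, h$mean_nmi_after)) > 0))
    ks <- vapply(0:nrow(h), function(t) {
      sum(vapply(state_at(res$history, t)$partitions, n_clusters,
                 integer(1)))
    }, integer(1))
    expect_equal(diff(ks), rep(-1L, nrow(h)))
  }
})

test_that("every output cluster is a union of input clusters", {
  set.seed(43)
  labs <- random_partition_set(70, 3, 6)
  res <- consensus_merge(partition_set(labs))
  for (r in 1:3) {
    tab <- table(labs[[r]], res$merged$partitions[[r]]$labels)
    # each input cluster maps to exactly one output cluster
    expect_true(all(rowSums(tab > 0) == 1))
  }
})

test_that("merging is invariant to consistent relabeling and reordering", {
  set.seed(47)
  labs <- random_partition_set(50, 3, 5)
  res1 <- consensus_merge(partition_set(labs))
  # relabel clusters of partition 2 (bijectively), preserving first-appearance
  # canonical order so the tie-break contract is comparable
  ids <- unique(labs[[2]])
  map <- setNames(paste0("z", seq_along(ids)), ids)
  labs2 <- labs
  labs2[[2]] <- unname(map[labs[[2]]])
  res2 <- consensus_merge(partition_set(labs2))
  expect_equal(nrow(res1$history$steps), nrow(res2$history$steps))
  expect_equal(res1$history$steps$mean_nmi_after,
               res2$history$steps$mean_nmi_after, tolerance = 1e-12)
  for (r in 1:3) {
    expect_equal(ari(res1$merged$partitions[[r]],
                     res2$merged$partitions[[r]]), 1)
  }
  # reorder observations consistently across partitions
  perm <- sample(50)
  res3 <- consensus_merge(partition_set(lapply(labs, `[`, perm)))
  expect_equal(res3$history$steps$mean_nmi_after,
               res1$history$steps$mean_nmi_after, tolerance = 1e-12)
})

test_that("state_at replays the history consistently", {
  set.seed(53)
  labs <- random_partition_set(60, 3, 6)
  res <- consensus_merge(partition_set(labs))
  h <- res$history
  expect_equal(state_at(h, 0)$partitions[[1]]$labels, labs[[1]])
  final <- state_at(h, nrow(h$steps))
  for (r in 1:3) {
    expect_equal(final$partitions[[r]]$labels,
                 res$merged$partitions[[r]]$labels)
  }
  for (t in seq_len(nrow(h$steps))) {
    expect_equal(mean_pairwise_nmi(state_at(h, t)), h$steps$mean_nmi_after[t],
                 tolerance = 1e-12)
  }
  expect_error(state_at(h, nrow(h$steps) + 1), "between 0 and")
})

test_that("slice_at_fraction returns the earliest state reaching the gain", {
  set.seed(59)
  labs <- random_partition_set(60, 3, 6)
  res <- consensus_merge(partition_set(labs))
  h <- res$history
  expect_equal(slice_at_fraction(h, 0)$partitions[[1]]$labels, labs[[1]])
  expect_equal(slice_at_fraction(h, 1)$partitions[[1]]$labels,
               res$merged$partitions[[1]]$labels)
  if (nrow(h$steps) >= 2) {
    m <- 0.5
    gain <- (h$steps$mean_nmi_after - h$initial_mean) /
      (h$steps$mean_nmi_after[nrow(h$steps)] - h$initial_mean)
    first <- which(gain >= m)[1]
    got <- slice_at_fraction(h, m)
    expect_equal(got$partitions[[1]]$labels,
                 state_at(h, first)$partitions[[1]]$labels)
  }
  expect_error(slice_at_fraction(h, 1.5), "0, 1")
  # stop_fraction plumbed through consensus_merge
  res0 <- consensus_merge(partition_set(labs), stop_fraction = 0)
  expect_equal(res0$merged$partitions[[2]]$labels, labs[[2]])
})

test_that("sentinel-labeled observations are never merged or counted", {
  a <- c("a", "a", "b", "b", "c", "-1", "-1")
  b <- c("x", "x", "x", "y", "y", "y", "-1")
  res <- consensus_merge(partition_set(list(a, b)))
  for (p in res$merged$partitions) {
    expect_false("-1" %in% p$cluster_ids)
  }
  expect_equal(res$merged$partitions[[1]]$labels[6:7], c("-1", "-1"))
  h <- res$history$steps
  expect_false(any(h$cluster_a == "-1" | h$cluster_b == "-1"))
})

test_that("ARI works as the merging criterion", {
  ps <- toy_set()
  res <- consensus_merge(ps, metric = "ari")
  expect_equal(res$history$steps$mean_nmi_after, 1)
  expect_equal(vapply(res$merged$partitions, n_clusters, integer(1)),
               c(2L, 2L))
  set.seed(61)
  labs <- random_partition_set(60, 3, 5)
  res <- consensus_merge(partition_set(labs), metric = "ari")
  oracle <- bf_greedy(labs, metric = "ari")
  for (r in 1:3) {
    expect_equal(res$merged$partitions[[r]]$labels, oracle$labels[[r]])
  }
})

test_that("merge histories serialize with the contractual columns", {
  res <- consensus_merge(toy_set())
  f <- withr::local_tempfile(fileext = ".csv")
  write_history(res$history, f)
  got <- read.csv(f, colClasses = c(partition = "character",
                                    cluster_a = "character",
                                    cluster_b = "character"))
  expect_equal(names(got), c("step", "partition", "cluster_a", "cluster_b",
                             "delta", "mean_nmi_after"))
  expect_equal(got$cluster_a, "b")
})
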