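# Independent brute-force oracles, deliberately written against the raw
# labels (base::table + direct formulas) rather than the package's cached
# incremental machinery.

bf_nmi <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  H <- function(x) {
    p <- x[x > 0] / n
    -sum(p * log(p))
  }
  h1 <- H(rowSums(tab))
  h2 <- H(colSums(tab))
  if (h1 == 0 && h2 == 0) return(1)
  if (h1 == 0 || h2 == 0) return(0)
  pij <- tab / n
  pi_ <- rowSums(tab) / n
  pj_ <- colSums(tab) / n
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      if (tab[i, j] > 0) mi <- mi + pij[i, j] * log(pij[i, j] / (pi_[i] * pj_[j]))
    }
  }
  unname(2 * mi / (h1 + h2))
}

bf_mean_metric <- function(labs, metric = "nmi") {
  R <- length(labs)
  f <- if (metric == "nmi") bf_nmi else
    function(a, b) mclust::adjustedRandIndex(a, b)
  vals <- c()
  for (r in seq_len(R - 1)) {
    for (s in seq(r + 1, R)) vals <- c(vals, f(labs[[r]], labs[[s]]))
  }
  mean(vals)
}

# one full greedy pass, re-tabulating everything from raw labels each step;
# same tie-break contract (smallest partition, then smallest first-appearance
# cluster pair)
bf_greedy <- function(labs, metric = "nmi") {
  steps <- list()
  repeat {
    base <- bf_mean_metric(labs, metric)
    R <- length(labs)
    best <- list(delta = 0)
    for (r in seq_len(R)) {
      ids <- unique(labs[[r]])
      if (length(ids) < 2) next
      for (i in seq_len(length(ids) - 1)) {
        for (j in seq(i + 1, length(ids))) {
          cand <- labs
          cand[[r]][cand[[r]] == ids[j]] <- ids[i]
          d <- bf_mean_metric(cand, metric) - base
          # mean delta * C(R,2) equals the summed pairwise delta up to a
          # constant factor, so argmax and sign agree with the package
          if (d > best$delta + 1e-13) {
            best <- list(delta = d, r = r, a = ids[i], b = ids[j])
          }
        }
      }
    }
    if (best$delta <= 1e-13) break
    labs[[best$r]][labs[[best$r]] == best$b] <- best$a
    steps[[length(steps) + 1L]] <- c(best$r, best$a, best$b)
  }
  list(labels = labs, steps = steps)
}

random_labels <- function(n, k) {
  # guarantee every cluster non-empty
  paste0("k", c(seq_len(k), sample(seq_len(k), n - k, replace = TRUE)))
}

random_partition_set <- function(n, R, kmax) {
  ks <- sample(2:kmax, R, replace = TRUE)
  lapply(ks, function(k) random_labels(n, k))
}
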