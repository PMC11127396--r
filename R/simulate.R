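# Synthetic data generators: a 2-D Gaussian-grid mixture and a
# Splatter-style hierarchical negative binomial count simulator
# (gene base means -> per-group fold changes -> per-cell library factors ->
# Poisson-Gamma counts). Both are bit-reproducible given (config, seed).

new_sim_result <- function(data, truth, config, type) {
  structure(list(data = data, truth = truth, config = config, type = type),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  dims <- if (x$type == "counts") {
    sprintf("%d genes x %d cells", nrow(x$data), ncol(x$data))
  } else {
    sprintf("%d points x %d dims", nrow(x$data), ncol(x$data))
  }
  cat(sprintf("<sim_result (%s): %s, %d groups>\n", x$type, dims,
              n_clusters(x$truth)))
  invisible(x)
}

#' Simulate a grid of bivariate normal components
#'
#' Isotropic, unit-variance bivariate normal components with centers arranged
#' on a regular grid (default 3 x 3, 100 points per component, centers
#' spaced 5 standard deviations apart) — a low-dimensional testbed where the
#' true group structure is unambiguous and over-clusterings have clear
#' redundant clusters to merge away.
#'
#' @param rows,cols grid dimensions.
#' @param points_per_component points drawn from each component.
#' @param spacing distance between neighboring centers, in sd units.
#' @param seed RNG seed.
#' @return a `sim_result` with `data` (n x 2 coordinate matrix) and `truth`
#'   (a `partition` with one label per component).
#' @export
simulate_gauss_grid <- function(rows = 3L, cols = 3L,
                                points_per_component = 100L, spacing = 5,
                                seed = 1L) {
  if (rows < 1 || cols < 1 || points_per_component < 1 || spacing <= 0) {
    stop("invalid grid configuration", call. = FALSE)
  }
  centers <- expand.grid(x = spacing * seq_len(cols),
                         y = spacing * seq_len(rows))
  G <- nrow(centers)
  n <- G * points_per_component
  coords <- withr::with_seed(seed, {
    matrix(stats::rnorm(2 * n), ncol = 2) +
      as.matrix(centers)[rep(seq_len(G), each = points_per_component), ]
  })
  colnames(coords) <- c("x", "y")
  rownames(coords) <- sprintf("p%d", seq_len(n))
  truth <- partition(rep(sprintf("g%d", seq_len(G)),
                         each = points_per_component),
                     name = "truth", unclustered_label = NULL)
  new_sim_result(coords, truth,
                 list(rows = rows, cols = cols,
                      points_per_component = points_per_component,
                      spacing = spacing, seed = seed),
                 "coordinates")
}

group_sizes <- function(n, props) {
  G <- length(props)
  sizes <- pmax(1L, floor(props * n))
  while (sum(sizes) > n) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  while (sum(sizes) < n) {
    deficit <- props * n - sizes
    i <- which.max(deficit)
    sizes[i] <- sizes[i] + 1L
  }
  sizes
}

#' Simulate grouped negative binomial count data
#'
#' Hierarchical count model in the Splatter family: gene base means are drawn
#' from a Gamma distribution; each group applies log-normal fold changes to a
#' random `de_prob` fraction of genes; each cell carries a log-normal library
#' size factor; counts are negative binomial around the resulting means.
#' Increasing `de_prob` or `de_fc_sigma` increases the separation between
#' groups. Defaults match the benchmark regime used throughout the package:
#' 5000 cells, 10,000 genes, 30 well-separated groups.
#'
#' @param n_cells,n_genes,n_groups dataset dimensions.
#' @param de_prob per-gene probability of group-specific differential
#'   expression.
#' @param de_fc_sigma sd of the log fold changes of DE genes.
#' @param libsize_sigma sd of the log cell library-size factors.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param group_props group proportions (default uniform); must sum to 1.
#' @param mean_shape,mean_rate Gamma parameters of the gene base means.
#' @param seed RNG seed.
#' @param sparse return a `dgCMatrix` (default) instead of a dense matrix.
#' @return a `sim_result` with `data` (genes x cells count matrix, ids in
#'   dimnames) and `truth` (group `partition`).
#' @export
simulate_counts <- function(n_cells = 5000L, n_genes = 10000L,
                            n_groups = 30L, de_prob = 0.3,
                            de_fc_sigma = 1.0, libsize_sigma = 0.25,
                            dispersion = 0.4, group_props = NULL,
                            mean_shape = 0.6, mean_rate = 0.3,
                            seed = 1L, sparse = TRUE) {
  if (de_prob < 0 || de_prob > 1) stop("de_prob must be in [0, 1]",
                                       call. = FALSE)
  if (dispersion <= 0) stop("dispersion must be positive", call. = FALSE)
  if (n_groups < 1 || n_cells < n_groups) {
    stop("need at least one cell per group", call. = FALSE)
  }
  if (is.null(group_props)) group_props <- rep(1 / n_groups, n_groups)
  if (length(group_props) != n_groups ||
      abs(sum(group_props) - 1) > 1e-8 || any(group_props <= 0)) {
    stop("group_props must be positive and sum to 1", call. = FALSE)
  }
  out <- withr::with_seed(seed, {
    base_mean <- stats::rgamma(n_genes, shape = mean_shape, rate = mean_rate)
    fc <- matrix(1, n_genes, n_groups)
    for (g in seq_len(n_groups)) {
      de <- stats::runif(n_genes) < de_prob
      fc[de, g] <- exp(stats::rnorm(sum(de), 0, de_fc_sigma))
    }
    sizes <- group_sizes(n_cells, group_props)
    groups <- sample(rep.int(seq_len(n_groups), sizes))
    lib <- exp(stats::rnorm(n_cells, 0, libsize_sigma))
    size_nb <- 1 / dispersion
    chunk <- max(1L, floor(2e6 / n_genes))
    tri_i <- list(); tri_j <- list(); tri_x <- list()
    dense <- if (!sparse) matrix(0L, n_genes, n_cells) else NULL
    start <- 1L
    while (start <= n_cells) {
      cols <- start:min(start + chunk - 1L, n_cells)
      mu <- base_mean * fc[, groups[cols], drop = FALSE]
      mu <- sweep(mu, 2, lib[cols], `*`)
      cnt <- stats::rnbinom(length(mu), mu = mu, size = size_nb)
      if (sparse) {
        nz <- which(cnt > 0)
        tri_i[[length(tri_i) + 1L]] <- ((nz - 1L) %% n_genes) + 1L
        tri_j[[length(tri_j) + 1L]] <- cols[((nz - 1L) %/% n_genes) + 1L]
        tri_x[[length(tri_x) + 1L]] <- cnt[nz]
      } else {
        dense[, cols] <- cnt
      }
      start <- start + chunk
    }
    counts <- if (sparse) {
      Matrix::sparseMatrix(i = unlist(tri_i), j = unlist(tri_j),
                           x = unlist(tri_x), dims = c(n_genes, n_cells))
    } else dense
    list(counts = counts, groups = groups)
  })
  dimnames(out$counts) <- list(sprintf("gene%d", seq_len(n_genes)),
                               sprintf("cell%d", seq_len(n_cells)))
  truth <- partition(sprintf("group%d", out$groups), name = "truth",
                     unclustered_label = NULL)
  new_sim_result(out$counts, truth,
                 list(n_cells = n_cells, n_genes = n_genes,
                      n_groups = n_groups, de_prob = de_prob,
                      de_fc_sigma = de_fc_sigma,
                      libsize_sigma = libsize_sigma,
                      dispersion = dispersion, group_props = group_props,
                      mean_shape = mean_shape, mean_rate = mean_rate,
                      seed = seed),
                 "counts")
}

#' Reduced-dimensional embedding of a count matrix
#'
#' Depth-scales each cell to the median library size, log1p-transforms,
#' keeps the most variable genes, and projects onto principal components —
#' the standard preprocessing ahead of clustering.
#'
#' @param counts genes x cells count matrix.
#' @param dims number of principal components.
#' @param n_hvg number of highly variable genes retained.
#' @return cells x dims coordinate matrix.
#' @export
embed_counts <- function(counts, dims = 10L, n_hvg = 500L) {
  counts <- as_count_matrix(counts)
  depth <- Matrix::colSums(counts)
  depth[depth == 0] <- 1
  sf <- stats::median(depth) / depth
  if (inherits(counts, "sparseMatrix")) {
    y <- methods::as(counts %*% Matrix::Diagonal(x = sf), "CsparseMatrix")
    y@x <- log1p(y@x)
  } else {
    y <- log1p(sweep(counts, 2, sf, `*`))
  }
  n <- ncol(y)
  rm1 <- Matrix::rowMeans(y)
  rm2 <- Matrix::rowMeans(y * y)
  v <- (rm2 - rm1^2) * n / max(1, n - 1)
  hvg <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, nrow(y)))]
  pc <- stats::prcomp(t(as.matrix(y[hvg, , drop = FALSE])), center = TRUE,
                      scale. = FALSE)
  k <- min(dims, ncol(pc$x))
  pc$x[, seq_len(k), drop = FALSE]
}

#' Nonlinear 2-D embedding via a kNN-graph force-directed layout
#'
#' Builds the k-nearest-neighbor graph of the observations (Euclidean
#' distance in the supplied coordinates, typically a PCA) and lays it out
#' with the Fruchterman--Reingold force-directed algorithm, components
#' arranged on a grid. Like t-SNE/UMAP, and unlike any linear projection,
#' this separates many well-separated groups in two dimensions, which is
#' what makes it a useful input space for over-clustering. Deterministic for
#' a fixed seed.
#'
#' @param coords observations x features numeric matrix (e.g., PCA
#'   coordinates).
#' @param knn neighbors per observation in the graph.
#' @param seed RNG seed for the layout.
#' @return observations x 2 coordinate matrix.
#' @export
graph_embed <- function(coords, knn = 15L, seed = 1L) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n <= knn) stop("need more observations than knn", call. = FALSE)
  d <- as.matrix(stats::dist(coords))
  idx <- t(apply(d, 1, function(r) order(r)[2:(knn + 1L)]))
  g <- igraph::simplify(igraph::graph_from_edgelist(
    cbind(rep(seq_len(n), knn), as.vector(idx)), directed = FALSE))
  ly <- withr::with_seed(seed, igraph::layout_components(
    g, layout = igraph::layout_with_fr))
  rownames(ly) <- rownames(coords)
  colnames(ly) <- c("dim1", "dim2")
  ly
}

#' Deliberately over-partition a dataset
#'
#' Clusters the data with more clusters than the expected number of groups so
#' that a merging method has redundant clusters to work with. Counts are
#' embedded first ([embed_counts()]); coordinates are used as-is unless an
#' embedding is requested. Clusters that come out empty are dropped.
#'
#' @param data a `sim_result`, a genes x cells count matrix (sparse
#'   matrices are always treated as counts), or an observations x features
#'   coordinate matrix.
#' @param method `"kmeans"` or `"agglomerative"` (hierarchical clustering on
#'   Euclidean distances, cut at `k`).
#' @param k requested number of clusters (2 <= k <= n).
#' @param linkage linkage for the agglomerative method (default
#'   `"complete"`, the [stats::hclust()] default).
#' @param embed `"none"` (coordinates used directly; counts get the default
#'   10-dimensional PCA), `"pca"` (10 PCs) or `"tsne_like"` (2-D embedding).
#' @param seed RNG seed (k-means initialization).
#' @param name partition name; default describes method and embedding.
#' @param data_type override the counts/coordinates guess for dense
#'   matrices.
#' @return a `partition`.
#' @export
over_cluster <- function(data, method = c("kmeans", "agglomerative"),
                         k = 20L, embed = c("none", "pca", "tsne_like"),
                         seed = 1L, name = NULL,
                         data_type = c("auto", "counts", "coordinates"),
                         linkage = "complete") {
  method <- match.arg(method)
  embed <- match.arg(embed)
  data_type <- match.arg(data_type)
  if (inherits(data, "sim_result")) {
    data_type <- data$type
    data <- data$data
  }
  if (data_type == "auto") {
    data_type <- if (inherits(data, "Matrix")) "counts" else "coordinates"
  }
  coords <- if (data_type == "counts") {
    pca <- embed_counts(data, dims = 10L)
    if (embed == "tsne_like") graph_embed(pca, seed = seed) else pca
  } else {
    x <- as.matrix(data)
    if (embed == "tsne_like") {
      graph_embed(x, seed = seed)
    } else if (embed == "pca") {
      stats::prcomp(x, center = TRUE)$x[, seq_len(min(10L, ncol(x))),
                                        drop = FALSE]
    } else x
  }
  n <- nrow(coords)
  if (k < 2 || k > n) stop("k must be between 2 and n = ", n, call. = FALSE)
  labels <- if (method == "kmeans") {
    withr::with_seed(seed, stats::kmeans(coords, centers = k, nstart = 10L,
                                         iter.max = 100L)$cluster)
  } else {
    stats::cutree(stats::hclust(stats::dist(coords), method = linkage), k)
  }
  if (is.null(name)) {
    name <- paste0(method, if (embed != "none") paste0("_", embed),
                   "_k", k)
  }
  partition(paste0("c", labels), name = name, unclustered_label = NULL)
}

#' Standard trio of over-clusterings for benchmarking
#'
#' k-means on a 10-dimensional PCA, k-means on a nonlinear 2-D embedding
#' ([graph_embed()]), and agglomerative clustering on the PCA — three inputs
#' of deliberately excessive resolution for consensus merging.
#'
#' @param sim a `sim_result` from [simulate_counts()] (or a genes x cells
#'   count matrix).
#' @param k requested clusters per input.
#' @param seed RNG seed.
#' @return a `partition_set` of the three inputs.
#' @export
benchmark_inputs <- function(sim, k = 40L, seed = 1L) {
  counts <- if (inherits(sim, "sim_result")) sim$data else sim
  pca <- embed_counts(counts, dims = 10L)
  km_pca <- over_cluster(pca, "kmeans", k = k, seed = seed,
                         name = "kmeans_pca", data_type = "coordinates")
  km_2d <- over_cluster(graph_embed(pca, seed = seed), "kmeans", k = k,
                        seed = seed + 1L, name = "kmeans_2d",
                        data_type = "coordinates")
  hc_pca <- over_cluster(pca, "agglomerative", k = k, seed = seed,
                         name = "hclust_pca", data_type = "coordinates")
  partition_set(list(km_pca, km_2d, hc_pca))
}

#' Downsample cells of a simulated dataset
#'
#' Uniform subsample of cells without replacement; the truth labels are
#' subset accordingly. The stratified option guarantees at least one cell
#' per truth group.
#'
#' @param sim a `sim_result` (counts or coordinates).
#' @param fraction fraction of cells to keep, in (0, 1].
#' @param seed RNG seed.
#' @param stratified keep every truth group represented.
#' @return a `sim_result` on the subsample, with the chosen cell indices in
#'   attribute `cell_index`.
#' @export
downsample_cells <- function(sim, fraction, seed = 1L, stratified = FALSE) {
  stopifnot(inherits(sim, "sim_result"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  n <- length(sim$truth$labels)
  m <- max(1L, round(fraction * n))
  idx <- withr::with_seed(seed, {
    if (stratified) {
      groups <- split(seq_len(n), sim$truth$labels)
      first <- vapply(groups, function(g) if (length(g) == 1) g else
        sample(g, 1L), integer(1))
      rest <- setdiff(seq_len(n), first)
      extra <- if (m > length(first)) sample(rest, m - length(first)) else
        integer(0)
      sort(c(first[seq_len(min(m, length(first)))], extra))
    } else {
      sort(sample(seq_len(n), m))
    }
  })
  data <- if (sim$type == "counts") sim$data[, idx, drop = FALSE] else
    sim$data[idx, , drop = FALSE]
  truth <- partition(sim$truth$labels[idx], name = sim$truth$name,
                     unclustered_label = sim$truth$unclustered_label)
  out <- new_sim_result(data, truth,
                        c(sim$config, list(fraction = fraction,
                                           downsample_seed = seed)),
                        sim$type)
  attr(out, "cell_index") <- idx
  out
}
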