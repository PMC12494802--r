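#' ROC AUC by the Mann-Whitney pair-counting convention
#'
#' Probability that a random positive outscores a random negative, with ties
#' credited 0.5 — computed via the rank-sum identity, identical to the
#' explicit pair count.
#'
#' @param pos_scores,neg_scores Nonempty numeric score vectors.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop("both score vectors must be nonempty", call. = FALSE)
  }
  np <- length(pos_scores); nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Average precision
#'
#' Sum over positives, in descending score order (ties broken by stable
#' input order), of precision-at-that-rank times the recall step 1/P.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; at least one positive required.
#' @return AP in [0, 1].
#' @export
average_precision <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1)
  if (npos == 0L) stop("average precision requires at least one positive", call. = FALSE)
  ord <- order(-scores)                 # stable: ties keep input order
  lab <- labels[ord]
  hits <- cumsum(lab)
  prec <- hits / seq_along(lab)
  sum(prec[lab == 1]) / npos
}

#' Link-prediction evaluation on an edge set
#'
#' @param z Embedding matrix.
#' @param pos,neg 0-based m x 2 edge index matrices.
#' @return List with \code{auc}, \code{average_precision},
#'   \code{pr_curve} (data frame of recall/precision points) and the raw
#'   positive/negative score vectors.
#' @export
link_prediction_result <- function(z, pos, neg) {
  sp <- decode_edges(z, pos)
  sn <- decode_edges(z, neg)
  labels <- rep(c(1, 0), c(length(sp), length(sn)))
  scores <- c(sp, sn)
  ord <- order(-scores)
  lab <- labels[ord]
  hits <- cumsum(lab)
  pr <- data.frame(recall = hits / sum(lab), precision = hits / seq_along(lab))
  list(auc = roc_auc(sp, sn),
       average_precision = average_precision(scores, labels),
       pr_curve = pr, pos_scores = sp, neg_scores = sn)
}

#' Mean silhouette score
#'
#' For each point, \eqn{(b - a) / max(a, b)} where a is the mean Euclidean
#' distance to its own cluster's other members (0 for singletons, whose
#' silhouette is 0 by convention) and b the smallest mean distance to
#' another cluster.
#'
#' @param embeddings n x d matrix.
#' @param labels Cluster labels, at least two distinct values.
#' @return Mean silhouette in [-1, 1].
#' @export
silhouette_score <- function(embeddings, labels) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("silhouette requires at least two clusters", call. = FALSE)
  n <- nrow(embeddings)
  d <- as.matrix(stats::dist(embeddings))
  sizes <- tabulate(labels, k)
  # mean distance from every point to every cluster via group sums
  sums <- rowsum(t(d), labels)          # k x n: sum of distances to each cluster
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- labels[i]
    if (sizes[ci] <= 1L) { s[i] <- 0; next }
    a <- sums[ci, i] / (sizes[ci] - 1L)
    others <- setdiff(seq_len(k), ci)
    b <- min(sums[others, i] / sizes[others])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Seeded k-means labels
#'
#' Lloyd's algorithm with 10 random restarts under a fixed seed, keeping the
#' lowest-inertia solution; used to derive cluster labels for silhouette
#' scoring when no ground-truth partition is given.
#'
#' @param embeddings n x d matrix.
#' @param k Number of clusters (2 <= k <= n).
#' @param seed Integer seed.
#' @return Integer label vector of length n.
#' @export
kmeans_labels <- function(embeddings, k = 5L, seed = 1L) {
  n <- nrow(embeddings)
  if (k > n) stop("k must not exceed the number of points", call. = FALSE)
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  set.seed(as.integer(seed))
  n_distinct <- nrow(unique(round(embeddings, 12)))
  km <- suppressWarnings(stats::kmeans(embeddings, centers = min(k, n_distinct),
                                       nstart = 10, iter.max = 100,
                                       algorithm = "Lloyd"))
  km$cluster
}

#' Neighborhood preservation at k
#'
#' For every node with at least one undirected graph neighbor: the fraction
#' of its k nearest embedding neighbors (Euclidean, self excluded, ties by
#' index) that are graph neighbors, divided by k; averaged over eligible
#' nodes.
#'
#' @param graph A \code{regulatory_graph}.
#' @param embeddings Embedding matrix over the same nodes.
#' @param k Neighborhood size (default 5; must be < n).
#' @return Value in [0, 1].
#' @export
neighborhood_preservation <- function(graph, embeddings, k = 5L) {
  n <- n_nodes(graph)
  stopifnot(nrow(embeddings) == n)
  if (k >= n) stop("k must be smaller than the number of nodes", call. = FALSE)
  adj <- matrix(FALSE, n, n)
  e <- graph$edges
  adj[e + 1L] <- TRUE
  adj[e[, c(2, 1), drop = FALSE] + 1L] <- TRUE
  diag(adj) <- FALSE
  d <- as.matrix(stats::dist(embeddings))
  diag(d) <- Inf
  vals <- numeric(0)
  for (i in seq_len(n)) {
    nbrs <- which(adj[i, ])
    if (length(nbrs) == 0L) next
    knn <- order(d[i, ])[seq_len(k)]
    vals <- c(vals, length(intersect(knn, nbrs)) / k)
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

as_igraph_undirected <- function(graph) {
  g <- igraph::graph_from_edgelist(graph$edges + 1L, directed = TRUE)
  g <- igraph::add_vertices(g, max(0L, n_nodes(graph) - igraph::vcount(g)))
  igraph::as_undirected(igraph::simplify(g), mode = "collapse")
}

#' Centrality-embedding correlation table
#'
#' Correlates per-node L2 embedding norms with degree, betweenness,
#' closeness and eigenvector centrality (Pearson and Spearman). All
#' centralities are computed on the undirected simple projection of the
#' graph; eigenvector centrality uses the largest connected component with
#' zeros elsewhere; closeness of isolated nodes is treated as 0. A constant
#' norm vector yields NA correlations.
#'
#' @param graph A \code{regulatory_graph}.
#' @param embeddings Embedding matrix over the same nodes.
#' @return Data frame with columns \code{measure}, \code{pearson},
#'   \code{spearman}.
#' @export
centrality_correlations <- function(graph, embeddings) {
  stopifnot(nrow(embeddings) == n_nodes(graph))
  g <- as_igraph_undirected(graph)
  norms <- sqrt(rowSums(embeddings^2))
  cent <- list(
    degree = igraph::degree(g),
    betweenness = igraph::betweenness(g, normalized = TRUE),
    closeness = {
      cl <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
      cl[!is.finite(cl)] <- 0
      cl
    },
    eigenvector = {
      comp <- igraph::components(g)
      big <- which.max(comp$csize)
      ev <- numeric(igraph::vcount(g))
      members <- which(comp$membership == big)
      sub <- igraph::induced_subgraph(g, members)
      ev[members] <- igraph::eigen_centrality(sub)$vector
      ev
    }
  )
  safe_cor <- function(x, y, method) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    suppressWarnings(stats::cor(x, y, method = method))
  }
  data.frame(
    measure = names(cent),
    pearson = vapply(cent, safe_cor, numeric(1), y = norms, method = "pearson"),
    spearman = vapply(cent, safe_cor, numeric(1), y = norms, method = "spearman"),
    row.names = NULL
  )
}

shared_histograms <- function(x, y, bins) {
  lo <- min(x, y); hi <- max(x, y)
  if (hi <= lo) return(NULL)  # degenerate dimension
  edges <- seq(lo, hi, length.out = bins + 1L)
  hx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  hy <- findInterval(y, edges, rightmost.closed = TRUE, all.inside = TRUE)
  list(p = tabulate(hx, bins) / length(x), q = tabulate(hy, bins) / length(y))
}

hist_kl <- function(p, q, eps = 1e-12) {
  p <- p + eps; q <- q + eps
  p <- p / sum(p); q <- q / sum(q)
  sum(p * log(p / q))
}

#' Per-dimension histogram KL divergence between two samples
#'
#' Each dimension is binned on shared edges spanning the pooled range
#' (default 50 bins); counts are epsilon-smoothed (1e-12) and renormalized
#' before computing KL(p||q) in nats, both directions, plus the symmetric
#' average. Degenerate dimensions (zero pooled range) contribute 0 and are
#' flagged.
#'
#' @param X,Y Samples with the same number of columns.
#' @param bins Number of histogram bins.
#' @return List with vectors \code{kl_xy}, \code{kl_yx}, \code{kl_sym},
#'   their means, and \code{degenerate} flags.
#' @export
kl_per_dimension <- function(X, Y, bins = 50L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(ncol(X) == ncol(Y))
  d <- ncol(X)
  kl_xy <- kl_yx <- numeric(d)
  degenerate <- logical(d)
  for (j in seq_len(d)) {
    h <- shared_histograms(X[, j], Y[, j], bins)
    if (is.null(h)) { degenerate[j] <- TRUE; next }
    kl_xy[j] <- hist_kl(h$p, h$q)
    kl_yx[j] <- hist_kl(h$q, h$p)
  }
  kl_sym <- (kl_xy + kl_yx) / 2
  list(kl_xy = kl_xy, kl_yx = kl_yx, kl_sym = kl_sym,
       mean_kl_xy = mean(kl_xy), mean_kl_yx = mean(kl_yx),
       mean_kl_sym = mean(kl_sym), degenerate = degenerate)
}

#' Mean per-dimension Jensen-Shannon distance
#'
#' Histogram JS divergence (natural log) per dimension on shared bin edges;
#' the distance is its square root, bounded by sqrt(ln 2) ~ 0.8326; the mean
#' across dimensions is returned.
#'
#' @inheritParams kl_per_dimension
#' @return Scalar mean JS distance.
#' @export
jensen_shannon_distance <- function(X, Y, bins = 50L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(ncol(X) == ncol(Y))
  vals <- vapply(seq_len(ncol(X)), function(j) {
    h <- shared_histograms(X[, j], Y[, j], bins)
    if (is.null(h)) return(0)
    m <- (h$p + h$q) / 2
    sqrt(0.5 * hist_kl(h$p, m) + 0.5 * hist_kl(h$q, m))
  }, numeric(1))
  mean(vals)
}

# exact 1D empirical Wasserstein-1: integral of |F_X - F_Y| between pooled
# support points (general sample sizes)
wasserstein_1d <- function(x, y) {
  all_v <- sort(c(x, y))
  if (length(all_v) < 2L) return(0)
  deltas <- diff(all_v)
  grid <- all_v[-length(all_v)]
  fx <- stats::ecdf(x)(grid)
  fy <- stats::ecdf(y)(grid)
  sum(abs(fx - fy) * deltas)
}

#' Mean per-dimension 1D Wasserstein distance
#'
#' Exact empirical Wasserstein-1 (area between quantile functions) per
#' dimension, averaged across dimensions.
#'
#' @param X,Y Samples with the same number of columns.
#' @return Nonnegative scalar.
#' @export
wasserstein_mean <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(ncol(X) == ncol(Y), nrow(X) > 0L, nrow(Y) > 0L)
  mean(vapply(seq_len(ncol(X)),
              function(j) wasserstein_1d(X[, j], Y[, j]), numeric(1)))
}

#' Squared maximum mean discrepancy with RBF kernels
#'
#' Biased V-statistic \code{mean(Kxx) + mean(Kyy) - 2 mean(Kxy)} with
#' \eqn{k(x, y) = \exp(-||x - y||^2 / (2\sigma^2))}, evaluated on a grid of
#' bandwidths. The reported quantity is the squared MMD.
#'
#' @param X,Y Samples with the same dimensionality.
#' @param sigmas Positive kernel bandwidths.
#' @return Named numeric vector of squared-MMD values, one per sigma.
#' @export
mmd_rbf <- function(X, Y, sigmas = c(0.1, 0.5, 1.0, 2.0, 5.0)) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(ncol(X) == ncol(Y))
  if (any(sigmas <= 0)) stop("sigma must be positive", call. = FALSE)
  sq_dists <- function(A, B) {
    an <- rowSums(A^2); bn <- rowSums(B^2)
    pmax(outer(an, bn, "+") - 2 * A %*% t(B), 0)
  }
  dxx <- sq_dists(X, X); dyy <- sq_dists(Y, Y); dxy <- sq_dists(X, Y)
  out <- vapply(sigmas, function(s) {
    mean(exp(-dxx / (2 * s^2))) + mean(exp(-dyy / (2 * s^2))) -
      2 * mean(exp(-dxy / (2 * s^2)))
  }, numeric(1))
  names(out) <- as.character(sigmas)
  out
}

#' Decoder scores grouped by regulation type
#'
#' Scores every annotation row (duplicates included — the row, not the
#' deduplicated edge, is the unit) with the inner-product decoder and
#' summarizes mean and standard deviation per regulation label.
#'
#' @param interactions A \code{regulatory_interactions} table.
#' @param graph The graph built from it (supplies the node index).
#' @param z Embedding matrix in node-index order.
#' @return Data frame: regulation, count, mean_score, sd_score.
#' @export
regulation_type_scores <- function(interactions, graph, z) {
  idx_tf <- graph$node_index[interactions$tf]
  idx_tg <- graph$node_index[interactions$target]
  if (anyNA(idx_tf) || anyNA(idx_tg)) {
    stop("interaction references a symbol absent from the graph", call. = FALSE)
  }
  s <- decode_edges(z, cbind(idx_tf, idx_tg))
  agg <- split(s, interactions$regulation)
  data.frame(
    regulation = names(agg),
    count = vapply(agg, length, integer(1)),
    mean_score = vapply(agg, function(v) if (length(v)) mean(v) else NA_real_, numeric(1)),
    sd_score = vapply(agg, function(v) if (length(v) > 1L) stats::sd(v) else 0, numeric(1)),
    row.names = NULL
  )
}

#' Two-component PCA projection
#'
#' Column-centered SVD projection onto the top two principal components,
#' with the sign convention that each component's largest-magnitude loading
#' is positive.
#'
#' @param X n x d matrix, n >= 2.
#' @return List with \code{coords} (n x 2) and \code{explained_variance}
#'   (length-2 fractions of total variance, descending).
#' @export
pca_2d <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2L)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = 2, nv = 2)
  flip <- vapply(1:2, function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  coords <- sweep(Xc %*% sv$v[, 1:2, drop = FALSE], 2, flip, "*")
  ev <- sv$d^2 / sum(sv$d^2)
  list(coords = coords, explained_variance = ev[1:2])
}

#' Embedding-quality summary (silhouette + neighborhood preservation)
#'
#' @param graph A \code{regulatory_graph}.
#' @param embeddings Embedding matrix over the graph's nodes.
#' @param k Neighborhood size for preservation.
#' @param kmeans_k Number of k-means clusters for the silhouette labels.
#' @param seed Seed for k-means.
#' @return List with \code{silhouette}, \code{neighborhood_preservation},
#'   \code{k}, \code{labels}.
#' @export
embedding_quality <- function(graph, embeddings, k = 5L, kmeans_k = 5L, seed = 1L) {
  labels <- kmeans_labels(embeddings, kmeans_k, seed)
  list(silhouette = silhouette_score(embeddings, labels),
       neighborhood_preservation = neighborhood_preservation(graph, embeddings, k),
       k = k, labels = labels)
}
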