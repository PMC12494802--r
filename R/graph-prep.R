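#' One-hot node identity features
#'
#' Each node's input feature is the indicator of its own index, giving the
#' |V| x |V| identity matrix in node-index order (the transductive setting:
#' the model learns everything from the graph structure).
#'
#' @param graph A \code{regulatory_graph}.
#' @return A |V| x |V| numeric matrix with rownames = node symbols.
#' @export
one_hot_features <- function(graph) {
  stopifnot(inherits(graph, "regulatory_graph"))
  n <- n_nodes(graph)
  x <- diag(n)
  dimnames(x) <- list(graph$nodes, NULL)
  x
}

#' Symmetrically normalized GCN propagation matrix
#'
#' Computes \eqn{\tilde{D}^{-1/2} \tilde{A} \tilde{D}^{-1/2}} where
#' \eqn{\tilde{A} = A_{sym} + I}, \eqn{A_{sym}} the symmetrized 0/1
#' adjacency of the directed edge list (edge weights unity), and
#' \eqn{\tilde{D}} its degree diagonal. Directedness is preserved in the
#' edge list for decoding and evaluation; message passing uses the
#' symmetric operator, the stable convention for GCN stacks.
#'
#' @param graph A \code{regulatory_graph}.
#' @return A dense symmetric |V| x |V| matrix.
#' @export
propagation_matrix <- function(graph) {
  stopifnot(inherits(graph, "regulatory_graph"))
  n <- n_nodes(graph)
  a <- matrix(0, n, n)
  e <- graph$edges
  a[e + 1L] <- 1                       # (src, dst) 0-based pairs
  a[e[, c(2, 1), drop = FALSE] + 1L] <- 1
  diag(a) <- 0
  at <- a + diag(n)
  dinv <- 1 / sqrt(rowSums(at))
  at * outer(dinv, dinv)
}

#' Train/validation/test edge split with matched negative sampling
#'
#' Positive (true) directed edges are partitioned uniformly at random into
#' test (\code{test_frac}, default 20\%), validation
#' (\code{val_frac_of_train} of the remainder, default 10\%; used for early
#' stopping so test edges never influence it) and training sets. Each
#' positive set gets an equal-sized set of negatives sampled uniformly from
#' ordered non-edge pairs excluding self-loops; negatives never collide with
#' any true edge and the three negative sets are mutually disjoint.
#'
#' @param graph A \code{regulatory_graph} with at least 10 edges.
#' @param test_frac Fraction of edges held out for testing, in (0, 1).
#' @param val_frac_of_train Fraction of the training portion carved out for
#'   validation, in [0, 1).
#' @param seed Integer seed; identical seeds give identical splits.
#' @return A list of class \code{edge_split} with 0-based m x 2 integer
#'   matrices \code{train_pos}, \code{val_pos}, \code{test_pos},
#'   \code{train_neg}, \code{val_neg}, \code{test_neg}, and \code{seed}.
#' @export
split_edges <- function(graph, test_frac = 0.2, val_frac_of_train = 0.1, seed = 1L) {
  stopifnot(inherits(graph, "regulatory_graph"))
  m <- n_edges(graph); n <- n_nodes(graph)
  if (m < 10L) stop("graph must have at least 10 edges to split", call. = FALSE)
  if (test_frac <= 0 || test_frac >= 1) stop("test_frac must be in (0,1)", call. = FALSE)
  if (val_frac_of_train < 0 || val_frac_of_train >= 1) {
    stop("val_frac_of_train must be in [0,1)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n_test <- round(test_frac * m)
  n_train_all <- m - n_test
  n_val <- round(val_frac_of_train * n_train_all)
  perm <- sample.int(m)
  test_id <- perm[seq_len(n_test)]
  val_id <- perm[n_test + seq_len(n_val)]
  train_id <- perm[-seq_len(n_test + n_val)]
  e <- graph$edges
  neg <- sample_negative_edges(graph, m, seed = NULL) # uses current RNG stream
  split <- list(
    train_pos = e[train_id, , drop = FALSE],
    val_pos = e[val_id, , drop = FALSE],
    test_pos = e[test_id, , drop = FALSE],
    train_neg = neg[seq_along(train_id), , drop = FALSE],
    val_neg = neg[length(train_id) + seq_along(val_id), , drop = FALSE],
    test_neg = neg[length(train_id) + length(val_id) + seq_along(test_id), , drop = FALSE],
    seed = as.integer(seed)
  )
  class(split) <- "edge_split"
  split
}

#' Sample negative (non-)edges uniformly
#'
#' Draws \code{n_neg} distinct ordered (source, target) pairs that are
#' neither self-loops nor true directed edges of the graph. Reverse pairs of
#' true edges are eligible. Uses the current RNG stream when
#' \code{seed = NULL}.
#'
#' @param graph A \code{regulatory_graph}.
#' @param n_neg Number of negatives required.
#' @param seed Optional integer seed.
#' @return 0-based n_neg x 2 integer matrix.
#' @export
sample_negative_edges <- function(graph, n_neg, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- n_nodes(graph)
  n_pairs <- as.double(n) * (n - 1)   # ordered pairs without self-loops
  if (n_pairs - n_edges(graph) < n_neg) {
    stop("graph too dense to supply the requested number of negatives", call. = FALSE)
  }
  edge_key <- graph$edges[, 1] * n + graph$edges[, 2]
  out <- integer(0)
  got <- 0L
  taken <- integer(0)
  while (got < n_neg) {
    k <- max(2L * (n_neg - got), 32L)
    src <- sample.int(n, k, replace = TRUE) - 1L
    dst <- sample.int(n, k, replace = TRUE) - 1L
    key <- src * n + dst
    ok <- src != dst & !(key %in% edge_key) & !(key %in% taken) & !duplicated(key)
    key <- key[ok]
    if (length(key) > n_neg - got) key <- key[seq_len(n_neg - got)]
    taken <- c(taken, key)
    got <- length(taken)
  }
  cbind(source = taken %/% n, target = taken %% n)
}
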