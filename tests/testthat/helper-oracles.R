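# Independent oracles used across the suite. These stay deliberately naive
# (dense matrices, double loops) so they share no code path with the
# implementation they check.

# dense 2^n x 2^n operator acting as `u` on qubit q (qubit 0 = MSB)
oracle_single_qubit_op <- function(n, q, u) {
  left <- diag(2^q)
  right <- diag(2^(n - 1 - q))
  kronecker(kronecker(left, u), right)
}

oracle_cnot_op <- function(n, control, target) {
  dim <- 2^n
  cs <- 2^(n - 1 - control); ts <- 2^(n - 1 - target)
  U <- matrix(0, dim, dim)
  for (b in 0:(dim - 1)) {
    b2 <- if (bitwAnd(b, cs) != 0) bitwXor(b, ts) else b
    U[b2 + 1, b + 1] <- 1
  }
  U
}

oracle_ry <- function(theta) {
  matrix(c(cos(theta / 2), sin(theta / 2), -sin(theta / 2), cos(theta / 2)), 2)
}

oracle_rz <- function(theta) {
  diag(c(exp(-1i * theta / 2), exp(1i * theta / 2)))
}

# full circuit unitary: RY(theta_q), RZ(theta_q) on each qubit, then the
# CNOT chain, as explicit matrix products
oracle_encode_vector <- function(theta, entangle = TRUE) {
  n <- length(theta)
  U <- diag(2^n) + 0i
  for (q in seq_len(n) - 1) {
    U <- oracle_single_qubit_op(n, q, oracle_ry(theta[q + 1])) %*% U
    U <- oracle_single_qubit_op(n, q, oracle_rz(theta[q + 1])) %*% U
  }
  if (entangle && n > 1) {
    for (q in seq_len(n - 1) - 1) {
      U <- oracle_cnot_op(n, q, q + 1) %*% U
    }
  }
  psi0 <- complex(2^n); psi0[1] <- 1
  as.vector(U %*% psi0)
}

oracle_pauli_z <- function(psi, n, q) {
  zop <- oracle_single_qubit_op(n, q, diag(c(1, -1)))
  Re(sum(Conj(psi) * (zop %*% psi)))
}

# AUC by explicit pair counting with half-credit ties
oracle_auc_paircount <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# silhouette by direct per-point double loop
oracle_silhouette <- function(x, labels) {
  labels <- as.integer(factor(labels))
  n <- nrow(x)
  ed <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, ed, numeric(1), i = i))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      mem <- which(labels == cl)
      b <- min(b, mean(vapply(mem, ed, numeric(1), i = i)))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# neighborhood preservation by direct loops
oracle_neighborhood_preservation <- function(graph, x, k) {
  n <- nrow(x)
  nbrs <- vector("list", n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges[r, 1] + 1; j <- graph$edges[r, 2] + 1
    if (i != j) {
      nbrs[[i]] <- union(nbrs[[i]], j)
      nbrs[[j]] <- union(nbrs[[j]], i)
    }
  }
  vals <- c()
  for (i in seq_len(n)) {
    if (length(nbrs[[i]]) == 0) next
    dd <- apply(x, 1, function(r) sqrt(sum((r - x[i, ])^2)))
    dd[i] <- Inf
    knn <- order(dd)[seq_len(k)]
    vals <- c(vals, length(intersect(knn, nbrs[[i]])) / k)
  }
  mean(vals)
}

# squared MMD by explicit double loops
oracle_mmd <- function(X, Y, sigma) {
  kf <- function(a, b) exp(-sum((a - b)^2) / (2 * sigma^2))
  sxx <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(X)))
    sxx <- sxx + kf(X[i, ], X[j, ])
  syy <- 0
  for (i in seq_len(nrow(Y))) for (j in seq_len(nrow(Y)))
    syy <- syy + kf(Y[i, ], Y[j, ])
  sxy <- 0
  for (i in seq_len(nrow(X))) for (j in seq_len(nrow(Y)))
    sxy <- sxy + kf(X[i, ], Y[j, ])
  sxx / nrow(X)^2 + syy / nrow(Y)^2 - 2 * sxy / (nrow(X) * nrow(Y))
}

# dense brute-force GCN propagation matrix
oracle_propagation <- function(graph) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n)
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges[r, 1] + 1; j <- graph$edges[r, 2] + 1
    if (i != j) { A[i, j] <- 1; A[j, i] <- 1 }
  }
  At <- A + diag(n)
  D <- diag(1 / sqrt(rowSums(At)))
  D %*% At %*% D
}
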