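#' Hyperparameters for the graph autoencoder
#'
#' Defaults follow the reference configuration: hidden width 128, embedding
#' dimension 64, ReLU activations with layer normalization after each graph
#' convolution, dropout 0.1, Adam at learning rate 0.01 with weight decay
#' 5e-4 on the weight matrices, 100 full-batch epochs with early stopping at
#' patience 10 on validation loss.
#'
#' @param hidden_dim Hidden layer width.
#' @param embedding_dim Output embedding dimension.
#' @param dropout Dropout probability applied between the two layers in
#'   training mode.
#' @param learning_rate,weight_decay Adam step size and L2 coefficient.
#' @param epochs Maximum number of full-batch epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param seed Integer seed controlling initialization, dropout and
#'   per-epoch negative resampling.
#' @return A list of class \code{gae_config}.
#' @export
gae_config <- function(hidden_dim = 128L, embedding_dim = 64L, dropout = 0.1,
                       learning_rate = 0.01, weight_decay = 5e-4,
                       epochs = 100L, patience = 10L, seed = 1L) {
  structure(list(hidden_dim = as.integer(hidden_dim),
                 embedding_dim = as.integer(embedding_dim),
                 dropout = dropout, learning_rate = learning_rate,
                 weight_decay = weight_decay, epochs = as.integer(epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "gae_config")
}

glorot_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Weights: seeded uniform Glorot. Output-layer norm gain starts at
# 1/sqrt(d) so initial decoder logits are O(1): with unit gains the
# nonnegative embeddings give every pair a logit near +d/2, the saturated
# negatives then drive a global shrinkage that lands in the absorbing
# all-zero-embedding state (where the inner-product decoder has zero
# gradient). Keeping initial logits small avoids that collapse.
init_gae_params <- function(input_dim, config) {
  set.seed(config$seed)
  h <- config$hidden_dim; d <- config$embedding_dim
  list(W1 = glorot_uniform(input_dim, h), b1 = numeric(h),
       g1 = rep(1, h), s1 = numeric(h),
       W2 = glorot_uniform(h, d), b2 = numeric(d),
       g2 = rep(1 / sqrt(d), d), s2 = numeric(d))
}

LN_EPS <- 1e-5

layer_norm_forward <- function(x, gain, shift) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(out = sweep(xhat, 2, gain, "*") + rep(shift, each = nrow(x)),
       xhat = xhat, inv = inv)
}

layer_norm_backward <- function(dout, cache, gain) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2, gain, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx, dgain = colSums(dout * xhat), dshift = colSums(dout))
}

#' One graph-convolution layer
#'
#' Computes \code{relu(layer_norm(P \%*\% H \%*\% W + b))} with per-feature
#' gain and shift, the building block of the two-layer encoder. Layer
#' normalization acts on the pre-activation (the graph convolution's
#' output); the ReLU follows it, so stacking two layers leaves the final
#' embeddings nonnegative and normalization keeps roughly half of every
#' row's units active, which prevents whole-layer ReLU death during
#' training.
#'
#' @param H Node feature matrix (n x f).
#' @param P Propagation matrix from [propagation_matrix()] (n x n).
#' @param W Weight matrix (f x f').
#' @param bias Length-f' bias vector.
#' @param gain,shift Layer-norm parameters (default identity transform).
#' @return n x f' activation matrix.
#' @export
gcn_layer <- function(H, P, W, bias = numeric(ncol(W)),
                      gain = rep(1, ncol(W)), shift = numeric(ncol(W))) {
  if (ncol(H) != nrow(W)) stop("shape mismatch: ncol(H) != nrow(W)", call. = FALSE)
  a <- P %*% H %*% W + rep(bias, each = nrow(P))
  pmax(layer_norm_forward(a, gain, shift)$out, 0)
}

# Full forward pass with caches for backprop. Each layer: graph
# convolution -> layer norm -> ReLU; the second layer's ReLU makes the
# embeddings nonnegative.
gae_forward <- function(params, features, P, mode = c("eval", "train"),
                        dropout = 0.1) {
  mode <- match.arg(mode)
  M1 <- P %*% features
  A1 <- M1 %*% params$W1 + rep(params$b1, each = nrow(P))
  ln1 <- layer_norm_forward(A1, params$g1, params$s1)
  R1 <- pmax(ln1$out, 0)
  D1 <- R1
  mask <- NULL
  if (mode == "train" && dropout > 0) {
    mask <- matrix(stats::runif(length(D1)) >= dropout, nrow(D1), ncol(D1))
    D1 <- D1 * mask / (1 - dropout)
  }
  M2 <- P %*% D1
  A2 <- M2 %*% params$W2 + rep(params$b2, each = nrow(P))
  ln2 <- layer_norm_forward(A2, params$g2, params$s2)
  Z <- pmax(ln2$out, 0)
  list(Z = Z, M1 = M1, A1 = A1, ln1 = ln1, mask = mask, M2 = M2, A2 = A2,
       ln2 = ln2, dropout = dropout, mode = mode)
}

gae_backward <- function(params, cache, dZ) {
  dln2 <- dZ * (cache$ln2$out > 0)
  bn2 <- layer_norm_backward(dln2, cache$ln2, params$g2)
  dA2 <- bn2$dx
  dW2 <- crossprod(cache$M2, dA2)
  db2 <- colSums(dA2)
  dM2 <- dA2 %*% t(params$W2)
  dD1 <- crossprod_sym_prop(cache$P, dM2)
  if (!is.null(cache$mask)) dD1 <- dD1 * cache$mask / (1 - cache$dropout)
  dln1 <- dD1 * (cache$ln1$out > 0)
  bn1 <- layer_norm_backward(dln1, cache$ln1, params$g1)
  dA1 <- bn1$dx
  dW1 <- crossprod(cache$M1, dA1)
  db1 <- colSums(dA1)
  list(W1 = dW1, b1 = db1, g1 = bn1$dgain, s1 = bn1$dshift,
       W2 = dW2, b2 = db2, g2 = bn2$dgain, s2 = bn2$dshift)
}

# P is symmetric so t(P) %*% X == P %*% X
crossprod_sym_prop <- function(P, X) P %*% X

#' Encode nodes to embeddings
#'
#' Runs the two-layer graph-convolutional encoder. In \code{eval} mode the
#' pass is deterministic (dropout disabled); embeddings are nonnegative by
#' construction (final ReLU).
#'
#' @param params Parameter list from [train_gae()] or internal
#'   initialization.
#' @param features Node feature matrix (one-hot identity in the standard
#'   pipeline).
#' @param P Propagation matrix.
#' @param mode \code{"eval"} (deterministic) or \code{"train"} (dropout
#'   active).
#' @param dropout Dropout probability in train mode.
#' @return An \code{embedding_matrix}: n x embedding_dim numeric matrix with
#'   attribute \code{model_tag = "GAE"} and rownames in node order.
#' @export
encode <- function(params, features, P, mode = c("eval", "train"), dropout = 0.1) {
  if (any(!vapply(params[c("W1", "W2")], function(w) all(is.finite(w)), TRUE))) {
    stop("non-finite encoder parameters", call. = FALSE)
  }
  z <- gae_forward(params, features, P, mode, dropout)$Z
  rownames(z) <- rownames(features)
  embedding_matrix(z, "GAE")
}

#' Tag a numeric matrix as a node-embedding matrix
#'
#' @param values n x d numeric matrix, rows in node-index order.
#' @param model_tag Producing model: "GAE", "GAN" or "QUANTUM".
#' @return The matrix with class \code{embedding_matrix} and a
#'   \code{model_tag} attribute.
#' @export
embedding_matrix <- function(values, model_tag = c("GAE", "GAN", "QUANTUM")) {
  model_tag <- match.arg(model_tag)
  stopifnot(is.matrix(values), all(is.finite(values)))
  structure(values, model_tag = model_tag,
            class = c("embedding_matrix", class(values)))
}

#' Inner-product edge decoder
#'
#' Edge probability for a node pair (i, j) is
#' \eqn{\sigma(z_i \cdot z_j)}, the logistic function of the embedding
#' inner product; symmetric under swapping i and j.
#'
#' @param z Embedding matrix (n x d).
#' @param pairs m x 2 matrix of 0-based node index pairs.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
decode_edges <- function(z, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (any(pairs < 0L) || any(pairs >= nrow(z))) {
    stop("edge index out of range", call. = FALSE)
  }
  logits <- rowSums(z[pairs[, 1] + 1L, , drop = FALSE] *
                    z[pairs[, 2] + 1L, , drop = FALSE])
  stats::plogis(logits)
}

#' Binary cross-entropy loss
#'
#' Mean of \eqn{-[y \log s + (1-y) \log(1-s)]} with scores clipped to
#' \code{[eps, 1-eps]} so saturated predictions stay finite.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 vector of the same length.
#' @param eps Clipping constant (default 1e-12).
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(scores, labels, eps = 1e-12) {
  stopifnot(length(scores) == length(labels))
  s <- pmin(pmax(scores, eps), 1 - eps)
  -mean(labels * log(s) + (1 - labels) * log(1 - s))
}

# Loss and analytic gradient (w.r.t. z) of bce_loss(decode_edges(z, pairs)).
# The gradient of BCE through the logistic link is (s - y) on the logit, so
# dL/dz_i = mean-normalized sum over incident pairs of (s - y) z_j.
bce_decoder_grad <- function(z, pairs, labels) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  s <- decode_edges(z, pairs)
  loss <- bce_loss(s, labels)
  dlogit <- (s - labels) / length(labels)
  i <- pairs[, 1] + 1L; j <- pairs[, 2] + 1L
  dz <- matrix(0, nrow(z), ncol(z))
  ci <- dlogit * z[j, , drop = FALSE]
  cj <- dlogit * z[i, , drop = FALSE]
  acc_i <- rowsum(ci, i)
  acc_j <- rowsum(cj, j)
  dz[as.integer(rownames(acc_i)), ] <- dz[as.integer(rownames(acc_i)), ] + acc_i
  dz[as.integer(rownames(acc_j)), ] <- dz[as.integer(rownames(acc_j)), ] + acc_j
  list(loss = loss, grad = dz, scores = s)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, weight_decay = 0,
                      betas = c(0.9, 0.999), eps = 1e-8,
                      decay_names = c("W1", "W2")) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && nm %in% decay_names) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train the graph autoencoder
#'
#' Full-batch training: each epoch scores the training positives plus an
#' equal number of freshly resampled negatives (the fixed split negatives
#' are reserved for evaluation), takes one Adam step, and monitors BCE on
#' the fixed validation positives/negatives in deterministic eval mode.
#' Training stops early when the validation loss has not improved for
#' \code{config$patience} epochs; the parameters from the best epoch are
#' returned along with eval-mode embeddings.
#'
#' @param graph A \code{regulatory_graph}.
#' @param features Node feature matrix (defaults to one-hot identity).
#' @param split An \code{edge_split} from [split_edges()].
#' @param config A [gae_config()].
#' @return List with \code{params}, \code{history} (data frame of epoch,
#'   train_loss, val_loss), \code{best_epoch}, \code{stopped_epoch}, and
#'   \code{embeddings} (eval-mode \code{embedding_matrix} at the best
#'   epoch).
#' @export
train_gae <- function(graph, features = one_hot_features(graph), split,
                      config = gae_config()) {
  stopifnot(inherits(graph, "regulatory_graph"), inherits(split, "edge_split"))
  P <- propagation_matrix(graph)
  params <- init_gae_params(ncol(features), config)  # also seeds the RNG
  opt <- adam_init(params)
  val_pairs <- rbind(split$val_pos, split$val_neg)
  val_labels <- rep(c(1, 0), c(nrow(split$val_pos), nrow(split$val_neg)))
  has_val <- nrow(val_pairs) > 0L
  best_val <- Inf; best_params <- params; best_epoch <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  epochs_since_best <- 0L
  stopped <- config$epochs
  for (epoch in seq_len(config$epochs)) {
    neg <- sample_negative_edges(graph, nrow(split$train_pos), seed = NULL)
    pairs <- rbind(split$train_pos, neg)
    labels <- rep(c(1, 0), c(nrow(split$train_pos), nrow(neg)))
    fwd <- gae_forward(params, features, P, "train", config$dropout)
    fwd$P <- P
    dec <- bce_decoder_grad(fwd$Z, pairs, labels)
    if (!is.finite(dec$loss)) {
      stop(sprintf("training loss diverged (non-finite) at epoch %d", epoch),
           call. = FALSE)
    }
    grads <- gae_backward(params, fwd, dec$grad)
    stepped <- adam_step(params, grads, opt, config$learning_rate,
                         config$weight_decay)
    params <- stepped$params; opt <- stepped$state
    z_eval <- gae_forward(params, features, P, "eval")$Z
    val_loss <- if (has_val) {
      bce_loss(decode_edges(z_eval, val_pairs), val_labels)
    } else dec$loss
    history <- rbind(history, data.frame(epoch = epoch, train_loss = dec$loss,
                                         val_loss = val_loss))
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_params <- params; best_epoch <- epoch
      epochs_since_best <- 0L
    } else {
      epochs_since_best <- epochs_since_best + 1L
      if (epochs_since_best >= config$patience) { stopped <- epoch; break }
    }
  }
  z <- gae_forward(best_params, features, P, "eval")$Z
  rownames(z) <- graph$nodes
  list(params = best_params,
       history = history,
       best_epoch = best_epoch,
       stopped_epoch = stopped,
       embeddings = embedding_matrix(z, "GAE"))
}
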