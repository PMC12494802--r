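#' Hyperparameters for the adversarial embedding generator
#'
#' Defaults match the reference configuration: generator 64 -> 128 -> 64 ->
#' 64 with batch normalization and LeakyReLU (slope 0.2) on hidden layers;
#' discriminator 64 -> 64 -> 32 -> 1 with LeakyReLU (slope 0.2), dropout
#' 0.3 and sigmoid output; Adam at learning rate 2e-4 with betas
#' (0.5, 0.999); 100 epochs, mini-batches of 64; binary cross-entropy with
#' label smoothing targets real = 0.9, fake = 0.1.
#'
#' @param noise_dim,embedding_dim Input noise and output embedding
#'   dimensions (both 64).
#' @param epochs,batch_size Training schedule.
#' @param learning_rate,betas Adam settings shared by both networks.
#' @param label_real,label_fake Smoothed BCE targets.
#' @param dropout Discriminator dropout probability.
#' @param leaky_slope Negative slope of LeakyReLU.
#' @param bn_momentum Batch-norm running-statistics momentum.
#' @param seed Integer seed.
#' @return A list of class \code{gan_config}.
#' @export
gan_config <- function(noise_dim = 64L, embedding_dim = 64L, epochs = 100L,
                       batch_size = 64L, learning_rate = 2e-4,
                       betas = c(0.5, 0.999), label_real = 0.9,
                       label_fake = 0.1, dropout = 0.3, leaky_slope = 0.2,
                       bn_momentum = 0.1, seed = 1L) {
  structure(list(noise_dim = as.integer(noise_dim),
                 embedding_dim = as.integer(embedding_dim),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, betas = betas,
                 label_real = label_real, label_fake = label_fake,
                 dropout = dropout, leaky_slope = leaky_slope,
                 bn_momentum = bn_momentum, seed = as.integer(seed)),
            class = "gan_config")
}

init_generator_params <- function(config) {
  dims <- c(config$noise_dim, 128L, 64L, config$embedding_dim)
  p <- list()
  for (l in 1:3) {
    p[[paste0("W", l)]] <- glorot_uniform(dims[l], dims[l + 1])
    p[[paste0("b", l)]] <- numeric(dims[l + 1])
  }
  for (l in 1:2) { # batch norm on hidden layers only
    p[[paste0("g", l)]] <- rep(1, dims[l + 1])
    p[[paste0("s", l)]] <- numeric(dims[l + 1])
  }
  p
}

init_discriminator_params <- function(config) {
  dims <- c(config$embedding_dim, 64L, 32L, 1L)
  p <- list()
  for (l in 1:3) {
    p[[paste0("W", l)]] <- glorot_uniform(dims[l], dims[l + 1])
    p[[paste0("b", l)]] <- numeric(dims[l + 1])
  }
  p
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)

BN_EPS <- 1e-5

batch_norm_forward <- function(x, gain, shift, running, train, momentum) {
  if (train) {
    if (nrow(x) < 2L) stop("batch norm requires batch size >= 2 in train mode",
                           call. = FALSE)
    mu <- colMeans(x)
    v <- colMeans(sweep(x, 2, mu)^2) # biased batch variance
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
  }
  xhat <- sweep(sweep(x, 2, mu), 2, sqrt(v + BN_EPS), "/")
  out <- sweep(sweep(xhat, 2, gain, "*"), 2, shift, "+")
  list(out = out, xhat = xhat, inv = 1 / sqrt(v + BN_EPS), running = running)
}

batch_norm_backward <- function(dout, cache, gain) {
  xhat <- cache$xhat
  n <- nrow(xhat)
  dxhat <- sweep(dout, 2, gain, "*")
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  # standard batch-norm gradient: inv * (dxhat - mean(dxhat) - xhat * mean(dxhat*xhat))
  dx <- sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, "*")
  dx <- sweep(dx, 2, cache$inv, "*")
  list(dx = dx, dgain = colSums(dout * xhat), dshift = colSums(dout))
}

#' Generator forward pass
#'
#' Maps Gaussian noise to synthetic 64-dimensional embeddings through two
#' hidden layers with batch normalization and LeakyReLU; the output layer is
#' linear. In train mode batch statistics are used (batch size must be at
#' least 2) and running statistics are updated; eval mode uses the frozen
#' running statistics and is deterministic given the noise.
#'
#' @param gen A generator state list (params + running stats), as created
#'   inside [train_gan()].
#' @param noise batch x 64 matrix of standard Gaussian noise.
#' @param mode "train" or "eval".
#' @return batch x 64 matrix of synthetic embeddings (with caches attached
#'   as attributes in train mode for internal use).
#' @export
generator_forward <- function(gen, noise, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  train <- mode == "train"
  p <- gen$params; cfg <- gen$config
  A1 <- noise %*% p$W1 + rep(p$b1, each = nrow(noise))
  bn1 <- batch_norm_forward(A1, p$g1, p$s1, gen$running1, train, cfg$bn_momentum)
  H1 <- leaky_relu(bn1$out, cfg$leaky_slope)
  A2 <- H1 %*% p$W2 + rep(p$b2, each = nrow(noise))
  bn2 <- batch_norm_forward(A2, p$g2, p$s2, gen$running2, train, cfg$bn_momentum)
  H2 <- leaky_relu(bn2$out, cfg$leaky_slope)
  out <- H2 %*% p$W3 + rep(p$b3, each = nrow(noise))
  attr(out, "cache") <- list(noise = noise, A1 = A1, bn1 = bn1, H1 = H1,
                             A2 = A2, bn2 = bn2, H2 = H2)
  out
}

generator_backward <- function(gen, cache, dout) {
  p <- gen$params; slope <- gen$config$leaky_slope
  dW3 <- crossprod(cache$H2, dout); db3 <- colSums(dout)
  dH2 <- dout %*% t(p$W3)
  dbn2 <- dH2 * ifelse(cache$bn2$out > 0, 1, slope)
  bb2 <- batch_norm_backward(dbn2, cache$bn2, p$g2)
  dA2 <- bb2$dx
  dW2 <- crossprod(cache$H1, dA2); db2 <- colSums(dA2)
  dH1 <- dA2 %*% t(p$W2)
  dbn1 <- dH1 * ifelse(cache$bn1$out > 0, 1, slope)
  bb1 <- batch_norm_backward(dbn1, cache$bn1, p$g1)
  dA1 <- bb1$dx
  dW1 <- crossprod(cache$noise, dA1); db1 <- colSums(dA1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3,
       g1 = bb1$dgain, s1 = bb1$dshift, g2 = bb2$dgain, s2 = bb2$dshift)
}

#' Discriminator forward pass
#'
#' Scores 64-dimensional embeddings as real (1) or fake (0) through two
#' LeakyReLU hidden layers with dropout (train mode only) and a sigmoid
#' output.
#'
#' @param disc Discriminator state list (params + config), as created inside
#'   [train_gan()].
#' @param x batch x 64 embedding matrix.
#' @param mode "train" or "eval".
#' @return Probability vector in (0, 1) (cache attached as attribute).
#' @export
discriminator_forward <- function(disc, x, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  p <- disc$params; cfg <- disc$config
  if (ncol(x) != nrow(p$W1)) stop("discriminator input must have 64 columns",
                                  call. = FALSE)
  train <- mode == "train"
  A1 <- x %*% p$W1 + rep(p$b1, each = nrow(x))
  H1 <- leaky_relu(A1, cfg$leaky_slope)
  m1 <- NULL
  if (train && cfg$dropout > 0) {
    m1 <- matrix(stats::runif(length(H1)) >= cfg$dropout, nrow(H1), ncol(H1))
    H1 <- H1 * m1 / (1 - cfg$dropout)
  }
  A2 <- H1 %*% p$W2 + rep(p$b2, each = nrow(x))
  H2 <- leaky_relu(A2, cfg$leaky_slope)
  m2 <- NULL
  if (train && cfg$dropout > 0) {
    m2 <- matrix(stats::runif(length(H2)) >= cfg$dropout, nrow(H2), ncol(H2))
    H2 <- H2 * m2 / (1 - cfg$dropout)
  }
  logit <- drop(H2 %*% p$W3 + p$b3)
  s <- stats::plogis(logit)
  attr(s, "cache") <- list(x = x, A1 = A1, H1 = H1, m1 = m1, A2 = A2, H2 = H2,
                           m2 = m2, logit = logit)
  s
}

# dlogit: gradient of the loss w.r.t. the output logit (length batch).
# Returns gradients for discriminator params and (optionally) the input.
discriminator_backward <- function(disc, cache, dlogit, need_dx = FALSE) {
  p <- disc$params; cfg <- disc$config; slope <- cfg$leaky_slope
  dlogit <- matrix(dlogit, ncol = 1)
  dW3 <- crossprod(cache$H2, dlogit); db3 <- sum(dlogit)
  dH2 <- dlogit %*% t(p$W3)
  if (!is.null(cache$m2)) dH2 <- dH2 * cache$m2 / (1 - cfg$dropout)
  dA2 <- dH2 * ifelse(cache$A2 > 0, 1, slope)
  dW2 <- crossprod(cache$H1, dA2); db2 <- colSums(dA2)
  dH1 <- dA2 %*% t(p$W2)
  if (!is.null(cache$m1)) dH1 <- dH1 * cache$m1 / (1 - cfg$dropout)
  dA1 <- dH1 * ifelse(cache$A1 > 0, 1, slope)
  dW1 <- crossprod(cache$x, dA1); db1 <- colSums(dA1)
  out <- list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                           W3 = dW3, b3 = db3))
  if (need_dx) out$dx <- dA1 %*% t(p$W1)
  out
}

smoothed_bce <- function(scores, target, eps = 1e-12) {
  s <- pmin(pmax(scores, eps), 1 - eps)
  -mean(target * log(s) + (1 - target) * log(1 - s))
}

#' Train the adversarial generator/discriminator on GAE embeddings
#'
#' The GAE node embeddings serve as the "real" sample. Each mini-batch takes
#' one discriminator step (smoothed BCE: real target 0.9, fake target 0.1)
#' followed by one generator step (non-saturating BCE pushing fake scores
#' toward 0.9). Per-epoch history records both losses and the mean
#' discriminator score on real and on freshly generated embeddings
#' (eval-mode scoring).
#'
#' @param real_embeddings n x 64 \code{embedding_matrix} from [train_gae()].
#' @param config A [gan_config()].
#' @return List with \code{generator} and \code{discriminator} state lists
#'   and \code{history} (data frame: epoch, gen_loss, disc_loss, real_score,
#'   fake_score).
#' @export
train_gan <- function(real_embeddings, config = gan_config()) {
  stopifnot(is.matrix(real_embeddings), ncol(real_embeddings) == config$embedding_dim)
  set.seed(config$seed)
  gen <- list(params = init_generator_params(config),
              running1 = list(mean = numeric(128), var = rep(1, 128)),
              running2 = list(mean = numeric(64), var = rep(1, 64)),
              config = config)
  disc <- list(params = init_discriminator_params(config), config = config)
  opt_g <- adam_init(gen$params)
  opt_d <- adam_init(disc$params)
  n <- nrow(real_embeddings)
  real <- unclass(real_embeddings); attr(real, "model_tag") <- NULL
  history <- data.frame(epoch = integer(0), gen_loss = numeric(0),
                        disc_loss = numeric(0), real_score = numeric(0),
                        fake_score = numeric(0))
  wdecay <- c("W1", "W2", "W3")
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(n)
    g_losses <- d_losses <- numeric(0)
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1L, n)]
      if (length(idx) < 2L) next # batch norm needs >= 2 samples
      xb <- real[idx, , drop = FALSE]
      b <- length(idx)
      ## discriminator step
      noise <- matrix(stats::rnorm(b * config$noise_dim), b)
      fake <- generator_forward(gen, noise, "train")
      gen$running1 <- attr(fake, "cache")$bn1$running
      gen$running2 <- attr(fake, "cache")$bn2$running
      s_real <- discriminator_forward(disc, xb, "train")
      s_fake <- discriminator_forward(disc, as.matrix(fake), "train")
      d_loss <- 0.5 * (smoothed_bce(s_real, config$label_real) +
                       smoothed_bce(s_fake, config$label_fake))
      if (!is.finite(d_loss)) stop("discriminator loss non-finite", call. = FALSE)
      # d/dlogit of mean BCE toward target t is (s - t)/b; the 0.5 averages
      # the real and fake halves
      gr <- discriminator_backward(disc, attr(s_real, "cache"),
                                   0.5 * (as.numeric(s_real) - config$label_real) / b)
      gf <- discriminator_backward(disc, attr(s_fake, "cache"),
                                   0.5 * (as.numeric(s_fake) - config$label_fake) / b)
      gd <- mapply(function(a, b) a + b, gr$grads, gf$grads, SIMPLIFY = FALSE)
      st <- adam_step(disc$params, gd, opt_d, config$learning_rate,
                      weight_decay = 0, betas = config$betas,
                      decay_names = wdecay)
      disc$params <- st$params; opt_d <- st$state
      ## generator step (fresh noise, non-saturating toward the real target)
      noise <- matrix(stats::rnorm(b * config$noise_dim), b)
      fake <- generator_forward(gen, noise, "train")
      gcache <- attr(fake, "cache")
      gen$running1 <- gcache$bn1$running
      gen$running2 <- gcache$bn2$running
      s_fake <- discriminator_forward(disc, as.matrix(fake), "train")
      g_loss <- smoothed_bce(s_fake, config$label_real)
      if (!is.finite(g_loss)) stop("generator loss non-finite", call. = FALSE)
      dres <- discriminator_backward(disc, attr(s_fake, "cache"),
                                     (as.numeric(s_fake) - config$label_real) / b,
                                     need_dx = TRUE)
      gg <- generator_backward(gen, gcache, dres$dx)
      st <- adam_step(gen$params, gg, opt_g, config$learning_rate,
                      weight_decay = 0, betas = config$betas,
                      decay_names = wdecay)
      gen$params <- st$params; opt_g <- st$state
      g_losses <- c(g_losses, g_loss); d_losses <- c(d_losses, d_loss)
    }
    ## epoch-level monitoring in eval mode (does not consume training RNG order
    ## beyond the draws made here, which are part of the seeded stream)
    noise <- matrix(stats::rnorm(n * config$noise_dim), n)
    fake_eval <- generator_forward(gen, noise, "eval")
    real_score <- mean(discriminator_forward(disc, real, "eval"))
    fake_score <- mean(discriminator_forward(disc, as.matrix(fake_eval), "eval"))
    history <- rbind(history, data.frame(
      epoch = epoch, gen_loss = mean(g_losses), disc_loss = mean(d_losses),
      real_score = real_score, fake_score = fake_score))
  }
  list(generator = gen, discriminator = disc, history = history)
}

#' Per-node synthetic embeddings from a trained generator
#'
#' The generator is unconditional, so node identity cannot influence its
#' output; row k of the seeded noise batch is assigned to node index k. This
#' is the assignment under which downstream link prediction with generator
#' embeddings is expected to sit near chance.
#'
#' @param gen Trained generator state from [train_gan()].
#' @param n_nodes Number of nodes (rows) to generate.
#' @param seed Integer seed for the noise.
#' @param node_names Optional rownames.
#' @return An \code{embedding_matrix} (tag "GAN") of shape n_nodes x 64.
#' @export
generate_node_embeddings <- function(gen, n_nodes, seed = 1L, node_names = NULL) {
  set.seed(as.integer(seed))
  noise <- matrix(stats::rnorm(n_nodes * gen$config$noise_dim), n_nodes)
  z <- generator_forward(gen, noise, "eval")
  attr(z, "cache") <- NULL
  z <- as.matrix(z)
  if (!is.null(node_names)) rownames(z) <- node_names
  embedding_matrix(z, "GAN")
}
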