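test_that("generator forward is deterministic in eval mode with 64-dim output", {
  cfg <- gan_config(seed = 3)
  set.seed(3)
  gen <- list(params = grnembed:::init_generator_params(cfg),
              running1 = list(mean = numeric(128), var = rep(1, 128)),
              running2 = list(mean = numeric(64), var = rep(1, 64)),
              config = cfg)
  noise <- matrix(rnorm(10 * 64), 10)
  a <- generator_forward(gen, noise, "eval")
  b <- generator_forward(gen, noise, "eval")
  expect_equal(as.matrix(a), as.matrix(b))
  expect_equal(ncol(a), 64L)
  # zero weights in eval mode: output is the final bias everywhere
  gen0 <- gen
  gen0$params <- lapply(gen0$params, function(p) p * 0)
  out0 <- generator_forward(gen0, noise, "eval")
  expect_true(all(abs(out0) < 1e-12))
  # batch of 1 in train mode is an error (batch norm)
  expect_error(generator_forward(gen, noise[1, , drop = FALSE], "train"),
               "batch size")
})

test_that("discriminator outputs probabilities and validates input width", {
  cfg <- gan_config(seed = 4)
  set.seed(4)
  disc <- list(params = grnembed:::init_discriminator_params(cfg), config = cfg)
  x <- matrix(rnorm(20 * 64), 20)
  s <- discriminator_forward(disc, x, "eval")
  expect_true(all(s > 0 & s < 1))
  expect_equal(as.numeric(discriminator_forward(disc, x, "eval")), as.numeric(s))
  disc0 <- disc; disc0$params <- lapply(disc0$params, function(p) p * 0)
  expect_equal(as.numeric(discriminator_forward(disc0, x, "eval")),
               rep(0.5, 20))
  expect_error(discriminator_forward(disc, x[, 1:10], "eval"), "64")
})

test_that("generator/discriminator backward passes match finite differences", {
  cfg <- gan_config(seed = 9, dropout = 0)
  set.seed(9)
  gen <- list(params = grnembed:::init_generator_params(cfg),
              running1 = list(mean = numeric(128), var = rep(1, 128)),
              running2 = list(mean = numeric(64), var = rep(1, 64)),
              config = cfg)
  disc <- list(params = grnembed:::init_discriminator_params(cfg), config = cfg)
  noise <- matrix(rnorm(6 * 64), 6)
  target <- 0.9
  lossfn <- function(gp) {
    g2 <- gen; g2$params <- gp
    fake <- generator_forward(g2, noise, "train")
    s <- discriminator_forward(disc, as.matrix(fake), "eval")
    grnembed:::smoothed_bce(s, target)
  }
  fake <- generator_forward(gen, noise, "train")
  s <- discriminator_forward(disc, as.matrix(fake), "eval")
  dres <- grnembed:::discriminator_backward(disc, attr(s, "cache"),
                                            (as.numeric(s) - target) / 6,
                                            need_dx = TRUE)
  gg <- grnembed:::generator_backward(gen, attr(fake, "cache"), dres$dx)
  h <- 1e-6
  set.seed(10)
  for (nm in c("W1", "b2", "g1", "s2", "W3")) {
    for (k in sample(seq_along(gen$params[[nm]]), 3)) {
      pp <- gen$params; pp[[nm]][k] <- pp[[nm]][k] + h
      pm <- gen$params; pm[[nm]][k] <- pm[[nm]][k] - h
      fd <- (lossfn(pp) - lossfn(pm)) / (2 * h)
      expect_lt(abs(fd - gg[[nm]][k]), 1e-5)
    }
  }
})

test_that("train_gan runs, is reproducible, and keeps scores in bounds", {
  gan <- fixture_trained_gan()
  h <- gan$history
  expect_equal(nrow(h), 100L)
  expect_true(all(h$real_score > 0 & h$real_score < 1))
  expect_true(all(h$fake_score > 0 & h$fake_score < 1))
  # smoothed targets imply an entropy floor on the discriminator loss
  expect_true(all(h$disc_loss[-1] >= 0.3))
  gan2 <- train_gan(fixture_trained_gae()$embeddings, gan_config(seed = 7))
  expect_identical(gan2$history, h)
})

test_that("batch-norm eval mode uses frozen running statistics", {
  gan <- fixture_trained_gan()
  set.seed(12)
  noise <- matrix(rnorm(16 * 64), 16)
  ev <- as.matrix(generator_forward(gan$generator, noise, "eval"))
  set.seed(12)
  tr <- as.matrix(generator_forward(gan$generator, noise, "train"))
  expect_false(isTRUE(all.equal(ev, tr)))
  expect_equal(ev, as.matrix(generator_forward(gan$generator, noise, "eval")))
})

test_that("per-node embeddings are reproducible with the right shape", {
  gan <- fixture_trained_gan()
  z1 <- generate_node_embeddings(gan$generator, 50, seed = 2)
  z2 <- generate_node_embeddings(gan$generator, 50, seed = 2)
  expect_identical(unclass(z1), unclass(z2))
  expect_equal(dim(z1), c(50L, 64L))
  expect_equal(attr(z1, "model_tag"), "GAN")
  expect_false(identical(unclass(z1),
                         unclass(generate_node_embeddings(gan$generator, 50, seed = 3))))
})
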