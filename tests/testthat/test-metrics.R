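test_that("roc_auc equals the pair-counting oracle and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8), c(0.2, 0.1)), 1)
  expect_equal(roc_auc(rep(0.5, 5), rep(0.5, 7)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.4), c(0.5, 0.1)), 0.75)
  expect_error(roc_auc(numeric(0), 1), "nonempty")
  set.seed(14)
  for (i in 1:200) {
    np <- sample(2:12, 1); nn <- sample(2:12, 1)
    pos <- round(runif(np), 2); neg <- round(runif(nn), 2) # rounded: forces ties
    expect_equal(roc_auc(pos, neg), oracle_auc_paircount(pos, neg))
  }
})

test_that("average_precision has its closed-form values", {
  expect_equal(average_precision(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(average_precision(c(0.9, 0.8), c(0, 1)), 0.5)
  set.seed(2)
  s <- runif(50); l <- rbinom(50, 1, 0.4)
  ap <- average_precision(s, l)
  expect_gte(ap, 0); expect_lte(ap, 1)
  expect_error(average_precision(s, rep(0, 50)), "positive")
})

test_that("silhouette matches the brute-force oracle and its limits", {
  set.seed(3)
  # two tight far-apart clusters
  x <- rbind(matrix(rnorm(40, 0, 0.05), 20), matrix(rnorm(40, 10, 0.05), 20))
  lab <- rep(1:2, each = 20)
  expect_gt(silhouette_score(x, lab), 0.9)
  # random labels on structureless points: near zero
  y <- matrix(rnorm(1000), 500, 2)
  expect_lt(abs(silhouette_score(y, sample(1:3, 500, TRUE))), 0.05)
  # oracle agreement on 50-point fixtures, including singleton clusters
  for (s in 1:3) {
    set.seed(s)
    z <- matrix(rnorm(100), 50, 2)
    lz <- c(1, sample(1:4, 49, TRUE))
    expect_equal(silhouette_score(z, lz), oracle_silhouette(z, lz),
                 tolerance = 1e-12)
  }
  expect_error(silhouette_score(x, rep(1, 40)), "two clusters")
})

test_that("kmeans_labels is seeded and recovers separated blobs", {
  set.seed(5)
  blobs <- rbind(matrix(rnorm(60, 0, 1), 30), matrix(rnorm(60, 20, 1), 30),
                 matrix(rnorm(60, -20, 1), 30))
  truth <- rep(1:3, each = 30)
  lab <- kmeans_labels(blobs, 3, seed = 4)
  expect_identical(lab, kmeans_labels(blobs, 3, seed = 4))
  # perfect recovery up to label permutation
  expect_equal(length(unique(paste(truth, lab))), 3L)
  expect_error(kmeans_labels(blobs, 100), "exceed")
})

test_that("neighborhood_preservation matches oracle and construction limits", {
  # complete graph on 6 nodes: every node's 5 graph neighbors are exactly
  # its 5 nearest points under any embedding -> preservation is 1
  syms <- c("A", "B", "C", "D", "E", "F")
  rows <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    rows <- c(rows, paste(syms[i], syms[j], "Unknown", sep = "\t"))
  }
  g <- build_graph(parse_interaction_table(rows))
  set.seed(1)
  x <- matrix(rnorm(12), 6, 2)
  expect_equal(neighborhood_preservation(g, x, k = 5), 1)
  for (s in 1:3) {
    set.seed(s)
    gg <- build_graph(generate_network(network_gen_config(
      n_tf = 8, n_target = 22, n_overlap = 0, n_rows = 40,
      duplicate_fraction = 0.05, n_modules = 2, seed = s)))
    emb <- matrix(rnorm(length(gg$nodes) * 4), ncol = 4)
    expect_equal(neighborhood_preservation(gg, emb, 5),
                 oracle_neighborhood_preservation(gg, emb, 5),
                 tolerance = 1e-12)
  }
  expect_error(neighborhood_preservation(g, x, k = 6), "smaller")
})

test_that("random embeddings give near-chance neighborhood preservation", {
  g <- fixture_small_graph()
  set.seed(77)
  vals <- replicate(5, {
    emb <- matrix(rnorm(200 * 8), 200)
    neighborhood_preservation(g, emb, 5)
  })
  # expectation for random ranking: mean over nodes of deg/(n-1)
  adj <- table(factor(c(g$edges[, 1], g$edges[, 2]), levels = 0:199))
  deg <- as.numeric(adj)  # upper bound on undirected degree (dups negligible)
  expected <- mean(deg[deg > 0] / 199)
  expect_lt(abs(mean(vals) - expected), 0.02)
})

test_that("centrality correlations behave on engineered inputs", {
  # star graph: the hub dominates degree and betweenness
  rows <- paste0("HUB\tL", 1:8, "\tUnknown")
  g <- build_graph(parse_interaction_table(rows))
  # norms exactly proportional to degree -> Pearson 1 on the degree row
  deg <- c(8, rep(1, 8))
  emb <- cbind(deg, 0)
  ct <- centrality_correlations(g, emb)
  expect_equal(ct$pearson[ct$measure == "degree"], 1)
  expect_equal(ct$spearman[ct$measure == "degree"],
               centrality_correlations(g, cbind(deg^3, 0))$spearman[1])
  # constant norms: correlation undefined -> NA
  expect_true(all(is.na(centrality_correlations(g, cbind(rep(2, 9), 0))$pearson)))
})

test_that("KL estimator is nonnegative, zero on identity, and consistent", {
  set.seed(6)
  X <- matrix(rnorm(500 * 3), 500)
  kl0 <- kl_per_dimension(X, X)
  expect_equal(kl0$kl_xy, rep(0, 3), tolerance = 1e-12)
  expect_equal(kl0$mean_kl_sym, 0, tolerance = 1e-12)
  Y <- matrix(rnorm(500 * 3, 2), 500)
  kl <- kl_per_dimension(X, Y)
  expect_true(all(kl$kl_xy >= 0 & kl$kl_yx >= 0))
  # error vs the closed form KL(N(1,1)||N(0,1)) = 0.5 shrinks with n
  e_small <- abs(kl_per_dimension(generate_gaussian_embeddings(1000, 1, 1, seed = 1),
                                  generate_gaussian_embeddings(1000, 1, 0, seed = 2))$mean_kl_xy - 0.5)
  e_big <- abs(kl_per_dimension(generate_gaussian_embeddings(100000, 1, 1, seed = 1),
                                generate_gaussian_embeddings(100000, 1, 0, seed = 2))$mean_kl_xy - 0.5)
  expect_lt(e_big, e_small)
  # degenerate dimension flagged, KL 0 by convention
  Z <- cbind(rep(1, 100))
  klz <- kl_per_dimension(Z, Z)
  expect_true(klz$degenerate[1])
  expect_equal(klz$kl_xy[1], 0)
})

test_that("JS distance is symmetric, bounded, and exact at the extremes", {
  set.seed(8)
  X <- matrix(rnorm(400 * 2), 400)
  expect_equal(jensen_shannon_distance(X, X), 0, tolerance = 1e-10)
  Y <- matrix(rnorm(400 * 2, 1), 400)
  expect_equal(jensen_shannon_distance(X, Y), jensen_shannon_distance(Y, X))
  disjoint <- matrix(runif(400) + 10, 200)
  base <- matrix(runif(400), 200)
  expect_equal(jensen_shannon_distance(base, disjoint), sqrt(log(2)),
               tolerance = 1e-3)
})

test_that("Wasserstein mean has its translation and point-mass values", {
  expect_equal(wasserstein_mean(matrix(rep(2, 10)), matrix(rep(-1.5, 25))), 3.5)
  set.seed(9)
  X <- matrix(rnorm(2000), 1000, 2)
  expect_equal(wasserstein_mean(X, X), 0)
  Y <- X + 0.8   # pure location shift
  expect_equal(wasserstein_mean(X, Y), 0.8, tolerance = 1e-8)
  Z <- matrix(rnorm(2000, 0.8), 1000, 2)
  expect_equal(wasserstein_mean(X, Z), 0.8, tolerance = 0.08)
})

test_that("MMD matches closed forms and the double-loop oracle", {
  x <- matrix(c(0, 0), 1)
  y <- matrix(c(2, 0), 1)      # ||x - y||^2 = 4 = 2 sigma^2 at sigma = sqrt(2)
  got <- mmd_rbf(x, y, sigmas = sqrt(2))
  expect_equal(unname(got), 2 * (1 - exp(-1)), tolerance = 1e-12)
  set.seed(10)
  X <- matrix(rnorm(15 * 3), 15)
  Y <- matrix(rnorm(12 * 3, 1), 12)
  expect_equal(unname(mmd_rbf(X, X, 1)), 0, tolerance = 1e-12)
  for (s in c(0.5, 1, 2)) {
    expect_equal(unname(mmd_rbf(X, Y, s)), oracle_mmd(X, Y, s), tolerance = 1e-12)
  }
  # kernel saturates as sigma grows
  expect_lt(unname(mmd_rbf(X, Y, 1e6)), 1e-8)
  expect_error(mmd_rbf(X, Y, -1), "positive")
})

test_that("regulation_type_scores groups per annotation row", {
  ints <- parse_interaction_table(table1_rows())
  g <- build_graph(ints)
  z0 <- matrix(0, 6, 4)
  rs <- regulation_type_scores(ints, g, z0)
  expect_equal(sum(rs$count), 5L)
  expect_equal(rs$count[rs$regulation == "Unknown"], 3L)
  expect_true(all(rs$mean_score[rs$count > 0] == 0.5))
  expect_true(all(rs$sd_score == 0))
  bad <- ints; bad$tf[1] <- "NOT_A_NODE"
  expect_error(regulation_type_scores(bad, g, z0), "absent")
})

test_that("pca_2d matches the covariance eigendecomposition oracle", {
  set.seed(11)
  X <- matrix(rnorm(20 * 5), 20)
  p <- pca_2d(X)
  ev <- eigen(stats::cov(X) * (19 / 20))  # svd uses 1/n scaling implicitly
  ev_frac <- ev$values / sum(ev$values)
  expect_equal(p$explained_variance, ev_frac[1:2], tolerance = 1e-10)
  # coordinates match up to the documented sign convention
  for (j in 1:2) {
    v <- ev$vectors[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    ref <- scale(X, scale = FALSE) %*% v
    expect_equal(unname(p$coords[, j]), as.numeric(ref), tolerance = 1e-8)
  }
  # collinear points: second component explains ~nothing
  line <- cbind(1:50, 2 * (1:50) + 3)
  expect_lt(pca_2d(line)$explained_variance[2], 1e-12)
})
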