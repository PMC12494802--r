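# Shared fixtures. Training runs are cached in this environment so the
# expensive objects are built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

table1_rows <- function() {
  c("AHR\tIL13\tUnknown\t22981205",
    "AHR\tIL1B\tUnknown\t23349129",
    "AHR\tIL6\tActivation\t20511231",
    "AHR\tIL6\tUnknown\t18483242; 23349129",
    "AIP\tNFKB2\tRepression\t21984905")
}

fixture_small_graph <- function() {
  if (is.null(.fixture_cache$graph)) {
    .fixture_cache$graph <- build_graph(generate_network(small_network_config(seed = 1)))
  }
  .fixture_cache$graph
}

fixture_trained_gae <- function() {
  if (is.null(.fixture_cache$gae)) {
    g <- fixture_small_graph()
    sp <- split_edges(g, seed = 1)
    .fixture_cache$gae_split <- sp
    .fixture_cache$gae <- train_gae(g, split = sp, config = gae_config(seed = 101))
  }
  .fixture_cache$gae
}

fixture_gae_split <- function() {
  fixture_trained_gae()
  .fixture_cache$gae_split
}

fixture_trained_gan <- function() {
  if (is.null(.fixture_cache$gan)) {
    .fixture_cache$gan <- train_gan(fixture_trained_gae()$embeddings,
                                    gan_config(seed = 7))
  }
  .fixture_cache$gan
}

# 5-seed GAE/GAN comparison used by both the module directional tests and
# the acceptance criteria; cached because it is the slowest block.
fixture_multiseed_comparison <- function() {
  if (is.null(.fixture_cache$multiseed)) {
    g <- fixture_small_graph()
    neg_eval <- sample_negative_edges(g, nrow(g$edges), seed = 900)
    rows <- lapply(1:5, function(s) {
      sp <- split_edges(g, seed = s)
      gae <- train_gae(g, split = sp, config = gae_config(seed = s + 100))
      gan <- train_gan(gae$embeddings, gan_config(seed = s + 200))
      z_gan <- generate_node_embeddings(gan$generator, nrow(gae$embeddings),
                                        seed = s + 300)
      q_gae <- embedding_quality(g, gae$embeddings, seed = s)
      q_gan <- embedding_quality(g, z_gan, seed = s)
      data.frame(
        seed = s,
        recon_auc = roc_auc(decode_edges(gae$embeddings, g$edges),
                            decode_edges(gae$embeddings, neg_eval)),
        gan_test_auc = link_prediction_result(z_gan, sp$test_pos, sp$test_neg)$auc,
        gan_recon_auc = roc_auc(decode_edges(z_gan, g$edges),
                                decode_edges(z_gan, neg_eval)),
        gae_sil = q_gae$silhouette, gan_sil = q_gan$silhouette,
        gae_np = q_gae$neighborhood_preservation,
        gan_np = q_gan$neighborhood_preservation,
        gae_degree_pearson = centrality_correlations(g, gae$embeddings)$pearson[1],
        gan_degree_pearson = centrality_correlations(g, z_gan)$pearson[1]
      )
    })
    .fixture_cache$multiseed <- do.call(rbind, rows)
  }
  .fixture_cache$multiseed
}
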