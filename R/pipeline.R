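#' Full run configuration
#'
#' Bundles every stage's settings with the reference defaults. Per-stage
#' seeds are derived deterministically from the master seed and the stage
#' name so any stage can be rerun in isolation.
#'
#' @param input Either \code{NULL} (use the synthetic generator), a path to
#'   a TRRUST-layout TSV, or a \code{regulatory_interactions} data frame.
#' @param network A [network_gen_config()] used when \code{input} is NULL
#'   (its seed is overridden by the derived stage seed).
#' @param test_frac,val_frac_of_train Edge-split fractions.
#' @param gae A [gae_config()].
#' @param gan A [gan_config()].
#' @param circuit A [circuit_spec()].
#' @param metric_k Neighborhood-preservation k.
#' @param kmeans_k Clusters for silhouette labels.
#' @param bins Histogram bins for KL/JS.
#' @param sigmas MMD bandwidth grid.
#' @param seed Master seed.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(input = NULL,
                       network = network_gen_config(),
                       test_frac = 0.2, val_frac_of_train = 0.1,
                       gae = gae_config(), gan = gan_config(),
                       circuit = circuit_spec(),
                       metric_k = 5L, kmeans_k = 5L, bins = 50L,
                       sigmas = c(0.1, 0.5, 1.0, 2.0, 5.0),
                       seed = 1L) {
  structure(list(input = input, network = network, test_frac = test_frac,
                 val_frac_of_train = val_frac_of_train, gae = gae, gan = gan,
                 circuit = circuit, metric_k = as.integer(metric_k),
                 kmeans_k = as.integer(kmeans_k), bins = as.integer(bins),
                 sigmas = sigmas, seed = as.integer(seed)),
            class = "run_config")
}

#' Derive a per-stage seed from the master seed
#'
#' Deterministic 31-bit hash of (master seed, stage name); stable across
#' platforms and R sessions, so any stage can be reproduced without
#' rerunning the whole pipeline.
#'
#' @param master_seed Integer master seed.
#' @param stage Stage name string.
#' @return Integer in [1, 2^31 - 2].
#' @export
stage_seed <- function(master_seed, stage) {
  h <- as.double(master_seed) %% 2147483647
  for (code in utf8ToInt(stage)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h + 1)
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[grnembed] %s %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

with_stage <- function(stage, verbose, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
  })
  pipeline_log(verbose, "stage %-18s done in %.2fs", stage,
               proc.time()[["elapsed"]] - t0)
  out
}

#' Run the full GAE / GAN / quantum comparison
#'
#' Stages, in order: load or generate the interaction table; build the
#' directed graph; split edges 80/20 with validation carved from training;
#' train the graph autoencoder; train the adversarial pair on its
#' embeddings; draw per-node generator embeddings; compute quantum features
#' from the GAE embeddings; run the metric battery (link prediction on both
#' held-out and all-edge reconstruction, embedding quality, centrality
#' correlations, divergences between GAE and GAN embedding distributions,
#' regulation-type scores, 2D PCA). All randomness flows from per-stage
#' seeds derived from \code{config$seed}.
#'
#' @param config A [run_config()].
#' @param verbose Log stage timings to stderr.
#' @return An \code{evaluation_report} list; see the serialized JSON layout
#'   in [write_report()].
#' @export
run_comparison <- function(config = run_config(), verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  interactions <- with_stage("load_data", verbose, {
    if (is.null(config$input)) {
      netcfg <- config$network
      netcfg$seed <- stage_seed(config$seed, "generate_network")
      generate_network(netcfg)
    } else if (is.character(config$input)) {
      parse_interaction_table(config$input)
    } else {
      config$input
    }
  })
  graph <- with_stage("build_graph", verbose, build_graph(interactions))
  split <- with_stage("split_edges", verbose,
    split_edges(graph, config$test_frac, config$val_frac_of_train,
                seed = stage_seed(config$seed, "split_edges")))
  gae_cfg <- config$gae
  gae_cfg$seed <- stage_seed(config$seed, "train_gae")
  gae_fit <- with_stage("train_gae", verbose,
    train_gae(graph, one_hot_features(graph), split, gae_cfg))
  gan_cfg <- config$gan
  gan_cfg$seed <- stage_seed(config$seed, "train_gan")
  gan_fit <- with_stage("train_gan", verbose,
    train_gan(gae_fit$embeddings, gan_cfg))
  z_gae <- gae_fit$embeddings
  z_gan <- with_stage("gan_embeddings", verbose,
    generate_node_embeddings(gan_fit$generator, n_nodes(graph),
                             seed = stage_seed(config$seed, "gan_embeddings"),
                             node_names = graph$nodes))
  z_q <- with_stage("quantum_features", verbose,
    quantum_feature_matrix(z_gae, config$circuit))
  report <- with_stage("metrics", verbose, {
    mseed <- stage_seed(config$seed, "metrics")
    all_pos <- graph$edges
    all_neg <- sample_negative_edges(graph, nrow(all_pos), seed = mseed)
    lp <- function(z) list(
      test = link_prediction_result(z, split$test_pos, split$test_neg),
      reconstruction = link_prediction_result(z, all_pos, all_neg))
    quality <- function(z) embedding_quality(graph, z, config$metric_k,
                                             config$kmeans_k, seed = mseed)
    kl <- kl_per_dimension(z_gae, z_gan, config$bins)
    list(
      dataset = summary(graph),
      link_prediction = list(GAE = lp(z_gae), GAN = lp(z_gan)),
      embedding_quality = list(GAE = quality(z_gae), GAN = quality(z_gan),
                               QUANTUM = quality(z_q)),
      centrality = list(GAE = centrality_correlations(graph, z_gae),
                        GAN = centrality_correlations(graph, z_gan),
                        QUANTUM = centrality_correlations(graph, z_q)),
      divergence = list(
        kl = kl,
        jensen_shannon_distance = jensen_shannon_distance(z_gae, z_gan, config$bins),
        wasserstein_mean = wasserstein_mean(z_gae, z_gan),
        mmd = mmd_rbf(z_gae, z_gan, config$sigmas),
        log_base = "natural"),
      regulation_scores = list(
        GAE = regulation_type_scores(interactions, graph, z_gae),
        GAN = regulation_type_scores(interactions, graph, z_gan)),
      pca = list(GAE = pca_2d(z_gae), GAN = pca_2d(z_gan))
    )
  })
  report$histories <- list(gae = gae_fit$history, gan = gan_fit$history)
  report$provenance <- list(seed = config$seed,
                            gae_best_epoch = gae_fit$best_epoch,
                            gae_stopped_epoch = gae_fit$stopped_epoch,
                            package_version = as.character(utils::packageVersion("grnembed")))
  report$embeddings <- list(GAE = z_gae, GAN = z_gan, QUANTUM = z_q)
  report$graph <- graph
  class(report) <- "evaluation_report"
  report
}

strip_for_json <- function(report) {
  r <- unclass(report)
  r$embeddings <- NULL
  r$graph <- NULL
  r$link_prediction <- lapply(r$link_prediction, function(m)
    lapply(m, function(e) list(auc = e$auc, average_precision = e$average_precision)))
  r$embedding_quality <- lapply(r$embedding_quality, function(q)
    q[c("silhouette", "neighborhood_preservation", "k")])
  r
}

#' Serialize an evaluation report
#'
#' Writes the metric portion of the report (no embedding matrices) as
#' pretty-printed JSON; optionally exports embeddings as TSV and histories
#' as CSV next to it.
#'
#' @param report An \code{evaluation_report} from [run_comparison()].
#' @param path Output JSON path.
#' @param export_tables Also write embeddings/histories beside \code{path}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path, export_tables = FALSE) {
  jsonlite::write_json(strip_for_json(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  if (export_tables) {
    base <- sub("\\.json$", "", path)
    for (tag in names(report$embeddings)) {
      z <- report$embeddings[[tag]]
      df <- data.frame(node = rownames(z) %||% seq_len(nrow(z)),
                       unclass(z), check.names = FALSE)
      utils::write.table(df, paste0(base, "_", tolower(tag), "_embeddings.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.csv(report$histories$gae, paste0(base, "_gae_history.csv"),
                     row.names = FALSE)
    utils::write.csv(report$histories$gan, paste0(base, "_gan_history.csv"),
                     row.names = FALSE)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.evaluation_report <- function(x, ...) {
  ds <- x$dataset
  cat(sprintf("evaluation_report: %d nodes, %d unique edges, %d annotation rows\n",
              ds$n_nodes, ds$n_edges, ds$n_rows))
  for (m in names(x$link_prediction)) {
    lp <- x$link_prediction[[m]]
    cat(sprintf("  %-7s test AUC %.3f AP %.3f | reconstruction AUC %.3f AP %.3f\n",
                m, lp$test$auc, lp$test$average_precision,
                lp$reconstruction$auc, lp$reconstruction$average_precision))
  }
  for (m in names(x$embedding_quality)) {
    q <- x$embedding_quality[[m]]
    cat(sprintf("  %-7s silhouette %.3f | neighborhood@%d %.3f\n",
                m, q$silhouette, q$k, q$neighborhood_preservation))
  }
  dv <- x$divergence
  cat(sprintf("  divergence GAE vs GAN: sym KL %.3f | JS dist %.3f | W1 %.3f\n",
              dv$kl$mean_kl_sym, dv$jensen_shannon_distance, dv$wasserstein_mean))
  invisible(x)
}
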