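#' Configuration for the synthetic regulatory-network generator
#'
#' The defaults emulate the statistical shape of a curated human TF-target
#' interaction extract: 231 regulators and 536 targets with a partial overlap
#' giving 706 distinct symbols, 1454 annotation rows collapsing to roughly
#' 1207 unique directed edges, heavy-tailed regulator out-degree, and
#' regulation labels distributed Unknown/Activation/Repression as
#' 659/532/263 of the rows. Planted modules (default 5 communities with 80%
#' within-module edge retention) give clustering and neighborhood metrics a
#' recoverable signal.
#'
#' @param n_tf Number of regulator symbols.
#' @param n_target Number of target symbols.
#' @param n_overlap Number of symbols acting as both regulator and target
#'   (total nodes = n_tf + n_target - n_overlap).
#' @param n_rows Number of annotation rows to emit.
#' @param duplicate_fraction Fraction of rows that repeat an already emitted
#'   (tf, target) pair, in [0, 1).
#' @param out_degree_exponent Positive power-law exponent for regulator
#'   out-degree propensities (larger = heavier concentration on hubs).
#' @param n_modules Number of planted communities.
#' @param within_module_prob Probability that an edge's target is drawn from
#'   the TF's own module.
#' @param regulation_probs Length-3 probability vector over
#'   (Unknown, Activation, Repression); must sum to 1.
#' @param seed Integer seed; the generator is bit-reproducible under it.
#' @return A list of class \code{network_gen_config}.
#' @export
network_gen_config <- function(n_tf = 231L, n_target = 536L, n_overlap = 61L,
                               n_rows = 1454L, duplicate_fraction = 0.17,
                               out_degree_exponent = 1.8, n_modules = 5L,
                               within_module_prob = 0.8,
                               regulation_probs = c(659, 532, 263) / 1454,
                               seed = 1L) {
  stopifnot(n_tf >= 1, n_target >= 1, n_overlap >= 0,
            n_overlap <= min(n_tf, n_target),
            n_rows >= 1, duplicate_fraction >= 0, duplicate_fraction < 1,
            out_degree_exponent > 0, n_modules >= 1,
            within_module_prob >= 0, within_module_prob <= 1,
            length(regulation_probs) == 3L, all(regulation_probs >= 0),
            abs(sum(regulation_probs) - 1) < 1e-8)
  structure(list(
    n_tf = as.integer(n_tf), n_target = as.integer(n_target),
    n_overlap = as.integer(n_overlap), n_rows = as.integer(n_rows),
    duplicate_fraction = duplicate_fraction,
    out_degree_exponent = out_degree_exponent,
    n_modules = as.integer(n_modules),
    within_module_prob = within_module_prob,
    regulation_probs = regulation_probs,
    seed = as.integer(seed)
  ), class = "network_gen_config")
}

# Symbols: TFs are TF0001..; pure targets are G0001..; overlap symbols are
# TFs that also appear as targets.
synthetic_symbols <- function(config) {
  tf <- sprintf("TF%04d", seq_len(config$n_tf))
  pure_targets <- sprintf("G%04d", seq_len(config$n_target - config$n_overlap))
  overlap <- tf[seq_len(config$n_overlap)]
  list(tf = tf, targets = c(overlap, pure_targets))
}

# Deterministic internals shared by generate_network() and
# planted_partition_labels(): module assignment and out-degree propensities
# are drawn first, from the config seed, so both entry points agree.
synthetic_network_state <- function(config) {
  set.seed(config$seed)
  sym <- synthetic_symbols(config)
  n_tf <- config$n_tf
  n_tgt <- length(sym$targets)
  tf_module <- sample.int(config$n_modules, n_tf, replace = TRUE)
  tgt_module <- sample.int(config$n_modules, n_tgt, replace = TRUE)
  # overlap symbols (the first n_overlap targets are TF symbols) belong to
  # a single community: their target-side module is their TF module
  if (config$n_overlap > 0L) {
    tgt_module[seq_len(config$n_overlap)] <- tf_module[seq_len(config$n_overlap)]
  }
  # heavy-tailed out-degree propensity: Pareto(alpha) weights via inverse CDF,
  # tail index = out_degree_exponent (smaller exponent => heavier hubs)
  w <- stats::runif(n_tf)^(-1 / config$out_degree_exponent)
  w <- w / sum(w)
  list(sym = sym, tf_module = tf_module, tgt_module = tgt_module, tf_weight = w)
}

#' Generate a synthetic TRRUST-like interaction table
#'
#' Draws annotation rows one at a time: a regulator is chosen with
#' heavy-tailed propensity, its target comes from the regulator's planted
#' module with probability \code{within_module_prob} (uniformly otherwise),
#' and the regulation label is i.i.d. from \code{regulation_probs}. After the
#' first row, each subsequent row is an exact duplicate of an earlier (tf,
#' target) pair with probability \code{duplicate_fraction}, which reproduces
#' the rows-vs-unique-edges gap seen in curated databases. Each row gets a
#' synthetic 8-digit PubMed id.
#'
#' @param config A [network_gen_config()].
#' @return A \code{regulatory_interactions} data frame with
#'   \code{config$n_rows} rows, bit-identical under the same seed.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "network_gen_config"))
  state <- synthetic_network_state(config)
  sym <- state$sym
  n_tf <- config$n_tf
  n_tgt <- length(sym$targets)
  n_unique_demand <- config$n_rows - round(config$duplicate_fraction * config$n_rows)
  if (n_tf * n_tgt < n_unique_demand) {
    stop("infeasible config: more unique edges demanded than (tf, target) pairs exist",
         call. = FALSE)
  }
  tgt_by_module <- split(seq_len(n_tgt), state$tgt_module)
  tf_by_module <- split(seq_len(n_tf), state$tf_module)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  pair_tf <- integer(0); pair_tgt <- integer(0)
  remember <- function(ti, gi) {
    key <- paste0(ti, "_", gi)
    if (!is.null(seen[[key]])) return(FALSE)
    seen[[key]] <- TRUE
    pair_tf[length(pair_tf) + 1L] <<- ti
    pair_tgt[length(pair_tgt) + 1L] <<- gi
    TRUE
  }
  draw_tf_for_target <- function(gi) {
    mod <- state$tgt_module[gi]
    pool <- tf_by_module[[as.character(mod)]]
    for (attempt in 1:400) {
      ti <- if (attempt <= 200L && length(pool) > 0L &&
                stats::runif(1) < config$within_module_prob) {
        pool[sample.int(length(pool), 1L,
                        prob = state$tf_weight[pool] / sum(state$tf_weight[pool]))]
      } else if (attempt <= 200L) {
        sample.int(n_tf, 1L, prob = state$tf_weight)
      } else sample.int(n_tf, 1L)
      if (!identical(sym$tf[ti], sym$targets[gi]) && remember(ti, gi)) return(ti)
    }
    stop("could not cover a target symbol; config too dense", call. = FALSE)
  }
  draw_target_for_tf <- function(ti) {
    mod <- state$tf_module[ti]
    pool <- tgt_by_module[[as.character(mod)]]
    for (attempt in 1:10000) {
      gi <- if (attempt <= 200L && length(pool) > 0L &&
                stats::runif(1) < config$within_module_prob) {
        pool[sample.int(length(pool), 1L)]
      } else sample.int(n_tgt, 1L)
      if (!identical(sym$tf[ti], sym$targets[gi]) && remember(ti, gi)) return(gi)
    }
    stop("could not find an unseen (tf, target) pair; config too dense", call. = FALSE)
  }
  # fill-phase sampler: hub-weighted at first, but a saturated hub (all its
  # feasible targets already used) falls back to uniform joint redraws
  draw_phase2_pair <- function() {
    for (attempt in 1:10000) {
      if (attempt <= 200L) {
        ti <- sample.int(n_tf, 1L, prob = state$tf_weight)
        pool <- tgt_by_module[[as.character(state$tf_module[ti])]]
        gi <- if (length(pool) > 0L && stats::runif(1) < config$within_module_prob) {
          pool[sample.int(length(pool), 1L)]
        } else sample.int(n_tgt, 1L)
      } else {
        ti <- sample.int(n_tf, 1L)
        gi <- sample.int(n_tgt, 1L)
      }
      if (!identical(sym$tf[ti], sym$targets[gi]) && remember(ti, gi)) {
        return(c(ti, gi))
      }
    }
    stop("could not find an unseen (tf, target) pair; config too dense", call. = FALSE)
  }
  ## phase 1 -- coverage: every target symbol receives at least one edge and
  ## every regulator emits at least one, so the node roster is fixed by the
  ## config (n_tf + n_target - n_overlap nodes), matching the curated-extract
  ## bookkeeping where symbol counts are properties of the dataset itself.
  rows_tf <- integer(0); rows_tgt <- integer(0)
  for (gi in sample.int(n_tgt)) {
    ti <- draw_tf_for_target(gi)
    rows_tf <- c(rows_tf, ti); rows_tgt <- c(rows_tgt, gi)
  }
  uncovered <- setdiff(seq_len(n_tf), unique(rows_tf))
  for (ti in uncovered) {
    gi <- draw_target_for_tf(ti)
    rows_tf <- c(rows_tf, ti); rows_tgt <- c(rows_tgt, gi)
  }
  n_cov <- length(rows_tf)
  if (n_cov > config$n_rows) {
    stop(sprintf("n_rows (%d) too small to cover all %d symbols at least once",
                 config$n_rows, n_tf + n_tgt), call. = FALSE)
  }
  ## phase 2 -- remaining rows: hub-weighted unique pairs, with duplicates of
  ## already-emitted pairs injected so the overall duplicate budget
  ## round(duplicate_fraction * n_rows) is met in expectation.
  n_left <- config$n_rows - n_cov
  n_dup_target <- min(round(config$duplicate_fraction * config$n_rows), n_left)
  dup_prob <- if (n_left > 0) n_dup_target / n_left else 0
  for (r in seq_len(n_left)) {
    if (stats::runif(1) < dup_prob) {
      k <- sample.int(length(pair_tf), 1L)
      rows_tf <- c(rows_tf, pair_tf[k]); rows_tgt <- c(rows_tgt, pair_tgt[k])
    } else {
      pr <- draw_phase2_pair()
      rows_tf <- c(rows_tf, pr[1]); rows_tgt <- c(rows_tgt, pr[2])
    }
  }
  ord <- sample.int(config$n_rows)   # interleave phases in the emitted table
  rows_tf <- rows_tf[ord]; rows_tgt <- rows_tgt[ord]
  reg <- REGULATION_LEVELS[
    sample.int(3L, config$n_rows, replace = TRUE, prob = config$regulation_probs)]
  pmids <- as.list(sprintf("%08d", sample.int(89999999L, config$n_rows, replace = TRUE) + 10000000L))
  new_interactions(sym$tf[rows_tf], sym$targets[rows_tgt], reg, pmids)
}

#' Test-scale synthetic network configuration
#'
#' A 200-node fixture obtained by scaling every count of the full-scale
#' default by 200/706, preserving the emulated network's composition and
#' mean degree: 65 regulators, 152 targets, 17 overlapping symbols (200
#' nodes), 412 annotation rows collapsing to roughly 345 unique directed
#' edges, 5 planted modules. A full training plus evaluation round on it
#' completes in seconds; used throughout the test suite.
#'
#' @param seed Integer seed.
#' @param ... Overrides forwarded to [network_gen_config()].
#' @return A \code{network_gen_config}.
#' @export
small_network_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(n_tf = 65L, n_target = 152L, n_overlap = 17L, n_rows = 412L,
         duplicate_fraction = 0.17, n_modules = 5L, within_module_prob = 0.8,
         seed = seed),
    list(...))
  do.call(network_gen_config, args)
}

#' Planted module labels for a generated network
#'
#' Returns the community assignment used while generating edges, keyed by
#' node symbol, for the graph built from [generate_network()] with the same
#' config. TF symbols carry their TF-module id; pure target symbols carry
#' their target-module id.
#'
#' @param config The same [network_gen_config()] passed to
#'   [generate_network()].
#' @return Named integer vector (symbol -> module id in 1..n_modules).
#' @export
planted_partition_labels <- function(config) {
  stopifnot(inherits(config, "network_gen_config"))
  state <- synthetic_network_state(config)
  sym <- state$sym
  labels <- c(stats::setNames(state$tf_module, sym$tf),
              stats::setNames(state$tgt_module, sym$targets))
  labels[!duplicated(names(labels))] # overlap symbols keep their TF module
}

#' Gaussian embedding samples for metric validation
#'
#' Fixture generator for the divergence estimators: an n x d matrix with
#' independent Gaussian columns of given means and standard deviations.
#'
#' @param n Sample size.
#' @param d Dimension.
#' @param mean Scalar or length-d mean vector.
#' @param scale Scalar or length-d positive standard deviations.
#' @param seed Integer seed.
#' @return An n x d numeric matrix, deterministic under the seed.
#' @export
generate_gaussian_embeddings <- function(n, d, mean = 0, scale = 1, seed = 1L) {
  stopifnot(n >= 1, d >= 1, all(scale > 0))
  mean <- rep_len(mean, d); scale <- rep_len(scale, d)
  set.seed(as.integer(seed))
  z <- matrix(stats::rnorm(n * d), n, d)
  sweep(sweep(z, 2, scale, "*"), 2, mean, "+")
}
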