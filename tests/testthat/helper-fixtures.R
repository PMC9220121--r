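# Shared fixtures, built lazily once per test run.

.fx <- new.env(parent = emptyenv())

# Small two-domain datasets for unit tests (fast).
fx_small <- function() {
  if (is.null(.fx$small)) {
    .fx$small <- list(
      source = generate_domain(domain_config("source", n_scenes = 30,
                                             seed = 401L)),
      target = generate_domain(domain_config("target", n_scenes = 12,
                                             seed = 402L)))
  }
  .fx$small
}

# A tiny trained-enough FEN over the small source domain (for graph tests).
fx_small_fen <- function() {
  if (is.null(.fx$fen)) {
    ds <- fx_small()
    crops <- scene_crops(ds$source, 16L)
    fen <- build_backbone(
      fen_config(n_classes = 9, stage_channels = c(4L, 8L),
                 blocks_per_stage = c(1L, 1L), input_size = 16L,
                 cbs = list(kind = "e_cbs", sigma0 = 1)),
      classes = ds$source$class_vocabulary, seed = 11L)
    .fx$fen <- train_classifier(fen, crops$crops, crops$labels, epochs = 2L,
                                seed = 12L)
  }
  .fx$fen
}

fx_small_table <- function() {
  if (is.null(.fx$table)) {
    .fx$table <- make_embedding_table(
      surgical_vocabulary("target"), dim = 32L, seed = 7L)
  }
  .fx$table
}

# Full desk-scale study fixture: 200 source / 50 target scenes, trained
# 9-class FEN, incrementally extended 11-class FEN, and graph embeddings of
# both domains. Built once; used by the end-to-end acceptance checks.
fx_protocol <- function() {
  if (is.null(.fx$protocol)) {
    cfg <- experiment_config("desk_scale", seed = 1L)
    datasets <- surgraph:::protocol_datasets(cfg)
    fens <- surgraph:::protocol_fen(cfg, datasets)
    table <- make_embedding_table(datasets$target$class_vocabulary,
                                  dim = cfg$embedding_dim,
                                  seed = surgraph:::derive_seed(cfg$seed, "emb"))
    .fx$protocol <- list(
      cfg = cfg, datasets = datasets, fens = fens, table = table,
      emb_src = embed_dataset(datasets$source, fens$fen11, table),
      emb_tgt = embed_dataset(datasets$target, fens$fen11, table))
  }
  .fx$protocol
}

# Random scene embedding in the graph's input format (for fuzz/grad tests).
random_embedding <- function(n_nodes, dv = 10L, ds = 6L) {
  k <- n_nodes - 1L
  list(V = matrix(rnorm(dv * n_nodes), dv),
       S = matrix(rnorm(ds * n_nodes), ds),
       pairs = if (k > 0) cbind(rep(1L, k), 1L + seq_len(k))
               else matrix(integer(), 0L, 2L),
       Fsp = matrix(rnorm(14L * max(k, 0L)), 14L),
       labels = {
         m <- matrix(0L, 13L, max(k, 0L))
         if (k > 0) m[cbind(sample.int(13L, k, replace = TRUE), seq_len(k))] <- 1L
         m
       },
       n = n_nodes)
}

# Synthetic over-confident classifier: labels drawn from the softmax of
# moderate logits (calibrated by construction), then logits scaled by 5.
overconfident_fixture <- function(n = 4000L, K = 13L, seed = 77L) {
  surgraph:::with_seed(seed, {
    logits <- matrix(rnorm(K * n, sd = 1.5), K, n)
    p <- exp(logits) / rep(colSums(exp(logits)), each = K)
    labels <- vapply(seq_len(n), function(i)
      sample.int(K, 1L, prob = p[, i]), 0L)
    list(logits = logits * 5, labels = labels)
  })
}
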