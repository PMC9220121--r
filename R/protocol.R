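# Experiment orchestration: configuration presets, the end-to-end protocol
# (simulate -> train FEN -> extend FEN -> train teacher -> domain
# generalize -> evaluate), and the multi-seed retention experiment comparing
# incremental DG against the naive baselines.

#' Experiment configuration presets
#'
#' `desk_scale` (default) runs the whole pipeline in minutes on one CPU:
#' 200 source / 50 target scenes at 128 x 128, a small residual FEN
#' (stages 8/16, 24 x 24 crops), 32-dim word embeddings, and a shortened DG
#' schedule (n = 40, 120 main epochs at Adam 1e-3, 15 fine-tune epochs at
#' 1e-4). `paper_scale` mirrors the full-scale settings (1560/143 scenes at
#' 1280 x 1024, ResNet18-dimension FEN on 224 x 224 crops, 300-dim
#' embeddings, n = 143, 250 epochs at 1e-5, 80 fine-tune epochs at 1e-6) and
#' is provided for completeness; [run_protocol()] warns about its compute
#' cost.
#'
#' @param preset `"desk_scale"` or `"paper_scale"`.
#' @param seed Master seed; every stage derives its own stream from it.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(preset = c("desk_scale", "paper_scale"),
                              seed = 1L) {
  preset <- match.arg(preset)
  seed <- as.integer(seed)
  cfg <- if (preset == "desk_scale") {
    list(
      preset = preset, seed = seed,
      scenes = list(n_source = 200L, n_target = 50L,
                    width = 128L, height = 128L, longtail_exponent = 1.5),
      fen = list(stage_channels = c(8L, 16L), blocks_per_stage = c(1L, 1L),
                 input_size = 24L, epochs = 12L, batch = 20L, lr0 = 5e-3,
                 cbs = list(kind = "e_cbs", sigma0 = 1, decay = 0.9,
                            period = 5L),
                 tnorm = 3, label_smoothing = 0,
                 il = list(memory = 50L, epochs = 6L, finetune_epochs = 15L,
                           lr = 5e-4, distill_weight = 1, distill_temp = 2)),
      embedding_dim = 32L,
      graph = list(hidden_dim = 32L, readout_hidden = 64L, tnorm = 1.5,
                   ecbs = list(enabled = TRUE, sigma0 = 1, decay = 0.985,
                               period = 20L)),
      dg = dg_config(n_sample = 40L, kd_weight = 0.5, lr_main = 1e-3,
                     lr_finetune = 1e-4, epochs_main = 120L,
                     epochs_finetune = 15L, batch = 16L, seed = seed))
  } else {
    list(
      preset = preset, seed = seed,
      scenes = list(n_source = 1560L, n_target = 143L,
                    width = 1280L, height = 1024L, longtail_exponent = 1.5),
      fen = list(stage_channels = c(64L, 128L, 256L, 512L),
                 blocks_per_stage = c(2L, 2L, 2L, 2L),
                 input_size = 224L, epochs = 30L, batch = 20L, lr0 = 1e-3,
                 cbs = list(kind = "e_cbs", sigma0 = 1, decay = 0.9,
                            period = 5L),
                 tnorm = 3, label_smoothing = 0,
                 il = list(memory = 50L, epochs = 30L, finetune_epochs = 15L,
                           lr = 5e-4, distill_weight = 1, distill_temp = 2)),
      embedding_dim = 300L,
      graph = list(hidden_dim = 128L, readout_hidden = 256L, tnorm = 1.5,
                   ecbs = list(enabled = TRUE, sigma0 = 1, decay = 0.985,
                               period = 20L)),
      dg = dg_config(seed = seed))
  }
  structure(cfg, class = "experiment_config")
}

#' Validate an experiment configuration
#'
#' Schema check run before any compute: required sections, types and value
#' ranges. Called by [run_protocol()]; exported for config files loaded from
#' YAML.
#'
#' @param config An `experiment_config` (or a compatible list).
#' @return The config, invisibly; errors with a message on violation.
#' @export
validate_experiment_config <- function(config) {
  for (key in c("preset", "seed", "scenes", "fen", "embedding_dim",
                "graph", "dg")) {
    stop_if(is.null(config[[key]]), "experiment config is missing '", key, "'")
  }
  sc <- config$scenes
  stop_if(!is_count(sc$n_source) || !is_count(sc$n_target),
          "scene counts must be positive integers")
  stop_if(!is_count(config$embedding_dim) || config$embedding_dim < 8,
          "embedding_dim must be an integer >= 8")
  stop_if(!inherits(config$dg, "dg_config") && !is.list(config$dg),
          "dg section must be a dg_config")
  stop_if(config$dg$n_sample > sc$n_source,
          "dg n_sample exceeds the source dataset size")
  invisible(config)
}

#' Load an experiment configuration from YAML
#'
#' Reads a preset name plus overrides: top-level `preset` and `seed`, and any
#' of the nested sections, which are merged over the preset defaults.
#'
#' @param path YAML file.
#' @return A validated `experiment_config`.
#' @export
load_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- experiment_config(y$preset %||% "desk_scale", y$seed %||% 1L)
  for (key in intersect(names(y), c("scenes", "fen", "graph"))) {
    cfg[[key]] <- modifyList(cfg[[key]], y[[key]])
  }
  if (!is.null(y$embedding_dim)) cfg$embedding_dim <- as.integer(y$embedding_dim)
  if (!is.null(y$dg)) {
    cfg$dg <- do.call(dg_config, modifyList(unclass(cfg$dg), y$dg))
  }
  validate_experiment_config(cfg)
  cfg
}

# Build the two domain datasets of an experiment.
protocol_datasets <- function(config) {
  sc <- config$scenes
  src <- generate_domain(domain_config(
    "source", n_scenes = sc$n_source, seed = derive_seed(config$seed, "src"),
    width = sc$width, height = sc$height,
    longtail_exponent = sc$longtail_exponent))
  tgt <- generate_domain(domain_config(
    "target", n_scenes = sc$n_target, seed = derive_seed(config$seed, "tgt"),
    width = sc$width, height = sc$height,
    longtail_exponent = sc$longtail_exponent))
  list(source = src, target = tgt)
}

# Train the FEN on source crops (9 classes) and extend it to the target's
# novel classes (11) with exemplar memory + distillation.
protocol_fen <- function(config, datasets, verbose = FALSE) {
  fc <- config$fen
  src_crops <- scene_crops(datasets$source, fc$input_size)
  classes9 <- datasets$source$class_vocabulary
  fen <- build_backbone(
    fen_config(n_classes = length(classes9),
               stage_channels = fc$stage_channels,
               blocks_per_stage = fc$blocks_per_stage,
               input_size = fc$input_size, cbs = fc$cbs,
               tnorm = tnorm_config(fc$tnorm),
               label_smoothing = fc$label_smoothing),
    classes = classes9, seed = derive_seed(config$seed, "fen"))
  fen <- train_classifier(fen, src_crops$crops, src_crops$labels,
                          epochs = fc$epochs, batch = fc$batch, lr0 = fc$lr0,
                          seed = derive_seed(config$seed, "fen-fit"),
                          verbose = verbose)
  tgt_crops <- scene_crops(datasets$target, fc$input_size)
  novel <- datasets$target$config$novel_classes
  is_novel <- tgt_crops$labels %in% novel
  memory <- build_memory(src_crops$crops, src_crops$labels,
                         capacity = fc$il$memory,
                         seed = derive_seed(config$seed, "mem"))
  fen11 <- incremental_extend(fen, tgt_crops$crops[is_novel],
                              tgt_crops$labels[is_novel], memory,
                              epochs = fc$il$epochs,
                              finetune_epochs = fc$il$finetune_epochs,
                              batch = fc$batch, lr = fc$il$lr,
                              distill_weight = fc$il$distill_weight,
                              distill_temp = fc$il$distill_temp,
                              seed = derive_seed(config$seed, "il"))
  list(fen9 = fen, fen11 = fen11)
}

new_graph_for <- function(config, embeds_dim_visual, seed) {
  gc <- config$graph
  build_graph_model(graph_config(
    visual_dim = embeds_dim_visual, semantic_dim = config$embedding_dim,
    hidden_dim = gc$hidden_dim, readout_hidden = gc$readout_hidden,
    tnorm = tnorm_config(gc$tnorm), ecbs = gc$ecbs), seed = seed)
}

#' Run the full incremental-DG protocol
#'
#' Executes the stage sequence end-to-end: simulate both domains, train the
#' feature extractor on the source's 9 entity classes, extend it to 11 with
#' exemplar memory and distillation, embed both domains, train the teacher
#' graph on the source domain, domain-generalize the student (plus the
#' naive-adaptation and naive-DG comparison arms when `compare = TRUE`), and
#' evaluate every model on both domains. Artifacts (manifest, metrics,
#' reliability data) are written under `out_dir`.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created); `NULL` skips writing.
#' @param compare Also run the naive-adaptation and naive-DG arms.
#' @param verbose Progress messages.
#' @return Invisibly, a list with the datasets, models and a `metrics` data
#'   frame (one row per model x domain).
#' @export
run_protocol <- function(config = experiment_config(), out_dir = NULL,
                         compare = FALSE, verbose = FALSE) {
  validate_experiment_config(config)
  if (config$preset == "paper_scale") {
    warning("paper_scale preset is compute-heavy; expect GPU-scale runtimes",
            call. = FALSE)
  }
  say <- function(...) if (verbose) message(...)
  say("simulating domains")
  datasets <- protocol_datasets(config)
  say("training feature extractor (9 classes) and extending to 11")
  fens <- protocol_fen(config, datasets, verbose = verbose)
  table <- make_embedding_table(datasets$target$class_vocabulary,
                                dim = config$embedding_dim,
                                seed = derive_seed(config$seed, "emb"))
  say("embedding scenes")
  emb_src <- embed_dataset(datasets$source, fens$fen11, table)
  emb_tgt <- embed_dataset(datasets$target, fens$fen11, table)
  dv <- nrow(emb_src$scenes[[1]]$V)
  dgc <- config$dg
  dgc$seed <- derive_seed(config$seed, "dg")
  say("training teacher on source")
  teacher <- train_source(new_graph_for(config, dv,
                                        derive_seed(config$seed, "gmodel")),
                          emb_src, dgc)
  say("incremental domain generalization")
  student <- incremental_domain_generalize(teacher_student_pair(teacher),
                                           emb_tgt, emb_src, dgc)
  models <- list(teacher = teacher, incremental_dg = student)
  if (compare) {
    say("baseline arms")
    models$domain_adaptation <- naive_adapt(teacher, emb_tgt, dgc)
    models$naive_dg <- naive_dg(teacher, emb_tgt, emb_src, dgc)
  }
  metrics <- do.call(rbind, lapply(names(models), function(nm) {
    do.call(rbind, lapply(list(emb_src, emb_tgt), function(em) {
      r <- evaluate_domain(models[[nm]], em)
      data.frame(model = nm, domain = em$domain_id, acc = r$acc,
                 map = r$map, recall = r$recall, ece = r$ece,
                 n_edges = r$n_edges)
    }))
  }))
  result <- list(datasets = datasets, fens = fens, table = table,
                 embeddings = list(source = emb_src, target = emb_tgt),
                 models = models, metrics = metrics, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, preset = config$preset,
           stages = c("simulate", "train-fen", "extend-fen", "embed",
                      "train-teacher", "dg", "evaluate")),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         dataframe = "rows", digits = NA)
    rel <- evaluate_domain(models$incremental_dg, emb_src)$reliability
    jsonlite::write_json(unclass(rel), file.path(out_dir, "reliability.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(result)
}

#' Multi-seed retention experiment
#'
#' For each seed: trains a fresh teacher on the source embeddings, then runs
#' the three phase-2 regimes — naive domain adaptation (target only), naive
#' DG (target only + balanced fine-tune) and KD-based incremental DG — and
#' evaluates each arm on both domains. This is the desk-scale analogue of
#' the full-scale comparison of adaptation regimes: the naive arms forget
#' the source domain, distillation retains it.
#'
#' @param emb_src,emb_tgt Domain embeddings from [embed_dataset()].
#' @param config An [experiment_config()] (graph + dg sections are used).
#' @param seeds Integer vector of training seeds.
#' @return Data frame with one row per seed x arm: source and target
#'   accuracy, mAP and recall.
#' @export
retention_experiment <- function(emb_src, emb_tgt,
                                 config = experiment_config(),
                                 seeds = 1:5) {
  dv <- nrow(emb_src$scenes[[1]]$V)
  rows <- list()
  for (sd in seeds) {
    dgc <- config$dg
    dgc$seed <- derive_seed(config$seed, paste0("ret-", sd))
    teacher <- train_source(new_graph_for(config, dv,
                                          derive_seed(sd, "gmodel")),
                            emb_src, dgc)
    arms <- list(
      teacher = teacher,
      domain_adaptation = naive_adapt(teacher, emb_tgt, dgc),
      naive_dg = naive_dg(teacher, emb_tgt, emb_src, dgc),
      incremental_dg = incremental_domain_generalize(
        teacher_student_pair(teacher), emb_tgt, emb_src, dgc))
    for (nm in names(arms)) {
      rs <- evaluate_domain(arms[[nm]], emb_src)
      rt <- evaluate_domain(arms[[nm]], emb_tgt)
      rows[[length(rows) + 1L]] <- data.frame(
        seed = sd, arm = nm,
        acc_source = rs$acc, acc_target = rt$acc,
        map_source = rs$map, map_target = rt$map,
        recall_source = rs$recall, recall_target = rt$recall,
        ece_source = rs$ece, ece_target = rt$ece,
        n_edges_source = rs$n_edges, n_edges_target = rt$n_edges)
    }
  }
  do.call(rbind, rows)
}
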