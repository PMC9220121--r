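# Loss functions and training regimes for domain generalization of the graph
# network: multi-label soft-margin source training, teacher-student knowledge
# distillation on a sampled source subset, balanced fine-tuning, and the
# naive adaptation / naive DG baselines the method is compared against.

#' Multi-label soft-margin loss
#'
#' Mean over classes and edges of the element-wise binary cross entropy on
#' sigmoid outputs: \eqn{-[y \log\sigma(x) + (1-y)\log(1-\sigma(x))]}.
#'
#' @param logits Numeric vector or `classes x edges` matrix of (T-scaled)
#'   logits.
#' @param targets Binary vector/matrix of the same shape.
#' @return Scalar loss.
#' @examples
#' msl_loss(matrix(0, 13, 2), matrix(rep(c(1, rep(0, 12)), 2), 13))  # log(2)
#' @export
msl_loss <- function(logits, targets) {
  stop_if(!identical(dim(as.matrix(logits)), dim(as.matrix(targets))),
          "logits/targets shape mismatch")
  stop_if(!all(targets %in% c(0, 1)), "targets must be binary")
  x <- as.numeric(logits); y <- as.numeric(targets)
  # stable: log(1 + exp(-|x|)) formulation
  mean(pmax(x, 0) - x * y + log1p(exp(-abs(x))))
}

msl_grad <- function(logits, targets, denom) {
  (sigmoid(logits) - targets) / denom
}

#' Knowledge-distillation loss
#'
#' Cross entropy between the teacher's softmax distribution and the
#' student's: \eqn{-\sum_c \mathrm{softmax}(t)_c \log\mathrm{softmax}(s)_c},
#' averaged over edges. The teacher side is a constant (no gradient flows
#' into it).
#'
#' @param student_logits,teacher_logits `classes x edges` matrices (or
#'   vectors) of equal shape.
#' @return Scalar loss.
#' @examples
#' kd_loss(rep(0, 13), rep(0, 13))  # log(13): entropy of the uniform
#' @export
kd_loss <- function(student_logits, teacher_logits) {
  s <- as.matrix(student_logits); t <- as.matrix(teacher_logits)
  stop_if(!identical(dim(s), dim(t)), "student/teacher shape mismatch")
  pt <- softmax_cols(t)
  -mean(colSums(pt * log_softmax_cols(s)))
}

kd_grad <- function(student_logits, teacher_logits, denom) {
  (softmax_cols(as.matrix(student_logits)) -
     softmax_cols(as.matrix(teacher_logits))) / denom
}

#' Domain-generalization training configuration
#'
#' Defaults are the full-scale settings: `n_sample = 143` source frames,
#' distillation weight fixed at 0.5, constant learning rate `1e-5` with Adam
#' for the main phases, `1e-6` for 80 epochs of balanced fine-tuning, batch
#' size 32. The desk-scale preset in [experiment_config()] shrinks these.
#'
#' @param n_sample Source frames sampled for the distillation term and for
#'   balanced fine-tuning.
#' @param kd_weight Weight of the distillation loss inside `L_nSD`.
#' @param lr_main,epochs_main Learning rate / epochs for source training and
#'   the phase-2 generalization.
#' @param lr_finetune,epochs_finetune Balanced fine-tuning schedule.
#' @param batch Scenes per optimisation step.
#' @param seed Run seed; every random choice derives from it.
#' @param resample_per_epoch Redraw the source sample each epoch instead of
#'   once per run.
#' @param kd_tnorm_teacher Apply T-Norm to the teacher logits inside the KD
#'   term as well (default keeps the teacher side un-normalized).
#' @return An object of class `dg_config`.
#' @export
dg_config <- function(n_sample = 143L, kd_weight = 0.5, lr_main = 1e-5,
                      lr_finetune = 1e-6, epochs_main = 250L,
                      epochs_finetune = 80L, batch = 32L, seed = 0L,
                      resample_per_epoch = FALSE, kd_tnorm_teacher = FALSE) {
  stop_if(kd_weight < 0, "`kd_weight` must be >= 0")
  structure(list(n_sample = as.integer(n_sample), kd_weight = kd_weight,
                 lr_main = lr_main, lr_finetune = lr_finetune,
                 epochs_main = as.integer(epochs_main),
                 epochs_finetune = as.integer(epochs_finetune),
                 batch = as.integer(batch), seed = as.integer(seed),
                 resample_per_epoch = resample_per_epoch,
                 kd_tnorm_teacher = kd_tnorm_teacher),
            class = "dg_config")
}

#' Teacher-student pair
#'
#' Wraps a source-trained graph model as a frozen teacher together with a
#' trainable copy (the student). The teacher's parameters are never updated.
#'
#' @param teacher A source-trained `graph_model`.
#' @return An object of class `teacher_student_pair`.
#' @export
teacher_student_pair <- function(teacher) {
  stopifnot(inherits(teacher, "graph_model"))
  structure(list(teacher = teacher, student = teacher),
            class = "teacher_student_pair")
}

#' Per-step DG losses
#'
#' Composes the phase-2 loss from already T-Norm-scaled network outputs:
#' `L_TD` is the multi-label soft-margin loss on the target batch, `L_nSD`
#' the soft-margin loss on the sampled source batch plus `kd_weight` (0.5)
#' times the distillation loss between student and teacher on that batch,
#' and `L_DG = L_TD + L_nSD`.
#'
#' @param student_out_target,gt_target Student outputs and binary ground
#'   truth on the target batch (`classes x edges`).
#' @param student_out_source,gt_source Same for the sampled source batch.
#' @param teacher_out_source Teacher outputs on the source batch; required.
#' @param cfg A [dg_config()].
#' @return List with `L_TD`, `L_nSD`, `L_DG`.
#' @export
dg_step_losses <- function(student_out_target, gt_target,
                           student_out_source, gt_source,
                           teacher_out_source, cfg = dg_config()) {
  stop_if(is.null(teacher_out_source), "teacher outputs are required")
  L_TD <- msl_loss(student_out_target, gt_target)
  L_nSD <- msl_loss(student_out_source, gt_source) +
    cfg$kd_weight * kd_loss(student_out_source, teacher_out_source)
  list(L_TD = L_TD, L_nSD = L_nSD, L_DG = L_TD + L_nSD)
}

# ---- shared graph training loop --------------------------------------------

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

# groups: list of list(embeds = list of scene embeddings,
#                      teacher_logits = NULL or list parallel to embeds,
#                      kd_weight = 0)
# Target and sampled-source scenes form separate groups; batches stay
# homogeneous within a group and are interleaved in shuffled order.
graph_train <- function(model, groups, epochs, lr, batch, seed,
                        advance_curriculum = TRUE) {
  opt <- adam_init(model$params)
  losses <- numeric(epochs)
  log <- attr(model, "data_log") %||% integer()
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      if (advance_curriculum && !is.null(model$curriculum)) {
        model$curriculum$current_epoch <- model$curriculum$current_epoch + 1L
      }
      sched <- list()
      for (gi in seq_along(groups)) {
        idx <- sample.int(length(groups[[gi]]$embeds))
        for (start in seq(1L, length(idx), by = batch)) {
          sched[[length(sched) + 1L]] <-
            list(g = gi, idx = idx[start:min(start + batch - 1L, length(idx))])
        }
      }
      sched <- sched[sample.int(length(sched))]
      ep_loss <- 0; ep_edges <- 0L
      for (bt in sched) {
        grp <- groups[[bt$g]]
        fws <- lapply(grp$embeds[bt$idx],
                      function(E) graph_forward(model, E, train = TRUE))
        n_edges <- sum(vapply(fws, function(f) ncol(f$logits), 0L))
        if (n_edges == 0L) next
        grads <- NULL
        bloss <- 0
        for (j in seq_along(fws)) {
          fw <- fws[[j]]
          if (ncol(fw$logits) == 0L) next
          E <- grp$embeds[[bt$idx[j]]]
          dlog <- msl_grad(fw$logits, E$labels, 13 * n_edges)
          bloss <- bloss + sum(
            pmax(fw$logits, 0) - fw$logits * E$labels +
              log1p(exp(-abs(fw$logits)))) / (13 * n_edges)
          kw <- grp$kd_weight %||% 0
          if (kw > 0) {
            tl <- grp$teacher_logits[[bt$idx[j]]]
            dlog <- dlog + kw * kd_grad(fw$logits, tl, n_edges)
            bloss <- bloss + kw *
              (-sum(softmax_cols(tl) * log_softmax_cols(fw$logits))) / n_edges
          }
          grads <- add_grads(grads, graph_backward(model, fw$cache, dlog))
        }
        upd <- adam_update(model$params, grads, opt, lr)
        model$params <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + bloss * n_edges
        ep_edges <- ep_edges + n_edges
      }
      losses[ep] <- ep_loss / max(ep_edges, 1L)
    }
  })
  for (gi in seq_along(groups)) {
    nm <- names(groups)[gi] %||% paste0("group", gi)
    if (is.na(nm) || nm == "") nm <- paste0("group", gi)
    prev <- if (nm %in% names(log)) log[[nm]] else 0L
    log[nm] <- prev + length(groups[[gi]]$embeds) * epochs
  }
  attr(model, "data_log") <- log
  attr(model, "loss_history") <- losses
  model
}

#' Train the graph network on the source domain
#'
#' Multi-label soft-margin training with Adam on the source embeddings; the
#' returned model is the frozen teacher for the subsequent DG phase (its
#' parameters are copied, never shared).
#'
#' @param model A fresh [build_graph_model()] model.
#' @param source A [embed_dataset()] embedding of the source domain.
#' @param cfg A [dg_config()].
#' @param epochs Override `cfg$epochs_main` (used by short runs).
#' @return The trained `graph_model`, with per-epoch losses in attribute
#'   `"loss_history"` and dataset usage counts in `"data_log"`.
#' @export
train_source <- function(model, source, cfg = dg_config(), epochs = NULL) {
  stopifnot(inherits(model, "graph_model"),
            inherits(source, "graph_embeddings"))
  graph_train(model,
              groups = list(source = list(embeds = source$scenes)),
              epochs = epochs %||% cfg$epochs_main,
              lr = cfg$lr_main, batch = cfg$batch,
              seed = derive_seed(cfg$seed, "train-source"))
}

# Teacher outputs on a set of embedded scenes; optionally with the T-Norm
# division undone (the printed KD composition passes un-normalized teacher
# logits).
teacher_outputs <- function(teacher, embeds_list, tnorm_teacher) {
  Tn <- teacher$config$tnorm$temperature
  lapply(embeds_list, function(E) {
    lg <- graph_forward(teacher, E)$logits
    if (tnorm_teacher) lg else lg * Tn
  })
}

#' Knowledge-distillation-based incremental domain generalization
#'
#' Phase-2 training of the student: each epoch iterates the full target
#' dataset (soft-margin loss against ground truth) interleaved with a seeded
#' sample of `n_sample` source scenes (soft-margin loss plus `kd_weight`
#' times the distillation loss against the frozen teacher), followed by
#' [balanced_finetune()]. Distillation anchors the student to the teacher's
#' source-domain behaviour, so source accuracy is retained while the model
#' generalizes to the target domain.
#'
#' @param pair A [teacher_student_pair()].
#' @param target,source [embed_dataset()] embeddings of each domain.
#' @param cfg A [dg_config()].
#' @return The trained student `graph_model`.
#' @export
incremental_domain_generalize <- function(pair, target, source,
                                          cfg = dg_config()) {
  stopifnot(inherits(pair, "teacher_student_pair"))
  n <- cfg$n_sample
  stop_if(n > length(source$scenes),
          "n_sample exceeds the source dataset size")
  teacher <- pair$teacher
  student <- pair$student
  if (cfg$resample_per_epoch) {
    for (ep in seq_len(cfg$epochs_main)) {
      ids <- with_seed(derive_seed(cfg$seed, paste0("dg-sample-", ep)),
                       sample.int(length(source$scenes), n))
      src <- source$scenes[ids]
      tl <- teacher_outputs(teacher, src, cfg$kd_tnorm_teacher)
      student <- graph_train(
        student,
        groups = list(target = list(embeds = target$scenes),
                      source_sample = list(embeds = src, teacher_logits = tl,
                                           kd_weight = cfg$kd_weight)),
        epochs = 1L, lr = cfg$lr_main, batch = cfg$batch,
        seed = derive_seed(cfg$seed, paste0("dg-ep-", ep)))
    }
  } else {
    ids <- with_seed(derive_seed(cfg$seed, "dg-sample"),
                     sample.int(length(source$scenes), n))
    src <- source$scenes[ids]
    tl <- teacher_outputs(teacher, src, cfg$kd_tnorm_teacher)
    student <- graph_train(
      student,
      groups = list(target = list(embeds = target$scenes),
                    source_sample = list(embeds = src, teacher_logits = tl,
                                         kd_weight = cfg$kd_weight)),
      epochs = cfg$epochs_main, lr = cfg$lr_main, batch = cfg$batch,
      seed = derive_seed(cfg$seed, "dg-phase2"))
  }
  balanced_finetune(student, source, target, cfg)
}

#' Balanced fine-tuning on both domains
#'
#' Final DG phase: soft-margin training on equally sized seeded samples from
#' the source and target domains at the (small) fine-tuning learning rate.
#'
#' @param student A `graph_model`.
#' @param source,target Domain embeddings.
#' @param cfg A [dg_config()]; uses `n_sample`, `lr_finetune`,
#'   `epochs_finetune`.
#' @return The fine-tuned `graph_model`.
#' @export
balanced_finetune <- function(student, source, target, cfg = dg_config()) {
  m <- min(cfg$n_sample, length(source$scenes), length(target$scenes))
  if (cfg$epochs_finetune == 0L || m == 0L) return(student)
  ids_s <- with_seed(derive_seed(cfg$seed, "ft-source"),
                     sample.int(length(source$scenes), m))
  ids_t <- with_seed(derive_seed(cfg$seed, "ft-target"),
                     sample.int(length(target$scenes), m))
  graph_train(student,
              groups = list(finetune_source = list(embeds = source$scenes[ids_s]),
                            finetune_target = list(embeds = target$scenes[ids_t])),
              epochs = cfg$epochs_finetune, lr = cfg$lr_finetune,
              batch = cfg$batch,
              seed = derive_seed(cfg$seed, "ft"))
}

#' Baseline regimes: naive adaptation and naive DG
#'
#' `naive_adapt()` continues training the source model on the target domain
#' only (it never touches source data; see the model's `"data_log"`
#' attribute). `naive_dg()` additionally applies [balanced_finetune()] on
#' `n_sample` scenes from each domain. Neither uses distillation.
#'
#' @param teacher Source-trained `graph_model`.
#' @param target,source Domain embeddings.
#' @param cfg A [dg_config()].
#' @return The adapted `graph_model`.
#' @export
naive_adapt <- function(teacher, target, cfg = dg_config()) {
  attr(teacher, "data_log") <- NULL      # audit the adaptation phase only
  graph_train(teacher,
              groups = list(target = list(embeds = target$scenes)),
              epochs = cfg$epochs_main, lr = cfg$lr_main, batch = cfg$batch,
              seed = derive_seed(cfg$seed, "adapt"))
}

#' @rdname naive_adapt
#' @export
naive_dg <- function(teacher, target, source, cfg = dg_config()) {
  student <- naive_adapt(teacher, target, cfg)
  balanced_finetune(student, source, target, cfg)
}
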