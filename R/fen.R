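# Feature extraction network (FEN): a width/depth-configurable residual CNN
# trained to classify entity crops, whose penultimate (global-average-pooled)
# activations embed entities as graph node features.
#
# E-CBS placement follows the curriculum-by-smoothing recipe: one
# LoG-smoothing layer appended to the stem convolution and one
# Gaussian-smoothing layer inside every residual block (variant "cbs" uses
# Gaussian everywhere, "cbs_log" LoG everywhere). All smoothing layers share
# one curriculum state; their kernels are recomputed whenever sigma decays and
# the layers drop out entirely once sigma falls below a numeric floor.

#' Feature-extractor configuration
#'
#' @param n_classes Number of entity classes (>= 2).
#' @param stage_channels Channel width per stage (ResNet18 preset:
#'   `c(64, 128, 256, 512)`; desk preset `c(8, 16)`).
#' @param blocks_per_stage Residual blocks per stage.
#' @param input_size Square input side in pixels; crops are resized to this.
#' @param cbs Curriculum-smoothing options: list with `kind` (`"none"`,
#'   `"cbs"`, `"cbs_log"` or `"e_cbs"`), `sigma0`, `decay`, `period`,
#'   `zero_sum` (LoG mean-subtraction) and `floor` (sigma below which the
#'   smoothing layers become identity).
#' @param tnorm A [tnorm_config()]; the FEN default temperature is 3.
#' @param label_smoothing Label-smoothing mass in `[0, 1)`.
#' @return An object of class `fen_config`.
#' @export
fen_config <- function(n_classes, stage_channels = c(8L, 16L),
                       blocks_per_stage = c(1L, 1L), input_size = 24L,
                       cbs = list(kind = "e_cbs", sigma0 = 1, decay = 0.9,
                                  period = 5L, zero_sum = FALSE, floor = 1e-3),
                       tnorm = tnorm_config(3),
                       label_smoothing = 0) {
  stop_if(!is_count(n_classes) || n_classes < 2, "`n_classes` must be >= 2")
  stop_if(length(stage_channels) != length(blocks_per_stage),
          "`stage_channels` and `blocks_per_stage` must have equal length")
  stop_if(any(blocks_per_stage < 1), "each stage needs at least one block")
  stop_if(input_size %% 2^(length(stage_channels) - 1L) != 0,
          "`input_size` must be divisible by 2^(n_stages - 1)")
  cbs <- modifyList(list(kind = "none", sigma0 = 1, decay = 0.9, period = 5L,
                         zero_sum = FALSE, floor = 1e-3), cbs)
  stop_if(!cbs$kind %in% c("none", "cbs", "cbs_log", "e_cbs"),
          "cbs$kind must be one of none/cbs/cbs_log/e_cbs")
  structure(list(n_classes = as.integer(n_classes),
                 stage_channels = as.integer(stage_channels),
                 blocks_per_stage = as.integer(blocks_per_stage),
                 input_size = as.integer(input_size),
                 cbs = cbs, tnorm = tnorm,
                 label_smoothing = label_smoothing),
            class = "fen_config")
}

# Smoothing kernels for the stem and the residual blocks under each CBS
# variant; NULL when smoothing is off or sigma is below the floor.
fen_kernels <- function(config, sigma) {
  kind <- config$cbs$kind
  if (kind == "none" || is.null(sigma) || sigma < config$cbs$floor) {
    return(list(stem = NULL, block = NULL))
  }
  logk <- log_kernel_2d(kernel_spec("LoG", sigma, 3L),
                        zero_sum = isTRUE(config$cbs$zero_sum))
  gauk <- gaussian_kernel_2d(kernel_spec("Gaussian", sigma, 3L))
  switch(kind,
         cbs = list(stem = gauk, block = gauk),
         cbs_log = list(stem = logk, block = logk),
         e_cbs = list(stem = logk, block = gauk))
}

#' Build a feature-extraction backbone
#'
#' Constructs the residual CNN with seeded He initialisation. When curriculum
#' smoothing is enabled the model carries a shared [curriculum_state()]
#' (advanced once per training epoch) controlling every smoothing layer.
#'
#' @param config A [fen_config()].
#' @param classes Optional character vector naming the classes (length
#'   `n_classes`); integer labels are used otherwise.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `fen_model`.
#' @export
build_backbone <- function(config, classes = NULL, seed = 0L) {
  stopifnot(inherits(config, "fen_config"))
  if (!is.null(classes)) {
    stop_if(length(classes) != config$n_classes,
            "`classes` must have length n_classes")
  }
  ch <- config$stage_channels
  nb <- config$blocks_per_stage
  params <- with_seed(derive_seed(seed, "fen-init"), {
    p <- list(stem_W = he_init(9L * 3L, ch[1]), stem_b = numeric(ch[1]))
    for (s in seq_along(ch)) {
      if (s > 1L) {
        p[[sprintf("tr%d_W", s)]] <- he_init(ch[s - 1L], ch[s])
        p[[sprintf("tr%d_b", s)]] <- numeric(ch[s])
      }
      for (b in seq_len(nb[s])) {
        p[[sprintf("s%db%d_W1", s, b)]] <- he_init(9L * ch[s], ch[s])
        p[[sprintf("s%db%d_b1", s, b)]] <- numeric(ch[s])
        p[[sprintf("s%db%d_W2", s, b)]] <- he_init(9L * ch[s], ch[s])
        p[[sprintf("s%db%d_b2", s, b)]] <- numeric(ch[s])
      }
    }
    p$head_W <- he_init(ch[length(ch)], config$n_classes) * 0.5
    p$head_b <- numeric(config$n_classes)
    p
  })
  curriculum <- if (config$cbs$kind != "none") {
    curriculum_state(config$cbs$sigma0, config$cbs$decay, config$cbs$period, 0L)
  } else NULL
  structure(list(config = config, params = params, curriculum = curriculum,
                 classes = classes %||% as.character(seq_len(config$n_classes))),
            class = "fen_model")
}

#' @export
print.fen_model <- function(x, ...) {
  cat(sprintf("fen_model: %d classes, stages [%s], cbs=%s, T=%.2f\n",
              x$config$n_classes,
              paste(x$config$stage_channels, collapse = ","),
              x$config$cbs$kind, x$config$tnorm$temperature))
  invisible(x)
}

# How many LoG / Gaussian smoothing layers the architecture carries.
fen_smoothing_layout <- function(model) {
  kind <- model$config$cbs$kind
  nblocks <- sum(model$config$blocks_per_stage)
  switch(kind,
         none = c(log = 0L, gaussian = 0L),
         cbs = c(log = 0L, gaussian = 1L + nblocks),
         cbs_log = c(log = 1L + nblocks, gaussian = 0L),
         e_cbs = c(log = 1L, gaussian = nblocks))
}

# Forward pass. X: S x S x 3 x B with values in [0, 1]. Inputs are centred
# at zero (x - 0.5) so first-layer gradients decorrelate across filters.
# Returns T-scaled logits (B x K), penultimate features (B x C_last) and,
# when `train`, the caches needed for backward.
fen_forward <- function(model, X, sigma = NULL, train = FALSE) {
  cfg <- model$config
  p <- model$params
  X <- X - 0.5
  if (is.null(sigma) && !is.null(model$curriculum)) {
    sigma <- curriculum_sigma(model$curriculum)
  }
  kern <- fen_kernels(cfg, sigma)
  caches <- list()
  rec <- function(nm, val) if (train) caches[[nm]] <<- val

  cs <- conv2d_forward(X, p$stem_W, p$stem_b, 3L)
  rec("stem", cs)
  x <- cs$out
  if (!is.null(kern$stem)) {
    C <- dim(x)[3]
    Wd <- depthwise_weight(kern$stem, C)
    sm <- conv2d_forward(x, Wd, NULL, 3L)
    rec("stem_sm", list(cache = sm, Wd = Wd))
    x <- sm$out
  }
  rec("stem_mask", x > 0)
  x <- relu(x)

  ch <- cfg$stage_channels
  for (s in seq_along(ch)) {
    if (s > 1L) {
      rec(sprintf("pool%d_dim", s), dim(x))
      x <- avgpool2_forward(x)
      ct <- conv2d_forward(x, p[[sprintf("tr%d_W", s)]],
                           p[[sprintf("tr%d_b", s)]], 1L)
      rec(sprintf("tr%d", s), ct)
      x <- ct$out
    }
    for (b in seq_len(cfg$blocks_per_stage[s])) {
      id <- sprintf("s%db%d", s, b)
      x_in <- x
      c1 <- conv2d_forward(x, p[[paste0(id, "_W1")]], p[[paste0(id, "_b1")]], 3L)
      rec(paste0(id, "_c1"), c1)
      h <- c1$out
      if (!is.null(kern$block)) {
        C <- dim(h)[3]
        Wd <- depthwise_weight(kern$block, C)
        sm <- conv2d_forward(h, Wd, NULL, 3L)
        rec(paste0(id, "_sm"), list(cache = sm, Wd = Wd))
        h <- sm$out
      }
      rec(paste0(id, "_m1"), h > 0)
      h <- relu(h)
      c2 <- conv2d_forward(h, p[[paste0(id, "_W2")]], p[[paste0(id, "_b2")]], 3L)
      rec(paste0(id, "_c2"), c2)
      y <- x_in + c2$out
      rec(paste0(id, "_m2"), y > 0)
      x <- relu(y)
    }
  }

  d <- dim(x)
  feat <- t(matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4]))
  logits <- sweep(feat %*% p$head_W, 2L, p$head_b, "+") /
    cfg$tnorm$temperature
  rec("feat_dim", d)
  rec("feat", feat)
  list(logits = logits, feat = feat, caches = if (train) caches else NULL)
}

# Backward pass; dlogits is the gradient w.r.t. the T-scaled logits (B x K).
fen_backward <- function(model, caches, dlogits) {
  cfg <- model$config
  p <- model$params
  g <- list()
  draw <- dlogits / cfg$tnorm$temperature
  g$head_W <- crossprod(caches$feat, draw)
  g$head_b <- colSums(draw)
  dfeat <- tcrossprod(draw, p$head_W)
  d <- caches$feat_dim
  dx <- array(rep(as.vector(t(dfeat)), each = d[1] * d[2]) / (d[1] * d[2]), d)

  ch <- cfg$stage_channels
  for (s in rev(seq_along(ch))) {
    for (b in rev(seq_len(cfg$blocks_per_stage[s]))) {
      id <- sprintf("s%db%d", s, b)
      dy <- dx * caches[[paste0(id, "_m2")]]
      bk2 <- conv2d_backward(caches[[paste0(id, "_c2")]],
                             p[[paste0(id, "_W2")]], dy)
      g[[paste0(id, "_W2")]] <- bk2$dW
      g[[paste0(id, "_b2")]] <- bk2$db
      dh <- bk2$dX * caches[[paste0(id, "_m1")]]
      sm <- caches[[paste0(id, "_sm")]]
      if (!is.null(sm)) {
        dh <- conv2d_backward(sm$cache, sm$Wd, dh,
                              need_weight_grad = FALSE)$dX
      }
      bk1 <- conv2d_backward(caches[[paste0(id, "_c1")]],
                             p[[paste0(id, "_W1")]], dh)
      g[[paste0(id, "_W1")]] <- bk1$dW
      g[[paste0(id, "_b1")]] <- bk1$db
      dx <- dy + bk1$dX               # skip connection
    }
    if (s > 1L) {
      bkt <- conv2d_backward(caches[[sprintf("tr%d", s)]],
                             p[[sprintf("tr%d_W", s)]], dx)
      g[[sprintf("tr%d_W", s)]] <- bkt$dW
      g[[sprintf("tr%d_b", s)]] <- bkt$db
      dx <- avgpool2_backward(bkt$dX, caches[[sprintf("pool%d_dim", s)]])
    }
  }
  dx <- dx * caches$stem_mask
  if (!is.null(caches$stem_sm)) {
    dx <- conv2d_backward(caches$stem_sm$cache, caches$stem_sm$Wd, dx,
                          need_weight_grad = FALSE)$dX
  }
  bks <- conv2d_backward(caches$stem, p$stem_W, dx, need_input_grad = FALSE)
  g$stem_W <- bks$dW
  g$stem_b <- bks$db
  g
}

# Cross-entropy with optional label smoothing on T-scaled logits.
# logits: B x K; labels: integer in 1..K. Returns loss and dlogits.
ce_loss_grad <- function(logits, labels, label_smoothing = 0) {
  B <- nrow(logits); K <- ncol(logits)
  lp <- t(log_softmax_cols(t(logits)))
  q <- matrix(label_smoothing / K, B, K)
  q[cbind(seq_len(B), labels)] <- q[cbind(seq_len(B), labels)] +
    (1 - label_smoothing)
  loss <- -sum(q * lp) / B
  dlogits <- (exp(lp) - q) / B
  list(loss = loss, dlogits = dlogits)
}

stack_crops <- function(crops) {
  d <- dim(crops[[1]])
  X <- array(0, c(d, length(crops)))
  for (i in seq_along(crops)) X[, , , i] <- crops[[i]]
  X
}

#' Train the feature extractor on labelled crops
#'
#' Minimises (optionally label-smoothed) cross entropy on T-Norm-scaled
#' logits with momentum SGD and an exponentially decaying learning rate,
#' advancing the shared curriculum-smoothing state once per epoch. Matches
#' the standard recipe: learning rate decaying from `1e-3`, 30 epochs,
#' batch 20.
#'
#' @param model A [build_backbone()] model.
#' @param crops List of `S x S x 3` arrays with values in `[0, 1]`.
#' @param labels Character vector of class names (must appear in
#'   `model$classes`) or integer labels in `1..n_classes`.
#' @param epochs,batch,lr0,lr_decay Optimisation hyper-parameters; `lr_decay`
#'   multiplies the learning rate each epoch.
#' @param seed Integer seed (shuffling order).
#' @param verbose Print per-epoch loss/accuracy/sigma.
#' @return The trained `fen_model`, with a `history` data frame attached.
#' @export
train_classifier <- function(model, crops, labels, epochs = 30L, batch = 20L,
                             lr0 = 1e-3, lr_decay = 0.93, seed = 0L,
                             verbose = FALSE) {
  stopifnot(inherits(model, "fen_model"))
  stop_if(length(crops) == 0L, "empty training set")
  labels <- fen_label_index(model, labels)
  n <- length(crops)
  opt <- sgd_init(model$params)
  hist <- data.frame(epoch = integer(), loss = numeric(), acc = numeric(),
                     sigma = numeric())
  with_seed(derive_seed(seed, "fen-train"), {
    for (ep in seq_len(epochs)) {
      if (!is.null(model$curriculum)) {
        model$curriculum$current_epoch <- ep - 1L
      }
      sigma <- if (!is.null(model$curriculum))
        curriculum_sigma(model$curriculum) else NA_real_
      lr <- lr0 * lr_decay^(ep - 1L)
      ord <- sample.int(n)
      ep_loss <- 0; ep_hit <- 0L
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, n)]
        X <- stack_crops(crops[idx])
        fw <- fen_forward(model, X, train = TRUE)
        cl <- ce_loss_grad(fw$logits, labels[idx],
                           model$config$label_smoothing)
        grads <- fen_backward(model, fw$caches, cl$dlogits)
        upd <- sgd_update(model$params, grads, opt, lr)
        model$params <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + cl$loss * length(idx)
        ep_hit <- ep_hit + sum(max.col(fw$logits) == labels[idx])
      }
      hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / n,
                                     acc = ep_hit / n, sigma = sigma))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  acc %.3f  sigma %.4f",
                        ep, ep_loss / n, ep_hit / n, sigma))
      }
    }
  })
  model$history <- hist
  model
}

fen_label_index <- function(model, labels) {
  if (is.character(labels)) {
    idx <- match(labels, model$classes)
    stop_if(anyNA(idx), "labels contain classes unknown to the model: ",
            paste(unique(labels[is.na(idx)]), collapse = ", "))
    idx
  } else {
    stop_if(any(labels < 1) || any(labels > model$config$n_classes),
            "integer labels out of range")
    as.integer(labels)
  }
}

#' Penultimate-layer features for a crop
#'
#' Runs the backbone in evaluation mode and returns the global-average-pooled
#' activation feeding the classifier — the feature embedding used for graph
#' nodes. Dimension equals the last stage width.
#'
#' @param model A `fen_model`.
#' @param crop One `S x S x 3` array, or a list of them.
#' @return A numeric vector (single crop) or a matrix with one row per crop.
#' @export
extract_features <- function(model, crop) {
  crops <- if (is.list(crop)) crop else list(crop)
  fw <- fen_forward(model, stack_crops(crops), train = FALSE)
  if (is.list(crop)) fw$feat else drop(fw$feat)
}

# Classify crops; returns list(pred index, T-scaled logits matrix).
fen_predict <- function(model, crops, chunk = 64L) {
  n <- length(crops)
  logits <- NULL
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- fen_forward(model, stack_crops(crops[idx]), train = FALSE)
    logits <- rbind(logits, fw$logits)
  }
  list(pred = max.col(logits), logits = logits)
}

# ---- crop extraction -------------------------------------------------------

# Nearest-neighbour resize of an H x W x C array to S x S (deterministic
# integer-grid mapping).
resize_nn <- function(img, S) {
  d <- dim(img)
  ri <- pmin(pmax(floor((seq_len(S) - 0.5) * d[1] / S) + 1L, 1L), d[1])
  ci <- pmin(pmax(floor((seq_len(S) - 0.5) * d[2] / S) + 1L, 1L), d[2])
  img[ri, ci, , drop = FALSE]
}

# Crop one entity from a scene image (half-open box) and resize; values
# scaled to [0, 1].
crop_entity <- function(image, bbox, size) {
  b <- round(bbox)
  stop_if(b[1] < 0 || b[2] < 0 || b[3] > dim(image)[2] || b[4] > dim(image)[1],
          "entity crop lies outside the image")
  sub <- image[(b[2] + 1):b[4], (b[1] + 1):b[3], , drop = FALSE]
  resize_nn(sub / 255, size)
}

#' Extract all entity crops of a dataset
#'
#' @param dataset A `surg_dataset`.
#' @param size Output crop side (defaults to 24).
#' @return List with `crops` (list of arrays) and `labels` (class names).
#' @export
scene_crops <- function(dataset, size = 24L) {
  crops <- list(); labels <- character()
  for (sc in dataset$scenes) {
    for (e in seq_len(nrow(sc$entities))) {
      crops[[length(crops) + 1L]] <-
        crop_entity(sc$image, as.numeric(sc$entities[e, c("x0", "y0", "x1", "y1")]),
                    size)
      labels <- c(labels, sc$entities$class[e])
    }
  }
  list(crops = crops, labels = labels)
}

# ---- exemplar memory -------------------------------------------------------

#' Build an exemplar memory for incremental learning
#'
#' Selects up to `capacity` crops across the classes present in `labels`,
#' with a per-class quota of `floor(capacity / n_classes)` and the remainder
#' going to the most frequent classes. Strategies: `"random"` (seeded
#' uniform) or `"herding"` (iCaRL-style greedy selection keeping the running
#' exemplar feature mean closest to the class feature mean; requires
#' `model`).
#'
#' @param crops List of crop arrays.
#' @param labels Class name per crop.
#' @param capacity Total memory budget (default 50).
#' @param strategy `"random"` or `"herding"`.
#' @param seed Integer seed for the random strategy.
#' @param model `fen_model` used to embed crops when `strategy = "herding"`.
#' @return An object of class `exemplar_memory`: list with `crops`, `labels`,
#'   `capacity`.
#' @export
build_memory <- function(crops, labels, capacity = 50L,
                         strategy = c("random", "herding"), seed = 0L,
                         model = NULL) {
  strategy <- match.arg(strategy)
  stop_if(length(crops) != length(labels), "crops/labels length mismatch")
  classes <- unique(labels)
  counts <- table(labels)
  quota <- rep(capacity %/% length(classes), length(classes))
  names(quota) <- classes
  rem <- capacity - sum(quota)
  if (rem > 0L) {
    top <- names(sort(counts, decreasing = TRUE))[seq_len(rem)]
    quota[top] <- quota[top] + 1L
  }
  sel <- integer()
  with_seed(derive_seed(seed, "memory"), {
    for (cl in classes) {
      idx <- which(labels == cl)
      take <- min(quota[[cl]], length(idx))
      if (take == 0L) {
        warning("class '", cl, "' received no memory slots")
        next
      }
      if (strategy == "random") {
        sel <- c(sel, sample(idx, take))
      } else {
        stop_if(is.null(model), "herding requires `model`")
        feats <- extract_features(model, crops[idx])
        mu <- colMeans(feats)
        chosen <- integer()
        acc <- numeric(ncol(feats))
        for (k in seq_len(take)) {
          cand <- setdiff(seq_along(idx), chosen)
          d2 <- vapply(cand, function(i)
            sum((mu - (acc + feats[i, ]) / k)^2), 0)
          pick <- cand[which.min(d2)]
          chosen <- c(chosen, pick)
          acc <- acc + feats[pick, ]
        }
        sel <- c(sel, idx[chosen])
      }
    }
  })
  structure(list(crops = crops[sel], labels = labels[sel],
                 capacity = as.integer(capacity)),
            class = "exemplar_memory")
}

#' @export
print.exemplar_memory <- function(x, ...) {
  cat(sprintf("exemplar_memory: %d / %d slots, %d classes\n",
              length(x$crops), x$capacity, length(unique(x$labels))))
  invisible(x)
}

# Widen the classification head by k fresh classes; old rows untouched.
widen_head <- function(model, new_classes, seed = 0L) {
  stop_if(any(new_classes %in% model$classes),
          "new classes overlap existing classes: ",
          paste(intersect(new_classes, model$classes), collapse = ", "))
  k <- length(new_classes)
  d <- nrow(model$params$head_W)
  fresh <- with_seed(derive_seed(seed, "widen"),
                     matrix(rnorm(d * k, sd = 0.01), d, k))
  model$params$head_W <- cbind(model$params$head_W, fresh)
  model$params$head_b <- c(model$params$head_b, numeric(k))
  model$classes <- c(model$classes, new_classes)
  model$config$n_classes <- model$config$n_classes + k
  model
}

#' Extend the feature extractor to novel classes incrementally
#'
#' Widens the classification head (old weight rows preserved bit-for-bit),
#' then trains on the novel-class data plus the exemplar memory with a
#' distillation-regularised loss: cross entropy over all classes plus
#' `distill_weight` times the cross entropy between the frozen old model's
#' softened old-class distribution and the new model's softened old-class
#' logits (distillation temperature `distill_temp`). A balanced fine-tuning
#' phase on equal per-class samples follows.
#'
#' Setting `memory = NULL` and `distill_weight = 0` yields the naive
#' fine-tuning baseline that forgets old classes.
#'
#' @param model Source-trained `fen_model`.
#' @param new_crops,new_labels Novel-class data; classes must be disjoint
#'   from `model$classes`.
#' @param memory An [build_memory()] exemplar memory, or `NULL`.
#' @param epochs Incremental training epochs (0 returns the widened,
#'   untrained model).
#' @param finetune_epochs Balanced fine-tuning epochs (default 15).
#' @param batch,lr Optimisation parameters.
#' @param distill_weight Weight of the distillation term.
#' @param distill_temp Distillation softening temperature.
#' @param seed Integer seed.
#' @return The extended `fen_model` with `n_classes + k` outputs.
#' @export
incremental_extend <- function(model, new_crops, new_labels, memory,
                               epochs = 8L, finetune_epochs = 15L,
                               batch = 20L, lr = 5e-4,
                               distill_weight = 1, distill_temp = 2,
                               seed = 0L) {
  stopifnot(inherits(model, "fen_model"))
  new_classes <- unique(new_labels)
  K_old <- model$config$n_classes
  old_model <- model                   # frozen teacher for distillation
  model <- widen_head(model, new_classes, seed)
  if (epochs == 0L) return(model)

  crops <- new_crops
  labels <- new_labels
  if (!is.null(memory)) {
    crops <- c(crops, memory$crops)
    labels <- c(labels, memory$labels)
  }
  lab_idx <- fen_label_index(model, labels)
  n <- length(crops)
  Tt <- model$config$tnorm$temperature
  opt <- sgd_init(model$params)
  with_seed(derive_seed(seed, "fen-il"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch)) {
        idx <- ord[start:min(start + batch - 1L, n)]
        X <- stack_crops(crops[idx])
        fw <- fen_forward(model, X, train = TRUE)
        cl <- ce_loss_grad(fw$logits, lab_idx[idx])
        dlogits <- cl$dlogits
        if (distill_weight > 0) {
          old <- fen_forward(old_model, X, train = FALSE)
          # soften raw (un-T-Normed) logits with the distillation temperature
          pt <- t(softmax_cols(t(old$logits * Tt) / distill_temp))
          zs <- (fw$logits[, seq_len(K_old), drop = FALSE] * Tt) / distill_temp
          ps <- t(softmax_cols(t(zs)))
          B <- length(idx)
          # gradient of distill_weight * distill_temp^2 * CE(pt, ps) w.r.t.
          # the T-scaled logits (Hinton T^2 scaling keeps magnitudes stable)
          dlogits[, seq_len(K_old)] <- dlogits[, seq_len(K_old)] +
            distill_weight * distill_temp * Tt * (ps - pt) / B
        }
        grads <- fen_backward(model, fw$caches, dlogits)
        upd <- sgd_update(model$params, grads, opt, lr)
        model$params <- upd$params
        opt <- upd$state
      }
    }
    # balanced fine-tune: equal per-class sample counts
    if (finetune_epochs > 0L) {
      per <- min(table(labels))
      keep <- unlist(lapply(unique(labels), function(cl) {
        idx <- which(labels == cl)
        if (length(idx) > per) sample(idx, per) else idx
      }))
      kn <- length(keep)
      for (ep in seq_len(finetune_epochs)) {
        ord <- sample(keep)
        for (start in seq(1L, kn, by = batch)) {
          idx <- ord[start:min(start + batch - 1L, kn)]
          X <- stack_crops(crops[idx])
          fw <- fen_forward(model, X, train = TRUE)
          cl <- ce_loss_grad(fw$logits, lab_idx[idx])
          grads <- fen_backward(model, fw$caches, cl$dlogits)
          upd <- sgd_update(model$params, grads, opt, lr / 5)
          model$params <- upd$params
          opt <- upd$state
        }
      }
    }
  })
  model
}
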