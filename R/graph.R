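# Visual-semantic graph attention network over scene entities.
#
# Scene entities become nodes of two parallel complete digraphs (no
# self-loops): the visual graph carries [crop feature, whole-scene feature,
# normalized box geometry] from the FEN, the semantic graph carries
# word-embedding vectors of the class names. Each graph runs one round of
# single-head attention (leaky-ReLU of a learned bilinear score, softmax over
# in-neighbours); the propagated graphs are concatenated into a combined
# graph whose tissue->instrument edges, augmented with 14-dim box-pair
# spatial features, are read out by an MLP into 13 interaction logits divided
# by the T-Norm temperature.
#
# The exported operations (embed_visual_graph, attention_propagate, ...)
# expose the pipeline stepwise; graph_forward/graph_backward fuse the same
# computation with hand-derived gradients for training.

#' Graph-network configuration
#'
#' @param visual_dim Visual node-feature dimension (twice the FEN feature
#'   width plus 8 geometry terms).
#' @param semantic_dim Word-embedding dimension.
#' @param hidden_dim Attention-projection width per graph.
#' @param readout_hidden Hidden width of the edge-readout MLP.
#' @param n_interactions Number of interaction classes (13).
#' @param tnorm A [tnorm_config()]; graph default temperature 1.5.
#' @param ecbs List with `enabled`, `sigma0`, `decay`, `period`, `floor`:
#'   the 1D LoG smoothing of aggregated visual messages and its curriculum.
#' @param leaky_slope Negative slope of the attention leaky-ReLU.
#' @return An object of class `graph_config`.
#' @export
graph_config <- function(visual_dim, semantic_dim, hidden_dim = 32L,
                         readout_hidden = 64L, n_interactions = 13L,
                         tnorm = tnorm_config(1.5),
                         ecbs = list(enabled = TRUE, sigma0 = 1,
                                     decay = 0.985, period = 20L,
                                     floor = 1e-3),
                         leaky_slope = 0.2) {
  ecbs <- modifyList(list(enabled = FALSE, sigma0 = 1, decay = 0.985,
                          period = 20L, floor = 1e-3), ecbs)
  structure(list(visual_dim = as.integer(visual_dim),
                 semantic_dim = as.integer(semantic_dim),
                 hidden_dim = as.integer(hidden_dim),
                 readout_hidden = as.integer(readout_hidden),
                 n_interactions = as.integer(n_interactions),
                 tnorm = tnorm, ecbs = ecbs, leaky_slope = leaky_slope),
            class = "graph_config")
}

#' Build a graph-network model
#'
#' @param config A [graph_config()].
#' @param seed Integer seed for initialisation.
#' @return An object of class `graph_model`.
#' @export
build_graph_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "graph_config"))
  dh <- config$hidden_dim
  hr <- config$readout_hidden
  du <- 4L * dh + 14L
  params <- with_seed(derive_seed(seed, "graph-init"), list(
    Wv = he_init(config$visual_dim, dh), bv = numeric(dh),
    Ws = he_init(config$semantic_dim, dh), bs = numeric(dh),
    Av = he_init(dh, dh) * 0.3, As = he_init(dh, dh) * 0.3,
    R1 = he_init(du, hr), r1 = numeric(hr),
    R2 = he_init(hr, config$n_interactions) * 0.5,
    r2 = numeric(config$n_interactions)))
  curriculum <- if (isTRUE(config$ecbs$enabled)) {
    curriculum_state(config$ecbs$sigma0, config$ecbs$decay,
                     config$ecbs$period, 0L)
  } else NULL
  structure(list(config = config, params = params, curriculum = curriculum),
            class = "graph_model")
}

#' @export
print.graph_model <- function(x, ...) {
  cat(sprintf("graph_model: dv=%d ds=%d dh=%d, ecbs=%s, T=%.2f\n",
              x$config$visual_dim, x$config$semantic_dim,
              x$config$hidden_dim,
              if (isTRUE(x$config$ecbs$enabled)) "on" else "off",
              x$config$tnorm$temperature))
  invisible(x)
}

# Current 1D LoG message-smoothing kernel, or NULL below the sigma floor.
graph_ecbs_kernel <- function(model, sigma = NULL) {
  cfg <- model$config$ecbs
  if (!isTRUE(cfg$enabled)) return(NULL)
  if (is.null(sigma)) {
    sigma <- if (!is.null(model$curriculum))
      curriculum_sigma(model$curriculum) else cfg$sigma0
  }
  if (sigma < cfg$floor) return(NULL)
  log_kernel_1d(kernel_spec("LoG", sigma, 3L))
}

# ---- spatial edge features -------------------------------------------------

#' Box-pair spatial features
#'
#' The 14-dimensional geometry vector embedded on combined-graph edges:
#' normalized centres of both boxes (4), normalized widths/heights (4),
#' centre offset (2), log size ratios (2), IoU (1), and the area fraction of
#' the tight box enclosing both (1). All entries are in image-normalized
#' units.
#'
#' @param boxA,boxB Length-4 boxes `(x0, y0, x1, y1)`, half-open pixels.
#' @param image_wh Length-2 `(width, height)`.
#' @return Numeric vector of length 14.
#' @export
spatial_edge_features <- function(boxA, boxB, image_wh) {
  a <- as.numeric(boxA); b <- as.numeric(boxB)
  W <- image_wh[1]; H <- image_wh[2]
  wa <- a[3] - a[1]; ha <- a[4] - a[2]
  wb <- b[3] - b[1]; hb <- b[4] - b[2]
  stop_if(wa <= 0 || ha <= 0 || wb <= 0 || hb <= 0,
          "zero-area box in spatial_edge_features")
  ca <- c((a[1] + a[3]) / 2, (a[2] + a[4]) / 2)
  cb <- c((b[1] + b[3]) / 2, (b[2] + b[4]) / 2)
  enclose <- (max(a[3], b[3]) - min(a[1], b[1])) *
    (max(a[4], b[4]) - min(a[2], b[2]))
  c(ca[1] / W, ca[2] / H, cb[1] / W, cb[2] / H,
    wa / W, ha / H, wb / W, hb / H,
    (cb[1] - ca[1]) / W, (cb[2] - ca[2]) / H,
    log(wb / wa), log(hb / ha),
    box_iou(a, b), enclose / (W * H))
}

# ---- stepwise graph operations --------------------------------------------

new_graph <- function(kind, features, class_names, roles, boxes, image_wh) {
  dimnames(features) <- NULL
  structure(list(kind = kind, features = features, class_names = class_names,
                 roles = roles, boxes = boxes, image_wh = image_wh,
                 n = ncol(features)),
            class = "surg_graph")
}

#' @export
print.surg_graph <- function(x, ...) {
  cat(sprintf("surg_graph (%s): %d nodes, feature dim %d\n",
              x$kind, x$n, nrow(x$features)))
  invisible(x)
}

# Normalized geometry portion of a visual node feature.
box_geometry <- function(b, W, H) {
  c(b[1] / W, b[2] / H, b[3] / W, b[4] / H,
    (b[1] + b[3]) / (2 * W), (b[2] + b[4]) / (2 * H),
    (b[3] - b[1]) / W, (b[4] - b[2]) / H)
}

#' Embed a scene into the visual graph
#'
#' One node per entity over a complete digraph (no self-loops). Node features
#' concatenate the FEN penultimate feature of the entity crop, the FEN
#' feature of the whole frame (scene context), and 8 normalized box-geometry
#' terms.
#'
#' @param scene A `surg_scene`.
#' @param fen A trained (or untrained) `fen_model`.
#' @return A `surg_graph` of kind `"visual"`.
#' @export
embed_visual_graph <- function(scene, fen) {
  stopifnot(inherits(scene, "surg_scene"), inherits(fen, "fen_model"))
  size <- fen$config$input_size
  W <- dim(scene$image)[2]; H <- dim(scene$image)[1]
  scene_feat <- extract_features(fen, resize_nn(scene$image / 255, size))
  n <- nrow(scene$entities)
  crops <- lapply(seq_len(n), function(e)
    crop_entity(scene$image, as.numeric(scene$entities[e, c("x0", "y0", "x1", "y1")]),
                size))
  crop_feat <- extract_features(fen, crops)   # n x df
  feats <- vapply(seq_len(n), function(e) {
    b <- as.numeric(scene$entities[e, c("x0", "y0", "x1", "y1")])
    c(crop_feat[e, ], scene_feat, box_geometry(b, W, H))
  }, numeric(ncol(crop_feat) * 2L + 8L))
  boxes <- as.matrix(scene$entities[, c("x0", "y0", "x1", "y1")])
  new_graph("visual", feats, scene$entities$class, scene$entities$role,
            boxes, c(W, H))
}

#' Embed a scene into the semantic graph
#'
#' Node features are the word-embedding vectors of the entity class names;
#' topology matches the visual graph.
#'
#' @param scene A `surg_scene`.
#' @param table An [make_embedding_table()] embedding table.
#' @return A `surg_graph` of kind `"semantic"`.
#' @export
embed_semantic_graph <- function(scene, table) {
  stopifnot(inherits(scene, "surg_scene"))
  missing <- setdiff(scene$entities$class, colnames(table))
  stop_if(length(missing) > 0L, "class name(s) not in embedding table: ",
          paste(missing, collapse = ", "))
  feats <- table[, scene$entities$class, drop = FALSE]
  W <- dim(scene$image)[2]; H <- dim(scene$image)[1]
  boxes <- as.matrix(scene$entities[, c("x0", "y0", "x1", "y1")])
  new_graph("semantic", unclass(feats), scene$entities$class,
            scene$entities$role, boxes, c(W, H))
}

# Core single-graph attention round; returns H', alpha and forward
# intermediates (for the fused backward).
propagate_core <- function(X, Wp, bp, A, slope, kern1d) {
  N <- ncol(X)
  Z <- Wp_mult(Wp, bp, X)
  if (N == 1L) {
    Hn <- relu(Z)
    return(list(H = Hn, Z = Z, alpha = matrix(0, 1, 1), M = Z * 0,
                Mpre = NULL, P = NULL, mask = Hn > 0))
  }
  P <- crossprod(Z, A %*% Z)           # P[i, j] = z_i' A z_j
  S <- lrelu(P, slope)
  diag(S) <- -Inf
  E <- exp(sweep(S, 2L, apply(S, 2L, max), "-"))
  alpha <- sweep(E, 2L, colSums(E), "/")
  Mpre <- Z %*% alpha                  # column j: sum_i alpha_ij z_i
  M <- if (!is.null(kern1d)) conv1d_cols(Mpre, kern1d) else Mpre
  pre <- Z + M
  list(H = relu(pre), Z = Z, alpha = alpha, M = M, Mpre = Mpre, P = P,
       mask = pre > 0)
}

Wp_mult <- function(Wp, bp, X) sweep(crossprod(Wp, X), 1L, bp, "+")

# 1D convolution of each column with a symmetric length-3 kernel, zero pad.
conv1d_cols <- function(M, k) {
  d <- nrow(M)
  out <- k[2] * M
  if (d > 1L) {
    out[2:d, ] <- out[2:d, , drop = FALSE] + k[1] * M[1:(d - 1), , drop = FALSE]
    out[1:(d - 1), ] <- out[1:(d - 1), , drop = FALSE] +
      k[3] * M[2:d, , drop = FALSE]
  }
  out
}

#' One round of graph attention propagation
#'
#' Per directed edge `i -> j` the score is a leaky-ReLU of the learned
#' bilinear form `z_i' A z_j` on projected features; scores are
#' softmax-normalized over each node's in-neighbours, and the new node
#' feature is `relu(z_j + m_j)` where `m_j` is the attention-weighted
#' neighbour sum. With `use_ecbs = TRUE` (visual graph only) the aggregated
#' message is smoothed along the feature axis with the current 1D LoG kernel
#' before the nonlinearity. Single-node graphs pass through with `m = 0`.
#'
#' @param graph A `surg_graph` from [embed_visual_graph()] or
#'   [embed_semantic_graph()].
#' @param model A [build_graph_model()] model.
#' @param use_ecbs Apply the 1D LoG message smoothing.
#' @param sigma Override the curriculum sigma (otherwise taken from the
#'   model's curriculum state).
#' @return The graph with propagated features; attention weights are
#'   attached as attribute `"alpha"` (columns sum to 1 over in-neighbours).
#' @export
attention_propagate <- function(graph, model, use_ecbs = FALSE, sigma = NULL) {
  stopifnot(inherits(graph, "surg_graph"), inherits(model, "graph_model"))
  if (graph$n == 0L) return(graph)
  p <- model$params
  kern <- if (use_ecbs) graph_ecbs_kernel(model, sigma) else NULL
  core <- if (graph$kind == "visual") {
    propagate_core(graph$features, p$Wv, p$bv, p$Av,
                   model$config$leaky_slope, kern)
  } else {
    propagate_core(graph$features, p$Ws, p$bs, p$As,
                   model$config$leaky_slope, kern)
  }
  out <- graph
  out$features <- core$H
  out$kind <- paste0(graph$kind, "_propagated")
  attr(out, "alpha") <- core$alpha
  out
}

#' Combine propagated visual and semantic graphs
#'
#' Concatenates node features of the two propagated graphs (combined
#' dimension is the sum of the two); topologies must match.
#'
#' @param gv,gs Propagated visual and semantic `surg_graph`s.
#' @return A `surg_graph` of kind `"combined"`.
#' @export
combine_graphs <- function(gv, gs) {
  stopifnot(inherits(gv, "surg_graph"), inherits(gs, "surg_graph"))
  stop_if(gv$n != gs$n || !identical(gv$class_names, gs$class_names),
          "graph topology mismatch between visual and semantic graphs")
  out <- gv
  out$features <- rbind(gv$features, gs$features)
  out$kind <- "combined"
  out
}

#' Read out interaction predictions from the combined graph
#'
#' For every tissue->instrument edge, an MLP on `[source node, destination
#' node, spatial features]` produces 13 interaction logits which are divided
#' by the T-Norm temperature; probabilities are element-wise sigmoids
#' (multi-label). A scene without instruments yields an empty (zero-edge)
#' prediction.
#'
#' @param gc A combined `surg_graph`.
#' @param model A `graph_model`.
#' @param tnorm Optional [tnorm_config()] overriding the model's.
#' @return An object of class `interaction_prediction`: list with `logits`
#'   (13 x k), `probs`, and `pairs` (k x 2 node indices).
#' @export
readout_interactions <- function(gc, model, tnorm = NULL) {
  stopifnot(inherits(gc, "surg_graph"), inherits(model, "graph_model"))
  Tn <- (tnorm %||% model$config$tnorm)$temperature
  t_idx <- which(gc$roles == "tissue")
  i_idx <- which(gc$roles == "instrument")
  pairs <- if (length(t_idx) && length(i_idx)) {
    cbind(tissue = rep(t_idx[1], length(i_idx)), instrument = i_idx)
  } else {
    matrix(integer(), 0L, 2L, dimnames = list(NULL, c("tissue", "instrument")))
  }
  k <- nrow(pairs)
  K <- model$config$n_interactions
  if (k == 0L) {
    return(structure(list(logits = matrix(numeric(), K, 0L),
                          probs = matrix(numeric(), K, 0L), pairs = pairs),
                     class = "interaction_prediction"))
  }
  Fsp <- vapply(seq_len(k), function(e)
    spatial_edge_features(gc$boxes[pairs[e, 1], ], gc$boxes[pairs[e, 2], ],
                          gc$image_wh), numeric(14L))
  U <- rbind(gc$features[, pairs[, 1], drop = FALSE],
             gc$features[, pairs[, 2], drop = FALSE],
             matrix(Fsp, 14L, k))
  p <- model$params
  Hid <- relu(sweep(crossprod(p$R1, U), 1L, p$r1, "+"))
  logits <- sweep(crossprod(p$R2, Hid), 1L, p$r2, "+") / Tn
  structure(list(logits = logits, probs = sigmoid(logits), pairs = pairs),
            class = "interaction_prediction")
}

#' @export
print.interaction_prediction <- function(x, ...) {
  cat(sprintf("interaction_prediction: %d edges x %d classes\n",
              ncol(x$logits), nrow(x$logits)))
  invisible(x)
}

# ---- scene embeddings and the fused train/eval path ------------------------

# Precompute everything the graph network consumes for one scene: visual and
# semantic node features, readout pairs, spatial features and labels. The
# FEN stays frozen during graph training, so this runs once per dataset.
embed_scene <- function(scene, fen, table) {
  gv <- embed_visual_graph(scene, fen)
  gs <- embed_semantic_graph(scene, table)
  t_idx <- which(gv$roles == "tissue")
  i_idx <- which(gv$roles == "instrument")
  pairs <- cbind(rep(t_idx[1], length(i_idx)), i_idx)
  Fsp <- if (length(i_idx)) {
    vapply(seq_along(i_idx), function(e)
      spatial_edge_features(gv$boxes[pairs[e, 1], ], gv$boxes[pairs[e, 2], ],
                            gv$image_wh), numeric(14L))
  } else matrix(numeric(), 14L, 0L)
  labels <- NULL
  if (!is.null(scene$interactions)) {
    ord <- match(i_idx, scene$interactions$pairs$instrument)
    labels <- t(scene$interactions$labels[ord, , drop = FALSE])  # 13 x k
  }
  list(V = gv$features, S = gs$features, pairs = pairs,
       Fsp = matrix(Fsp, 14L, length(i_idx)), labels = labels,
       n = gv$n)
}

#' Precompute graph inputs for a whole dataset
#'
#' Embeds every scene with the (frozen) feature extractor and the word
#' embedding table. Graph training and evaluation consume these embeddings.
#'
#' @param dataset A `surg_dataset`.
#' @param fen A `fen_model`.
#' @param table An embedding table covering the dataset's vocabulary.
#' @return An object of class `graph_embeddings` (list of per-scene
#'   embeddings with the domain id attached).
#' @export
embed_dataset <- function(dataset, fen, table) {
  stopifnot(inherits(dataset, "surg_dataset"))
  scenes <- lapply(dataset$scenes, embed_scene, fen = fen, table = table)
  structure(list(scenes = scenes, domain_id = dataset$domain_id),
            class = "graph_embeddings")
}

#' @export
print.graph_embeddings <- function(x, ...) {
  cat(sprintf("graph_embeddings: %d scenes, domain '%s'\n",
              length(x$scenes), x$domain_id))
  invisible(x)
}

# Fused forward over one embedded scene. Returns T-scaled logits (13 x k)
# plus caches for the backward pass.
graph_forward <- function(model, E, sigma = NULL, train = FALSE) {
  p <- model$params
  slope <- model$config$leaky_slope
  kern <- graph_ecbs_kernel(model, sigma)
  cv <- propagate_core(E$V, p$Wv, p$bv, p$Av, slope, kern)
  cs <- propagate_core(E$S, p$Ws, p$bs, p$As, slope, NULL)
  k <- ncol(E$Fsp)
  Tn <- model$config$tnorm$temperature
  if (k == 0L) {
    return(list(logits = matrix(numeric(), model$config$n_interactions, 0L),
                cache = NULL))
  }
  Cc <- rbind(cv$H, cs$H)
  U <- rbind(Cc[, E$pairs[, 1], drop = FALSE],
             Cc[, E$pairs[, 2], drop = FALSE], E$Fsp)
  pre1 <- sweep(crossprod(p$R1, U), 1L, p$r1, "+")
  Hid <- relu(pre1)
  logits <- sweep(crossprod(p$R2, Hid), 1L, p$r2, "+") / Tn
  cache <- if (train) list(cv = cv, cs = cs, U = U, Hid = Hid,
                           mask1 = pre1 > 0, kern = kern, E = E) else NULL
  list(logits = logits, cache = cache)
}

# Backward through one propagated graph; dH is the gradient at the
# propagated node features. Returns dW, db, dA (input features are fixed).
propagate_backward <- function(core, X, A, slope, kern, dH) {
  G <- dH * core$mask
  dZ <- G
  N <- ncol(X)
  if (N > 1L) {
    dM <- if (!is.null(kern)) conv1d_cols(G, rev(kern)) else G
    dZ <- dZ + dM %*% t(core$alpha)
    dalpha <- crossprod(core$Z, dM)
    ssum <- colSums(core$alpha * dalpha)
    dS <- core$alpha * sweep(dalpha, 2L, ssum, "-")
    dP <- dS * lrelu_grad(core$P, slope)
    diag(dP) <- 0
    dA <- core$Z %*% dP %*% t(core$Z)
    dZ <- dZ + A %*% core$Z %*% t(dP) + crossprod(A, core$Z) %*% dP
  } else {
    dA <- array(0, dim(A))
  }
  list(dW = X %*% t(dZ), db = rowSums(dZ), dA = dA)
}

# Fused backward; dlogits (13 x k) w.r.t. the T-scaled logits.
graph_backward <- function(model, cache, dlogits) {
  p <- model$params
  Tn <- model$config$tnorm$temperature
  dh <- model$config$hidden_dim
  E <- cache$E
  k <- ncol(dlogits)
  draw <- dlogits / Tn
  g <- list(
    R2 = cache$Hid %*% t(draw), r2 = rowSums(draw))
  dHid <- (p$R2 %*% draw) * cache$mask1
  g$R1 <- cache$U %*% t(dHid)
  g$r1 <- rowSums(dHid)
  dU <- p$R1 %*% dHid
  N <- ncol(cache$cv$H)
  dC <- matrix(0, 2L * dh, N)
  for (e in seq_len(k)) {
    dC[, E$pairs[e, 1]] <- dC[, E$pairs[e, 1]] + dU[seq_len(2L * dh), e]
    dC[, E$pairs[e, 2]] <- dC[, E$pairs[e, 2]] +
      dU[2L * dh + seq_len(2L * dh), e]
  }
  bv <- propagate_backward(cache$cv, E$V, p$Av, model$config$leaky_slope,
                           cache$kern, dC[seq_len(dh), , drop = FALSE])
  bs <- propagate_backward(cache$cs, E$S, p$As, model$config$leaky_slope,
                           NULL, dC[dh + seq_len(dh), , drop = FALSE])
  g$Wv <- bv$dW; g$bv <- bv$db; g$Av <- bv$dA
  g$Ws <- bs$dW; g$bs <- bs$db; g$As <- bs$dA
  g
}

# Predict logits for every scene of an embeddings object (eval mode).
graph_predict <- function(model, embeds) {
  lapply(embeds$scenes, function(E) graph_forward(model, E)$logits)
}
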