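# Scene-graph network: embeddings, attention, combination, spatial features,
# readout, and the permutation / duplicate-instrument contracts.

make_scene <- function(classes, boxes, seed = 99) {
  ents <- lapply(seq_along(classes), function(i)
    entity_spec(classes[i], boxes[[i]]))
  set.seed(seed)
  img <- render_scene(ents, 64, 64)
  wh <- c(64, 64)
  instr <- which(classes != "kidney")
  labels <- matrix(0L, length(instr), 13L,
                   dimnames = list(NULL, interaction_vocabulary()))
  for (j in seq_along(instr)) {
    e <- ents[[instr[j]]]
    labels[j, ] <- interaction_rule(ents[[which(classes == "kidney")]], e,
                                    e$class_name, wh)
  }
  surgraph:::new_scene(img, ents,
                       list(pairs = data.frame(
                         tissue = rep(which(classes == "kidney"), length(instr)),
                         instrument = instr),
                         labels = labels),
                       "source")
}

toy_model <- function(fen, seed = 21) {
  dv <- 2L * tail(fen$config$stage_channels, 1) + 8L
  build_graph_model(graph_config(visual_dim = dv, semantic_dim = 32L,
                                 hidden_dim = 8L, readout_hidden = 12L,
                                 ecbs = list(enabled = TRUE, sigma0 = 1)),
                    seed = seed)
}

test_that("visual/semantic embedding builds the documented graph structure", {
  fen <- fx_small_fen()
  tab <- fx_small_table()
  sc <- make_scene(c("kidney", "suction", "stapler"),
                   list(c(10, 10, 40, 40), c(20, 20, 44, 44),
                        c(46, 46, 62, 62)))
  gv <- embed_visual_graph(sc, fen)
  gs <- embed_semantic_graph(sc, tab)
  expect_equal(gv$n, 3L)
  expect_equal(nrow(gv$features), 2L * 8L + 8L)
  expect_identical(gs$class_names, gv$class_names)   # same topology
  expect_equal(nrow(gs$features), 32L)
  # same class name -> identical semantic features
  sc2 <- make_scene(c("kidney", "suction", "suction"),
                    list(c(10, 10, 40, 40), c(20, 20, 44, 44),
                         c(46, 46, 62, 62)))
  gs2 <- embed_semantic_graph(sc2, tab)
  expect_identical(gs2$features[, 2], gs2$features[, 3])
  # deterministic in eval mode
  expect_identical(embed_visual_graph(sc, fen)$features, gv$features)
  # unknown class errors with its name
  tab_small <- make_embedding_table(c("kidney", "suction"), 32, 1)
  expect_error(embed_semantic_graph(sc, tab_small), "stapler")
})

test_that("attention weights normalize over in-neighbours", {
  fen <- fx_small_fen()
  tab <- fx_small_table()
  sc <- make_scene(c("kidney", "suction", "stapler", "bipolar forceps"),
                   list(c(10, 10, 40, 40), c(20, 20, 44, 44),
                        c(46, 46, 62, 62), c(2, 44, 20, 62)))
  m <- toy_model(fen)
  gv <- attention_propagate(embed_visual_graph(sc, fen), m, use_ecbs = TRUE)
  a <- attr(gv, "alpha")
  expect_equal(unname(colSums(a)), rep(1, 4), tolerance = 1e-6)
  expect_true(all(diag(a) == 0))
  # two nodes: the single in-neighbour carries weight 1
  sc2 <- make_scene(c("kidney", "suction"),
                    list(c(10, 10, 40, 40), c(20, 20, 44, 44)))
  gv2 <- attention_propagate(embed_visual_graph(sc2, fen), m)
  expect_equal(attr(gv2, "alpha")[2, 1], 1)
})

test_that("single-entity scenes degrade gracefully", {
  fen <- fx_small_fen()
  tab <- fx_small_table()
  sc <- make_scene("kidney", list(c(10, 10, 40, 40)))
  m <- toy_model(fen)
  gv <- attention_propagate(embed_visual_graph(sc, fen), m)
  gs <- attention_propagate(embed_semantic_graph(sc, tab), m)
  pred <- readout_interactions(combine_graphs(gv, gs), m)
  expect_equal(ncol(pred$logits), 0L)
})

test_that("graph combination concatenates features preserving node order", {
  fen <- fx_small_fen()
  tab <- fx_small_table()
  sc <- make_scene(c("kidney", "suction", "stapler"),
                   list(c(10, 10, 40, 40), c(20, 20, 44, 44),
                        c(46, 46, 62, 62)))
  m <- toy_model(fen)
  gv <- attention_propagate(embed_visual_graph(sc, fen), m, use_ecbs = TRUE)
  gs <- attention_propagate(embed_semantic_graph(sc, tab), m)
  gc <- combine_graphs(gv, gs)
  dh <- m$config$hidden_dim
  expect_equal(nrow(gc$features), 2L * dh)    # d_c = d_v' + d_s'
  expect_identical(gc$features[1:dh, ], gv$features)
  expect_identical(gc$class_names, gv$class_names)
  # zero semantic features -> combined nodes reduce to padded visual features
  gs0 <- gs
  gs0$features <- gs$features * 0
  gc0 <- combine_graphs(gv, gs0)
  expect_identical(gc0$features[dh + 1:dh, ], gs$features * 0)
  expect_identical(gc0$features[1:dh, ], gv$features)
})

test_that("spatial features hit their closed-form values", {
  wh <- c(128, 128)
  b <- c(20, 30, 60, 70)
  f <- spatial_edge_features(b, b, wh)
  expect_length(f, 14L)
  expect_equal(f[9:12], rep(0, 4))   # offsets and log ratios
  expect_equal(f[13], 1)             # IoU of identical boxes
  f2 <- spatial_edge_features(c(0, 0, 10, 10), c(100, 100, 120, 120), wh)
  expect_equal(f2[13], 0)
  expect_error(spatial_edge_features(c(0, 0, 0, 10), b, wh), "zero-area")
})

test_that("analytic IoU matches a pixel-counting oracle on random integer boxes", {
  set.seed(17)
  for (i in 1:40) {
    a <- sort(sample(0:32, 2)); a2 <- sort(sample(0:32, 2))
    b <- sort(sample(0:32, 2)); b2 <- sort(sample(0:32, 2))
    if (a[1] == a[2] || a2[1] == a2[2] || b[1] == b[2] || b2[1] == b2[2]) next
    A <- c(a[1], a2[1], a[2], a2[2])
    B <- c(b[1], b2[1], b[2], b2[2])
    grid <- expand.grid(x = 0:31, y = 0:31)
    inA <- grid$x >= A[1] & grid$x < A[3] & grid$y >= A[2] & grid$y < A[4]
    inB <- grid$x >= B[1] & grid$x < B[3] & grid$y >= B[2] & grid$y < B[4]
    want <- if (!any(inA & inB)) 0 else sum(inA & inB) / sum(inA | inB)
    expect_equal(spatial_edge_features(A, B, c(32, 32))[13], want,
                 tolerance = 1e-6)
  }
})

test_that("readout yields one prediction per instrument and shares T-Norm", {
  fen <- fx_small_fen()
  tab <- fx_small_table()
  sc <- make_scene(c("kidney", "suction", "stapler", "bipolar forceps"),
                   list(c(10, 10, 40, 40), c(20, 20, 44, 44),
                        c(46, 46, 62, 62), c(2, 44, 20, 62)))
  m <- toy_model(fen)
  gv <- attention_propagate(embed_visual_graph(sc, fen), m, use_ecbs = TRUE)
  gs <- attention_propagate(embed_semantic_graph(sc, tab), m)
  gc <- combine_graphs(gv, gs)
  pred <- readout_interactions(gc, m)
  expect_equal(ncol(pred$logits), 3L)
  expect_equal(nrow(pred$logits), 13L)
  expect_true(all(pred$probs > 0 & pred$probs < 1))
  pred1 <- readout_interactions(gc, m, tnorm = tnorm_config(1))
  expect_equal(pred$logits,
               apply_tnorm(pred1$logits, m$config$tnorm))
})

test_that("logits stay finite over many random embeddings", {
  set.seed(23)
  m <- build_graph_model(graph_config(visual_dim = 10, semantic_dim = 6,
                                      hidden_dim = 5, readout_hidden = 7,
                                      ecbs = list(enabled = TRUE)), seed = 3)
  for (i in 1:1000) {
    E <- random_embedding(sample(1:4, 1), dv = 10L, ds = 6L)
    lg <- surgraph:::graph_forward(m, E)$logits
    expect_true(all(is.finite(lg)))
  }
})

test_that("relabelling entities permutes predictions consistently", {
  fen <- fx_small_fen()
  tab <- fx_small_table()
  classes <- c("kidney", "suction", "stapler", "bipolar forceps")
  # disjoint boxes so the raster is identical under any draw order
  boxes <- list(c(10, 10, 30, 30), c(36, 8, 56, 24),
                c(40, 40, 60, 60), c(8, 40, 24, 60))
  m <- toy_model(fen)
  run <- function(cl, bx) {
    sc <- make_scene(cl, bx)
    gv <- attention_propagate(embed_visual_graph(sc, fen), m, use_ecbs = TRUE)
    gs <- attention_propagate(embed_semantic_graph(sc, tab), m)
    pred <- readout_interactions(combine_graphs(gv, gs), m)
    # key predictions by instrument class (unique here)
    setNames(lapply(seq_len(ncol(pred$logits)), function(j) pred$logits[, j]),
             cl[pred$pairs[, 2]])
  }
  p1 <- run(classes, boxes)
  perm <- c(3, 1, 4, 2)
  p2 <- run(classes[perm], boxes[perm])
  for (nm in names(p1)) expect_equal(p2[[nm]], p1[[nm]], tolerance = 1e-10)
})

test_that("duplicate instruments receive identical logits", {
  fen <- fx_small_fen()
  tab <- fx_small_table()
  sc <- make_scene(c("kidney", "suction", "suction"),
                   list(c(10, 10, 40, 40), c(44, 8, 60, 24), c(44, 8, 60, 24)))
  m <- toy_model(fen)
  gv <- attention_propagate(embed_visual_graph(sc, fen), m, use_ecbs = TRUE)
  gs <- attention_propagate(embed_semantic_graph(sc, tab), m)
  pred <- readout_interactions(combine_graphs(gv, gs), m)
  expect_equal(pred$logits[, 1], pred$logits[, 2], tolerance = 1e-10)
})
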