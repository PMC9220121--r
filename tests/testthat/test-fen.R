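# Feature extractor: structure, E-CBS placement, training, features,
# exemplar memory and incremental extension.

test_that("E-CBS placement matches the architecture contract", {
  cfg <- fen_config(n_classes = 3, stage_channels = c(4, 6),
                    blocks_per_stage = c(1, 1), input_size = 8,
                    cbs = list(kind = "e_cbs"))
  m <- build_backbone(cfg, seed = 1)
  layout <- surgraph:::fen_smoothing_layout(m)
  expect_equal(layout[["log"]], 1L)        # one LoG after the stem
  expect_equal(layout[["gaussian"]], 2L)   # one Gaussian per residual block
  layout <- surgraph:::fen_smoothing_layout(
    build_backbone(fen_config(3, c(4, 6), c(1, 1), 8,
                              cbs = list(kind = "cbs")), seed = 1))
  expect_equal(unname(layout), c(0L, 3L))
})

test_that("below the sigma floor the forward pass equals the no-CBS model", {
  cfg_on <- fen_config(4, c(4, 6), c(1, 1), 8, cbs = list(kind = "e_cbs"))
  cfg_off <- fen_config(4, c(4, 6), c(1, 1), 8, cbs = list(kind = "none"))
  m_on <- build_backbone(cfg_on, seed = 5)
  m_off <- build_backbone(cfg_off, seed = 5)
  m_off$params <- m_on$params
  set.seed(1)
  X <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  f_on <- surgraph:::fen_forward(m_on, X, sigma = 1e-6)
  f_off <- surgraph:::fen_forward(m_off, X)
  expect_equal(f_on$logits, f_off$logits)
  # and with sigma above the floor they differ
  f_s <- surgraph:::fen_forward(m_on, X, sigma = 1)
  expect_gt(max(abs(f_s$logits - f_off$logits)), 1e-8)
})

test_that("logit and feature dimensions follow the config", {
  m <- build_backbone(fen_config(5, c(4, 8), c(1, 1), 8), seed = 2)
  set.seed(2)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  fw <- surgraph:::fen_forward(m, array(x, c(8, 8, 3, 1)))
  expect_length(fw$logits, 5L)
  expect_length(extract_features(m, x), 8L)  # last stage width
  expect_identical(extract_features(m, x), extract_features(m, x))
})

test_that("initial cross entropy is about ln(K) and training fits a separable toy", {
  set.seed(33)
  # two-class colour blobs
  mk <- function(col) {
    x <- array(runif(16 * 16 * 3, 0, 0.15), c(16, 16, 3))
    x[5:12, 5:12, col] <- x[5:12, 5:12, col] + 0.7
    x
  }
  crops <- c(lapply(1:20, function(i) mk(1)), lapply(1:20, function(i) mk(3)))
  labels <- rep(c("red", "blue"), each = 20)
  m <- build_backbone(fen_config(2, c(4, 8), c(1, 1), 16,
                                 cbs = list(kind = "e_cbs")),
                      classes = c("red", "blue"), seed = 9)
  fw <- surgraph:::fen_forward(m, surgraph:::stack_crops(crops[c(1, 21)]))
  l0 <- surgraph:::ce_loss_grad(fw$logits, c(1L, 2L))$loss
  expect_lt(abs(l0 - log(2)) / log(2), 0.2)
  m <- train_classifier(m, crops, labels, epochs = 30, batch = 10,
                        lr0 = 2e-2, lr_decay = 0.97, seed = 4)
  expect_gte(tail(m$history$acc, 1), 0.95)
  # label smoothing changes the optimisation trajectory
  m_ls <- build_backbone(fen_config(2, c(4, 8), c(1, 1), 16,
                                    cbs = list(kind = "e_cbs"),
                                    label_smoothing = 0.1),
                         classes = c("red", "blue"), seed = 9)
  m_ls <- train_classifier(m_ls, crops, labels, epochs = 3, batch = 10,
                           lr0 = 5e-3, seed = 4)
  m_0 <- build_backbone(fen_config(2, c(4, 8), c(1, 1), 16,
                                   cbs = list(kind = "e_cbs")),
                        classes = c("red", "blue"), seed = 9)
  m_0 <- train_classifier(m_0, crops, labels, epochs = 3, batch = 10,
                          lr0 = 5e-3, seed = 4)
  expect_false(isTRUE(all.equal(tail(m_ls$history$loss, 1),
                                tail(m_0$history$loss, 1))))
  expect_error(train_classifier(m, list(), character()), "empty")
})

test_that("features separate classes after training on the toy task", {
  fen <- fx_small_fen()
  ds <- fx_small()
  crops <- scene_crops(ds$source, 16L)
  feats <- extract_features(fen, crops$crops)
  lab <- crops$labels
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  set.seed(6)
  same <- c(); diff <- c()
  for (i in 1:200) {
    ij <- sample(length(lab), 2)
    cs <- cosine(feats[ij[1], ], feats[ij[2], ])
    if (lab[ij[1]] == lab[ij[2]]) same <- c(same, cs) else diff <- c(diff, cs)
  }
  expect_gt(mean(same), mean(diff))
})

test_that("memory quotas split the capacity with remainder to frequent classes", {
  classes9 <- surgical_vocabulary("source")
  counts <- c(20, 15, 12, 10, 9, 8, 8, 8, 8)
  labels <- rep(classes9, counts)
  crops <- replicate(length(labels), array(0, c(2, 2, 3)), simplify = FALSE)
  mem <- build_memory(crops, labels, capacity = 50, seed = 3)
  tab <- table(mem$labels)
  expect_lte(length(mem$crops), 50L)
  expect_true(all(tab %in% c(5L, 6L)))     # floor(50/9) = 5, remainder 5
  expect_equal(sum(tab == 6L), 5L)
  # the remainder goes to the most frequent classes
  expect_true(all(names(tab)[tab == 6L] %in% classes9[1:5]))
  mem2 <- build_memory(crops, labels, capacity = 50, seed = 3)
  expect_identical(mem$labels, mem2$labels)
})

test_that("herding picks the feature-mean nearest neighbour first", {
  ds <- fx_small()
  fen <- fx_small_fen()
  crops <- scene_crops(ds$source, 16L)
  keep <- crops$labels %in% c("kidney", "bipolar forceps")
  mem <- build_memory(crops$crops[keep], crops$labels[keep], capacity = 4,
                      strategy = "herding", model = fen, seed = 1)
  for (cl in unique(mem$labels)) {
    idx <- which(crops$labels[keep] == cl)
    feats <- extract_features(fen, crops$crops[keep][idx])
    mu <- colMeans(feats)
    nearest <- idx[which.min(colSums((t(feats) - mu)^2))]
    first_stored <- mem$crops[[match(cl, mem$labels)]]
    expect_identical(first_stored, crops$crops[keep][[nearest]])
  }
})

test_that("head widening preserves the old decision function exactly", {
  fen <- fx_small_fen()
  wide <- incremental_extend(fen, list(), character(0), NULL, epochs = 0)
  expect_equal(wide$config$n_classes, 9L)   # no new classes requested
  wide <- surgraph:::widen_head(fen, c("new1", "new2"), seed = 2)
  expect_equal(wide$config$n_classes, 11L)
  expect_identical(wide$params$head_W[, 1:9], fen$params$head_W)
  expect_identical(wide$params$head_b[1:9], fen$params$head_b)
  set.seed(8)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  old_logits <- surgraph:::fen_forward(fen, x)$logits
  new_logits <- surgraph:::fen_forward(wide, x)$logits
  expect_equal(new_logits[, 1:9], old_logits[1, ])
  expect_error(surgraph:::widen_head(fen, "kidney"), "overlap")
})

test_that("a huge distillation weight freezes old-class logits", {
  ds <- fx_small()
  fen <- fx_small_fen()
  tgt_crops <- scene_crops(ds$target, 16L)
  novel <- ds$target$config$novel_classes
  is_novel <- tgt_crops$labels %in% novel
  src_crops <- scene_crops(ds$source, 16L)
  mem <- build_memory(src_crops$crops, src_crops$labels, capacity = 27,
                      seed = 2)
  before <- surgraph:::fen_predict(fen, mem$crops)$logits
  ext <- incremental_extend(fen, tgt_crops$crops[is_novel],
                            tgt_crops$labels[is_novel], mem,
                            epochs = 2, finetune_epochs = 0, lr = 1e-6,
                            distill_weight = 1e3, seed = 5)
  after <- surgraph:::fen_predict(ext, mem$crops)$logits[, 1:9]
  expect_lt(max(abs(after - before)), 0.05)
})
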