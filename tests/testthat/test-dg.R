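# DG losses and training regimes.

test_that("soft-margin loss hits its closed forms and elementwise oracle", {
  gt <- matrix(0L, 13, 3)
  gt[cbind(c(2, 5, 9), 1:3)] <- 1L
  expect_equal(msl_loss(matrix(0, 13, 3), gt), log(2), tolerance = 1e-12)
  # perfect-fit limit
  big <- ifelse(gt == 1, 40, -40)
  expect_lt(msl_loss(big, gt), 1e-12)
  # random case vs direct elementwise formula
  set.seed(12)
  z <- matrix(rnorm(13 * 5, sd = 2), 13, 5)
  y <- matrix(rbinom(65, 1, 0.3), 13, 5)
  p <- 1 / (1 + exp(-z))
  oracle <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(msl_loss(z, y), oracle, tolerance = 1e-8)
  expect_error(msl_loss(z, y + 0.5), "binary")
  expect_error(msl_loss(z, y[, 1:2]), "mismatch")
})

test_that("distillation loss equals teacher entropy plus KL", {
  expect_equal(kd_loss(rep(0, 13), rep(0, 13)), log(13), tolerance = 1e-12)
  set.seed(4)
  s <- matrix(rnorm(13 * 4), 13, 4)
  t <- matrix(rnorm(13 * 4), 13, 4)
  pt <- apply(t, 2, function(c) exp(c) / sum(exp(c)))
  ps <- apply(s, 2, function(c) exp(c) / sum(exp(c)))
  H <- -colSums(pt * log(pt))
  KL <- colSums(pt * log(pt / ps))
  expect_equal(kd_loss(s, t), mean(H + KL), tolerance = 1e-8)
  # minimized exactly when the student matches the teacher distribution
  expect_lt(kd_loss(t, t), kd_loss(t + matrix(rnorm(52, sd = 0.3), 13), t))
  expect_error(kd_loss(s, t[, 1:2]), "mismatch")
})

test_that("dg_step_losses composes the 0.5-weighted sum of its parts", {
  cfg <- dg_config()
  expect_equal(cfg$kd_weight, 0.5)
  gt1 <- matrix(0L, 13, 2); gt1[cbind(c(1, 6), 1:2)] <- 1L
  z0 <- matrix(0, 13, 2)
  out <- dg_step_losses(z0, gt1, z0, gt1, z0, cfg)
  expect_equal(out$L_TD, log(2), tolerance = 1e-12)
  expect_equal(out$L_nSD, log(2) + 0.5 * log(13), tolerance = 1e-12)
  expect_equal(out$L_DG, 2 * log(2) + 0.5 * log(13), tolerance = 1e-12)
  # random case vs independently composed oracles
  set.seed(99)
  st <- matrix(rnorm(26), 13); ss <- matrix(rnorm(26), 13)
  tt <- matrix(rnorm(26), 13)
  g1 <- matrix(rbinom(26, 1, 0.2), 13); g2 <- matrix(rbinom(26, 1, 0.2), 13)
  out <- dg_step_losses(st, g1, ss, g2, tt, cfg)
  expect_equal(out$L_DG,
               msl_loss(st, g1) + msl_loss(ss, g2) + 0.5 * kd_loss(ss, tt),
               tolerance = 1e-8)
  # student identical to teacher with a perfect ground-truth fit: only the
  # 0.5-weighted teacher entropy survives
  zfit <- ifelse(g2 == 1, 40, -40)
  out <- dg_step_losses(ifelse(g1 == 1, 40, -40), g1, zfit, g2, zfit, cfg)
  pt <- apply(zfit, 2, function(c) exp(c - max(c)) / sum(exp(c - max(c))))
  expect_equal(out$L_DG, 0.5 * mean(-colSums(pt * log(pt))),
               tolerance = 1e-6)
  expect_error(dg_step_losses(st, g1, ss, g2, NULL, cfg), "teacher")
})

toy_embeds <- function(n_scenes, seed, domain = "source") {
  set.seed(seed)
  structure(list(scenes = lapply(seq_len(n_scenes), function(i)
    random_embedding(sample(2:4, 1))), domain_id = domain),
    class = "graph_embeddings")
}

toy_graph <- function(seed = 1) {
  build_graph_model(graph_config(visual_dim = 10, semantic_dim = 6,
                                 hidden_dim = 6, readout_hidden = 8,
                                 ecbs = list(enabled = TRUE)), seed = seed)
}

test_that("source training is seeded-deterministic with decreasing loss", {
  emb <- toy_embeds(20, 5)
  cfg <- dg_config(n_sample = 5, lr_main = 1e-3, epochs_main = 30,
                   batch = 8, seed = 3)
  m1 <- train_source(toy_graph(), emb, cfg)
  m2 <- train_source(toy_graph(), emb, cfg)
  expect_identical(m1$params, m2$params)
  lh <- attr(m1, "loss_history")
  k <- length(lh) %/% 2
  expect_lt(mean(tail(lh, k)), mean(head(lh, k)))
})

test_that("teacher stays frozen and the naive arms touch the right data", {
  emb_s <- toy_embeds(20, 5)
  emb_t <- toy_embeds(8, 6, domain = "target")
  cfg <- dg_config(n_sample = 5, lr_main = 1e-3, epochs_main = 10,
                   epochs_finetune = 4, lr_finetune = 1e-4, batch = 8,
                   seed = 3)
  teacher <- train_source(toy_graph(), emb_s, cfg)
  probe <- surgraph:::graph_forward(teacher, emb_s$scenes[[1]])$logits
  student <- incremental_domain_generalize(teacher_student_pair(teacher),
                                           emb_t, emb_s, cfg)
  expect_identical(surgraph:::graph_forward(teacher, emb_s$scenes[[1]])$logits,
                   probe)
  expect_false(identical(student$params, teacher$params))
  # naive adaptation never sees source scenes
  adapted <- naive_adapt(teacher, emb_t, cfg)
  log <- attr(adapted, "data_log")
  expect_false(any(grepl("source", names(log))))
  # naive DG fine-tunes on n scenes from each domain (2n total)
  ndg <- naive_dg(teacher, emb_t, emb_s, cfg)
  log <- attr(ndg, "data_log")
  expect_equal(log[["finetune_source"]], 5L * cfg$epochs_finetune)
  expect_equal(log[["finetune_target"]], 5L * cfg$epochs_finetune)
  expect_error(
    incremental_domain_generalize(teacher_student_pair(teacher), emb_t,
                                  emb_s, dg_config(n_sample = 100)),
    "n_sample")
})

test_that("balanced fine-tuning samples equally and reproducibly", {
  emb_s <- toy_embeds(20, 5)
  emb_t <- toy_embeds(8, 6, domain = "target")
  cfg <- dg_config(n_sample = 6, lr_finetune = 1e-4, epochs_finetune = 3,
                   batch = 8, seed = 9)
  m <- toy_graph()
  f1 <- balanced_finetune(m, emb_s, emb_t, cfg)
  f2 <- balanced_finetune(m, emb_s, emb_t, cfg)
  expect_identical(f1$params, f2$params)
  log <- attr(f1, "data_log")
  expect_equal(log[["finetune_source"]], log[["finetune_target"]])
})
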