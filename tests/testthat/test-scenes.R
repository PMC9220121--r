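# Synthetic scene generator: determinism, invariants, long tail, labelling
# rule, embeddings, serialization.

test_that("generation is deterministic and respects scene invariants", {
  cfg <- domain_config("source", n_scenes = 10, seed = 123)
  d1 <- generate_domain(cfg)
  d2 <- generate_domain(cfg)
  expect_identical(d1, d2)
  for (sc in d1$scenes) {
    expect_equal(sum(sc$entities$role == "tissue"), 1L)
    n_instr <- sum(sc$entities$role == "instrument")
    expect_equal(nrow(sc$interactions$pairs), n_instr)
    expect_true(all(rowSums(sc$interactions$labels) >= 1))
    expect_true(all(sc$entities$x0 < sc$entities$x1))
    expect_true(all(sc$entities$y0 < sc$entities$y1))
    expect_true(all(sc$entities$class %in% d1$class_vocabulary))
  }
  expect_error(domain_config("source", n_scenes = 0, seed = 1), "positive")
})

test_that("instrument class frequencies are long-tailed under the Zipf exponent", {
  d <- generate_domain(domain_config("source", n_scenes = 500, seed = 31,
                                     longtail_exponent = 1.5))
  cls <- unlist(lapply(d$scenes, function(sc)
    sc$entities$class[sc$entities$role == "instrument"]))
  counts <- as.numeric(table(factor(cls, levels = surgical_vocabulary()[-1])))
  expect_true(all(diff(counts) <= 0))      # canonical rank order is monotone
  expect_gt(counts[1] / max(counts[length(counts)], 1), 5)
})

test_that("the labelling rule fires the documented branches", {
  wh <- c(128, 128)
  box <- c(40, 40, 80, 80)
  y <- interaction_rule(box, box, "monopolar curved scissors", wh)
  expect_equal(names(which(y == 1)), "cutting")
  y <- interaction_rule(box, box, "prograsp forceps", wh)
  expect_equal(names(which(y == 1)), "grasping")
  # disjoint boxes at opposite corners -> idle
  y <- interaction_rule(c(0, 0, 20, 20), c(108, 108, 128, 128),
                        "suction", wh)
  expect_equal(names(which(y == 1)), "idle")
  expect_error(interaction_rule(box, box, "lightsaber", wh), "unknown")
})

test_that("rule output matches an independent threshold oracle over a box grid", {
  # Brute-force oracle: pixel-counting IoU + direct centre distance, and a
  # re-statement of the thresholds (contact > 0.1; hover: disjoint and
  # distance < 0.35 * diagonal; else idle).
  wh <- c(64, 64)
  pixel_iou <- function(a, b) {
    grid <- expand.grid(x = 0:63, y = 0:63)
    inA <- grid$x >= a[1] & grid$x < a[3] & grid$y >= a[2] & grid$y < a[4]
    inB <- grid$x >= b[1] & grid$x < b[3] & grid$y >= b[2] & grid$y < b[4]
    if (!any(inA & inB)) 0 else sum(inA & inB) / sum(inA | inB)
  }
  starts <- seq(0, 48, by = 8)
  tissue <- c(16, 16, 48, 48)
  for (x0 in starts) for (y0 in starts) {
    box <- c(x0, y0, x0 + 16, y0 + 16)
    got <- interaction_rule(tissue, box, "monopolar curved scissors", wh)
    iou <- pixel_iou(tissue, box)
    d <- sqrt((32 - (x0 + 8))^2 + (32 - (y0 + 8))^2)
    want <- if (iou > 0.1) "cutting"
            else if (iou == 0 && d < 0.35 * sqrt(sum(wh^2))) "tissue manipulation"
            else "idle"
    expect_equal(names(which(got == 1)), want,
                 info = sprintf("box at (%d, %d)", x0, y0))
  }
})

test_that("generated labels are learnable from (IoU, distance, class)", {
  skip_if_not_installed("nnet")
  ds <- fx_protocol()$datasets$source
  et <- surgraph:::edge_table(ds)
  X <- model.matrix(~ iou + dist + class, et)
  fit <- nnet::multinom(factor(et$label) ~ X - 1, trace = FALSE, maxit = 300)
  expect_gte(mean(as.character(predict(fit)) == et$label), 0.95)
})

test_that("the target render of a scene spec is visibly shifted from the source", {
  cfg_s <- domain_config("source", n_scenes = 1, seed = 5)
  cfg_t <- domain_config("target", n_scenes = 1, seed = 5)
  set.seed(10); ents <- surgraph:::sample_scene_spec(cfg_s)
  set.seed(2); img_s <- render_scene(ents, 128, 128, cfg_s$shift_params)
  set.seed(2); img_t <- render_scene(ents, 128, 128, cfg_t$shift_params)
  expect_gt(mean(abs(img_s - img_t)), 8)
})

test_that("embedding table vectors are deterministic, unit-norm and distinct", {
  vocab <- surgical_vocabulary("target")
  t1 <- make_embedding_table(vocab, dim = 300, seed = 7)
  t2 <- make_embedding_table(vocab, dim = 300, seed = 7)
  expect_identical(t1[, "suction"], t2[, "suction"])
  norms <- sqrt(colSums(t1^2))
  expect_true(all(abs(norms - 1) < 1e-9))
  D <- as.matrix(dist(t(unclass(t1))))
  expect_gt(min(D[upper.tri(D)]), 0)
  expect_equal(ncol(t1), 11L)
  # same name, same vector regardless of surrounding vocabulary
  t3 <- make_embedding_table("suction", dim = 300, seed = 7)
  expect_identical(t1[, "suction"], t3[, "suction"])
  expect_error(make_embedding_table(c("a", "a"), 32, 1), "duplicate")
  expect_error(make_embedding_table("a", dim = 4, seed = 1), ">= 8")
})

test_that("annotation write/read is a round-trip identity", {
  ds <- generate_domain(domain_config("target", n_scenes = 4, seed = 55))
  path <- withr::local_tempdir()
  write_annotations(ds, path)
  back <- read_annotations(path)
  expect_equal(back, ds)
})

test_that("malformed annotation files raise parse errors naming the record", {
  path <- withr::local_tempdir()
  dir.create(file.path(path, "images"))
  img <- array(0L, c(8, 8, 3))
  png::writePNG(img / 255, file.path(path, "images", "scene_0001.png"))
  doc <- list(
    images = list(list(id = 1, file = "images/scene_0001.png", width = 8,
                       height = 8, domain = "source")),
    entities = list(list(id = 1, image_id = 1, class = "kidney",
                         bbox = c(6, 1, 2, 5))),    # x1 <= x0
    interactions = list(),
    vocabulary = list(tissue = "kidney", instruments = list("suction"),
                      interactions = as.list(interaction_vocabulary())))
  jsonlite::write_json(doc, file.path(path, "annotations.json"),
                       auto_unbox = TRUE)
  expect_error(read_annotations(path), "entity 1")
  expect_error(read_annotations(withr::local_tempdir()), "annotations.json")
})

test_that("a hand-written single-scene annotation file parses as expected", {
  path <- withr::local_tempdir()
  dir.create(file.path(path, "images"))
  png::writePNG(array(0.5, c(16, 16, 3)),
                file.path(path, "images", "scene_0001.png"))
  writeLines('{
    "images": [{"id": 1, "file": "images/scene_0001.png",
                "width": 16, "height": 16, "domain": "source"}],
    "entities": [
      {"id": 1, "image_id": 1, "class": "kidney", "bbox": [2, 2, 10, 10]},
      {"id": 2, "image_id": 1, "class": "suction", "bbox": [4, 4, 12, 12]}],
    "interactions": [
      {"image_id": 1, "tissue_id": 1, "instrument_id": 2, "labels": [7]}],
    "vocabulary": {"tissue": "kidney", "instruments": ["suction"],
                   "interactions": ["idle", "grasping", "retraction",
                     "tissue manipulation", "tool manipulation", "cutting",
                     "cauterization", "suction", "looping", "suturing",
                     "clipping", "staple", "ultrasound sensing"]}
  }', file.path(path, "annotations.json"))
  ds <- read_annotations(path)
  expect_length(ds$scenes, 1L)
  sc <- ds$scenes[[1]]
  expect_equal(nrow(sc$entities), 2L)
  expect_equal(sum(sc$entities$role == "tissue"), 1L)
  # 0-based label index 7 is the 8th class, "suction"
  expect_equal(colnames(sc$interactions$labels)[sc$interactions$labels[1, ] == 1],
               "suction")
})
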