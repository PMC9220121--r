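# COCO-flavoured annotation serialization.
#
# A dataset directory contains `annotations.json` plus `images/scene_NNNN.png`.
# JSON layout:
#   images:       [{id, file, width, height, domain}]
#   entities:     [{id, image_id, class, bbox: [x0, y0, x1, y1], style}]
#   interactions: [{image_id, tissue_id, instrument_id, labels: [0-based
#                   indices into vocabulary$interactions]}]
#   vocabulary:   {tissue, instruments, interactions}
#   config:       the generating domain_config (for exact round-trips)
# Boxes are 0-based half-open pixel coordinates, as everywhere in the package.

#' Write / read a dataset in the annotation dialect
#'
#' `write_annotations()` serializes a [generate_domain()] dataset to a
#' directory (`annotations.json` + lossless PNG frames);
#' `read_annotations()` reconstructs it. The pair is a round-trip identity:
#' `read_annotations(write_annotations(d, path))` equals `d`.
#'
#' @param dataset A `surg_dataset`.
#' @param path Directory to create/read.
#' @return `write_annotations()`: `path`, invisibly. `read_annotations()`:
#'   the reconstructed `surg_dataset`.
#' @export
write_annotations <- function(dataset, path) {
  stopifnot(inherits(dataset, "surg_dataset"))
  dir.create(file.path(path, "images"), recursive = TRUE, showWarnings = FALSE)
  images <- list(); entities <- list(); interactions <- list()
  eid <- 0L
  for (s in seq_along(dataset$scenes)) {
    sc <- dataset$scenes[[s]]
    file <- sprintf("images/scene_%04d.png", s)
    png::writePNG(sc$image / 255, file.path(path, file))
    images[[s]] <- list(id = s, file = file,
                        width = dim(sc$image)[2], height = dim(sc$image)[1],
                        domain = sc$domain_id)
    ids <- integer(nrow(sc$entities))
    for (e in seq_len(nrow(sc$entities))) {
      eid <- eid + 1L
      ids[e] <- eid
      entities[[eid]] <- list(
        id = eid, image_id = s, class = sc$entities$class[e],
        bbox = as.numeric(sc$entities[e, c("x0", "y0", "x1", "y1")]),
        style = sc$entities$style[e])
    }
    for (j in seq_len(nrow(sc$interactions$pairs))) {
      interactions[[length(interactions) + 1L]] <- list(
        image_id = s,
        tissue_id = ids[sc$interactions$pairs$tissue[j]],
        instrument_id = ids[sc$interactions$pairs$instrument[j]],
        labels = which(sc$interactions$labels[j, ] == 1L) - 1L)
    }
  }
  doc <- list(
    images = images, entities = entities, interactions = interactions,
    vocabulary = list(tissue = SOURCE_TISSUE,
                      instruments = setdiff(dataset$class_vocabulary,
                                            SOURCE_TISSUE),
                      interactions = dataset$interaction_vocabulary),
    config = unclass(dataset$config))
  jsonlite::write_json(doc, file.path(path, "annotations.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

need_key <- function(rec, key, what, id) {
  stop_if(is.null(rec[[key]]),
          "annotation parse error: ", what, " record ", id,
          " is missing key '", key, "'")
  rec[[key]]
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  jf <- file.path(path, "annotations.json")
  stop_if(!file.exists(jf), "no annotations.json under '", path, "'")
  doc <- tryCatch(jsonlite::fromJSON(jf, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed JSON in '", jf, "': ",
                         conditionMessage(e), call. = FALSE))
  for (key in c("images", "entities", "interactions", "vocabulary")) {
    stop_if(is.null(doc[[key]]),
            "annotation parse error: missing top-level key '", key, "'")
  }
  vocab <- doc$vocabulary
  interactions_vocab <- unlist(vocab$interactions)
  class_vocab <- c(vocab$tissue, unlist(vocab$instruments))

  # entities grouped per image, with invariant checks
  ent_by_img <- list()
  ent_pos <- list()  # global id -> (image_id, local index)
  for (rec in doc$entities) {
    id <- need_key(rec, "id", "entity", rec$id %||% "?")
    img <- need_key(rec, "image_id", "entity", id)
    bbox <- as.numeric(unlist(need_key(rec, "bbox", "entity", id)))
    cls <- need_key(rec, "class", "entity", id)
    stop_if(length(bbox) != 4L,
            "annotation parse error: entity ", id, " has a malformed bbox")
    stop_if(bbox[3] <= bbox[1] || bbox[4] <= bbox[2],
            "annotation parse error: entity ", id,
            " violates x0 < x1, y0 < y1")
    key <- as.character(img)
    local <- length(ent_by_img[[key]] %||% list()) + 1L
    ent_by_img[[key]] <- c(ent_by_img[[key]],
                           list(list(id = id, class = cls, bbox = bbox,
                                     style = rec$style %||% class_style(cls))))
    ent_pos[[as.character(id)]] <- c(img, local)
  }

  inter_by_img <- list()
  for (i in seq_along(doc$interactions)) {
    rec <- doc$interactions[[i]]
    img <- need_key(rec, "image_id", "interaction", i)
    t_id <- need_key(rec, "tissue_id", "interaction", i)
    i_id <- need_key(rec, "instrument_id", "interaction", i)
    labels <- unlist(need_key(rec, "labels", "interaction", i))
    stop_if(length(labels) < 1L ||
              any(labels < 0) || any(labels > 12),
            "annotation parse error: interaction ", i,
            " has invalid label indices")
    key <- as.character(img)
    inter_by_img[[key]] <- c(inter_by_img[[key]],
                             list(list(tissue = ent_pos[[as.character(t_id)]][2],
                                       instrument = ent_pos[[as.character(i_id)]][2],
                                       labels = as.integer(labels) + 1L)))
  }

  scenes <- vector("list", length(doc$images))
  domain_id <- NULL
  for (s in seq_along(doc$images)) {
    rec <- doc$images[[s]]
    id <- need_key(rec, "id", "image", s)
    img <- png::readPNG(file.path(path, need_key(rec, "file", "image", s)))
    if (length(dim(img)) == 2L) img <- array(img, c(dim(img), 1L))[, , c(1, 1, 1)]
    img <- round(img[, , 1:3] * 255)
    storage.mode(img) <- "integer"
    domain_id <- rec$domain %||% "source"
    ents <- ent_by_img[[as.character(id)]] %||% list()
    specs <- lapply(ents, function(e)
      entity_spec(e$class, e$bbox, e$style))
    inters <- inter_by_img[[as.character(id)]] %||% list()
    pairs <- data.frame(
      tissue = vapply(inters, function(x) as.integer(x$tissue), 0L),
      instrument = vapply(inters, function(x) as.integer(x$instrument), 0L))
    labels <- matrix(0L, length(inters), 13L,
                     dimnames = list(NULL, interactions_vocab))
    for (j in seq_along(inters)) labels[j, inters[[j]]$labels] <- 1L
    scenes[[s]] <- new_scene(img, specs, list(pairs = pairs, labels = labels),
                             domain_id)
  }

  config <- NULL
  if (!is.null(doc$config)) {
    cf <- doc$config
    config <- structure(list(
      domain = cf$domain, n_scenes = as.integer(cf$n_scenes),
      seed = as.integer(cf$seed),
      width = as.integer(cf$width), height = as.integer(cf$height),
      class_vocabulary = unlist(cf$class_vocabulary),
      interaction_vocabulary = unlist(cf$interaction_vocabulary),
      longtail_exponent = cf$longtail_exponent,
      shift_params = list(
        channel_offset = as.numeric(unlist(cf$shift_params$channel_offset)),
        hue_rotation = cf$shift_params$hue_rotation,
        texture_sd = cf$shift_params$texture_sd),
      novel_classes = as.character(unlist(cf$novel_classes)),
      multi_label = isTRUE(cf$multi_label)), class = "domain_config")
  }
  structure(list(scenes = scenes, domain_id = domain_id,
                 class_vocabulary = class_vocab,
                 interaction_vocabulary = interactions_vocab,
                 config = config),
            class = "surg_dataset")
}

#' Deterministic word-embedding table for class names
#'
#' Stands in for a pre-trained word2vec model: each class name is mapped to a
#' reproducible unit-norm vector derived from a seeded hash of the name, so
#' the same name receives the same vector in every domain and distinct names
#' receive distinct vectors.
#'
#' @param class_vocabulary Character vector of unique class names.
#' @param dim Embedding dimension, at least 8 (word2vec convention is 300).
#' @param seed Integer seed.
#' @return A `dim x length(class_vocabulary)` matrix with one unit-norm
#'   column per name (class `embedding_table`).
#' @export
make_embedding_table <- function(class_vocabulary, dim = 300L, seed = 0L) {
  stop_if(anyDuplicated(class_vocabulary) > 0L,
          "duplicate names in `class_vocabulary`")
  stop_if(!is_count(dim) || dim < 8, "`dim` must be an integer >= 8")
  tab <- vapply(class_vocabulary, function(nm) {
    v <- with_seed(derive_seed(seed, paste0("emb:", nm)), rnorm(dim))
    v / sqrt(sum(v^2))
  }, numeric(dim))
  structure(tab, class = c("embedding_table", class(tab)))
}
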