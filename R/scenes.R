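# Synthetic two-domain surgical-scene generator.
#
# Emulates the statistical structure of an instrument-tissue interaction
# dataset: every scene has exactly one tissue entity and 1-3 instruments with
# bounding boxes, instrument classes are drawn from a Zipf (long-tail)
# distribution, interaction labels over 13 classes are a deterministic
# function of box geometry and instrument class, and the target domain is
# rendered with a shifted palette/texture and may contain novel instrument
# classes absent from the source vocabulary.
#
# Coordinate convention: boxes are (x0, y0, x1, y1), 0-based, half-open
# [x0, x1) x [y0, y1) in pixel units; x runs along image width, y along
# height. Images are H x W x 3 integer arrays with values in 0..255.

SOURCE_TISSUE <- "kidney"

SOURCE_INSTRUMENTS <- c(
  "bipolar forceps", "prograsp forceps", "large needle driver",
  "monopolar curved scissors", "ultrasound probe", "suction",
  "clip applier", "stapler"
)

DEFAULT_NOVEL <- c("maryland dissector", "spatulated monopolar cautery")

INTERACTIONS_13 <- c(
  "idle", "grasping", "retraction", "tissue manipulation",
  "tool manipulation", "cutting", "cauterization", "suction", "looping",
  "suturing", "clipping", "staple", "ultrasound sensing"
)

# Contact verb fired when an instrument overlaps the tissue (IoU above the
# contact threshold); fixed per instrument class.
CONTACT_VERBS <- c(
  "bipolar forceps"             = "cauterization",
  "prograsp forceps"            = "grasping",
  "large needle driver"         = "suturing",
  "monopolar curved scissors"   = "cutting",
  "ultrasound probe"            = "ultrasound sensing",
  "suction"                     = "suction",
  "clip applier"                = "clipping",
  "stapler"                     = "staple",
  "maryland dissector"          = "grasping",
  "spatulated monopolar cautery" = "cauterization"
)

# Verb fired for a disjoint instrument hovering within the distance
# threshold: grasper-like classes retract, everything else manipulates.
GRASPER_CLASSES <- c("bipolar forceps", "prograsp forceps", "maryland dissector")

#' Interaction class vocabulary
#'
#' The fixed, ordered 13-class interaction vocabulary shared by both domains.
#' @return Character vector of length 13.
#' @export
interaction_vocabulary <- function() INTERACTIONS_13

#' Entity class vocabulary of a domain
#'
#' The source domain has 9 entity classes (1 tissue + 8 instruments); the
#' target domain adds 2 novel instrument classes. Which instruments are novel
#' is configurable via `novel_classes`.
#'
#' @param domain `"source"` or `"target"`.
#' @param novel_classes Instrument classes present only in the target domain.
#' @return Ordered character vector; the tissue class is first.
#' @export
surgical_vocabulary <- function(domain = c("source", "target"),
                                novel_classes = DEFAULT_NOVEL) {
  domain <- match.arg(domain)
  base <- c(SOURCE_TISSUE, SOURCE_INSTRUMENTS)
  if (domain == "source") base else c(base, novel_classes)
}

#' Entity specification
#'
#' One annotated entity: a class name, a bounding box `(x0, y0, x1, y1)` in
#' 0-based half-open pixel coordinates, and a render-style token
#' (`"shape#RRGGBB"`).
#'
#' @param class_name Entity class.
#' @param bbox Numeric length-4 vector `(x0, y0, x1, y1)` with `x0 < x1`,
#'   `y0 < y1`.
#' @param render_style Shape+colour token; derived from the class when `NULL`.
#' @return An object of class `entity_spec`.
#' @export
entity_spec <- function(class_name, bbox, render_style = NULL) {
  stop_if(!is.character(class_name) || length(class_name) != 1L,
          "`class_name` must be a single string")
  bbox <- as.numeric(bbox)
  stop_if(length(bbox) != 4L || any(!is.finite(bbox)),
          "`bbox` must be four finite numbers (x0, y0, x1, y1)")
  stop_if(bbox[1] >= bbox[3] || bbox[2] >= bbox[4],
          "invalid bbox for '", class_name, "': need x0 < x1 and y0 < y1")
  stop_if(bbox[1] < 0 || bbox[2] < 0, "bbox coordinates must be >= 0")
  structure(list(class_name = class_name, bbox = bbox,
                 render_style = render_style %||% class_style(class_name)),
            class = "entity_spec")
}

# Deterministic per-class style: shape from a rotating set, colour from a
# character hash of the name.
class_style <- function(class_name) {
  col <- class_color(class_name)
  shape <- if (class_name == SOURCE_TISSUE) {
    "ellipse"                          # tissue renders as a blob
  } else {
    h <- sum(utf8ToInt(class_name) * seq_along(utf8ToInt(class_name)))
    c("rect", "ellipse", "bar")[h %% 3L + 1L]
  }
  paste0(shape, sprintf("#%02X%02X%02X", col[1], col[2], col[3]))
}

class_color <- function(class_name) {
  if (class_name == SOURCE_TISSUE) return(c(165L, 70L, 80L))
  h <- sum(utf8ToInt(class_name) * seq_along(utf8ToInt(class_name)))
  # metallic-ish instrument palette spread by hash
  base <- c(120L + (h * 37L) %% 110L, 120L + (h * 61L) %% 110L,
            120L + (h * 83L) %% 110L)
  as.integer(base)
}

#' Domain generator configuration
#'
#' Describes one synthetic domain: how many scenes, the class vocabulary, the
#' long-tail exponent of the instrument-class distribution, the rendering
#' shift applied to every frame (how the target domain differs visually from
#' the source), and the novel classes present only in this domain's
#' vocabulary.
#'
#' @param domain `"source"` or `"target"`.
#' @param n_scenes Number of scenes to generate.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @param width,height Frame size in pixels (desk-scale default 128 x 128).
#' @param longtail_exponent Positive Zipf exponent `s`; instrument class `r`
#'   (by domain rank) is drawn with probability proportional to `r^-s`.
#' @param shift_params List with `channel_offset` (length-3 additive RGB
#'   shift), `hue_rotation` (in `[0, 1)`, channel-mixing amount) and
#'   `texture_sd` (pixel noise s.d.).
#' @param novel_classes Instrument classes present only in the target domain;
#'   must be empty for the source domain.
#' @param multi_label Emit a second interaction bit for deep-contact pairs
#'   (exercises the multi-label loss); default emits exactly one bit.
#' @param interaction_vocab Ordered 13-class interaction vocabulary.
#' @return An object of class `domain_config`.
#' @examples
#' cfg <- domain_config("source", n_scenes = 5, seed = 1)
#' ds <- generate_domain(cfg)
#' @export
domain_config <- function(domain = c("source", "target"), n_scenes, seed,
                          width = 128L, height = 128L,
                          longtail_exponent = 1.5,
                          shift_params = NULL,
                          novel_classes = if (match.arg(domain) == "target")
                            DEFAULT_NOVEL else character(),
                          multi_label = FALSE,
                          interaction_vocab = interaction_vocabulary()) {
  domain <- match.arg(domain)
  stop_if(!is_count(n_scenes), "`n_scenes` must be a positive integer")
  stop_if(!is.numeric(seed) || length(seed) != 1L, "`seed` must be an integer")
  stop_if(!is.numeric(longtail_exponent) || longtail_exponent <= 0,
          "`longtail_exponent` must be positive")
  stop_if(length(interaction_vocab) != 13L,
          "`interaction_vocab` must have exactly 13 entries")
  if (domain == "source") {
    stop_if(length(novel_classes) > 0L,
            "source domain cannot declare novel classes")
  } else {
    stop_if(length(novel_classes) == 0L ||
              any(novel_classes %in% c(SOURCE_TISSUE, SOURCE_INSTRUMENTS)),
            "`novel_classes` must be non-empty and disjoint from the source vocabulary")
  }
  vocab <- c(SOURCE_TISSUE, SOURCE_INSTRUMENTS, novel_classes)
  stop_if(anyDuplicated(vocab) > 0L, "class vocabulary has duplicates")
  if (is.null(shift_params)) {
    shift_params <- if (domain == "source") {
      list(channel_offset = c(0, 0, 0), hue_rotation = 0, texture_sd = 6)
    } else {
      list(channel_offset = c(25, 18, -12), hue_rotation = 0.25,
           texture_sd = 14)
    }
  }
  structure(list(domain = domain, n_scenes = as.integer(n_scenes),
                 seed = as.integer(seed),
                 width = as.integer(width), height = as.integer(height),
                 class_vocabulary = vocab,
                 interaction_vocabulary = interaction_vocab,
                 longtail_exponent = longtail_exponent,
                 shift_params = shift_params,
                 novel_classes = novel_classes,
                 multi_label = multi_label),
            class = "domain_config")
}

# Zipf weights over the domain's instrument ranking. In the target domain the
# novel classes are ranked first (the new procedure uses its own instruments
# most), followed by the source instruments; the source domain uses its
# canonical order.
instrument_ranking <- function(config) {
  if (config$domain == "source") SOURCE_INSTRUMENTS
  else c(config$novel_classes, SOURCE_INSTRUMENTS)
}

zipf_probs <- function(n, s) {
  w <- seq_len(n)^(-s)
  w / sum(w)
}

#' Deterministic interaction labelling rule
#'
#' Assigns the multi-hot interaction vector of a tissue-instrument pair as a
#' fixed function of box geometry and instrument class: overlap (IoU above
#' `iou_thresh`) fires the class-specific contact verb (scissors cut, forceps
#' grasp, ...); a disjoint instrument whose centre lies within `dist_thresh`
#' of the tissue centre (as a fraction of the image diagonal) fires
#' `"retraction"` for grasper-like classes and `"tissue manipulation"`
#' otherwise; anything else is `"idle"`. With `multi_label = TRUE` a
#' deep-contact pair (IoU > 0.3) additionally sets `"tool manipulation"`.
#'
#' This rule supplies the learnable ground truth of the synthetic fixtures;
#' it is deliberately a function of (IoU, centre distance, class) only.
#'
#' @param tissue,instrument [entity_spec()] objects (or bare length-4 boxes).
#' @param instrument_class Instrument class name; must be a known class.
#' @param image_wh Length-2 vector `(width, height)`.
#' @param iou_thresh Contact IoU threshold (default 0.1).
#' @param dist_thresh Hover distance threshold as a fraction of the image
#'   diagonal (default 0.35).
#' @param multi_label Allow a second bit (see above).
#' @return Named integer multi-hot vector of length 13.
#' @export
interaction_rule <- function(tissue, instrument, instrument_class, image_wh,
                             iou_thresh = 0.1, dist_thresh = 0.35,
                             multi_label = FALSE) {
  bt <- if (inherits(tissue, "entity_spec")) tissue$bbox else as.numeric(tissue)
  bi <- if (inherits(instrument, "entity_spec")) instrument$bbox
        else as.numeric(instrument)
  stop_if(!instrument_class %in% names(CONTACT_VERBS),
          "unknown instrument class: '", instrument_class, "'")
  W <- image_wh[1]; H <- image_wh[2]
  stop_if(any(c(bt, bi) < 0) || bt[3] > W || bi[3] > W || bt[4] > H || bi[4] > H,
          "bounding boxes must lie within the image")
  iou <- box_iou(bt, bi)
  d <- sqrt(((bt[1] + bt[3]) / 2 - (bi[1] + bi[3]) / 2)^2 +
              ((bt[2] + bt[4]) / 2 - (bi[2] + bi[4]) / 2)^2)
  dmax <- dist_thresh * sqrt(W^2 + H^2)
  y <- setNames(integer(13L), INTERACTIONS_13)
  if (iou > iou_thresh) {
    y[CONTACT_VERBS[[instrument_class]]] <- 1L
    if (multi_label && iou > 0.3) y["tool manipulation"] <- 1L
  } else if (iou == 0 && d > 0 && d < dmax) {
    verb <- if (instrument_class %in% GRASPER_CLASSES) "retraction"
            else "tissue manipulation"
    y[verb] <- 1L
  } else {
    y["idle"] <- 1L
  }
  y
}

# Exact IoU for half-open boxes (x0, y0, x1, y1).
box_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  if (inter <= 0) return(0)
  aa <- (a[3] - a[1]) * (a[4] - a[2])
  ab <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (aa + ab - inter)
}

# ---- geometry sampling -----------------------------------------------------

clamp_box <- function(b, W, H) {
  b <- c(max(0, min(b[1], W - 2)), max(0, min(b[2], H - 2)),
         max(2, min(b[3], W)), max(2, min(b[4], H)))
  if (b[3] <= b[1]) b[3] <- b[1] + 2
  if (b[4] <= b[2]) b[4] <- b[2] + 2
  round(b)
}

box_from_center <- function(cx, cy, w, h) c(cx - w / 2, cy - h / 2,
                                            cx + w / 2, cy + h / 2)

# Sample one scene layout: tissue box plus 1-3 instruments placed in one of
# three geometric regimes (contact / hover / far) that exercise all branches
# of the interaction rule.
sample_scene_spec <- function(config) {
  W <- config$width; H <- config$height
  diag <- sqrt(W^2 + H^2)
  tw <- runif(1, 0.30, 0.45) * W
  th <- runif(1, 0.30, 0.45) * H
  tc <- c(W / 2 + runif(1, -0.06, 0.06) * W, H / 2 + runif(1, -0.06, 0.06) * H)
  tbox <- clamp_box(box_from_center(tc[1], tc[2], tw, th), W, H)
  ranks <- instrument_ranking(config)
  probs <- zipf_probs(length(ranks), config$longtail_exponent)
  n_instr <- sample(1:3, 1L, prob = c(0.3, 0.45, 0.25))
  entities <- list(entity_spec(SOURCE_TISSUE, tbox))
  for (i in seq_len(n_instr)) {
    cls <- sample(ranks, 1L, prob = probs)
    regime <- sample(c("contact", "hover", "far"), 1L,
                     prob = c(0.45, 0.30, 0.25))
    iw <- runif(1, 0.25, 0.40) * W
    ih <- runif(1, 0.25, 0.40) * H
    tcx <- (tbox[1] + tbox[3]) / 2
    tcy <- (tbox[2] + tbox[4]) / 2
    if (regime == "contact") {
      cx <- tcx + runif(1, -0.15, 0.15) * (tbox[3] - tbox[1])
      cy <- tcy + runif(1, -0.15, 0.15) * (tbox[4] - tbox[2])
      box <- clamp_box(box_from_center(cx, cy, iw, ih), W, H)
    } else {
      theta <- runif(1, 0, 2 * pi)
      d <- if (regime == "hover") runif(1, 0.22, 0.33) * diag
           else runif(1, 0.38, 0.48) * diag
      box <- clamp_box(box_from_center(tcx + d * cos(theta),
                                       tcy + d * sin(theta),
                                       iw * 0.7, ih * 0.7), W, H)
      # push the box outward until disjoint from the tissue (preserves the
      # IoU = 0 branch of the labelling rule)
      tries <- 0L
      while (box_iou(tbox, box) > 0 && tries < 12L) {
        d <- d + 0.03 * diag
        box <- clamp_box(box_from_center(tcx + d * cos(theta),
                                         tcy + d * sin(theta),
                                         iw * 0.7, ih * 0.7), W, H)
        tries <- tries + 1L
      }
    }
    entities[[length(entities) + 1L]] <- entity_spec(cls, box)
  }
  entities
}

# ---- rendering -------------------------------------------------------------

#' Render a scene specification to an image
#'
#' Draws the entities of a scene (filled shapes in per-class colours over a
#' cavity-coloured background) and applies the domain's visual shift:
#' additive channel offset, channel-mixing hue rotation and Gaussian pixel
#' texture. Rendering consumes RNG draws (for the texture), so call it under
#' a seed for reproducibility.
#'
#' @param entities List of [entity_spec()]; the first is drawn first
#'   (bottom-most).
#' @param width,height Image size.
#' @param shift_params Visual shift list as in [domain_config()].
#' @return `height x width x 3` integer array, values in 0..255.
#' @export
render_scene <- function(entities, width, height,
                         shift_params = list(channel_offset = c(0, 0, 0),
                                             hue_rotation = 0,
                                             texture_sd = 6)) {
  W <- width; H <- height
  img <- array(0, c(H, W, 3L))
  bg <- c(62, 24, 28)
  for (ch in 1:3) img[, , ch] <- bg[ch]
  for (e in entities) {
    col <- class_color(e$class_name)
    shape <- sub("#.*$", "", e$render_style)
    b <- e$bbox
    xs <- (b[1] + 1):b[3]           # 1-based pixel columns covered
    ys <- (b[2] + 1):b[4]
    if (shape == "ellipse") {
      cx <- (b[1] + b[3]) / 2; cy <- (b[2] + b[4]) / 2
      rx <- (b[3] - b[1]) / 2; ry <- (b[4] - b[2]) / 2
      mask <- outer((ys - 0.5 - cy)^2 / ry^2, (xs - 0.5 - cx)^2 / rx^2, "+") <= 1
    } else if (shape == "bar") {
      # diagonal bar across the box
      mask <- abs(outer((ys - b[2]) / (b[4] - b[2]),
                        (xs - b[1]) / (b[3] - b[1]), "-")) <= 0.3
    } else {
      mask <- matrix(TRUE, length(ys), length(xs))
    }
    for (ch in 1:3) {
      sub <- img[ys, xs, ch]
      sub[mask] <- col[ch]
      img[ys, xs, ch] <- sub
    }
  }
  # domain shift: hue rotation mixes channels, then additive offset + texture
  a <- shift_params$hue_rotation %||% 0
  if (a > 0) {
    rot <- img[, , c(2, 3, 1)]
    img <- (1 - a) * img + a * rot
  }
  off <- shift_params$channel_offset %||% c(0, 0, 0)
  for (ch in 1:3) img[, , ch] <- img[, , ch] + off[ch]
  sd <- shift_params$texture_sd %||% 0
  if (sd > 0) img <- img + array(rnorm(length(img), sd = sd), dim(img))
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  img
}

# ---- scene / dataset construction ------------------------------------------

new_scene <- function(image, entities, interactions, domain_id) {
  roles <- vapply(entities, function(e)
    if (e$class_name == SOURCE_TISSUE) "tissue" else "instrument", "")
  stop_if(sum(roles == "tissue") != 1L,
          "a scene must contain exactly one tissue entity")
  ent_df <- data.frame(
    class = vapply(entities, `[[`, "", "class_name"),
    role = roles,
    x0 = vapply(entities, function(e) e$bbox[1], 0),
    y0 = vapply(entities, function(e) e$bbox[2], 0),
    x1 = vapply(entities, function(e) e$bbox[3], 0),
    y1 = vapply(entities, function(e) e$bbox[4], 0),
    style = vapply(entities, `[[`, "", "render_style"),
    stringsAsFactors = FALSE
  )
  structure(list(image = image, entities = ent_df,
                 interactions = interactions, domain_id = domain_id),
            class = "surg_scene")
}

#' Generate a synthetic domain dataset
#'
#' Draws `n_scenes` seeded scenes under the configuration: scene layouts,
#' Zipf-distributed instrument classes, rendered frames with the domain's
#' visual shift, and interaction labels from [interaction_rule()]. Identical
#' configurations (including the seed) produce byte-identical datasets.
#'
#' @param config A [domain_config()].
#' @return An object of class `surg_dataset`: a list with `scenes` (list of
#'   `surg_scene`), `domain_id`, `class_vocabulary`,
#'   `interaction_vocabulary` and the generating `config`.
#' @export
generate_domain <- function(config) {
  stopifnot(inherits(config, "domain_config"))
  with_seed(config$seed, {
    scenes <- vector("list", config$n_scenes)
    for (s in seq_len(config$n_scenes)) {
      entities <- sample_scene_spec(config)
      img <- render_scene(entities, config$width, config$height,
                          config$shift_params)
      instr_idx <- which(vapply(entities, `[[`, "", "class_name") != SOURCE_TISSUE)
      labels <- matrix(0L, length(instr_idx), 13L,
                       dimnames = list(NULL, INTERACTIONS_13))
      pairs <- data.frame(tissue = rep(1L, length(instr_idx)),
                          instrument = as.integer(instr_idx))
      for (j in seq_along(instr_idx)) {
        e <- entities[[instr_idx[j]]]
        labels[j, ] <- interaction_rule(entities[[1L]], e, e$class_name,
                                        c(config$width, config$height),
                                        multi_label = config$multi_label)
      }
      scenes[[s]] <- new_scene(img, entities,
                               list(pairs = pairs, labels = labels),
                               config$domain)
    }
    structure(list(scenes = scenes, domain_id = config$domain,
                   class_vocabulary = config$class_vocabulary,
                   interaction_vocabulary = config$interaction_vocabulary,
                   config = config),
              class = "surg_dataset")
  })
}

#' @export
print.surg_dataset <- function(x, ...) {
  cat(sprintf("surg_dataset: %d scenes, domain '%s', %d entity classes\n",
              length(x$scenes), x$domain_id, length(x$class_vocabulary)))
  invisible(x)
}

# Flatten a dataset's edges into a covariate table (IoU, centre distance,
# instrument class) with argmax labels; used by evaluation fixtures and the
# learnability check.
edge_table <- function(dataset) {
  rows <- list()
  for (sc in dataset$scenes) {
    ent <- sc$entities
    t_i <- which(ent$role == "tissue")
    bt <- as.numeric(ent[t_i, c("x0", "y0", "x1", "y1")])
    W <- dim(sc$image)[2]; H <- dim(sc$image)[1]
    for (j in seq_len(nrow(sc$interactions$pairs))) {
      ii <- sc$interactions$pairs$instrument[j]
      bi <- as.numeric(ent[ii, c("x0", "y0", "x1", "y1")])
      d <- sqrt(((bt[1] + bt[3]) / 2 - (bi[1] + bi[3]) / 2)^2 +
                  ((bt[2] + bt[4]) / 2 - (bi[2] + bi[4]) / 2)^2) /
        sqrt(W^2 + H^2)
      rows[[length(rows) + 1L]] <- data.frame(
        iou = box_iou(bt, bi), dist = d, class = ent$class[ii],
        label = INTERACTIONS_13[which.max(sc$interactions$labels[j, ])],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
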