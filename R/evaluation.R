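# Interaction-detection metrics: argmax edge accuracy, mean average
# precision over the 13 interaction classes, and macro recall at a fixed
# sigmoid threshold. Alternatives (micro recall, 11-point interpolated AP)
# are flag-selectable since the canonical definitions vary across the
# literature.

as_edge_matrix <- function(x) {
  if (is.list(x) && !is.matrix(x)) x <- do.call(cbind, x)
  as.matrix(x)
}

#' Edge accuracy
#'
#' Percentage of readout edges whose argmax-scored class is a set bit of the
#' multi-hot ground truth.
#'
#' @param predictions `classes x edges` score matrix (logits or
#'   probabilities), or a list of per-scene matrices.
#' @param ground_truth Binary matrix/list of the same total shape.
#' @return Accuracy in `[0, 100]`.
#' @examples
#' edge_accuracy(diag(3), diag(3))  # 100
#' @export
edge_accuracy <- function(predictions, ground_truth) {
  p <- as_edge_matrix(predictions)
  g <- as_edge_matrix(ground_truth)
  stop_if(!identical(dim(p), dim(g)), "prediction/ground-truth shape mismatch")
  stop_if(ncol(p) == 0L, "edge accuracy is undefined on an empty edge set")
  hit <- vapply(seq_len(ncol(p)), function(e) g[which.max(p[, e]), e] == 1, TRUE)
  100 * mean(hit)
}

# Average precision of one class: mean of precision at each positive, over
# edges ranked by decreasing score (the all-point step integral of the PR
# curve).
average_precision <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  npos <- sum(lab)
  if (npos == 0L) return(NA_real_)
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab == 1]) / npos
}

# 11-point interpolated variant (flag-selectable alternative).
average_precision_11pt <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  npos <- sum(lab)
  if (npos == 0L) return(NA_real_)
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  rec <- tp / npos
  mean(vapply(seq(0, 1, 0.1), function(r) {
    ok <- rec >= r
    if (any(ok)) max(prec[ok]) else 0
  }, 0))
}

#' Mean average precision over interaction classes
#'
#' Per-class AP is the all-point step integral of the precision-recall curve
#' over edges ranked by score; the mean is taken over classes with at least
#' one positive (classes without positives are excluded).
#'
#' @param score_matrix `edges x classes` numeric scores.
#' @param gt_matrix Binary `edges x classes` ground truth.
#' @param interpolation `"all_point"` (default) or `"11pt"`.
#' @return The mAP in `[0, 1]`, with per-class APs in attribute
#'   `"per_class_ap"` (`NA` for classes without positives).
#' @examples
#' mean_average_precision(matrix(c(0.9, 0.8, 0.7)), matrix(c(1, 0, 1)))
#' @export
mean_average_precision <- function(score_matrix, gt_matrix,
                                   interpolation = c("all_point", "11pt")) {
  interpolation <- match.arg(interpolation)
  s <- as.matrix(score_matrix); g <- as.matrix(gt_matrix)
  stop_if(!identical(dim(s), dim(g)), "score/ground-truth shape mismatch")
  apfun <- if (interpolation == "all_point") average_precision
           else average_precision_11pt
  ap <- vapply(seq_len(ncol(s)), function(cl) apfun(s[, cl], g[, cl]), 0)
  out <- mean(ap, na.rm = TRUE)
  attr(out, "per_class_ap") <- ap
  out
}

#' Macro recall at a fixed threshold
#'
#' Per-class recall `TP / (TP + FN)` with predictions thresholded at
#' `threshold`, macro-averaged over classes with at least one positive.
#' `micro = TRUE` pools all classes before the ratio.
#'
#' @param predictions `edges x classes` probabilities (e.g. sigmoids).
#' @param ground_truth Binary matrix of the same shape.
#' @param threshold Decision threshold (default 0.5).
#' @param micro Micro-average instead of macro.
#' @return Recall in `[0, 1]`.
#' @export
macro_recall <- function(predictions, ground_truth, threshold = 0.5,
                         micro = FALSE) {
  p <- as.matrix(predictions) >= threshold
  g <- as.matrix(ground_truth) == 1
  stop_if(!identical(dim(p), dim(g)), "prediction/ground-truth shape mismatch")
  if (micro) {
    return(sum(p & g) / max(sum(g), 1L))
  }
  rec <- vapply(seq_len(ncol(g)), function(cl) {
    npos <- sum(g[, cl])
    if (npos == 0L) return(NA_real_)
    sum(p[, cl] & g[, cl]) / npos
  }, 0)
  mean(rec, na.rm = TRUE)
}

#' Evaluate a graph model on one domain
#'
#' Runs the model over the embedded scenes in evaluation mode and reports
#' edge accuracy, mAP, macro recall, per-class AP, the expected calibration
#' error of the argmax prediction, and the edge count.
#'
#' @param model A `graph_model`.
#' @param embeds A [embed_dataset()] embedding of the evaluation domain.
#' @param tnorm Optional [tnorm_config()] override for the readout.
#' @return An object of class `metrics_report`.
#' @export
evaluate_domain <- function(model, embeds, tnorm = NULL) {
  stopifnot(inherits(model, "graph_model"),
            inherits(embeds, "graph_embeddings"))
  if (!is.null(tnorm)) {
    model$config$tnorm <- tnorm
  }
  logits <- graph_predict(model, embeds)
  gt <- lapply(embeds$scenes, function(E) E$labels)
  lg <- do.call(cbind, logits)
  gm <- do.call(cbind, gt)
  acc <- edge_accuracy(lg, gm)
  map <- mean_average_precision(t(sigmoid(lg)), t(gm))
  rec <- macro_recall(t(sigmoid(lg)), t(gm))
  argmax_gt <- apply(gm, 2L, which.max)
  conf <- confidence_from_logits(lg, argmax_gt)
  rel <- reliability(conf$confidence, conf$correct)
  structure(list(acc = acc, map = as.numeric(map),
                 recall = rec,
                 per_class_ap = attr(map, "per_class_ap"),
                 ece = rel$ece, n_edges = ncol(lg),
                 domain_id = embeds$domain_id,
                 reliability = rel),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "metrics_report [%s]: Acc %.2f  mAP %.4f  Recall %.4f  ECE %.4f  (%d edges)\n",
    x$domain_id %||% "?", x$acc, x$map, x$recall, x$ece, x$n_edges))
  invisible(x)
}

#' Serialize a metrics report to JSON
#'
#' @param report A `metrics_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  out <- report[c("acc", "map", "recall", "per_class_ap", "ece",
                  "n_edges", "domain_id")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
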