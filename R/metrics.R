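# Evaluation stack: F-beta, Dice, FNCR, lesion-level FROC, slide-level
# ROC-AUC, and a slide-resampling bootstrap.

#' Confusion counts of a binary prediction against truth
#'
#' @param pred logical vector/matrix of predictions.
#' @param truth logical vector/matrix of the same shape.
#' @return list with integer `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth)) {
    stop_invalid("pred and truth must have equal length")
  }
  pred <- as.logical(pred); truth <- as.logical(truth)
  list(tp = sum(pred & truth), fp = sum(pred & !truth),
       fn = sum(!pred & truth), tn = sum(!pred & !truth))
}

#' F-beta score
#'
#' F_beta = (1 + beta^2) * precision * recall /
#'          (beta^2 * precision + recall),
#' with precision = tp / (tp + fp) and recall = tp / (tp + fn).
#' beta = 0.5 weights precision over recall — appropriate when falsely
#' flagged regions are costlier than missed ones. Returns 0 when tp = 0
#' but errors exist; errors if tp + fp + fn = 0 (metric undefined).
#'
#' @param counts list with `tp`, `fp`, `fn` (see [confusion_counts()]).
#' @param beta precision/recall weight, default 0.5.
#' @return score in \[0, 1\].
#' @export
f_beta <- function(counts, beta = 0.5) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (any(c(tp, fp, fn) < 0)) stop_invalid("counts must be non-negative")
  if (tp + fp + fn == 0) {
    stop_invalid("F-beta undefined: no positive predictions or truths")
  }
  if (tp == 0) return(0)
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  b2 <- beta^2
  (1 + b2) * precision * recall / (b2 * precision + recall)
}

#' Dice coefficient of two binary masks
#'
#' 2 TP / (2 TP + FP + FN). Two empty masks score 1.0 by convention (a
#' slide with no tumor and no prediction is perfectly segmented).
#'
#' @param pred_binary predicted binary mask (logical or 0/1 matrix).
#' @param gt_mask ground-truth binary mask, same shape.
#' @return score in \[0, 1\].
#' @export
dice <- function(pred_binary, gt_mask) {
  if (!is.matrix(pred_binary) || !is.matrix(gt_mask)) {
    stop_invalid("dice expects matrices")
  }
  assert_same_shape(pred_binary, gt_mask, "prediction and ground truth")
  p <- pred_binary != 0; g <- gt_mask != 0
  tp <- sum(p & g)
  denom <- 2 * tp + sum(p & !g) + sum(!p & g)
  if (denom == 0) return(1.0)
  2 * tp / denom
}

#' False negative conversion rate (FNCR) of a refinement
#'
#' Pooled over the slide set: FNCR = sum_i N+_i / sum_i Ntotal_i, where
#' N+_i counts updated pixels of slide i that are ground-truth tumor
#' (correctly converted FNs) and Ntotal_i counts all updated pixels.
#' FNCR = 1 means only FN pixels were updated; near 0 means the
#' refinement mostly introduced false positives. The ratio is pooled
#' across slides, not averaged per slide.
#'
#' @param results list of `refinement_result` objects (or a single one).
#' @param gt_masks list of matching binary ground-truth masks.
#' @return score in \[0, 1\].
#' @export
fncr <- function(results, gt_masks) {
  if (inherits(results, "refinement_result")) results <- list(results)
  if (is.matrix(gt_masks)) gt_masks <- list(gt_masks)
  if (length(results) != length(gt_masks)) {
    stop_invalid("results and gt_masks must have equal length")
  }
  n_plus <- 0; n_total <- 0
  for (i in seq_along(results)) {
    upd <- results[[i]]$updated_pixels
    n_total <- n_total + length(upd)
    if (length(upd)) n_plus <- n_plus + sum(gt_masks[[i]][upd] != 0)
  }
  if (n_total == 0) {
    stop_invalid("FNCR undefined: no pixels were updated by the refinement")
  }
  n_plus / n_total
}

#' Candidate lesion detections from a probability heatmap
#'
#' One detection per positive connected component (pmap >= t2): the
#' coordinate of the component's maximum probability, with that maximum
#' as the detection confidence. This is the conventional way to turn a
#' heatmap into point detections for lesion-level FROC scoring.
#'
#' @param pmap probability map (fused or refined).
#' @param cfg a [threshold_config()] (uses `t2` and `connectivity`).
#' @return `data.table` with columns `row`, `col`, `confidence`.
#' @export
heatmap_detections <- function(pmap, cfg = threshold_config()) {
  assert_probabilities(pmap, "pmap")
  lab <- label_components(pmap >= cfg$t2, cfg$connectivity)
  ids <- setdiff(unique(as.integer(lab)), 0L)
  if (!length(ids)) {
    return(data.table::data.table(row = integer(0), col = integer(0),
                                  confidence = numeric(0)))
  }
  H <- nrow(pmap)
  out <- lapply(sort(ids), function(id) {
    px <- which(lab == id)
    best <- px[which.max(pmap[px])]
    data.table::data.table(row = (best - 1L) %% H + 1L,
                           col = (best - 1L) %/% H + 1L,
                           confidence = pmap[best])
  })
  data.table::rbindlist(out)
}

#' Lesion-level FROC score
#'
#' Free-response ROC following the Camelyon16 evaluation protocol: ground
#' truth lesions are the connected components of each slide's tumor mask;
#' a lesion counts as hit at a confidence threshold if any detection at or
#' above the threshold falls inside it; detections outside every lesion
#' are false positives. The score is the mean lesion sensitivity at the
#' configured average-false-positives-per-slide operating points
#' (sensitivity interpolated linearly in avg-FP, clamped at the curve
#' ends).
#'
#' @param detections named list (one element per slide, names = slide
#'   ids) of data.frames with columns `row`, `col`, `confidence` (see
#'   [heatmap_detections()]). Slides without detections contribute empty
#'   frames.
#' @param gt_masks named list of binary ground-truth masks for the same
#'   slides (normal slides = all-zero masks).
#' @param fp_points average-FP-per-slide operating points, default
#'   c(0.25, 0.5, 1, 2, 4, 8).
#' @param connectivity lesion-component connectivity (default 8).
#' @return score in \[0, 1\].
#' @export
froc_score <- function(detections, gt_masks,
                       fp_points = c(0.25, 0.5, 1, 2, 4, 8),
                       connectivity = 8L) {
  if (length(detections) != length(gt_masks)) {
    stop_invalid("detections and gt_masks must cover the same slides")
  }
  n_slides <- length(gt_masks)
  if (n_slides == 0) stop_invalid("empty slide set")

  total_lesions <- 0L
  hits <- list()   # per lesion: max confidence of any detection inside
  fp_conf <- numeric(0)
  for (i in seq_len(n_slides)) {
    lab <- label_components(gt_masks[[i]] != 0, connectivity)
    n_les <- if (any(lab > 0L)) max(lab) else 0L
    det <- detections[[i]]
    det_lab <- integer(0)
    if (!is.null(det) && nrow(det)) {
      det_lab <- lab[cbind(det$row, det$col)]
      fp_conf <- c(fp_conf, det$confidence[det_lab == 0L])
    }
    if (n_les > 0L) {
      for (l in seq_len(n_les)) {
        inside <- det_lab == l
        hits[[length(hits) + 1L]] <-
          if (any(inside)) max(det$confidence[inside]) else -Inf
      }
      total_lesions <- total_lesions + n_les
    }
  }
  if (total_lesions == 0L) {
    stop_invalid("FROC undefined: no lesions in the dataset")
  }
  hit_conf <- unlist(hits)

  thresholds <- sort(unique(c(hit_conf[is.finite(hit_conf)], fp_conf)),
                     decreasing = TRUE)
  if (!length(thresholds)) return(0.0)  # no detections at all
  sens <- vapply(thresholds, function(t) mean(hit_conf >= t), numeric(1))
  avg_fp <- vapply(thresholds, function(t) sum(fp_conf >= t) / n_slides,
                   numeric(1))
  # collapse duplicate avg-FP values to their best sensitivity
  curve <- data.table::data.table(fp = avg_fp, sens = sens)
  curve <- curve[, list(sens = max(sens)), by = "fp"]
  data.table::setorderv(curve, "fp")
  interp <- if (nrow(curve) == 1L) {
    rep(curve$sens, length(fp_points))
  } else {
    stats::approx(curve$fp, curve$sens, xout = fp_points,
                  rule = 2, ties = max)$y
  }
  mean(interp)
}

#' Slide-level ROC-AUC
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling of a per-slide
#' score — conventionally the maximum pixel probability of the (refined)
#' heatmap — against the slide's tumor/normal label.
#'
#' @param scores numeric per-slide scores.
#' @param labels logical (or 0/1) per-slide tumor labels.
#' @return AUC in \[0, 1\].
#' @export
slide_roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop_invalid("scores and labels must have equal length")
  }
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop_invalid("ROC-AUC undefined: both classes must be present")
  }
  r <- rank(scores)  # midranks for ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Slide-resampling bootstrap of a dataset-level statistic
#'
#' Resamples whole slides with replacement `n_boot` times (the slide is
#' the unit of replication) and recomputes the statistic on every
#' resample, so pooled formulas such as FNCR are re-pooled per resample.
#' Deterministic under a fixed seed.
#'
#' @param slide_inputs list with one element per slide; whatever the
#'   statistic needs.
#' @param statistic function(list_of_slide_inputs) -> single number.
#' @param n_boot number of bootstrap iterations, default 1000.
#' @param seed RNG seed recorded in the report.
#' @return list of class `evaluation_report`: `point` (statistic on the
#'   full set), `boot_mean`, `boot_sd`, `n_boot`, `seed`, `boot_values`.
#' @export
bootstrap_metric <- function(slide_inputs, statistic, n_boot = 1000L,
                             seed = 20240116L) {
  if (!is.list(slide_inputs) || length(slide_inputs) < 1L) {
    stop_invalid("bootstrap needs at least one slide")
  }
  n <- length(slide_inputs)
  point <- statistic(slide_inputs)
  boot_values <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      statistic(slide_inputs[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  structure(
    list(point = point, boot_mean = mean(boot_values),
         boot_sd = stats::sd(boot_values),
         n_boot = as.integer(n_boot), seed = as.integer(seed),
         boot_values = boot_values),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> point %.4f, bootstrap %.4f (%.4f), n_boot=%d, seed=%d\n",
              x$point, x$boot_mean, x$boot_sd, x$n_boot, x$seed))
  invisible(x)
}
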