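# SUA detection: region-level uncertainty aggregation, threshold
# calibration, FN flagging, and the pixel-independent baseline.

#' Aggregate per-pixel entropy within each NPR
#'
#' Scores every negative-prediction region by an aggregate of its pixels'
#' entropies: the arithmetic mean or the 90th percentile (linear
#' interpolation between order statistics). The mean is the default; the
#' two aggregations separate FN from TN regions about equally well, with
#' the mean marginally ahead.
#'
#' @param labels integer NPR label matrix from [extract_nprs()].
#' @param umap entropy map from [pixel_entropy()], same shape.
#' @param method `"mean"` or `"p90"`.
#' @param slide_id slide identifier recorded in the output (defaults to
#'   the `slide_id` attribute of `labels`, else `"slide"`).
#' @return `data.table` of region records with columns `slide_id`,
#'   `region_id`, `n_pixels`, `agg_uncertainty`; truth and prediction
#'   columns (`tumor_fraction`, `is_fn_truth`, `is_fn_predicted`) are
#'   added by [label_fn_truth()] and [detect_fn()].
#' @export
aggregate_region_uncertainty <- function(labels, umap,
                                         method = c("mean", "p90"),
                                         slide_id = NULL) {
  method <- match.arg(method)
  if (!is.matrix(labels)) stop_invalid("labels must be a matrix")
  assert_matrix(umap, "umap")
  assert_same_shape(labels, umap, "labels and uncertainty map")
  slide_id <- slide_id %||% attr(labels, "slide_id") %||% "slide"

  pos <- labels > 0L
  if (!any(pos)) {
    return(data.table::data.table(
      slide_id = character(0), region_id = integer(0),
      n_pixels = integer(0), agg_uncertainty = numeric(0)
    ))
  }
  dt <- data.table::data.table(region_id = as.integer(labels[pos]),
                               u = as.numeric(umap[pos]))
  agg_fun <- if (method == "mean") {
    function(u) mean(u)
  } else {
    function(u) unname(stats::quantile(u, 0.9, type = 7))
  }
  recs <- dt[, list(n_pixels = .N, agg_uncertainty = agg_fun(u)),
             by = "region_id"]
  data.table::setorderv(recs, "region_id")
  recs[, `:=`(slide_id = slide_id)]
  data.table::setcolorder(recs, c("slide_id", "region_id", "n_pixels",
                                  "agg_uncertainty"))
  recs[]
}

#' Attach ground-truth FN labels to region records
#'
#' A region is a true FN when at least `fn_fraction` of its pixels are
#' ground-truth tumor (default 0.9: "at least 90% missed tumor pixels",
#' boundary inclusive). Adds `tumor_fraction` and `is_fn_truth`.
#'
#' @param records region records from [aggregate_region_uncertainty()].
#' @param labels NPR label matrix the records came from.
#' @param gt_mask binary ground-truth tumor mask, same shape.
#' @param fn_fraction inclusive tumor-fraction threshold (default 0.9).
#' @return the records with `tumor_fraction` and `is_fn_truth` columns.
#' @export
label_fn_truth <- function(records, labels, gt_mask, fn_fraction = 0.9) {
  if (is.null(gt_mask)) {
    stop_invalid("ground truth unavailable: cannot label FN truth")
  }
  if (!is.matrix(labels)) stop_invalid("labels must be a matrix")
  assert_same_shape(labels, gt_mask, "labels and ground-truth mask")
  gt <- gt_mask != 0
  pos <- labels > 0L
  records <- data.table::as.data.table(records)
  if (!nrow(records)) {
    records[, `:=`(tumor_fraction = numeric(0), is_fn_truth = logical(0))]
    return(records[])
  }
  dt <- data.table::data.table(region_id = as.integer(labels[pos]),
                               tumor = as.numeric(gt[pos]))
  tf <- dt[, list(tumor_fraction = mean(tumor)), by = "region_id"]
  records <- merge(records, tf, by = "region_id", all.x = TRUE,
                   sort = FALSE)
  if (anyNA(records$tumor_fraction)) {
    stop_invalid("records reference region ids absent from the label map")
  }
  records[, `:=`(is_fn_truth = tumor_fraction >= fn_fraction)]
  data.table::setcolorder(records, c("slide_id", "region_id", "n_pixels",
                                     "agg_uncertainty"))
  records[]
}

# Exhaustive F-beta threshold scan used by both calibrators. Candidates
# are the midpoints between consecutive sorted unique scores, plus one
# candidate below the minimum (flag everything). Prediction is strict:
# flagged <=> score > tau. Ties in F-beta break toward the larger tau
# (higher precision).
fbeta_threshold_scan <- function(score, truth, beta = 0.5) {
  stopifnot(length(score) == length(truth))
  if (!any(truth) || all(truth)) {
    stop_invalid("calibration undefined: validation data must contain ",
                 "both FN and TN examples")
  }
  u <- sort(unique(score))
  cand <- if (length(u) > 1L) {
    c(u[1] - 1, (u[-length(u)] + u[-1]) / 2)
  } else {
    u - 1
  }
  fb <- vapply(cand, function(tau) {
    pred <- score > tau
    tp <- sum(pred & truth)
    if (tp == 0L) return(0)
    fp <- sum(pred & !truth)
    fn <- sum(!pred & truth)
    f_beta(list(tp = tp, fp = fp, fn = fn), beta = beta)
  }, numeric(1))
  best <- max(fb)
  tau <- max(cand[fb == best])   # tie -> larger tau
  list(tau = tau, f_beta = best,
       curve = data.table::data.table(tau = cand, f_beta = fb))
}

#' Calibrate the FN-detection threshold on validation regions
#'
#' The detection threshold tau is determined empirically on validation
#' data: every midpoint between consecutive unique aggregated-uncertainty
#' values is scored by the F-beta (default beta = 0.5, precision-weighted)
#' of the induced strict-greater classification against `is_fn_truth`,
#' and the maximizing candidate is returned, ties broken toward the
#' larger tau.
#'
#' @param records validation region records carrying `agg_uncertainty`
#'   and `is_fn_truth` with both classes present.
#' @param beta F-beta weight (default 0.5).
#' @return list of class `sua_calibration`: `tau`, `f_beta` (achieved on
#'   validation), `beta`, `n_regions`, and the scanned `curve`.
#' @export
calibrate_tau <- function(records, beta = 0.5) {
  records <- data.table::as.data.table(records)
  if (!nrow(records) || is.null(records$is_fn_truth)) {
    stop_invalid("calibration needs records with is_fn_truth")
  }
  scan <- fbeta_threshold_scan(records$agg_uncertainty,
                               records$is_fn_truth, beta)
  structure(
    list(tau = scan$tau, f_beta = scan$f_beta, beta = beta,
         n_regions = nrow(records), curve = scan$curve),
    class = "sua_calibration"
  )
}

#' @export
print.sua_calibration <- function(x, ...) {
  cat(sprintf(
    "<sua_calibration> tau = %.6f (F_beta=%.2f on %d validation regions: %.4f)\n",
    x$tau, x$beta, x$n_regions, x$f_beta))
  invisible(x)
}

#' Flag FN regions by thresholding the aggregated uncertainty
#'
#' A region is marked as a detected FN when its aggregated uncertainty is
#' strictly above tau.
#'
#' @param records region records with `agg_uncertainty`.
#' @param tau detection threshold (nats); a [calibrate_tau()] result is
#'   also accepted.
#' @return records with an `is_fn_predicted` column.
#' @export
detect_fn <- function(records, tau) {
  if (inherits(tau, "sua_calibration")) tau <- tau$tau
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau)) {
    stop_invalid("tau must be a single finite number")
  }
  records <- data.table::as.data.table(records)
  records[, `:=`(is_fn_predicted = agg_uncertainty > tau)]
  records[]
}

#' Pixel-independent baseline: calibrate the per-pixel entropy threshold
#'
#' The baseline treats each eligible pixel (t1 < softmax < t2, i.e. the
#' same pixels that make up NPRs) independently. Its threshold is
#' calibrated by the same F-beta scan as the SUA detector, against
#' pixel-level truth: an eligible pixel is a true FN iff it is
#' ground-truth tumor.
#'
#' @param pmaps list of fused probability maps (validation slides).
#' @param umaps list of matching entropy maps.
#' @param gt_masks list of matching binary ground-truth masks.
#' @param cfg a [threshold_config()].
#' @return list of class `sua_calibration` (threshold on pixel entropy).
#' @export
calibrate_tau_pixel <- function(pmaps, umaps, gt_masks, cfg) {
  stopifnot(length(pmaps) == length(umaps),
            length(pmaps) == length(gt_masks))
  score <- numeric(0); truth <- logical(0)
  for (i in seq_along(pmaps)) {
    eligible <- (pmaps[[i]] > cfg$t1) & (pmaps[[i]] < cfg$t2)
    score <- c(score, umaps[[i]][eligible])
    truth <- c(truth, gt_masks[[i]][eligible] != 0)
  }
  scan <- fbeta_threshold_scan(score, truth, cfg$beta)
  structure(
    list(tau = scan$tau, f_beta = scan$f_beta, beta = cfg$beta,
         n_regions = length(score), curve = scan$curve),
    class = "sua_calibration"
  )
}

#' Pixel-independent baseline: flag individual high-entropy pixels
#'
#' Flags pixels that are eligible (t1 < softmax < t2, exactly the NPR
#' membership rule — pixels at or above t2 are never flagged) and whose
#' own entropy is strictly above `tau_pixel`, with no spatial grouping.
#'
#' @param pmap fused probability map.
#' @param umap entropy map, same shape.
#' @param cfg a [threshold_config()].
#' @param tau_pixel pixel-entropy threshold (or a `sua_calibration`).
#' @return logical matrix of flagged pixels.
#' @export
baseline_detect_fn_pixels <- function(pmap, umap, cfg, tau_pixel) {
  if (inherits(tau_pixel, "sua_calibration")) tau_pixel <- tau_pixel$tau
  assert_probabilities(pmap, "pmap")
  assert_matrix(umap, "umap")
  assert_same_shape(pmap, umap, "probability and uncertainty maps")
  eligible <- (pmap > cfg$t1) & (pmap < cfg$t2)
  eligible & (umap > tau_pixel)
}
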