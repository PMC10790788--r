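# End-to-end orchestration: fuse -> entropy -> NPRs -> aggregate ->
# calibrate -> detect -> refine -> evaluate, over sets of slides.

# Normalize the accepted slide inputs (synthetic_scene, read_slide_bundle
# result, or a plain list with pmap / stack and optional gt_mask).
as_slide_input <- function(x, slide_id = NULL) {
  if (inherits(x, "synthetic_scene")) {
    pmap <- fuse_ensemble(x$stack)
    return(list(pmap = pmap, gt_mask = x$gt_mask,
                slide_id = x$spec$slide_id))
  }
  if (is.list(x) && !is.null(x$pmap)) {
    return(list(pmap = x$pmap, gt_mask = x$gt_mask,
                slide_id = x$slide_id %||% slide_id %||%
                  attr(x$pmap, "slide_id") %||% "slide"))
  }
  if (is.list(x) && !is.null(x$stack)) {
    pmap <- fuse_ensemble(x$stack)
    return(list(pmap = pmap, gt_mask = x$gt_mask,
                slide_id = x$slide_id %||% slide_id %||% "slide"))
  }
  stop_invalid("cannot interpret slide input")
}

#' Analyze one slide: NPRs, entropies and region records
#'
#' Runs the per-slide part of the pipeline: fused probability map ->
#' entropy map -> NPR label map -> region records (aggregated uncertainty
#' plus, when ground truth is present, tumor fraction and FN truth).
#'
#' @param slide a `synthetic_scene`, a [read_slide_bundle()] result, or a
#'   list with `pmap` (or `stack`) and optional `gt_mask`.
#' @param cfg a [threshold_config()].
#' @return list with `slide_id`, `pmap`, `umap`, `labels`, `records`,
#'   `gt_mask`.
#' @export
analyze_slide <- function(slide, cfg = threshold_config()) {
  s <- as_slide_input(slide)
  umap <- pixel_entropy(s$pmap)
  labels <- extract_nprs(s$pmap, cfg)
  records <- aggregate_region_uncertainty(labels, umap, cfg$aggregation,
                                          slide_id = s$slide_id)
  if (!is.null(s$gt_mask)) {
    records <- label_fn_truth(records, labels, s$gt_mask, cfg$fn_fraction)
  }
  list(slide_id = s$slide_id, pmap = s$pmap, umap = umap,
       labels = labels, records = records, gt_mask = s$gt_mask)
}

pixel_confusion <- function(analyses, masks_flagged) {
  pred <- logical(0); truth <- logical(0)
  for (i in seq_along(analyses)) {
    a <- analyses[[i]]
    eligible <- a$labels > 0L
    pred <- c(pred, masks_flagged[[i]][eligible])
    truth <- c(truth, a$gt_mask[eligible] != 0)
  }
  confusion_counts(pred, truth)
}

#' Run the full FN-detection experiment on a slide set
#'
#' Calibrates both detectors on the validation slides and evaluates them
#' on the test slides:
#'
#' * SUA: region-level aggregated-entropy threshold, F-beta on the
#'   region FN/TN classification;
#' * baseline: per-pixel entropy threshold on the same eligible pixels,
#'   F-beta on the pixel FN/TN classification;
#' * refinement: Dice before/after for both methods, pooled FNCR for
#'   both, optional lesion-level FROC and slide-level ROC-AUC, and
#'   optional slide-resampling bootstrap of the headline metrics.
#'
#' @param val_slides,test_slides lists of slide inputs (see
#'   [analyze_slide()]); all must carry ground truth.
#' @param cfg a [threshold_config()].
#' @param n_boot bootstrap iterations for the headline metrics (0 = no
#'   bootstrap).
#' @param seed bootstrap seed.
#' @param compute_froc also compute FROC / ROC-AUC before and after SUA
#'   refinement (needs lesions / both slide classes; `NA` otherwise).
#' @return list of class `sua_experiment` with calibration objects,
#'   pooled metrics and per-slide analyses.
#' @export
run_fn_experiment <- function(val_slides, test_slides,
                              cfg = threshold_config(),
                              n_boot = 0L, seed = 20240116L,
                              compute_froc = FALSE) {
  val <- lapply(val_slides, analyze_slide, cfg = cfg)
  test <- lapply(test_slides, analyze_slide, cfg = cfg)
  if (any(vapply(c(val, test), function(a) is.null(a$gt_mask), logical(1)))) {
    stop_invalid("run_fn_experiment needs ground truth on every slide")
  }

  # calibration on validation
  val_records <- data.table::rbindlist(lapply(val, `[[`, "records"))
  cal_region <- calibrate_tau(val_records, cfg$beta)
  cal_pixel <- calibrate_tau_pixel(
    lapply(val, `[[`, "pmap"), lapply(val, `[[`, "umap"),
    lapply(val, `[[`, "gt_mask"), cfg)

  # detection on test
  for (i in seq_along(test)) {
    test[[i]]$records <- detect_fn(test[[i]]$records, cal_region$tau)
    test[[i]]$baseline_mask <- baseline_detect_fn_pixels(
      test[[i]]$pmap, test[[i]]$umap, cfg, cal_pixel$tau)
  }
  test_records <- data.table::rbindlist(lapply(test, `[[`, "records"))
  sua_counts <- confusion_counts(test_records$is_fn_predicted,
                                 test_records$is_fn_truth)
  sua_fbeta <- tryCatch(f_beta(sua_counts, cfg$beta),
                        error = function(e) NA_real_)
  base_counts <- pixel_confusion(test, lapply(test, `[[`, "baseline_mask"))
  base_fbeta <- tryCatch(f_beta(base_counts, cfg$beta),
                         error = function(e) NA_real_)

  # refinement on test
  gt <- lapply(test, `[[`, "gt_mask")
  ref_sua <- lapply(test, function(a) {
    refine_sua(a$pmap, a$labels, a$records, cfg)
  })
  ref_base <- lapply(test, function(a) {
    refine_baseline(a$pmap, a$baseline_mask, cfg)
  })
  fncr_sua <- tryCatch(fncr(ref_sua, gt), error = function(e) NA_real_)
  fncr_base <- tryCatch(fncr(ref_base, gt), error = function(e) NA_real_)
  dice_orig <- mean(mapply(function(a, g) dice(a$pmap >= cfg$t2, g),
                           test, gt))
  dice_sua <- mean(mapply(function(r, g) dice(r$refined_binary, g),
                          ref_sua, gt))
  dice_base <- mean(mapply(function(r, g) dice(r$refined_binary, g),
                           ref_base, gt))

  metrics <- list(
    sua = list(f_beta = sua_fbeta, counts = sua_counts,
               fncr = fncr_sua, dice_refined = dice_sua),
    baseline = list(f_beta = base_fbeta, counts = base_counts,
                    fncr = fncr_base, dice_refined = dice_base),
    dice_original = dice_orig
  )

  if (compute_froc) {
    det_orig <- lapply(test, function(a) heatmap_detections(a$pmap, cfg))
    det_sua <- lapply(ref_sua, function(r) {
      heatmap_detections(r$refined_pmap, cfg)
    })
    metrics$froc_original <- tryCatch(froc_score(det_orig, gt),
                                      error = function(e) NA_real_)
    metrics$froc_sua <- tryCatch(froc_score(det_sua, gt),
                                 error = function(e) NA_real_)
    slide_labels <- vapply(gt, function(g) any(g != 0), logical(1))
    metrics$roc_auc_original <- tryCatch(
      slide_roc_auc(vapply(test, function(a) max(a$pmap), numeric(1)),
                    slide_labels),
      error = function(e) NA_real_)
    metrics$roc_auc_sua <- tryCatch(
      slide_roc_auc(vapply(ref_sua, function(r) max(r$refined_pmap),
                           numeric(1)), slide_labels),
      error = function(e) NA_real_)
  }

  boot <- NULL
  if (n_boot > 0L) {
    slide_inputs <- lapply(seq_along(test), function(i) {
      list(records = test[[i]]$records, ref_sua = ref_sua[[i]],
           ref_base = ref_base[[i]], gt = gt[[i]])
    })
    fbeta_stat <- function(slides) {
      rec <- data.table::rbindlist(lapply(slides, `[[`, "records"))
      tryCatch(
        f_beta(confusion_counts(rec$is_fn_predicted, rec$is_fn_truth),
               cfg$beta),
        error = function(e) NA_real_)
    }
    fncr_stat <- function(field) {
      function(slides) {
        tryCatch(
          fncr(lapply(slides, `[[`, field), lapply(slides, `[[`, "gt")),
          error = function(e) NA_real_)
      }
    }
    boot <- list(
      sua_f_beta = bootstrap_metric(slide_inputs, fbeta_stat, n_boot, seed),
      sua_fncr = bootstrap_metric(slide_inputs, fncr_stat("ref_sua"),
                                  n_boot, seed),
      baseline_fncr = bootstrap_metric(slide_inputs, fncr_stat("ref_base"),
                                       n_boot, seed)
    )
  }

  structure(
    list(cfg = cfg, calibration = list(region = cal_region,
                                       pixel = cal_pixel),
         metrics = metrics, bootstrap = boot,
         test = test, refinements = list(sua = ref_sua,
                                         baseline = ref_base)),
    class = "sua_experiment"
  )
}

#' @export
print.sua_experiment <- function(x, ...) {
  m <- x$metrics
  cat("<sua_experiment>\n")
  cat(sprintf("  tau (region) = %.4f, tau (pixel) = %.4f\n",
              x$calibration$region$tau, x$calibration$pixel$tau))
  cat(sprintf("  SUA      F_beta = %.4f  FNCR = %.4f  Dice = %.4f\n",
              m$sua$f_beta, m$sua$fncr, m$sua$dice_refined))
  cat(sprintf("  baseline F_beta = %.4f  FNCR = %.4f  Dice = %.4f\n",
              m$baseline$f_beta, m$baseline$fncr, m$baseline$dice_refined))
  cat(sprintf("  Dice (original) = %.4f\n", m$dice_original))
  invisible(x)
}
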