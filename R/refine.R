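# Segmentation refinement: convert detected FNs to positive predictions.
# Refinement only ever adds positives; rejecting false positives is a
# different task and is deliberately not performed here.

new_refinement_result <- function(pmap, cfg, update_mask, provenance,
                                  slide_id) {
  original_binary <- pmap >= cfg$t2
  update_mask <- update_mask & !original_binary
  refined_pmap <- pmap
  refined_pmap[update_mask] <- 1.0   # updated pixels become fully positive
  structure(
    list(
      refined_binary = original_binary | update_mask,
      refined_pmap = refined_pmap,
      original_binary = original_binary,
      updated_pixels = which(update_mask),
      provenance = provenance,
      slide_id = slide_id
    ),
    class = "refinement_result"
  )
}

#' @export
print.refinement_result <- function(x, ...) {
  cat(sprintf("<refinement_result> slide '%s' (%s): %d pixels updated\n",
              x$slide_id, x$provenance, length(x$updated_pixels)))
  invisible(x)
}

#' Refine a heatmap by converting detected-FN NPRs to positive
#'
#' Every pixel of every region flagged `is_fn_predicted` is updated to be
#' positive: set to probability 1.0 in the refined heatmap and included in
#' the refined binary mask alongside the original positives
#' (`pmap >= t2`). Pixels that were already positive are never counted as
#' updated, so refinement is idempotent and only ever adds positives.
#'
#' @param pmap fused probability map.
#' @param labels NPR label matrix matching `pmap`.
#' @param records region records carrying `is_fn_predicted` (see
#'   [detect_fn()]).
#' @param cfg a [threshold_config()].
#' @return `refinement_result`: list with `refined_binary`,
#'   `refined_pmap`, `original_binary`, `updated_pixels` (linear indices),
#'   `provenance = "sua"`, `slide_id`.
#' @export
refine_sua <- function(pmap, labels, records, cfg = threshold_config()) {
  assert_probabilities(pmap, "pmap")
  if (!is.matrix(labels)) stop_invalid("labels must be a matrix")
  assert_same_shape(pmap, labels, "probability map and labels")
  records <- data.table::as.data.table(records)
  if (is.null(records$is_fn_predicted)) {
    stop_invalid("records lack is_fn_predicted; run detect_fn() first")
  }
  n_regions <- if (any(labels > 0L)) max(labels) else 0L
  if (nrow(records) && any(!records$region_id %in% seq_len(n_regions))) {
    stop_invalid("records reference region ids absent from the label map")
  }
  flagged <- records$region_id[records$is_fn_predicted]
  update_mask <- matrix(FALSE, nrow(pmap), ncol(pmap))
  if (length(flagged)) update_mask[labels %in% flagged] <- TRUE
  new_refinement_result(pmap, cfg, update_mask, "sua",
                        attr(pmap, "slide_id") %||% "slide")
}

#' Refine a heatmap from baseline per-pixel flags
#'
#' Each flagged pixel is updated to positive individually, with the same
#' update semantics as [refine_sua()].
#'
#' @param pmap fused probability map.
#' @param baseline_pixel_mask logical matrix from
#'   [baseline_detect_fn_pixels()].
#' @param cfg a [threshold_config()].
#' @return `refinement_result` with `provenance = "baseline"`.
#' @export
refine_baseline <- function(pmap, baseline_pixel_mask,
                            cfg = threshold_config()) {
  assert_probabilities(pmap, "pmap")
  if (!is.matrix(baseline_pixel_mask)) {
    stop_invalid("baseline_pixel_mask must be a matrix")
  }
  assert_same_shape(pmap, baseline_pixel_mask, "probability map and mask")
  new_refinement_result(pmap, cfg, baseline_pixel_mask != 0, "baseline",
                        attr(pmap, "slide_id") %||% "slide")
}
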