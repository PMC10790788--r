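#' Build an ensemble stack of per-pixel tumor-probability maps
#'
#' An ensemble stack holds the K per-pixel softmax maps produced by a deep
#' ensemble for one slide. All members must share one shape and contain
#' finite values in \[0, 1\].
#'
#' @param members list of K numeric matrices, each a per-pixel tumor
#'   probability map with values in \[0, 1\].
#' @param slide_id character scalar identifying the slide.
#' @return An object of class `ensemble_stack`: a list with elements
#'   `members`, `slide_id` and `shape` (c(height, width)).
#' @examples
#' st <- ensemble_stack(list(matrix(0.2, 4, 4), matrix(0.4, 4, 4)), "s1")
#' fuse_ensemble(st)[1, 1]  # 0.3
#' @export
ensemble_stack <- function(members, slide_id = "slide") {
  if (!is.list(members) || length(members) < 1L) {
    stop_invalid("an ensemble stack needs at least one member map")
  }
  shape <- dim(members[[1L]])
  for (i in seq_along(members)) {
    assert_probabilities(members[[i]], sprintf("member %d", i))
    if (!identical(dim(members[[i]]), shape)) {
      stop_invalid("ensemble members must share one shape")
    }
  }
  structure(
    list(members = members, slide_id = as.character(slide_id), shape = shape),
    class = "ensemble_stack"
  )
}

#' @export
print.ensemble_stack <- function(x, ...) {
  cat(sprintf("<ensemble_stack> slide '%s': K=%d members, %d x %d px\n",
              x$slide_id, length(x$members), x$shape[1], x$shape[2]))
  invisible(x)
}

#' Fuse an ensemble into a single segmentation heatmap
#'
#' Ensemble predictions are fused by averaging the softmax score of the
#' members at every pixel, which is the standard deep-ensemble fusion rule.
#' The fused map is the "segmentation heatmap" consumed by NPR extraction
#' and (through [pixel_entropy()]) by the uncertainty estimate.
#'
#' @param stack an [ensemble_stack()] (a bare list of matrices is accepted).
#' @return numeric matrix of per-pixel mean probabilities, same shape as the
#'   members, with attribute `slide_id`.
#' @export
fuse_ensemble <- function(stack) {
  if (is.list(stack) && !inherits(stack, "ensemble_stack")) {
    stack <- ensemble_stack(stack)
  }
  if (!inherits(stack, "ensemble_stack")) {
    stop_invalid("fuse_ensemble expects an ensemble_stack or list of matrices")
  }
  fused <- Reduce(`+`, stack$members) / length(stack$members)
  attr(fused, "slide_id") <- stack$slide_id
  fused
}

#' Per-pixel predictive entropy of a fused probability map
#'
#' Computes the entropy of the ensemble-mean class distribution at each
#' pixel: H = -(p log p + (1 - p) log(1 - p)) in nats, with 0 log 0 = 0.
#' For a binary task H is bounded by log(2) ~ 0.693 and maximal at p = 0.5.
#' This "entropy of the mean" is the uncertainty heatmap aggregated by the
#' SUA detector; it is not the mean of per-member entropies.
#'
#' @param pmap numeric matrix of fused tumor probabilities in \[0, 1\].
#' @return numeric matrix of entropies (nats), same shape as `pmap`.
#' @examples
#' pixel_entropy(matrix(0.5))  # log(2)
#' @export
pixel_entropy <- function(pmap) {
  assert_probabilities(pmap, "pmap")
  h <- binary_entropy(pmap)
  attr(h, "slide_id") <- attr(pmap, "slide_id")
  h
}
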