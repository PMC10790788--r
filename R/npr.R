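#' Threshold and run configuration for NPR extraction and FN detection
#'
#' Bundles the thresholds that define negative-prediction regions (NPRs)
#' and how they are scored. An NPR is a connected component of pixels whose
#' fused softmax lies strictly between `t1` and `t2`: the upper threshold
#' `t2` is the positive-prediction cutoff (0.95 by convention, chosen in
#' the source study for ~8 average FROC false positives per slide on
#' validation data), and the lower bound `t1` exists only to stop NPRs
#' from growing without bound into the confident-negative background.
#' Typical sweeps use t1 in {0.55, 0.65, 0.75, 0.85}.
#'
#' @param t1 lower softmax bound, in \[0, 1).
#' @param t2 positive/segmentation threshold, in (0, 1\].
#' @param connectivity pixel adjacency, 8 (default, diagonal neighbors
#'   count) or 4.
#' @param aggregation region aggregation of pixel entropies: `"mean"`
#'   (default) or `"p90"` (90th percentile, linear interpolation).
#' @param tau FN-detection threshold on the aggregated entropy (nats);
#'   `NA` until calibrated.
#' @param min_region_px regions smaller than this many pixels are dropped
#'   (default 1 = keep all; single-pixel regions make percentile
#'   aggregation degenerate, so raising this can be useful with `"p90"`).
#' @param beta beta of the F-beta calibration objective (default 0.5,
#'   precision-weighted).
#' @param fn_fraction minimum ground-truth tumor fraction for an NPR to
#'   count as a true FN region (default 0.9, i.e. "at least 90% missed
#'   tumor pixels").
#' @return list of class `threshold_config`.
#' @export
threshold_config <- function(t1 = 0.55, t2 = 0.95, connectivity = 8L,
                             aggregation = c("mean", "p90"),
                             tau = NA_real_, min_region_px = 1L,
                             beta = 0.5, fn_fraction = 0.9) {
  aggregation <- match.arg(aggregation)
  if (!is.numeric(t1) || !is.numeric(t2) || t1 >= t2) {
    stop_invalid("invalid thresholds: need t1 < t2, got t1=", t1, " t2=", t2)
  }
  if (t1 < 0 || t2 > 1) stop_invalid("thresholds must lie in [0, 1]")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) {
    stop_invalid("connectivity must be 4 or 8")
  }
  if (!is.na(tau) && tau < 0) stop_invalid("tau must be >= 0")
  if (min_region_px < 1L) stop_invalid("min_region_px must be >= 1")
  if (fn_fraction < 0 || fn_fraction > 1) {
    stop_invalid("fn_fraction must lie in [0, 1]")
  }
  structure(
    list(t1 = t1, t2 = t2, connectivity = connectivity,
         aggregation = aggregation, tau = tau,
         min_region_px = as.integer(min_region_px),
         beta = beta, fn_fraction = fn_fraction),
    class = "threshold_config"
  )
}

#' Label connected components of a binary mask
#'
#' Union-find labeling over the pixel adjacency graph. Label ids are
#' assigned 1..R in raster-scan order (row-major) of each component's
#' first pixel, so output is deterministic.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix; 0 = background, 1..R = component ids.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask)) stop_invalid("mask must be a matrix")
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) return(lab)

  node <- integer(H * W)
  node[idx] <- seq_len(n)
  parent <- seq_len(n)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }

  offsets <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) {
    offsets <- c(offsets, list(c(1L, 1L), c(-1L, 1L)))
  }
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r_ok <- seq_len(H)
    r_ok <- r_ok[r_ok + dr >= 1L & r_ok + dr <= H]
    c_ok <- seq_len(W)
    c_ok <- c_ok[c_ok + dc >= 1L & c_ok + dc <= W]
    if (!length(r_ok) || !length(c_ok)) next
    both <- mask[r_ok, c_ok, drop = FALSE] &
      mask[r_ok + dr, c_ok + dc, drop = FALSE]
    w <- which(both)
    if (!length(w)) next
    nr <- length(r_ok)
    rr <- r_ok[(w - 1L) %% nr + 1L]
    cc <- c_ok[(w - 1L) %/% nr + 1L]
    a <- node[(cc - 1L) * H + rr]
    b <- node[(cc + dc - 1L) * H + rr + dr]
    for (k in seq_along(a)) {
      ra <- find_root(a[k]); rb <- find_root(b[k])
      if (ra != rb) parent[rb] <- ra
    }
  }

  roots <- vapply(seq_len(n), find_root, integer(1))
  # relabel components by raster-scan (row-major) first occurrence
  rows <- (idx - 1L) %% H + 1L
  cols <- (idx - 1L) %/% H + 1L
  scan_order <- order(rows, cols)
  new_id <- integer(n)
  next_id <- 0L
  for (k in scan_order) {
    r <- roots[k]
    if (new_id[r] == 0L) {
      next_id <- next_id + 1L
      new_id[r] <- next_id
    }
  }
  lab[idx] <- new_id[roots]
  lab
}

#' Extract negative-prediction regions from a segmentation heatmap
#'
#' Builds the binary eligibility mask `(pmap > t1) & (pmap < t2)` — both
#' inequalities strict, so pixels exactly at either threshold are
#' excluded — labels its connected components, drops components smaller
#' than `min_region_px`, and re-compacts the ids.
#'
#' @param pmap fused probability map (numeric matrix in \[0, 1\]).
#' @param cfg a [threshold_config()].
#' @return integer label matrix (0 = not in any NPR, 1..R = region ids)
#'   with attribute `slide_id`.
#' @export
extract_nprs <- function(pmap, cfg = threshold_config()) {
  assert_probabilities(pmap, "pmap")
  if (!inherits(cfg, "threshold_config")) {
    stop_invalid("cfg must be a threshold_config")
  }
  mask <- (pmap > cfg$t1) & (pmap < cfg$t2)
  lab <- label_components(mask, cfg$connectivity)
  if (cfg$min_region_px > 1L && any(lab > 0L)) {
    sizes <- tabulate(lab)
    keep <- which(sizes >= cfg$min_region_px)
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
  }
  attr(lab, "slide_id") <- attr(pmap, "slide_id")
  lab
}

#' Pixel coordinates of every labeled region
#'
#' @param labels integer label matrix from [extract_nprs()].
#' @return named list, one element per region id in increasing order; each
#'   element is an integer matrix with columns `row`, `col`.
#' @export
region_pixel_sets <- function(labels) {
  if (!is.matrix(labels)) stop_invalid("labels must be a matrix")
  pos <- which(labels > 0L)
  if (!length(pos)) return(structure(list(), names = character(0)))
  H <- nrow(labels)
  coords <- cbind(row = (pos - 1L) %% H + 1L, col = (pos - 1L) %/% H + 1L)
  split_idx <- split(seq_along(pos), labels[pos])
  out <- lapply(split_idx, function(i) coords[i, , drop = FALSE])
  out[order(as.integer(names(out)))]
}
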