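# Slide bundle I/O.
#
# Heatmaps are ordinary 2D rasters at whatever resolution the caller
# supplies; there is no WSI pyramid handling here. Rasters are stored as
# plain-text CSV matrices (one row per image row, "%.17g" formatting so
# doubles round-trip exactly) next to a JSON sidecar, `layout.json`, that
# declares the convention used by the directory.

#' Write a numeric matrix as a plain-text CSV raster
#'
#' Values are formatted with 17 significant digits so that doubles
#' round-trip bit-exactly through [read_matrix_raster()].
#'
#' @param x numeric matrix.
#' @param path output file path.
#' @export
write_matrix_raster <- function(x, path) {
  assert_matrix(x, "x")
  lines <- vapply(
    seq_len(nrow(x)),
    function(i) paste(sprintf("%.17g", x[i, ]), collapse = ","),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text CSV raster written by [write_matrix_raster()]
#'
#' @param path file path.
#' @return numeric matrix.
#' @export
read_matrix_raster <- function(path) {
  if (!file.exists(path)) stop_invalid("raster file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = ",")
  m <- as.matrix(dt)
  dimnames(m) <- NULL
  storage.mode(m) <- "double"
  m
}

# Binarize a ground-truth mask: any nonzero value (e.g. 255 in 8-bit
# exports) becomes 1.
binarize_mask <- function(mask) {
  assert_matrix(mask, "mask")
  if (anyNA(mask) || any(!is.finite(mask))) {
    stop_invalid("ground-truth mask contains non-finite values")
  }
  out <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  out
}

#' Read one slide bundle from disk
#'
#' A bundle directory holds the prediction evidence for one slide: either
#' the full ensemble (layout `"per_member"`, one raster per member) or an
#' already-fused probability map (layout `"fused"`), plus an optional
#' ground-truth tumor mask. A `layout.json` sidecar declares the
#' convention:
#'
#' ```json
#' {"layout": "per_member", "slide_id": "slide_001",
#'  "members": ["member_01.csv", ...], "mask": "gt.csv"}
#' ```
#'
#' @param path bundle directory.
#' @param layout optional layout list overriding / replacing the sidecar.
#' @return list with `stack` (an [ensemble_stack()], or `NULL` for fused
#'   layouts), `pmap` (fused probability map), `gt_mask` (binary 0/1
#'   integer matrix or `NULL`) and `slide_id`.
#' @export
read_slide_bundle <- function(path, layout = NULL) {
  if (!dir.exists(path)) stop_invalid("bundle directory not found: ", path)
  if (is.null(layout)) {
    sidecar <- file.path(path, "layout.json")
    if (!file.exists(sidecar)) {
      stop_invalid("no layout.json sidecar in ", path,
                   " and no layout supplied")
    }
    layout <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  kind <- layout$layout %||% "per_member"
  slide_id <- layout$slide_id %||% basename(path)

  stack <- NULL
  if (identical(kind, "per_member")) {
    files <- file.path(path, layout$members)
    missing <- files[!file.exists(files)]
    if (length(missing)) {
      stop_invalid("missing member rasters: ", paste(missing, collapse = ", "))
    }
    stack <- ensemble_stack(lapply(files, read_matrix_raster), slide_id)
    pmap <- fuse_ensemble(stack)
  } else if (identical(kind, "fused")) {
    pmap <- read_matrix_raster(file.path(path, layout$pmap %||% "pmap.csv"))
    assert_probabilities(pmap, "fused probability map")
    attr(pmap, "slide_id") <- slide_id
  } else {
    stop_invalid("unknown bundle layout: ", kind)
  }

  gt_mask <- NULL
  if (!is.null(layout$mask) && !is.na(layout$mask)) {
    mask_path <- file.path(path, layout$mask)
    if (!file.exists(mask_path)) {
      stop_invalid("declared mask file not found: ", mask_path)
    }
    gt_mask <- binarize_mask(read_matrix_raster(mask_path))
    assert_same_shape(pmap, gt_mask, "probability map and ground-truth mask")
  }

  list(stack = stack, pmap = pmap, gt_mask = gt_mask, slide_id = slide_id)
}

#' Write a slide bundle to disk
#'
#' Inverse of [read_slide_bundle()]; writes per-member rasters, the
#' optional mask, and the `layout.json` sidecar.
#'
#' @param stack an [ensemble_stack()].
#' @param path output directory (created if needed).
#' @param gt_mask optional binary ground-truth matrix.
#' @export
write_slide_bundle <- function(stack, path, gt_mask = NULL) {
  if (!inherits(stack, "ensemble_stack")) {
    stop_invalid("write_slide_bundle expects an ensemble_stack")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  member_files <- sprintf("member_%02d.csv", seq_along(stack$members))
  for (i in seq_along(stack$members)) {
    write_matrix_raster(stack$members[[i]], file.path(path, member_files[i]))
  }
  layout <- list(
    layout = "per_member",
    slide_id = stack$slide_id,
    members = member_files,
    mask = NULL
  )
  if (!is.null(gt_mask)) {
    assert_same_shape(stack$members[[1]], gt_mask, "members and mask")
    write_matrix_raster(gt_mask, file.path(path, "gt.csv"))
    layout$mask <- "gt.csv"
  }
  jsonlite::write_json(layout, file.path(path, "layout.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}
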