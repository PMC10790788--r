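# Synthetic slide generator.
#
# Emulates only the statistical structure the detector relies on, not
# H&E appearance: elliptical tumor blobs on a confident-negative
# background, where some blobs are rendered as sub-threshold FN
# candidates with elevated ensemble disagreement (higher entropy of the
# fused prediction) and others as in-range tumor-free distractors with
# baseline entropy. A domain-shift knob shrinks the FN/TN entropy gap.

#' Specification of a synthetic slide scene
#'
#' Entropy targets are stated in nats of the fused (ensemble-mean)
#' prediction, the quantity the SUA detector aggregates. A tumor-free
#' in-range distractor region sits at `base_entropy`; an FN-candidate
#' region sits at `base_entropy + delta * shift`. `shift = 1` is the
#' in-domain regime; `shift < 1` emulates domain shift degrading the
#' uncertainty signal by shrinking the separation.
#'
#' @param height,width scene size in pixels.
#' @param n_tumor_blobs number of tumor blobs; a fraction
#'   `fn_blob_fraction` of them are rendered as FN candidates (fused
#'   softmax inside (t1, t2)), the rest as detected tumor (softmax above
#'   t2).
#' @param fn_blob_fraction fraction of tumor blobs rendered as FN
#'   candidates, in \[0, 1\].
#' @param k_members ensemble size (default 5, a typical deep ensemble).
#' @param delta FN-vs-TN separation in mean fused entropy (nats),
#'   default 0.24.
#' @param shift domain-shift factor in \[0, 1\] multiplying `delta`
#'   (default 1 = in-domain).
#' @param background_npr_rate expected number of tumor-free in-range
#'   distractor regions (Poisson draw), default 4.
#' @param noise_sd per-pixel, per-member Gaussian softmax noise
#'   (default 0.01).
#' @param seed RNG seed; scenes are bit-reproducible given the seed.
#' @param base_entropy fused-entropy level of distractor regions (nats),
#'   default 0.42 (fused softmax about 0.83 — an in-range but fairly
#'   confident negative).
#' @param blob_entropy_sd between-blob SD of the entropy target (nats),
#'   default 0.05 — regions differ, as real NPRs do.
#' @param pixel_jitter_sd within-blob SD of the per-pixel fused softmax,
#'   default 0.06; this is what makes single-pixel entropy a noisy FN
#'   signal that regional aggregation denoises.
#' @param member_spread_sd SD of the per-blob, per-member softmax offset
#'   (ensemble disagreement), default 0.03; offsets are centered so the
#'   fused mean stays on target.
#' @param t1,t2 the threshold interval the planted in-range blobs target.
#' @param min_axis,max_axis ellipse semi-axis range in pixels.
#' @param slide_id slide identifier.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(height = 96L, width = 96L, n_tumor_blobs = 6L,
                       fn_blob_fraction = 0.5, k_members = 5L,
                       delta = 0.24, shift = 1.0,
                       background_npr_rate = 4, noise_sd = 0.01,
                       seed = 1L, base_entropy = 0.42,
                       blob_entropy_sd = 0.05, pixel_jitter_sd = 0.06,
                       member_spread_sd = 0.03,
                       t1 = 0.55, t2 = 0.95,
                       min_axis = 3.5, max_axis = 7.5,
                       slide_id = "slide") {
  spec <- list(height = as.integer(height), width = as.integer(width),
               n_tumor_blobs = as.integer(n_tumor_blobs),
               fn_blob_fraction = fn_blob_fraction,
               k_members = as.integer(k_members),
               delta = delta, shift = shift,
               background_npr_rate = background_npr_rate,
               noise_sd = noise_sd, seed = as.integer(seed),
               base_entropy = base_entropy,
               blob_entropy_sd = blob_entropy_sd,
               pixel_jitter_sd = pixel_jitter_sd,
               member_spread_sd = member_spread_sd,
               t1 = t1, t2 = t2, min_axis = min_axis, max_axis = max_axis,
               slide_id = as.character(slide_id))
  if (spec$n_tumor_blobs < 0 || spec$k_members < 1 ||
      spec$fn_blob_fraction < 0 || spec$fn_blob_fraction > 1 ||
      spec$delta < 0 || spec$shift < 0 || spec$shift > 1 ||
      spec$background_npr_rate < 0 || spec$noise_sd < 0) {
    stop_invalid("invalid scene_spec parameters")
  }
  if (spec$base_entropy + spec$delta >= log(2)) {
    stop_invalid("base_entropy + delta must stay below log(2) nats")
  }
  structure(spec, class = "scene_spec")
}

# Rasterize an ellipse; returns linear pixel indices, or NULL if empty.
ellipse_pixels <- function(cy, cx, a, b, theta, H, W) {
  rmax <- ceiling(max(a, b))
  rows <- max(1L, floor(cy - rmax)):min(H, ceiling(cy + rmax))
  cols <- max(1L, floor(cx - rmax)):min(W, ceiling(cx + rmax))
  dy <- rep(rows - cy, times = length(cols))
  dx <- rep(cols - cx, each = length(rows))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  if (!any(inside)) return(NULL)
  rr <- rep(rows, times = length(cols))[inside]
  cc <- rep(cols, each = length(rows))[inside]
  (cc - 1L) * H + rr
}

# Dilate a set of linear indices by `gap` pixels (Chebyshev) within HxW.
dilate_pixels <- function(px, gap, H, W) {
  r <- (px - 1L) %% H + 1L
  c <- (px - 1L) %/% H + 1L
  offs <- expand.grid(dr = -gap:gap, dc = -gap:gap)
  out <- integer(0)
  for (i in seq_len(nrow(offs))) {
    rr <- r + offs$dr[i]; cc <- c + offs$dc[i]
    ok <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    out <- c(out, (cc[ok] - 1L) * H + rr[ok])
  }
  unique(out)
}

#' Generate a synthetic slide scene
#'
#' Places non-overlapping elliptical blobs (with a 2-pixel gap so that
#' distinct blobs never merge under 8-connectivity) in three roles:
#'
#' * `detected-tumor`: ground-truth tumor, fused softmax above `t2` —
#'   correctly segmented;
#' * `fn-candidate`: ground-truth tumor (100% of blob pixels), fused
#'   softmax inside `(t1, t2)` with entropy around
#'   `base_entropy + delta * shift` — the planted false negatives;
#' * `tn-distractor`: tumor-free, fused softmax inside `(t1, t2)` with
#'   entropy around `base_entropy` — the in-range regions a detector
#'   must not flag.
#'
#' Each ensemble member receives a centered per-blob offset (zero-sum
#' across members, so the fused mean stays on target) plus i.i.d. pixel
#' noise; everything is clipped to \[0, 1\]. Deterministic under
#' `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return list of class `synthetic_scene`: `stack` ([ensemble_stack()]),
#'   `gt_mask` (0/1 integer matrix), `planted` (`data.table` with columns
#'   `blob_id`, `role`, `n_pixels` and list-column `pixels` of linear
#'   indices), and `spec`.
#' @export
generate_scene <- function(spec = scene_spec()) {
  if (!inherits(spec, "scene_spec")) stop_invalid("spec must be a scene_spec")
  H <- spec$height; W <- spec$width
  with_seed(spec$seed, {
    n_fn <- round(spec$n_tumor_blobs * spec$fn_blob_fraction)
    n_det <- spec$n_tumor_blobs - n_fn
    n_tn <- stats::rpois(1L, spec$background_npr_rate)
    roles <- c(rep("detected-tumor", n_det), rep("fn-candidate", n_fn),
               rep("tn-distractor", n_tn))

    occupied <- matrix(FALSE, H, W)
    blobs <- vector("list", length(roles))
    margin <- spec$max_axis + 1
    for (i in seq_along(roles)) {
      placed <- FALSE
      for (attempt in seq_len(300L)) {
        cy <- stats::runif(1, margin, H - margin)
        cx <- stats::runif(1, margin, W - margin)
        a <- stats::runif(1, spec$min_axis, spec$max_axis)
        b <- stats::runif(1, spec$min_axis, spec$max_axis)
        theta <- stats::runif(1, 0, pi)
        px <- ellipse_pixels(cy, cx, a, b, theta, H, W)
        if (is.null(px)) next
        halo <- dilate_pixels(px, 2L, H, W)
        if (any(occupied[halo])) next
        occupied[px] <- TRUE
        blobs[[i]] <- px
        placed <- TRUE
        break
      }
      if (!placed) {
        stop_invalid("capacity error: could not place blob ", i, " of ",
                     length(roles), " in a ", H, "x", W, " scene")
      }
    }

    # per-pixel fused target, starting from a confident-negative background
    p_pixel <- matrix(
      pmin(pmax(stats::rnorm(H * W, 0.05, 0.02), 0.001), 0.30), H, W)
    h_cap <- log(2) - 1e-3
    fn_target <- min(spec$base_entropy + spec$delta * spec$shift, h_cap)
    for (i in seq_along(roles)) {
      px <- blobs[[i]]
      if (roles[i] == "detected-tumor") {
        p_blob <- stats::runif(1, 0.965, 0.995)
        vals <- p_blob + stats::rnorm(length(px), 0, 0.01)
        p_pixel[px] <- pmin(pmax(vals, 0.96), 0.999)
      } else {
        e_blob <- if (roles[i] == "fn-candidate") fn_target else
          spec$base_entropy
        e_blob <- min(max(e_blob + stats::rnorm(1, 0, spec$blob_entropy_sd),
                          0.02), h_cap)
        p_blob <- entropy_inverse(e_blob)
        vals <- p_blob + stats::rnorm(length(px), 0, spec$pixel_jitter_sd)
        p_pixel[px] <- pmin(pmax(vals, spec$t1 + 0.02), spec$t2 - 0.02)
      }
    }

    # ensemble members: centered per-blob offsets + pixel noise
    members <- vector("list", spec$k_members)
    offset_maps <- replicate(spec$k_members, matrix(0, H, W),
                             simplify = FALSE)
    for (i in seq_along(roles)) {
      off <- stats::rnorm(spec$k_members, 0, spec$member_spread_sd)
      off <- off - mean(off)
      for (k in seq_len(spec$k_members)) {
        offset_maps[[k]][blobs[[i]]] <- off[k]
      }
    }
    # role map: 0 background, 1 detected-tumor, 2 in-range blob. Member
    # values are clipped per role so the construction guarantees hold
    # exactly: detected blobs threshold positive at t2, in-range blobs
    # stay strictly inside (t1, t2) after fusion.
    role_map <- matrix(0L, H, W)
    for (i in seq_along(roles)) {
      role_map[blobs[[i]]] <-
        if (roles[i] == "detected-tumor") 1L else 2L
    }
    for (k in seq_len(spec$k_members)) {
      m <- p_pixel + offset_maps[[k]] +
        stats::rnorm(H * W, 0, spec$noise_sd)
      m[role_map == 1L] <- pmax(m[role_map == 1L], spec$t2 + 0.005)
      m[role_map == 2L] <- pmin(pmax(m[role_map == 2L], spec$t1 + 0.005),
                                spec$t2 - 0.005)
      members[[k]] <- matrix(pmin(pmax(m, 0), 1), H, W)
    }

    gt_mask <- matrix(0L, H, W)
    for (i in seq_along(roles)) {
      if (roles[i] != "tn-distractor") gt_mask[blobs[[i]]] <- 1L
    }

    planted <- data.table::data.table(
      blob_id = seq_along(roles),
      role = roles,
      n_pixels = vapply(blobs, length, integer(1)),
      pixels = blobs
    )
    structure(
      list(stack = ensemble_stack(members, spec$slide_id),
           gt_mask = gt_mask, planted = planted, spec = spec),
      class = "synthetic_scene"
    )
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> '%s' %dx%d, K=%d\n", x$spec$slide_id,
              x$spec$height, x$spec$width, x$spec$k_members))
  print(x$planted[, c("blob_id", "role", "n_pixels")])
  invisible(x)
}

#' Write a synthetic scene to disk as a slide bundle
#'
#' Writes the ensemble stack and ground-truth mask in the standard bundle
#' layout (see [read_slide_bundle()]) plus a `truth_regions.csv` of the
#' planted blobs (one row per blob: `slide_id`, `blob_id`, `role`,
#' `n_pixels`).
#'
#' @param scene a [generate_scene()] result.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
scene_to_fixture <- function(scene, out_dir) {
  if (!inherits(scene, "synthetic_scene")) {
    stop_invalid("scene must be a synthetic_scene")
  }
  write_slide_bundle(scene$stack, out_dir, gt_mask = scene$gt_mask)
  truth <- scene$planted[, c("blob_id", "role", "n_pixels")]
  truth <- data.table::data.table(slide_id = scene$spec$slide_id, truth)
  data.table::fwrite(truth, file.path(out_dir, "truth_regions.csv"))
  invisible(out_dir)
}
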