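# Independent oracles used to cross-check the implementation. These are
# deliberately written with different algorithms (queue-based flood
# fill, explicit sort-and-interpolate, exhaustive enumeration) than the
# code under test.

# Queue-based flood-fill connected-component labeling; labels assigned
# in raster-scan (row-major) order of first unvisited pixel.
flood_fill_oracle <- function(mask, connectivity = 8L) {
  mask <- mask != 0
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  if (connectivity == 8L) {
    nb <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  } else {
    nb <- rbind(c(-1, 0), c(0, -1), c(0, 1), c(1, 0))
  }
  next_id <- 0L
  for (r in seq_len(H)) for (c in seq_len(W)) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    next_id <- next_id + 1L
    queue <- list(c(r, c))
    lab[r, c] <- next_id
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (i in seq_len(nrow(nb))) {
        rr <- cur[1] + nb[i, 1]; cc <- cur[2] + nb[i, 2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- next_id
          queue[[length(queue) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Canonical relabeling by raster-scan first occurrence, for comparing
# label maps up to id permutation.
canonical_labels <- function(lab) {
  H <- nrow(lab)
  pos <- which(lab > 0L)
  if (!length(pos)) return(lab)
  rows <- (pos - 1L) %% H + 1L
  cols <- (pos - 1L) %/% H + 1L
  remap <- integer(max(lab))
  nid <- 0L
  for (k in order(rows, cols)) {
    id <- lab[pos[k]]
    if (remap[id] == 0L) {
      nid <- nid + 1L
      remap[id] <- nid
    }
  }
  out <- lab
  out[pos] <- remap[lab[pos]]
  out
}

# Percentile with linear interpolation between order statistics
# (the "type 7" definition), written out explicitly.
percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  if (n == 1L) return(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Exhaustive maximum F-beta over every threshold-induced flag set:
# pred = score > v for every unique score value, plus flag-everything.
exhaustive_fbeta_max <- function(score, truth, beta = 0.5) {
  fb <- function(pred) {
    tp <- sum(pred & truth)
    if (tp == 0) return(0)
    prec <- tp / sum(pred)
    rec <- tp / sum(truth)
    (1 + beta^2) * prec * rec / (beta^2 * prec + rec)
  }
  cuts <- unique(score)
  best <- fb(rep(TRUE, length(score)))
  for (v in cuts) best <- max(best, fb(score > v))
  best
}

# Random region-record sets with both truth classes present.
random_records <- function(n, seed) {
  suaseg:::with_seed(seed, {
    truth <- c(TRUE, FALSE,
               stats::runif(n - 2) < 0.4)
    data.table::data.table(
      slide_id = "s", region_id = seq_len(n), n_pixels = 1L,
      agg_uncertainty = round(stats::runif(n, 0, log(2)), 3),
      is_fn_truth = truth)
  })
}

# Shorthand scene-set builders for experiment-level tests.
mk_scenes <- function(seeds, ...) {
  lapply(seeds, function(s) {
    generate_scene(scene_spec(..., seed = s,
                              slide_id = sprintf("s%03d", s)))
  })
}
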