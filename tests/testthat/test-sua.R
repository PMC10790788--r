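# Region aggregation, FN truth, calibration and detection.

mk_label_map <- function() {
  lab <- matrix(0L, 6, 6)
  lab[1, 1:5] <- 1L
  lab[3:4, 2:3] <- 2L
  lab
}

test_that("region aggregates: constant region, mean, and p90 oracle", {
  lab <- mk_label_map()
  umap <- matrix(0, 6, 6)
  umap[lab == 1L] <- 0.42
  umap[lab == 2L] <- c(0.1, 0.2, 0.3, 0.4)
  recs_m <- aggregate_region_uncertainty(lab, umap, "mean")
  expect_equal(recs_m$agg_uncertainty[1], 0.42)
  expect_equal(recs_m$agg_uncertainty[2], 0.25)
  recs_p <- aggregate_region_uncertainty(lab, umap, "p90")
  expect_equal(recs_p$agg_uncertainty[1], 0.42)  # constant region: p90 = mean

  umap[lab == 1L] <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  recs <- aggregate_region_uncertainty(lab, umap, "mean")
  expect_equal(recs$agg_uncertainty[1], 0.3)

  set.seed(3)
  for (i in 1:10) {
    vals <- runif(sample(2:30, 1), 0, log(2))
    umap[lab == 1L] <- 0
    umap2 <- matrix(0, 6, 6)
    lab2 <- matrix(0L, 6, 6)
    lab2[seq_along(vals)] <- 1L
    umap2[seq_along(vals)] <- vals
    got <- aggregate_region_uncertainty(lab2, umap2, "p90")$agg_uncertainty
    expect_equal(got, percentile_oracle(vals, 0.9))
  }
  expect_error(aggregate_region_uncertainty(lab, matrix(0, 3, 3)), "shape")
})

test_that("FN truth follows the inclusive 90% tumor-fraction rule", {
  lab <- matrix(0L, 4, 10)
  lab[1, ] <- 1L          # 10-pixel region
  lab[3, 1:4] <- 2L       # 4-pixel region
  umap <- matrix(0.3, 4, 10)
  recs <- aggregate_region_uncertainty(lab, umap, "mean")

  gt <- matrix(0L, 4, 10)
  gt[1, 1:9] <- 1L        # 9 of 10 tumor -> exactly 0.9, inclusive
  recs2 <- label_fn_truth(recs, lab, gt)
  expect_equal(recs2$tumor_fraction, c(0.9, 0))
  expect_identical(recs2$is_fn_truth, c(TRUE, FALSE))

  gt[1, ] <- 1L           # fully inside tumor
  recs3 <- label_fn_truth(recs, lab, gt)
  expect_equal(recs3$tumor_fraction[1], 1.0)
  expect_true(recs3$is_fn_truth[1])

  expect_error(label_fn_truth(recs, lab, NULL), "unavailable")
})

test_that("calibrate_tau separates a perfectly separable set and scans
           candidates exhaustively", {
  recs <- data.table::data.table(
    slide_id = "s", region_id = 1:6, n_pixels = 1L,
    agg_uncertainty = c(0.6, 0.6, 0.6, 0.2, 0.2, 0.2),
    is_fn_truth = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  cal <- calibrate_tau(recs)
  expect_equal(cal$f_beta, 1.0)
  expect_true(cal$tau > 0.2 && cal$tau <= 0.6)

  for (seed in 1:20) {
    r <- random_records(40, seed)
    cal <- calibrate_tau(r, beta = 0.5)
    expect_equal(cal$f_beta,
                 exhaustive_fbeta_max(r$agg_uncertainty, r$is_fn_truth, 0.5))
    # the returned tau actually achieves the reported F-beta
    pred <- r$agg_uncertainty > cal$tau
    expect_equal(f_beta(confusion_counts(pred, r$is_fn_truth)), cal$f_beta)
  }

  all_tn <- data.table::data.table(
    slide_id = "s", region_id = 1:3, n_pixels = 1L,
    agg_uncertainty = c(0.1, 0.2, 0.3), is_fn_truth = FALSE)
  expect_error(calibrate_tau(all_tn), "both")
})

test_that("detect_fn uses a strict threshold and is monotone in tau", {
  recs <- data.table::data.table(
    slide_id = "s", region_id = 1:4, n_pixels = 1L,
    agg_uncertainty = c(0.3, 0.5, 0.5, 0.7))
  out <- detect_fn(recs, 0.5)
  expect_identical(out$is_fn_predicted, c(FALSE, FALSE, FALSE, TRUE))
  out0 <- detect_fn(recs, 0)
  expect_true(all(out0$is_fn_predicted))

  set.seed(5)
  agg <- runif(100, 0, log(2))
  recs <- data.table::data.table(slide_id = "s", region_id = 1:100,
                                 n_pixels = 1L, agg_uncertainty = agg)
  taus <- sort(runif(10, 0, log(2)))
  prev <- rep(TRUE, 100)
  for (tau in taus) {
    flags <- detect_fn(recs, tau)$is_fn_predicted
    expect_identical(flags, agg > tau)  # independent comparison loop
    expect_true(all(prev[flags]))      # raising tau never adds a flag
    prev <- flags
  }
})

test_that("baseline flags eligible high-entropy pixels only", {
  cfg <- threshold_config()
  pmap <- matrix(c(0.7, 0.7, 0.96, 0.3), 2, 2)
  umap <- matrix(0.6, 2, 2)
  flags <- baseline_detect_fn_pixels(pmap, umap, cfg, tau_pixel = 0.5)
  # only eligible pixels (t1 < p < t2) can be flagged
  expect_identical(flags, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_false(any(baseline_detect_fn_pixels(pmap, umap, cfg, 0.7)))

  set.seed(6)
  pmap <- matrix(runif(400), 20, 20)
  umap <- pixel_entropy(pmap)
  tau <- 0.4
  flags <- baseline_detect_fn_pixels(pmap, umap, cfg, tau)
  oracle <- matrix(FALSE, 20, 20)
  for (i in seq_len(400)) {
    oracle[i] <- pmap[i] > cfg$t1 && pmap[i] < cfg$t2 && umap[i] > tau
  }
  expect_identical(unclass(flags), oracle)
})

test_that("aggregates lie within the region's pixel entropy range", {
  set.seed(8)
  pmap <- matrix(runif(48 * 48), 48, 48)
  umap <- pixel_entropy(pmap)
  lab <- extract_nprs(pmap, threshold_config())
  for (method in c("mean", "p90")) {
    recs <- aggregate_region_uncertainty(lab, umap, method)
    for (k in seq_len(nrow(recs))) {
      px <- umap[lab == recs$region_id[k]]
      expect_gte(recs$agg_uncertainty[k], min(px) - 1e-12)
      expect_lte(recs$agg_uncertainty[k], max(px) + 1e-12)
    }
  }
})
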