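# Metric machinery: F-beta, Dice, FNCR, FROC, ROC-AUC, bootstrap.

test_that("f_beta identities and edge cases", {
  # precision = recall = x  =>  F_beta = x, any beta
  for (x in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    tp <- round(x * 100); e <- 100 - tp
    for (beta in c(0.5, 1, 2)) {
      expect_equal(f_beta(list(tp = tp, fp = e, fn = e), beta), x)
    }
  }
  expect_equal(f_beta(list(tp = 0, fp = 3, fn = 2)), 0)
  # precision 0.8, recall 0.5, beta 0.5
  expect_equal(f_beta(list(tp = 4, fp = 1, fn = 4), 0.5), 0.714286,
               tolerance = 1e-6)
  expect_error(f_beta(list(tp = 0, fp = 0, fn = 0)), "undefined")
  # F_beta = 1 iff fp = fn = 0 with tp > 0
  expect_equal(f_beta(list(tp = 5, fp = 0, fn = 0)), 1)
  expect_lt(f_beta(list(tp = 5, fp = 1, fn = 0)), 1)
})

test_that("dice identities", {
  a <- matrix(c(1, 1, 0, 0), 2, 2)
  b <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(dice(a, a), 1.0)
  expect_equal(dice(a, b), 0.0)
  # TP=3, FP=1, FN=1 -> 6/8
  p <- matrix(c(1, 1, 1, 1, 0, 0), 2, 3)
  g <- matrix(c(1, 1, 1, 0, 1, 0), 2, 3)
  expect_equal(dice(p, g), 0.75)
  z <- matrix(0, 2, 2)
  expect_equal(dice(z, z), 1.0)
  expect_error(dice(a, matrix(0, 3, 3)), "shape")
})

test_that("fncr pools numerators and denominators across slides", {
  cfg <- threshold_config()
  # slide A: 4 updated, 3 tumor; slide B: 4 updated, 1 tumor -> 4/8
  pa <- matrix(0.7, 4, 4)
  ma <- matrix(FALSE, 4, 4); ma[1, 1:4] <- TRUE
  ga <- matrix(0L, 4, 4); ga[1, 1:3] <- 1L
  pb <- matrix(0.7, 4, 4)
  mb <- matrix(FALSE, 4, 4); mb[2, 1:4] <- TRUE
  gb <- matrix(0L, 4, 4); gb[2, 1] <- 1L
  ra <- refine_baseline(pa, ma, cfg); rb <- refine_baseline(pb, mb, cfg)
  expect_equal(fncr(list(ra, rb), list(ga, gb)), 0.5)
  # every updated pixel tumor -> exactly 1; none -> 0
  expect_equal(fncr(ra, ga * 0L + 1L), 1.0)
  expect_equal(fncr(ra, ga * 0L), 0.0)
  # pooled value lies between per-slide ratios
  pooled <- fncr(list(ra, rb), list(ga, gb))
  per <- c(fncr(ra, ga), fncr(rb, gb))
  expect_gte(pooled, min(per)); expect_lte(pooled, max(per))
  r0 <- refine_baseline(pa, matrix(FALSE, 4, 4), cfg)
  expect_error(fncr(r0, ga), "no pixels were updated")
})

test_that("froc_score: perfect detector and empty detector", {
  g <- matrix(0L, 10, 10); g[2:4, 2:4] <- 1L
  hit <- data.table::data.table(row = 3L, col = 3L, confidence = 0.99)
  none <- data.table::data.table(row = integer(0), col = integer(0),
                                 confidence = numeric(0))
  expect_equal(froc_score(list(hit), list(g)), 1.0)
  expect_equal(froc_score(list(none), list(g)), 0.0)
  expect_error(froc_score(list(hit), list(g * 0L)), "no lesions")
})

test_that("froc_score matches the hand-enumerated 3-slide toy value", {
  # slide 1: two lesions; detection in lesion 1 (0.9) + one FP (0.8)
  g1 <- matrix(0L, 12, 12); g1[1:2, 1:2] <- 1L; g1[8:9, 8:9] <- 1L
  d1 <- data.table::data.table(row = c(1L, 5L), col = c(1L, 5L),
                               confidence = c(0.9, 0.8))
  # slide 2: one lesion hit at 0.6, plus a strong FP (0.95)
  g2 <- matrix(0L, 12, 12); g2[4:6, 4:6] <- 1L
  d2 <- data.table::data.table(row = c(5L, 11L), col = c(5L, 11L),
                               confidence = c(0.6, 0.95))
  # slide 3: normal slide with one FP (0.7)
  g3 <- matrix(0L, 12, 12)
  d3 <- data.table::data.table(row = 2L, col = 10L, confidence = 0.7)
  # Hand enumeration over thresholds {.95,.9,.8,.7,.6} gives the curve
  # (avgFP, sens): (1/3, 1/3), (2/3, 1/3), (1, 2/3); reading it at
  # avgFP = {0.25,0.5,1,2,4,8} (clamped) gives (2*(1/3) + 4*(2/3)) / 6.
  expect_equal(froc_score(list(d1, d2, d3), list(g1, g2, g3)),
               (2 * (1 / 3) + 4 * (2 / 3)) / 6)
})

test_that("froc_score is invariant to slide order", {
  set.seed(31)
  gs <- lapply(1:3, function(i) {
    g <- matrix(0L, 10, 10); g[(2 * i):(2 * i + 1), 3:4] <- 1L; g
  })
  ds <- lapply(1:3, function(i) {
    data.table::data.table(row = sample(10, 3), col = sample(10, 3),
                           confidence = runif(3))
  })
  s1 <- froc_score(ds, gs)
  s2 <- froc_score(ds[c(3, 1, 2)], gs[c(3, 1, 2)])
  expect_equal(s1, s2)
})

test_that("heatmap_detections finds one local-max detection per
           positive component", {
  p <- matrix(0.1, 8, 8)
  p[2, 2:3] <- c(0.96, 0.98)
  p[6:7, 6] <- c(0.97, 0.955)
  det <- heatmap_detections(p, threshold_config())
  expect_equal(nrow(det), 2L)
  expect_equal(det$confidence, c(0.98, 0.97))
  expect_equal(det$row, c(2L, 6L))
  expect_equal(det$col, c(3L, 6L))
})

test_that("slide_roc_auc equals the pairwise Mann-Whitney count", {
  expect_equal(slide_roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(slide_roc_auc(rep(0.3, 6), c(TRUE, FALSE, TRUE, FALSE,
                                            TRUE, FALSE)), 0.5)
  set.seed(14)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    scores <- round(runif(n), 1)  # ties likely
    labels <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    pos <- scores[labels]; neg <- scores[!labels]
    wins <- 0
    for (a in pos) for (b in neg) {
      wins <- wins + (a > b) + 0.5 * (a == b)
    }
    expect_equal(slide_roc_auc(scores, labels),
                 wins / (length(pos) * length(neg)))
  }
  expect_error(slide_roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("bootstrap: determinism, SD = 0 for constants, exhaustive
           3-slide expectation", {
  slides <- list(list(num = 3, den = 4), list(num = 1, den = 4),
                 list(num = 2, den = 2))
  pooled <- function(s) {
    sum(vapply(s, `[[`, numeric(1), "num")) /
      sum(vapply(s, `[[`, numeric(1), "den"))
  }
  b1 <- bootstrap_metric(slides, pooled, n_boot = 500, seed = 99)
  b2 <- bootstrap_metric(slides, pooled, n_boot = 500, seed = 99)
  expect_identical(b1, b2)
  expect_equal(b1$point, 6 / 10)

  bc <- bootstrap_metric(slides, function(s) 0.7, n_boot = 100, seed = 1)
  expect_equal(bc$boot_sd, 0)
  expect_equal(bc$boot_mean, 0.7)

  # exhaustive expectation over the 27 equally likely ordered resamples
  grid <- expand.grid(1:3, 1:3, 1:3)
  exact <- mean(apply(grid, 1, function(idx) pooled(slides[idx])))
  b <- bootstrap_metric(slides, pooled, n_boot = 20000, seed = 7)
  expect_equal(b$boot_mean, exact, tolerance = 0.01)
})
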