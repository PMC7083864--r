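test_that("centroid matching handles the spec'd base cases", {
  pts <- cbind(row = c(10, 40, 90), col = c(10, 50, 20))
  m <- match_detections(pts, pts, radius = 5)
  expect_equal(unlist(m$counts), c(TP = 3L, FP = 0L, FN = 0L))

  # 3 predictions, 2 truths, all within radius -> TP = 2, FP = 1
  pred <- cbind(c(10, 11, 12), c(10, 10, 10))
  truth <- cbind(c(10.4, 11.4), c(10, 10))
  m <- match_detections(pred, truth, radius = 5)
  expect_equal(unlist(m$counts), c(TP = 2L, FP = 1L, FN = 0L))

  m <- match_detections(NULL, cbind(1:5, 1:5), radius = 3)
  expect_equal(unlist(m$counts), c(TP = 0L, FP = 0L, FN = 5L))
  expect_error(match_detections(pred, truth, radius = 0), "radius")
})

test_that("greedy matching never beats exhaustive optimal matching", {
  set.seed(31)
  for (case in 1:60) {
    np <- sample(0:6, 1); nt <- sample(0:6, 1)
    pred <- cbind(runif(np, 0, 40), runif(np, 0, 40))
    truth <- cbind(runif(nt, 0, 40), runif(nt, 0, 40))
    g <- match_detections(pred, truth, radius = 12)$counts$TP
    o <- optimal_match_tp(pred, truth, radius = 12)
    expect_lte(g, o)
    expect_gte(g, o - 1) # greedy nearest-neighbor is near-optimal on points
  }
})

test_that("metric formulas reproduce the printed worked examples", {
  # 404 correct detections out of 458 annotated cells
  r <- compute_metrics(list(TP = 404, FP = 0, FN = 54))
  expect_equal(round(r$S, 2), 0.88)
  # harmonic-mean identity on the S = 0.90, P = 0.72 row -> DC = 0.80
  expect_equal(round(2 * 0.90 * 0.72 / (0.90 + 0.72), 2), 0.80)
  # symmetric case
  r <- compute_metrics(list(TP = 7, FP = 7, FN = 7))
  expect_equal(c(r$S, r$P, r$DC), c(0.5, 0.5, 0.5))
})

test_that("undefined ratios are NaN with flags, never silent zeros", {
  r <- compute_metrics(list(TP = 0, FP = 0, FN = 5))
  expect_true(is.nan(r$P))
  expect_true(r$undefined[["P"]])
  expect_equal(r$S, 0)
  expect_error(compute_metrics(list(TP = 0, FP = 0, FN = 0)), "degenerate")
})

test_that("DC equals the harmonic mean of S and P (fuzzed)", {
  set.seed(32)
  for (i in 1:100) {
    cts <- list(TP = sample(1:500, 1), FP = sample(0:300, 1),
                FN = sample(0:300, 1))
    r <- compute_metrics(cts)
    expect_equal(r$DC, 2 * r$S * r$P / (r$S + r$P), tolerance = 1e-12)
  }
})

test_that("swapping prediction and truth swaps S and P, fixes DC", {
  set.seed(33)
  pred <- cbind(runif(8, 0, 60), runif(8, 0, 60))
  truth <- cbind(runif(6, 0, 60), runif(6, 0, 60))
  a <- compute_metrics(match_detections(pred, truth, 15)$counts)
  b <- compute_metrics(match_detections(truth, pred, 15)$counts)
  expect_equal(a$S, b$P)
  expect_equal(a$P, b$S)
  expect_equal(a$DC, b$DC)
  # pixel level
  m1 <- matrix(rbinom(100, 1, 0.4), 10)
  m2 <- matrix(rbinom(100, 1, 0.4), 10)
  pa <- pixel_metrics(m1, m2); pb <- pixel_metrics(m2, m1)
  expect_equal(pa$S, pb$P)
  expect_equal(pa$DC, pb$DC)
})

test_that("pixel metrics match a hand-countable fixture", {
  truth <- matrix(0, 10, 10); truth[1:5, 1:6] <- 1   # 30 px
  pred <- matrix(0, 10, 10); pred[2:6, 2:6] <- 1     # 25 px
  # overlap rows 2-5 x cols 2-6 = 20 px
  r <- pixel_metrics(pred, truth)
  expect_equal(r$counts$TP, 20)
  expect_equal(r$S, 20 / 30)
  expect_equal(r$P, 20 / 25)
  expect_equal(r$DC, 40 / 55)
  expect_equal(r$level, "pixel")
  expect_equal(pixel_metrics(pred, pred)$DC, 1)
  disj <- matrix(0, 10, 10); disj[8:10, 8:10] <- 1
  expect_equal(pixel_metrics(pred, disj)$DC, 0)
  expect_error(pixel_metrics(pred, matrix(0, 9, 10)), "shapes")
})

test_that("weighted averaging follows the 1/3-2/3 aggregation", {
  ra <- compute_metrics(list(TP = 90, FP = 35, FN = 10))
  rb <- compute_metrics(list(TP = 87, FP = 61, FN = 13))
  w <- weighted_average_metrics(list(ra, rb), c(1 / 3, 2 / 3))
  expect_equal(w$S, ra$S / 3 + 2 * rb$S / 3)
  # S values 0.90 (w = 1/3) and 0.87 (w = 2/3) -> 0.88
  mk <- function(S) structure(list(S = S, P = 0.5, DC = 0.5),
                              class = "metrics_report")
  expect_equal(round(weighted_average_metrics(
    list(mk(0.90), mk(0.87)), c(1 / 3, 2 / 3))$S, 2), 0.88)
  expect_equal(weighted_average_metrics(list(ra, ra), c(0.5, 0.5))$DC, ra$DC)
  expect_equal(weighted_average_metrics(list(ra, rb), c(1, 0))$P, ra$P)
  expect_error(weighted_average_metrics(list(ra, rb), c(0.6, 0.6)),
               "sum to 1")
})
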