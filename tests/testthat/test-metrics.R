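test_that("confusion counts match hand-enumerated pixels and conserve mass", {
  D <- matrix(c(1, 1, 0, 1), 2, 2)   # [[1,0],[1,1]] row-wise
  G <- matrix(c(1, 0, 1, 1), 2, 2)   # [[1,1],[0,1]]
  cc <- confusion_counts(D, G)
  expect_equal(cc$tp, 2)
  expect_equal(cc$tn, 0)
  expect_equal(cc$fp, 1)
  expect_equal(cc$fn, 1)

  # identity case and constant map
  gt <- matrix(rbinom(20, 1, 0.4), 4, 5)
  cid <- confusion_counts(gt, gt)
  expect_equal(cid$fp, 0)
  expect_equal(cid$fn, 0)
  expect_equal(cid$tp, sum(gt))
  chalf <- confusion_counts(matrix(0.5, 4, 5), gt)
  expect_equal(chalf$tp, 0.5 * sum(gt))
  expect_equal(chalf$fp, 0.5 * sum(1 - gt))

  # conservation for arbitrary continuous maps
  set.seed(11)
  for (k in 1:20) {
    p <- random_pair(8, 8, blobby = FALSE)
    cc <- confusion_counts(p$pred, p$gt)
    expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 64, tolerance = 1e-6)
  }

  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("precision/recall guard empty denominators", {
  pr <- precision_recall(list(tp = 2, fp = 1, fn = 1))
  expect_equal(unname(pr), c(2 / 3, 2 / 3))
  expect_equal(unname(precision_recall(list(tp = 5, fp = 0, fn = 0))), c(1, 1))
  expect_equal(precision_recall(list(tp = 0, fp = 3, fn = 2))[["precision"]], 0)
  expect_warning(pr0 <- precision_recall(list(tp = 0, fp = 0, fn = 0)), "returning 0")
  expect_equal(unname(pr0), c(0, 0))
})

test_that("dice and iou match hand counts and the algebraic identity", {
  pred <- matrix(0, 4, 4); pred[, 1:2] <- 1   # left half
  gt <- matrix(0, 4, 4); gt[1:2, ] <- 1       # top half
  expect_equal(dice(pred, gt), 0.5)
  expect_equal(iou(pred, gt), 1 / 3)
  expect_equal(dice(gt, gt), 1)
  a <- matrix(0, 3, 3); a[1, 1] <- 1
  b <- matrix(0, 3, 3); b[3, 3] <- 1
  expect_equal(dice(a, b), 0)
  expect_message(expect_equal(dice(a * 0, b * 0), 1), "convention")
  expect_message(expect_equal(iou(a * 0, b * 0), 1), "convention")

  set.seed(12)
  for (k in 1:25) {
    p <- random_pair(8, 8, blobby = FALSE)
    pb <- (p$pred >= 0.5) * 1
    i <- suppressMessages(iou(pb, p$gt))
    expect_equal(suppressMessages(dice(pb, p$gt)), 2 * i / (1 + i))
  }
})

test_that("mae behaves on exact, constant and inverted predictions", {
  gt <- matrix(rbinom(36, 1, 0.5), 6, 6)
  expect_equal(mae(gt, gt), 0)
  expect_equal(mae(matrix(0.5, 6, 6), gt), 0.5)
  expect_equal(mae(1 - gt, gt), 1)
})

test_that("weighted F-measure reduces to precision when P equals R", {
  gt <- matrix(0, 4, 4); gt[1:2, 1:2] <- 1
  expect_equal(fbeta_weighted(gt, gt), 1)
  # build a map with P = R = 2/3: tp = 2, fp = 1, fn = 1
  pred <- matrix(0, 4, 4); pred[1, 1] <- 1; pred[1, 2] <- 1; pred[3, 3] <- 1
  gt2 <- matrix(0, 4, 4); gt2[1, 1] <- 1; gt2[1, 2] <- 1; gt2[4, 4] <- 1
  expect_equal(fbeta_weighted(pred, gt2), 2 / 3)
  # P > 0, R = 0 impossible with soft counts; all-miss gives 0
  expect_equal(fbeta_weighted(matrix(0, 4, 4), gt), 0)
})

test_that("s-measure object term and degenerate fallbacks", {
  # constant prediction 0.5: object score 2*0.5/(0.25+1+0) = 0.8 on both sides
  expect_equal(mugennet:::s_object_term(rep(0.5, 10), 1), 0.8)
  gt <- matrix(0, 8, 8); gt[3:6, 3:6] <- 1
  expect_equal(s_measure(gt, gt), 1, tolerance = 1e-6)
  # all-background gt: driven by mean of prediction
  pred <- matrix(0.3, 8, 8)
  expect_equal(s_measure(pred, matrix(0, 8, 8)), 0.7)
  expect_equal(s_measure(pred, matrix(1, 8, 8)), 0.3)
})

test_that("e-measure sign algebra, degenerate cases and clamping", {
  gt <- matrix(0, 6, 6); gt[1:3, ] <- 1       # balanced half-foreground
  expect_equal(e_measure(gt, gt), 1, tolerance = 1e-6)
  # anti-correlated maps align at -1 everywhere; reported after clamping
  expect_equal(e_measure(1 - gt, gt), 0)
  # both constant
  expect_equal(e_measure(matrix(0.5, 4, 4), matrix(0, 4, 4)), 0)
  expect_equal(e_measure(matrix(1, 4, 4), matrix(1, 4, 4)), 1)
})

test_that("metrics are symmetric or dual under pred/gt exchange", {
  set.seed(13)
  for (k in 1:10) {
    p <- random_pair(8, 8, blobby = FALSE)
    pb <- (p$pred >= 0.5) * 1
    expect_equal(suppressMessages(dice(pb, p$gt)), suppressMessages(dice(p$gt, pb)))
    expect_equal(suppressMessages(iou(pb, p$gt)), suppressMessages(iou(p$gt, pb)))
    expect_equal(mae(pb, p$gt), mae(p$gt, pb))
    prf <- precision_recall(confusion_counts(pb, p$gt))
    prb <- precision_recall(confusion_counts(p$gt, pb))
    expect_equal(prf[["precision"]], prb[["recall"]])
    expect_equal(prf[["recall"]], prb[["precision"]])
  }
})

test_that("moving a prediction toward the ground truth improves dice and mae", {
  set.seed(14)
  p <- random_pair(12, 12)
  pred <- p$pred
  toward <- pred + 0.5 * (p$gt - pred)   # pointwise move toward gt
  expect_lte(mae(toward, p$gt), mae(pred, p$gt))
  d0 <- suppressMessages(dice((pred >= 0.5) * 1, p$gt))
  d1 <- suppressMessages(dice((toward >= 0.5) * 1, p$gt))
  expect_gte(d1, d0)
})

test_that("dataset evaluation aggregates per-image scores", {
  gt <- matrix(0, 8, 8); gt[2:5, 2:5] <- 1
  r1 <- evaluate_pairs(list(list(gt, gt)))
  expect_equal(unname(r1$means["mDice"]), 1)
  expect_equal(r1$per_image$dice, 1)
  # duplicated pair leaves means unchanged
  r2 <- evaluate_pairs(list(list(gt, gt), list(gt, gt)))
  expect_equal(r1$means, r2$means)
  # dice 1 and 0 average to 0.5
  off <- matrix(0, 8, 8); off[7:8, 7:8] <- 1
  r3 <- evaluate_pairs(list(list(gt, gt), list(off, gt)))
  expect_equal(unname(r3$means["mDice"]), 0.5)
  expect_error(evaluate_pairs(list()), "empty")
})
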