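test_that("boundary weight map is 1 on constant masks and peaks at edges", {
  cfg <- loss_config()
  expect_equal(boundary_weight_map(matrix(0, 40, 40), cfg), matrix(1, 40, 40))
  expect_equal(boundary_weight_map(matrix(1, 40, 40), cfg), matrix(1, 40, 40))

  # single foreground pixel centered in a full 31-window
  gt <- matrix(0, 41, 41); gt[21, 21] <- 1
  w <- boundary_weight_map(gt, cfg)
  expect_equal(w[21, 21], 1 + 5 * (1 - 1 / 961))
  expect_gte(min(w), 1)

  # symmetric under mask complement
  set.seed(21)
  g <- matrix(rbinom(64, 1, 0.5), 8, 8)
  expect_equal(boundary_weight_map(g, cfg), boundary_weight_map(1 - g, cfg))
})

test_that("weighted BCE matches analytic values and is scale-free in w", {
  cfg <- loss_config()
  gt <- matrix(rbinom(64, 1, 0.5), 8, 8)
  w1 <- matrix(1, 8, 8)
  expect_equal(weighted_bce(matrix(0.5, 8, 8), gt, w1, cfg), log(2),
               tolerance = 1e-6)
  # perfect prediction: loss at the eps floor
  expect_lt(weighted_bce(gt, gt, w1, cfg), 1e-6)
  # constant weight cancels in the normalization
  expect_equal(weighted_bce(matrix(0.3, 8, 8), gt, w1 * 7, cfg),
               weighted_bce(matrix(0.3, 8, 8), gt, w1, cfg))
  expect_error(weighted_bce(matrix(2, 8, 8), gt, w1, cfg), "\\[0, 1\\]")
})

test_that("weighted soft IoU covers perfect, half and disjoint predictions", {
  cfg <- loss_config()
  gt <- matrix(0, 8, 8); gt[2:5, 2:5] <- 1
  w <- boundary_weight_map(gt, cfg)
  expect_equal(weighted_iou(gt, gt, w, cfg), 0, tolerance = 1e-9)
  expect_equal(weighted_iou(matrix(0.5, 8, 8), matrix(1, 8, 8),
                            matrix(1, 8, 8), cfg), 0.5, tolerance = 1e-8)
  disj <- matrix(0, 8, 8); disj[7:8, 7:8] <- 1
  expect_equal(weighted_iou(disj, gt, matrix(1, 8, 8), cfg), 1, tolerance = 1e-6)
  # empty gt with empty prediction is not penalized
  expect_equal(weighted_iou(matrix(0, 8, 8), matrix(0, 8, 8),
                            matrix(1, 8, 8), cfg), 0)
})

test_that("branch loss composes IoU and BCE at n = 6/5", {
  gt <- matrix(1, 8, 8)
  l <- branch_loss(matrix(0.5, 8, 8), gt, loss_config())
  expect_equal(l[["iou"]], 0.5, tolerance = 1e-8)
  expect_equal(l[["bce"]], log(2), tolerance = 1e-6)
  expect_equal(l[["total"]], l[["iou"]] + 1.2 * l[["bce"]], tolerance = 1e-9)
  expect_equal(l[["total"]], 0.5 + 1.2 * log(2), tolerance = 1e-5)

  lp <- branch_loss(gt, gt, loss_config())
  expect_equal(unname(lp), c(0, 0, 0), tolerance = 1e-6)

  l0 <- branch_loss(matrix(0.5, 8, 8), gt, loss_config(n = 0))
  expect_equal(l0[["total"]], l0[["iou"]])
  expect_error(branch_loss(matrix(0.5, 4, 4), gt, loss_config()), "mismatch")
})

test_that("gain 0 reduces weighted losses to their unweighted form", {
  set.seed(22)
  gt <- matrix(0, 16, 16); gt[4:10, 5:12] <- 1
  pred <- matrix(runif(256), 16, 16)
  cfg0 <- loss_config(weight_gain = 0)
  w0 <- boundary_weight_map(gt, cfg0)
  expect_equal(w0, matrix(1, 16, 16))
  u <- matrix(1, 16, 16)
  expect_equal(weighted_bce(pred, gt, w0, cfg0), weighted_bce(pred, gt, u, cfg0),
               tolerance = 1e-9)
  expect_equal(weighted_iou(pred, gt, w0, cfg0), weighted_iou(pred, gt, u, cfg0),
               tolerance = 1e-9)
})

test_that("total loss is linear in the output weights and flags bad outputs", {
  set.seed(23)
  gt <- matrix(0, 8, 8); gt[3:6, 3:6] <- 1
  s1 <- matrix(runif(64), 8, 8)
  s2 <- matrix(runif(64), 8, 8)
  s3 <- matrix(runif(64), 8, 8)
  lb <- total_loss(s1, s2, s3, gt, loss_config())
  expect_equal(lb$total,
               lb$per_output$s_t[["total"]] + lb$per_output$s_r[["total"]] +
                 lb$per_output$s_z[["total"]], tolerance = 1e-6)
  expect_true(all(unlist(lb$per_output) >= 0))

  # perfect predictions give zero
  lp <- total_loss(gt, gt, gt, gt, loss_config())
  expect_equal(lp$total, 0, tolerance = 1e-5)

  # alpha = 1, beta = gamma = 0 equals the single-branch loss
  la <- total_loss(s1, s2, s3, gt, loss_config(beta = 0, gamma = 0))
  expect_equal(la$total, branch_loss(s1, gt, loss_config())[["total"]])

  # doubling all weights doubles the total
  l2 <- total_loss(s1, s2, s3, gt, loss_config(alpha = 2, beta = 2, gamma = 2))
  expect_equal(l2$total, 2 * lb$total, tolerance = 1e-9)

  # a missing side output contributes nothing
  lm <- total_loss(NULL, s2, s3, gt, loss_config())
  expect_equal(lm$total,
               lb$total - lb$per_output$s_t[["total"]], tolerance = 1e-9)
})

test_that("graph-side loss agrees with the numeric loss and its gradient descends", {
  set.seed(24)
  gt <- matrix(0, 8, 8); gt[3:6, 2:5] <- 1
  cfg <- loss_config()
  w <- boundary_weight_map(gt, cfg)
  logit <- array(rnorm(64), c(8, 8, 1, 1))
  node <- mugennet:::ag_leaf(logit)
  gl <- mugennet:::g_branch_loss(node, array(gt, c(8, 8, 1, 1)),
                                 array(w, c(8, 8, 1, 1)), cfg)
  p <- 1 / (1 + exp(-logit[, , 1, 1]))
  ln <- branch_loss(p, gt, cfg)
  expect_equal(as.numeric(gl$loss$val), ln[["total"]], tolerance = 1e-6)
  expect_equal(gl$iou, ln[["iou"]], tolerance = 1e-6)
  expect_equal(gl$bce, ln[["bce"]], tolerance = 1e-6)

  # analytic gradient matches central differences
  mugennet:::ag_backward(gl$loss)
  f <- function(v) {
    nd <- mugennet:::ag_const(array(v, c(8, 8, 1, 1)))
    as.numeric(mugennet:::g_branch_loss(nd, array(gt, c(8, 8, 1, 1)),
                                        array(w, c(8, 8, 1, 1)), cfg)$loss$val)
  }
  gn <- num_grad(f, as.vector(logit))
  expect_lt(max(abs(gn - as.vector(node$grad))), 1e-6)

  # a logistic prediction moving toward gt strictly decreases the loss
  for (k in 1:5) {
    gt2 <- matrix(rbinom(36, 1, 0.5), 6, 6)
    w2 <- boundary_weight_map(gt2, cfg)
    z <- matrix(rnorm(36), 6, 6)
    l_here <- branch_loss(1 / (1 + exp(-z)), gt2, cfg)[["total"]]
    z_better <- z + 0.5 * ((2 * gt2 - 1) * 4 - z)
    l_better <- branch_loss(1 / (1 + exp(-z_better)), gt2, cfg)[["total"]]
    expect_lt(l_better, l_here)
  }
})
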