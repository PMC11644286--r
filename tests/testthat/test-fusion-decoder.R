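desk_model <- function(seed = 1, ...) mugen_model(mugen_config("desk", ...), seed)

test_that("SE gates stay in (0,1), preserve shape, and saturate with large biases", {
  m <- desk_model(6)
  set.seed(51)
  t1 <- array(rnorm(8 * 8 * 32 * 2), c(8, 8, 32, 2))
  z <- se_attention(m, 2, t1)
  expect_equal(dim(z$out), dim(t1))
  expect_true(all(z$gates > 0 & z$gates < 1))
  # force the second bottleneck bias high: gates -> 1, output -> input
  m2 <- m
  m2$params[["fuse2.se2.b"]][] <- 50
  z2 <- se_attention(m2, 2, t1)
  expect_lt(max(abs(z2$out - t1)), 1e-6)
})

test_that("channel attention uses the max only and handles zero channels", {
  m <- desk_model(7)
  set.seed(52)
  r1 <- array(runif(8 * 8 * 32, 0, 2), c(8, 8, 32, 1))
  g1 <- channel_attention(m, 2, r1)$gates
  # shrink a non-maximal pixel of channel 3; its gate must not move
  r2 <- r1
  idx <- which(r2[, , 3, 1] < max(r2[, , 3, 1]), arr.ind = TRUE)[1, ]
  r2[idx[1], idx[2], 3, 1] <- r2[idx[1], idx[2], 3, 1] * 0.5
  g2 <- channel_attention(m, 2, r2)$gates
  expect_equal(g1, g2)
  # an all-zero feature map gates at sigmoid(network(0))
  r0 <- array(0, c(8, 8, 32, 1))
  g0 <- channel_attention(m, 2, r0)$gates
  b1 <- m$params[["fuse2.ca1.b"]]
  h <- ifelse(b1 > 0, b1, 0.01 * b1)   # leaky bottleneck activation
  expected <- 1 / (1 + exp(-(h %*% m$params[["fuse2.ca2.w"]] + m$params[["fuse2.ca2.b"]])))
  expect_equal(as.vector(g0), as.vector(expected), tolerance = 1e-8)
})

test_that("fusion is residual: zeroed projection leaves exactly the skip path", {
  m <- desk_model(8)
  set.seed(53)
  t1 <- array(rnorm(8 * 8 * 32 * 2), c(8, 8, 32, 2))
  r1 <- array(rnorm(8 * 8 * 32 * 2), c(8, 8, 32, 2))
  m0 <- m
  m0$params[["fuse2.proj.w"]][] <- 0
  m0$params[["fuse2.proj.b"]][] <- 0
  m0$params[["fuse2.proj.bb"]][] <- 0
  y <- mugen_fuse(m0, 2, t1, r1)
  # skip path: 1x1 conv of the raw concatenation
  cat_raw <- mugennet:::ag_concat_c(mugennet:::ag_const(t1), mugennet:::ag_const(r1))
  sk <- mugennet:::ag_conv2d(cat_raw, mugennet:::ag_const(m0$params[["fuse2.skip.w"]]),
                             mugennet:::ag_const(m0$params[["fuse2.skip.b"]]), 1L, 0L)
  expect_equal(y, sk$val, tolerance = 1e-12)
  # shape contract and mismatch error
  expect_equal(dim(mugen_fuse(m, 2, t1, r1)), c(8L, 8L, 32L, 2L))
  expect_error(mugen_fuse(m, 2, t1[, , 1:16, , drop = FALSE], r1), "mismatch")
})

test_that("attention gates bound coefficients, upsample 2x and saturate open", {
  m <- desk_model(9)
  set.seed(54)
  g <- array(rnorm(8 * 8 * 16 * 2), c(8, 8, 16, 2))     # coarse
  x <- array(rnorm(16 * 16 * 16 * 2), c(16, 16, 16, 2)) # fine
  z <- attention_gate(m, 3, g, x)
  expect_equal(dim(z$out), dim(x))
  expect_equal(dim(z$alpha)[1:2], 2L * dim(g)[1:2])
  expect_true(all(z$alpha > 0 & z$alpha < 1))
  # large psi bias opens the gate fully: output ~ x
  m2 <- m
  m2$params[["dec.ag3.psi.b"]][] <- 60
  z2 <- attention_gate(m2, 3, g, x)
  expect_lt(max(abs(z2$out - x)), 1e-6)
  expect_error(attention_gate(m, 3, array(0, c(5, 5, 16, 2)), x), "scale mismatch")
})

test_that("the decoder walks the exact scale ladder", {
  m <- desk_model(10)
  set.seed(55)
  y1 <- array(rnorm(4 * 4 * 64), c(4, 4, 64, 1))
  y2 <- array(rnorm(8 * 8 * 32), c(8, 8, 32, 1))
  y3 <- array(rnorm(16 * 16 * 16), c(16, 16, 16, 1))
  d <- mugen_decode(m, y1, y2, y3)
  expect_equal(dim(d$z1), c(8L, 8L, 32L, 1L))
  expect_equal(dim(d$z2), c(16L, 16L, 16L, 1L))
  expect_equal(dim(d$z3), c(32L, 32L, 8L, 1L))
  expect_equal(dim(d$zout), c(64L, 64L, 1L, 1L))
  expect_true(all(d$zout >= 0 & d$zout <= 1))
  expect_identical(d, mugen_decode(m, y1, y2, y3))
  expect_error(mugen_decode(m, y1, y3, y2), "ladder")
})

test_that("the full forward emits bounded full-resolution maps for all ablations", {
  set.seed(56)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  for (ab in c("complete", "backbone", "backbone_tb", "backbone_cb")) {
    m <- mugen_model(mugen_config("desk", ablation = ab), seed = 11)
    o <- mugen_forward(m, x)
    expect_equal(dim(o$zout), c(64L, 64L, 1L, 1L))
    expect_true(all(o$zout >= 0 & o$zout <= 1))
    expect_equal(dim(o$sr), dim(o$zout))
    if (ab %in% c("complete", "backbone_tb")) {
      expect_equal(dim(o$st), dim(o$zout))
    } else {
      expect_null(o$st)
    }
  }
})

test_that("gradients reach every trainable parameter (no dead branch)", {
  m <- mugen_model(mugen_config("desk"), seed = 12)
  set.seed(57)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  y <- array(0, c(64, 64, 2)); y[20:44, 18:40, ] <- 1
  cfg <- loss_config()
  w <- array(1, c(64, 64, 2))
  for (i in 1:2) w[, , i] <- boundary_weight_map(y[, , i], cfg)
  ctx <- mugennet:::forward_ctx(m, training = TRUE, trainable = TRUE)
  out <- mugennet:::fw_full(ctx, mugennet:::ag_const(x))
  lt <- mugennet:::g_branch_loss(out$st_logit, y, w, cfg)
  lr <- mugennet:::g_branch_loss(out$sr_logit, y, w, cfg)
  lz <- mugennet:::g_branch_loss(out$zlogit, y, w, cfg)
  total <- mugennet:::ag_add(lt$loss, mugennet:::ag_add(lr$loss, lz$loss))
  mugennet:::ag_backward(total)
  norms <- vapply(names(m$params), function(nm) {
    g <- ctx$P[[nm]]$grad
    if (is.null(g)) return(NA_real_)
    sqrt(sum(g^2))
  }, numeric(1))
  expect_false(any(is.na(norms)))
  expect_true(all(is.finite(norms)))
  expect_true(all(norms > 0))
})
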