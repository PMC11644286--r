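# Numerical gradient checks for the reverse-mode engine: each op (or a short
# composite using it) is compared against central differences.

ag <- function(f) getFromNamespace(f, "mugennet")

check_grad <- function(build, x0, tol = 1e-6) {
  leaf <- ag("ag_leaf")(x0)
  out <- build(leaf)
  ag("ag_backward")(out)
  f <- function(v) {
    x <- v
    dim(x) <- mugennet:::.dim(x0)
    as.numeric(build(ag("ag_const")(x))$val)
  }
  gn <- num_grad(f, as.vector(x0))
  expect_lt(max(abs(gn - as.vector(leaf$grad))), tol)
}

test_that("elementwise, reduction and reshape op gradients are exact", {
  set.seed(31)
  x0 <- array(rnorm(24), c(4, 6))
  check_grad(function(x) ag("ag_sum")(ag("ag_mul")(ag("ag_relu")(x), ag("ag_const")(x0 * 0 + 2))), x0)
  check_grad(function(x) ag("ag_sum")(ag("ag_sigmoid")(x)), x0)
  check_grad(function(x) ag("ag_sum")(ag("ag_gelu")(x)), x0, tol = 1e-5)
  check_grad(function(x) ag("ag_mean")(ag("ag_clamp")(x, -0.5, 0.5)), x0)
  check_grad(function(x) ag("ag_sum")(ag("ag_aperm")(ag("ag_reshape")(x, c(2, 2, 6)), c(3, 1, 2))), x0)
  x1 <- array(runif(12, 0.2, 0.9), c(3, 4))
  check_grad(function(x) ag("ag_sum")(ag("ag_log")(x)), x1, tol = 1e-5)
})

test_that("matmul, linear, softmax and layernorm gradients are exact", {
  set.seed(32)
  A <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(20), 4, 5)
  b <- rnorm(5)
  sd_arr <- matrix(rnorm(15), 3, 5)
  sm_seed <- matrix(rnorm(12), 3, 4)
  ln_seed <- matrix(rnorm(12), 3, 4)
  check_grad(function(x) ag("ag_sum")(ag("ag_cmul")(ag("ag_matmul")(x, ag("ag_const")(W)), sd_arr)), A)
  check_grad(function(x) ag("ag_sum")(ag("ag_cmul")(ag("ag_linear")(x, ag("ag_const")(W), ag("ag_const")(b)), sd_arr)), A)
  check_grad(function(x) ag("ag_sum")(ag("ag_cmul")(ag("ag_softmax_rows")(x), sm_seed)), A, tol = 1e-5)
  g <- rnorm(4); be <- rnorm(4)
  check_grad(function(x) ag("ag_sum")(ag("ag_cmul")(
    ag("ag_layernorm")(x, ag("ag_const")(g), ag("ag_const")(be)),
    ln_seed)), A, tol = 1e-5)
})

test_that("conv2d gradients (weights, bias, input) are exact", {
  set.seed(33)
  x0 <- array(rnorm(5 * 6 * 2 * 2), c(5, 6, 2, 2))
  w0 <- array(rnorm(3 * 3 * 2 * 3) * 0.4, c(3, 3, 2, 3))
  b0 <- rnorm(3) * 0.1
  sd_arr <- NULL
  build_x <- function(x) {
    y <- ag("ag_conv2d")(x, ag("ag_const")(w0), ag("ag_const")(b0), 2L, 1L)
    if (is.null(sd_arr)) sd_arr <<- array(rnorm(length(y$val)), dim(y$val))
    ag("ag_sum")(ag("ag_cmul")(y, sd_arr))
  }
  check_grad(build_x, x0, tol = 1e-5)
  # weight and bias gradients
  xl <- ag("ag_const")(x0)
  wl <- ag("ag_leaf")(w0)
  bl <- ag("ag_leaf")(b0)
  out <- ag("ag_sum")(ag("ag_cmul")(ag("ag_conv2d")(xl, wl, bl, 2L, 1L), sd_arr))
  ag("ag_backward")(out)
  fw <- function(v) as.numeric(ag("ag_sum")(ag("ag_cmul")(
    ag("ag_conv2d")(xl, ag("ag_const")(array(v, dim(w0))), bl, 2L, 1L), sd_arr))$val)
  expect_lt(max(abs(num_grad(fw, as.vector(w0)) - as.vector(wl$grad))), 1e-5)
  fb <- function(v) as.numeric(ag("ag_sum")(ag("ag_cmul")(
    ag("ag_conv2d")(xl, wl, ag("ag_const")(v), 2L, 1L), sd_arr))$val)
  expect_lt(max(abs(num_grad(fb, b0) - as.vector(bl$grad))), 1e-5)
})

test_that("batchnorm, pooling, gating and upsampling gradients are exact", {
  set.seed(34)
  x0 <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  g0 <- runif(3, 0.5, 1.5); be0 <- rnorm(3)
  bn_build <- function(x) {
    st <- new.env(); st$mean <- numeric(3); st$var <- rep(1, 3)
    ag("ag_sum")(ag("ag_cmul")(
      ag("ag_batchnorm2d")(x, ag("ag_const")(g0), ag("ag_const")(be0), st, TRUE),
      bn_seed))
  }
  bn_seed <- array(rnorm(length(x0)), dim(x0))
  check_grad(bn_build, x0, tol = 1e-5)

  mx_seed <- matrix(rnorm(6), 3, 2)
  check_grad(function(x) ag("ag_sum")(ag("ag_gavgpool")(x)), x0)
  check_grad(function(x) ag("ag_sum")(ag("ag_cmul")(ag("ag_gmaxpool")(x), mx_seed)), x0, tol = 1e-5)
  up_seed <- array(rnorm(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  check_grad(function(x) ag("ag_sum")(ag("ag_cmul")(ag("ag_up2")(x), up_seed)), x0, tol = 1e-5)

  gates0 <- matrix(runif(6, 0.2, 0.8), 3, 2)
  check_grad(function(x) ag("ag_sum")(ag("ag_chan_gate")(x, ag("ag_const")(gates0))), x0)
  alpha0 <- array(runif(4 * 4 * 2), c(4, 4, 1, 2))
  check_grad(function(x) ag("ag_sum")(ag("ag_spatial_gate")(x, ag("ag_const")(alpha0))), x0)
  # gradient wrt the gate itself
  al <- ag("ag_leaf")(alpha0)
  out <- ag("ag_sum")(ag("ag_spatial_gate")(ag("ag_const")(x0), al))
  ag("ag_backward")(out)
  fa <- function(v) as.numeric(ag("ag_sum")(ag("ag_spatial_gate")(
    ag("ag_const")(x0), ag("ag_const")(array(v, dim(alpha0)))))$val)
  expect_lt(max(abs(num_grad(fa, as.vector(alpha0)) - as.vector(al$grad))), 1e-6)
})

test_that("shared subgraphs accumulate gradients once per use", {
  # diamond: s = sum(2x + 3x) must give gradient 5 everywhere
  x <- ag("ag_leaf")(matrix(1, 2, 2))
  s <- ag("ag_sum")(ag("ag_add")(ag("ag_cmul")(x, 2), ag("ag_cmul")(x, 3)))
  ag("ag_backward")(s)
  expect_equal(x$grad, matrix(5, 2, 2))
})

test_that("bilinear up2 interpolates constants exactly and halves align", {
  x <- array(3.5, c(4, 6, 1, 1))
  y <- ag("ag_up2")(ag("ag_const")(x))$val
  expect_equal(dim(y), c(8L, 12L, 1L, 1L))
  expect_equal(max(abs(y - 3.5)), 0)
})
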