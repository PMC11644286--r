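# Tape-based reverse-mode automatic differentiation on dense numeric arrays.
#
# A node is an environment holding a value, an (initially NULL) gradient, its
# parent nodes and a backward closure that pushes the node's gradient into its
# parents. Node ids increase monotonically as the graph is built forward, so
# decreasing-id order over the reachable set is a valid reverse topological
# order. Sized for small segmentation networks: feature maps are (H, W, C, N)
# arrays, token matrices are (rows, dim).

.ag <- new.env(parent = emptyenv())
.ag$n <- 0L
.ag$cache <- new.env(parent = emptyenv())

ag_reset_ids <- function() {
  .ag$n <- 0L
  invisible(NULL)
}

ag_node <- function(val, parents = list(), bw = NULL,
                    ng = any(vapply(parents, function(p) p$ng, logical(1)))) {
  # force the promises first: evaluating `val` may itself create nodes, and
  # ids must stay consistent with the graph
  force(parents)
  force(val)
  e <- new.env(parent = emptyenv())
  .ag$n <- .ag$n + 1L
  e$id <- .ag$n
  e$val <- val
  e$grad <- NULL
  e$parents <- parents
  e$bw <- bw
  e$ng <- isTRUE(ng)
  class(e) <- "ag_node"
  e
}

ag_leaf <- function(val) ag_node(val, ng = TRUE)
ag_const <- function(val) ag_node(val, ng = FALSE)

ag_accum <- function(p, g) {
  if (p$ng) p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

# Depth-first topological order: every node appears after all its parents.
ag_topo <- function(root) {
  visited <- new.env(parent = emptyenv())
  topo <- vector("list", 256L)
  k <- 0L
  visit <- function(n) {
    key <- as.character(n$id)
    if (!is.null(visited[[key]])) return(invisible(NULL))
    visited[[key]] <- TRUE
    for (p in n$parents) if (p$ng) visit(p)
    k <<- k + 1L
    if (k > length(topo)) topo[[2L * k]] <<- NULL
    topo[[k]] <<- n
    invisible(NULL)
  }
  visit(root)
  topo[seq_len(k)]
}

# Backpropagate from a scalar (length-1) node.
ag_backward <- function(root) {
  stopifnot(length(root$val) == 1L)
  topo <- ag_topo(root)
  root$grad <- array(1, dim = dim(root$val) %||% 1L)
  for (n in rev(topo)) {
    if (!is.null(n$bw) && !is.null(n$grad)) n$bw(n)
  }
  invisible(root)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.dim <- function(x) dim(x) %||% length(x)

# ---- elementwise ops -------------------------------------------------------

ag_add <- function(a, b) {
  ag_node(a$val + b$val, list(a, b), function(n) {
    ag_accum(a, n$grad); ag_accum(b, n$grad)
  })
}

ag_sub <- function(a, b) {
  ag_node(a$val - b$val, list(a, b), function(n) {
    ag_accum(a, n$grad); ag_accum(b, -n$grad)
  })
}

ag_neg <- function(a) ag_node(-a$val, list(a), function(n) ag_accum(a, -n$grad))

ag_mul <- function(a, b) {
  ag_node(a$val * b$val, list(a, b), function(n) {
    ag_accum(a, n$grad * b$val); ag_accum(b, n$grad * a$val)
  })
}

# multiply / add by a constant (array or scalar), not tracked
ag_cmul <- function(a, k) ag_node(a$val * k, list(a), function(n) ag_accum(a, n$grad * k))
ag_cadd <- function(a, k) ag_node(a$val + k, list(a), function(n) ag_accum(a, n$grad))

ag_relu <- function(a) {
  m <- a$val > 0
  ag_node(a$val * m, list(a), function(n) ag_accum(a, n$grad * m))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  ag_node(s, list(a), function(n) ag_accum(a, n$grad * s * (1 - s)))
}

ag_gelu <- function(a) {
  x <- a$val
  ph <- stats::pnorm(x)
  ag_node(x * ph, list(a), function(n) ag_accum(a, n$grad * (ph + x * stats::dnorm(x))))
}

ag_log <- function(a) {
  ag_node(log(a$val), list(a), function(n) ag_accum(a, n$grad / a$val))
}

ag_clamp <- function(a, lo, hi) {
  inside <- a$val > lo & a$val < hi
  ag_node(pmin(pmax(a$val, lo), hi), list(a), function(n) ag_accum(a, n$grad * inside))
}

# ---- reductions ------------------------------------------------------------

ag_sum <- function(a) {
  d <- .dim(a$val)
  ag_node(array(sum(a$val), 1L), list(a), function(n) {
    ag_accum(a, array(as.numeric(n$grad), d))
  })
}

ag_mean <- function(a) {
  d <- .dim(a$val)
  k <- length(a$val)
  ag_node(array(mean(a$val), 1L), list(a), function(n) {
    ag_accum(a, array(as.numeric(n$grad) / k, d))
  })
}

# scalar / scalar division (length-1 nodes)
ag_sdiv <- function(a, b) {
  ag_node(a$val / b$val, list(a, b), function(n) {
    g <- as.numeric(n$grad)
    ag_accum(a, array(g / as.numeric(b$val), 1L))
    ag_accum(b, array(-g * as.numeric(a$val) / as.numeric(b$val)^2, 1L))
  })
}

# ---- shape ops -------------------------------------------------------------

ag_reshape <- function(a, dims) {
  d0 <- .dim(a$val)
  v <- a$val
  dim(v) <- dims
  ag_node(v, list(a), function(n) {
    g <- n$grad
    dim(g) <- d0
    ag_accum(a, g)
  })
}

ag_aperm <- function(a, perm) {
  inv <- order(perm)
  ag_node(aperm(a$val, perm), list(a), function(n) ag_accum(a, aperm(n$grad, inv)))
}

# Gather y = a[idx] (idx linear, hits each source at most once when perm=TRUE).
ag_gather <- function(a, idx, outdim, perm = TRUE) {
  v <- a$val[idx]
  dim(v) <- outdim
  d0 <- .dim(a$val)
  ag_node(v, list(a), function(n) {
    g0 <- numeric(length(a$val))
    if (perm) {
      g0[idx] <- n$grad
    } else {
      s <- rowsum(as.vector(n$grad), idx)
      g0[as.numeric(rownames(s))] <- s
    }
    dim(g0) <- d0
    ag_accum(a, g0)
  })
}

ag_rowsel <- function(a, rows) {
  v <- a$val[rows, , drop = FALSE]
  d0 <- dim(a$val)
  ag_node(v, list(a), function(n) {
    g0 <- matrix(0, d0[1], d0[2])
    g0[rows, ] <- n$grad
    ag_accum(a, g0)
  })
}

# concat along channel axis (3rd) of (H, W, C, N) arrays
ag_concat_c <- function(a, b) {
  da <- dim(a$val); db <- dim(b$val)
  stopifnot(all(da[-3] == db[-3]))
  v <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  v[, , seq_len(da[3]), ] <- a$val
  v[, , da[3] + seq_len(db[3]), ] <- b$val
  ag_node(v, list(a, b), function(n) {
    ag_accum(a, n$grad[, , seq_len(da[3]), , drop = FALSE])
    ag_accum(b, n$grad[, , da[3] + seq_len(db[3]), , drop = FALSE])
  })
}

# ---- linear algebra --------------------------------------------------------

ag_matmul <- function(a, b) {
  ag_node(a$val %*% b$val, list(a, b), function(n) {
    ag_accum(a, tcrossprod(n$grad, b$val))
    ag_accum(b, crossprod(a$val, n$grad))
  })
}

# y = x %*% W + rep(bias) for matrices x (R x Din), W (Din x Dout), b (Dout)
ag_linear <- function(x, w, b) {
  v <- x$val %*% w$val
  v <- sweep(v, 2, b$val, "+")
  ag_node(v, list(x, w, b), function(n) {
    ag_accum(x, tcrossprod(n$grad, w$val))
    ag_accum(w, crossprod(x$val, n$grad))
    ag_accum(b, colSums(n$grad))
  })
}

ag_softmax_rows <- function(a) {
  x <- a$val
  x <- x - apply(x, 1, max)
  p <- exp(x)
  p <- p / rowSums(p)
  ag_node(p, list(a), function(n) {
    g <- n$grad
    ag_accum(a, p * (g - rowSums(g * p)))
  })
}

# ---- normalisation ---------------------------------------------------------

# LayerNorm over the columns of a (rows x D) matrix.
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  m <- x$val
  mu <- rowMeans(m)
  va <- rowMeans(m * m) - mu * mu
  invstd <- 1 / sqrt(va + eps)
  xhat <- (m - mu) * invstd
  v <- sweep(xhat, 2, gamma$val, "*")
  v <- sweep(v, 2, beta$val, "+")
  ag_node(v, list(x, gamma, beta), function(n) {
    g <- n$grad
    ag_accum(gamma, colSums(g * xhat))
    ag_accum(beta, colSums(g))
    gh <- sweep(g, 2, gamma$val, "*")
    ag_accum(x, (gh - rowMeans(gh) - xhat * rowMeans(gh * xhat)) * invstd)
  })
}

# BatchNorm over (H, W, N) per channel of an (H, W, C, N) array. `state` is an
# environment with $mean / $var running statistics, updated in training mode.
ag_batchnorm2d <- function(x, gamma, beta, state, training = TRUE,
                           momentum = 0.1, eps = 1e-5) {
  d <- dim(x$val)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  m <- matrix(aperm(x$val, c(1, 2, 4, 3)), ncol = C)
  if (training) {
    mu <- colMeans(m)
    va <- colMeans(m * m) - mu * mu
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(m, 2, mu)
  xhat <- sweep(xhat, 2, invstd, "*")
  ym <- sweep(xhat, 2, gamma$val, "*")
  ym <- sweep(ym, 2, beta$val, "+")
  y <- aperm(array(ym, c(H, W, N, C)), c(1, 2, 4, 3))
  ag_node(y, list(x, gamma, beta), function(n) {
    gm <- matrix(aperm(n$grad, c(1, 2, 4, 3)), ncol = C)
    ag_accum(gamma, colSums(gm * xhat))
    ag_accum(beta, colSums(gm))
    gh <- sweep(gm, 2, gamma$val, "*")
    if (training) {
      nr <- nrow(gm)
      dx <- sweep(gh, 2, colMeans(gh)) - sweep(xhat, 2, colMeans(gh * xhat), "*")
      dx <- sweep(dx, 2, invstd, "*")
    } else {
      dx <- sweep(gh, 2, invstd, "*")
    }
    ag_accum(x, aperm(array(dx, c(H, W, N, C)), c(1, 2, 4, 3)))
  })
}

# ---- convolution -----------------------------------------------------------

conv_index <- function(H, W, C, kh, kw, stride, pad, N) {
  key <- paste("cv", H, W, C, kh, kw, stride, pad, N, sep = "_")
  hit <- .ag$cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - kh) %/% stride + 1L
  Wo <- (Wp - kw) %/% stride + 1L
  ki <- rep(seq_len(kh), times = kw * C)
  kj <- rep(rep(seq_len(kw), each = kh), times = C)
  kc <- rep(seq_len(C), each = kh * kw)
  rowoff <- ki + (kj - 1L) * Hp + (kc - 1L) * Hp * Wp
  oh <- (seq_len(Ho) - 1L) * stride
  ow <- (seq_len(Wo) - 1L) * stride
  colbase <- as.vector(outer(oh, ow * Hp, "+"))
  idx0 <- outer(rowoff, colbase, "+")
  samp <- (seq_len(N) - 1L) * (Hp * Wp * C)
  idx <- as.vector(outer(as.vector(idx0), samp, "+"))
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp,
              K = kh * kw * C)
  .ag$cache[[key]] <- out
  out
}

# x: (H, W, Cin, N); w: (kh, kw, Cin, Cout); b: (Cout)
ag_conv2d <- function(x, w, b, stride = 1L, pad = 1L) {
  d <- dim(x$val)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  dw <- dim(w$val)
  kh <- dw[1]; kw <- dw[2]; Cout <- dw[4]
  stopifnot(dw[3] == C)
  ci <- conv_index(H, W, C, kh, kw, as.integer(stride), as.integer(pad), N)
  if (pad > 0L) {
    xp <- array(0, c(ci$Hp, ci$Wp, C, N))
    xp[pad + seq_len(H), pad + seq_len(W), , ] <- x$val
  } else {
    xp <- x$val
  }
  cols <- matrix(xp[ci$idx], nrow = ci$K)
  Wm <- matrix(w$val, nrow = ci$K)
  out <- crossprod(Wm, cols) + b$val
  y <- aperm(array(out, c(Cout, ci$Ho, ci$Wo, N)), c(2, 3, 1, 4))
  ag_node(y, list(x, w, b), function(n) {
    gm <- matrix(aperm(n$grad, c(3, 1, 2, 4)), nrow = Cout)
    ag_accum(w, array(tcrossprod(cols, gm), dim(w$val)))
    ag_accum(b, rowSums(gm))
    if (x$ng) {
      gcols <- Wm %*% gm
      s <- rowsum(as.vector(gcols), ci$idx)
      gxp <- numeric(ci$Hp * ci$Wp * C * N)
      gxp[as.numeric(rownames(s))] <- s
      dim(gxp) <- c(ci$Hp, ci$Wp, C, N)
      gx <- if (pad > 0L) {
        gxp[pad + seq_len(H), pad + seq_len(W), , , drop = FALSE]
      } else gxp
      ag_accum(x, gx)
    }
  })
}

# ---- interpolation ---------------------------------------------------------

# Bilinear interpolation matrix (half-pixel centers, edge-clamped).
resize_matrix <- function(n_in, n_out) {
  key <- paste("rz", n_in, n_out, sep = "_")
  hit <- .ag$cache[[key]]
  if (!is.null(hit)) return(hit)
  U <- matrix(0, n_out, n_in)
  sc <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * sc + 0.5
    lo <- floor(src)
    f <- src - lo
    lo1 <- min(max(lo, 1), n_in)
    hi1 <- min(max(lo + 1, 1), n_in)
    U[i, lo1] <- U[i, lo1] + (1 - f)
    U[i, hi1] <- U[i, hi1] + f
  }
  .ag$cache[[key]] <- U
  U
}

# numeric bilinear resize of an (H, W, C, N) array (also used by image IO)
bilinear_resize <- function(x, Hout, Wout) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Uh <- resize_matrix(H, Hout)
  Uw <- resize_matrix(W, Wout)
  B <- Uh %*% matrix(x, H)
  B <- aperm(array(B, c(Hout, W, C, N)), c(2, 1, 3, 4))
  Cm <- Uw %*% matrix(B, W)
  aperm(array(Cm, c(Wout, Hout, C, N)), c(2, 1, 3, 4))
}

ag_bilinear <- function(x, Hout, Wout) {
  d <- dim(x$val)
  H <- d[1]; W <- d[2]
  Uh <- resize_matrix(H, Hout)
  Uw <- resize_matrix(W, Wout)
  ag_node(bilinear_resize(x$val, Hout, Wout), list(x), function(n) {
    g <- n$grad
    C <- d[3]; N <- d[4]
    B <- t(Uh) %*% matrix(g, Hout)
    B <- aperm(array(B, c(H, Wout, C, N)), c(2, 1, 3, 4))
    Cm <- t(Uw) %*% matrix(B, Wout)
    ag_accum(x, aperm(array(Cm, c(W, H, C, N)), c(2, 1, 3, 4)))
  })
}

ag_up2 <- function(x) {
  d <- dim(x$val)
  ag_bilinear(x, 2L * d[1], 2L * d[2])
}

# ---- pooling and gating ----------------------------------------------------

# global max over (H, W): (H, W, C, N) -> (C, N)
ag_gmaxpool <- function(x) {
  d <- dim(x$val)
  HW <- d[1] * d[2]
  mm <- matrix(x$val, HW)
  am <- max.col(t(mm), ties.method = "first")
  v <- matrix(mm[cbind(am, seq_len(ncol(mm)))], d[3], d[4])
  ag_node(v, list(x), function(n) {
    g0 <- matrix(0, HW, ncol(mm))
    g0[cbind(am, seq_len(ncol(mm)))] <- as.vector(n$grad)
    dim(g0) <- d
    ag_accum(x, g0)
  })
}

# global mean over (H, W): (H, W, C, N) -> (C, N)
ag_gavgpool <- function(x) {
  d <- dim(x$val)
  HW <- d[1] * d[2]
  v <- matrix(colMeans(matrix(x$val, HW)), d[3], d[4])
  ag_node(v, list(x), function(n) {
    g0 <- matrix(rep(as.vector(n$grad) / HW, each = HW), HW)
    dim(g0) <- d
    ag_accum(x, g0)
  })
}

bc_channel <- function(gates, H, W, C, N) {
  aperm(array(gates, c(C, N, H, W)), c(3, 4, 1, 2))
}

# per-channel gates (C, N) applied to (H, W, C, N)
ag_chan_gate <- function(x, gates) {
  d <- dim(x$val)
  G <- bc_channel(gates$val, d[1], d[2], d[3], d[4])
  ag_node(x$val * G, list(x, gates), function(n) {
    ag_accum(x, n$grad * G)
    gg <- colSums(matrix(n$grad * x$val, d[1] * d[2]))
    ag_accum(gates, matrix(gg, d[3], d[4]))
  })
}

# one-channel spatial gate (H, W, 1, N) applied over all channels of (H, W, C, N)
ag_spatial_gate <- function(x, alpha) {
  d <- dim(x$val)
  a3 <- array(alpha$val, c(d[1], d[2], d[4]))
  A <- aperm(array(a3, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  ag_node(x$val * A, list(x, alpha), function(n) {
    ag_accum(x, n$grad * A)
    ga <- apply(n$grad * x$val, c(1, 2, 4), sum)
    dim(ga) <- dim(alpha$val)
    ag_accum(alpha, ga)
  })
}

# ---- matrix block ops (transformer) ----------------------------------------

ag_colsel <- function(a, cols) {
  v <- a$val[, cols, drop = FALSE]
  d0 <- dim(a$val)
  ag_node(v, list(a), function(n) {
    g0 <- matrix(0, d0[1], d0[2])
    g0[, cols] <- n$grad
    ag_accum(a, g0)
  })
}

ag_t2 <- function(a) ag_node(t(a$val), list(a), function(n) ag_accum(a, t(n$grad)))

ag_cbind <- function(xs) {
  widths <- vapply(xs, function(x) ncol(x$val), integer(1))
  v <- do.call(cbind, lapply(xs, function(x) x$val))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(v, xs, function(n) {
    for (i in seq_along(xs)) {
      ag_accum(xs[[i]], n$grad[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ag_rbind <- function(xs) {
  heights <- vapply(xs, function(x) nrow(x$val), integer(1))
  v <- do.call(rbind, lapply(xs, function(x) x$val))
  ends <- cumsum(heights)
  starts <- c(1L, head(ends, -1L) + 1L)
  ag_node(v, xs, function(n) {
    for (i in seq_along(xs)) {
      ag_accum(xs[[i]], n$grad[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

# add a (T x E) position code to a (T*N x E) stacked token matrix
ag_posadd <- function(x, pos, n_samples) {
  Tn <- nrow(pos$val)
  v <- x$val + pos$val[rep(seq_len(Tn), times = n_samples), , drop = FALSE]
  ag_node(v, list(x, pos), function(n) {
    ag_accum(x, n$grad)
    ag_accum(pos, rowsum(n$grad, rep(seq_len(Tn), times = n_samples)))
  })
}

# leaky ReLU (used in the SE/CA bottlenecks so channel gates cannot die)
ag_leakyrelu <- function(a, slope = 0.01) {
  m <- ifelse(a$val > 0, 1, slope)
  ag_node(a$val * m, list(a), function(n) ag_accum(a, n$grad * m))
}
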