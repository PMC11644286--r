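# Branch encoders: a ViT-style transformer branch and a residual CNN branch,
# each emitting a three-level feature pyramid at 1/16, 1/8 and 1/4 of the
# input resolution with matching channel dims.

forward_ctx <- function(model, training = FALSE, trainable = training) {
  wrap <- if (trainable) ag_leaf else ag_const
  list(P = lapply(model$params, wrap), bn = model$bn,
       cfg = model$config, training = training)
}

conv_bn <- function(ctx, name, x, stride = 1L, act = TRUE) {
  w <- ctx$P[[paste0(name, ".w")]]
  pad <- (dim(w$val)[1] - 1L) %/% 2L
  y <- ag_conv2d(x, w, ctx$P[[paste0(name, ".b")]], stride, pad)
  if (!is.null(ctx$bn[[name]])) {
    y <- ag_batchnorm2d(y, ctx$P[[paste0(name, ".g")]],
                        ctx$P[[paste0(name, ".bb")]],
                        ctx$bn[[name]], ctx$training)
  }
  if (act) y <- ag_relu(y)
  y
}

as_image_batch <- function(x, check_div = 16L) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  d <- dim(x)
  if (!is.null(check_div) && (d[1] %% check_div != 0L || d[2] %% check_div != 0L)) {
    stop(sprintf("image size %dx%d not divisible by %d", d[1], d[2], check_div))
  }
  x
}

# ---- patch embedding -------------------------------------------------------

patch_index <- function(H, W, C, N, P) {
  key <- paste("px", H, W, C, N, P, sep = "_")
  hit <- .ag$cache[[key]]
  if (!is.null(hit)) return(hit)
  Gh <- H %/% P; Gw <- W %/% P
  Tn <- Gh * Gw
  i <- rep(seq_len(P), times = P * C)
  j <- rep(rep(seq_len(P), each = P), times = C)
  cc <- rep(seq_len(C), each = P * P)
  colvec <- i + (j - 1L) * H + (cc - 1L) * H * W
  tt <- seq_len(Tn)
  gh <- (tt - 1L) %% Gh + 1L
  gw <- (tt - 1L) %/% Gh + 1L
  rowoff <- (gh - 1L) * P + (gw - 1L) * P * H
  sampoff <- (seq_len(N) - 1L) * H * W * C
  allrows <- rep(rowoff, times = N) + rep(sampoff, each = Tn)
  idx <- outer(allrows, colvec, "+")
  out <- list(idx = idx, Tn = Tn, Gh = Gh, Gw = Gw)
  .ag$cache[[key]] <- out
  out
}

#' Split an image batch into flattened patches
#'
#' Rearranges an (H, W, C) image or (H, W, C, N) batch into the `N = HW/P^2`
#' per-image patch vectors that feed the transformer branch (the learned
#' linear projection and position codes are applied inside
#' [transformer_encode()]). Patches are ordered column-major over the patch
#' grid; each row of `tokens` is one flattened P x P x C patch.
#'
#' @param x numeric image array, values in a normalized range.
#' @param patch patch side length P; H and W must be divisible by it.
#' @return list with `tokens` (T*N x P^2*C matrix), `n_patches` (T per
#'   image), and `grid` c(Gh, Gw).
#' @export
patchify <- function(x, patch = 16L) {
  x <- as_image_batch(x, check_div = NULL)
  d <- dim(x)
  if (d[1] %% patch != 0L || d[2] %% patch != 0L) {
    stop(sprintf("image size %dx%d not divisible by patch size %d",
                 d[1], d[2], patch))
  }
  pi <- patch_index(d[1], d[2], d[3], d[4], as.integer(patch))
  tokens <- matrix(x[pi$idx], nrow = pi$Tn * d[4])
  list(tokens = tokens, n_patches = pi$Tn, grid = c(pi$Gh, pi$Gw))
}

#' Multi-head scaled dot-product self-attention
#'
#' Computes `softmax(q k^T / sqrt(D_h)) v` per head and concatenates head
#' outputs. Inputs are already-projected token matrices; head slices are
#' taken over columns.
#'
#' @param q,k,v (T x E) matrices with E divisible by `n_heads`.
#' @param n_heads number of attention heads.
#' @return (T x E) output matrix.
#' @export
msa <- function(q, k, v, n_heads = 1L) {
  E <- ncol(q)
  stopifnot(ncol(k) == E, ncol(v) == E, nrow(k) == nrow(q), nrow(v) == nrow(q))
  if (E %% n_heads != 0L) stop("embedding dim not divisible by head count")
  Dh <- E %/% n_heads
  if (Dh <= 0) stop("per-head dimension must be positive")
  out <- matrix(0, nrow(q), E)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * Dh + seq_len(Dh)
    s <- tcrossprod(q[, cols, drop = FALSE], k[, cols, drop = FALSE]) / sqrt(Dh)
    s <- s - apply(s, 1, max)
    a <- exp(s)
    a <- a / rowSums(a)
    out[, cols] <- a %*% v[, cols, drop = FALSE]
  }
  out
}

fw_msa <- function(ctx, pre, X, Tn, N) {
  P <- ctx$P
  E <- ncol(X$val)
  h <- ctx$cfg$n_heads
  Dh <- E %/% h
  Q <- ag_linear(X, P[[paste0(pre, "q.w")]], P[[paste0(pre, "q.b")]])
  K <- ag_linear(X, P[[paste0(pre, "k.w")]], P[[paste0(pre, "k.b")]])
  V <- ag_linear(X, P[[paste0(pre, "v.w")]], P[[paste0(pre, "v.b")]])
  outs <- vector("list", N)
  for (n in seq_len(N)) {
    rows <- (n - 1L) * Tn + seq_len(Tn)
    qn <- ag_rowsel(Q, rows)
    kn <- ag_rowsel(K, rows)
    vn <- ag_rowsel(V, rows)
    hs <- vector("list", h)
    for (j in seq_len(h)) {
      cols <- (j - 1L) * Dh + seq_len(Dh)
      qh <- ag_colsel(qn, cols)
      kh <- ag_colsel(kn, cols)
      vh <- ag_colsel(vn, cols)
      A <- ag_softmax_rows(ag_cmul(ag_matmul(qh, ag_t2(kh)), 1 / sqrt(Dh)))
      hs[[j]] <- ag_matmul(A, vh)
    }
    outs[[n]] <- ag_cbind(hs)
  }
  O <- if (N == 1L) outs[[1L]] else ag_rbind(outs)
  ag_linear(O, P[[paste0(pre, "o.w")]], P[[paste0(pre, "o.b")]])
}

fw_transformer_block <- function(ctx, l, X, Tn, N) {
  P <- ctx$P
  pre <- paste0("tr.l", l, ".")
  h1 <- ag_layernorm(X, P[[paste0(pre, "ln1.g")]], P[[paste0(pre, "ln1.bb")]])
  X <- ag_add(X, fw_msa(ctx, pre, h1, Tn, N))
  h2 <- ag_layernorm(X, P[[paste0(pre, "ln2.g")]], P[[paste0(pre, "ln2.bb")]])
  m <- ag_gelu(ag_linear(h2, P[[paste0(pre, "m1.w")]], P[[paste0(pre, "m1.b")]]))
  m <- ag_linear(m, P[[paste0(pre, "m2.w")]], P[[paste0(pre, "m2.b")]])
  ag_add(X, m)
}

fw_transformer <- function(ctx, x) {
  cfg <- ctx$cfg
  P <- ctx$P
  d <- dim(x$val)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Pp <- cfg$patch
  pi <- patch_index(H, W, C, N, Pp)
  Tn <- pi$Tn
  if (nrow(P[["tr.pos"]]$val) != Tn) {
    stop(sprintf("input %dx%d yields %d patches but the model was built for %d",
                 H, W, Tn, nrow(P[["tr.pos"]]$val)))
  }
  X <- ag_gather(x, as.vector(pi$idx), c(Tn * N, Pp * Pp * C))
  X <- ag_linear(X, P[["tr.patch.w"]], P[["tr.patch.b"]])
  X <- ag_posadd(X, P[["tr.pos"]], N)
  for (l in seq_len(cfg$depth)) X <- fw_transformer_block(ctx, l, X, Tn, N)
  X <- ag_layernorm(X, P[["tr.lnf.g"]], P[["tr.lnf.bb"]])
  # tokens -> (Gh, Gw, E, N) grid
  E <- cfg$embed_dim
  gidx <- grid_index(Tn, E, N, pi$Gh, pi$Gw)
  G <- ag_gather(X, gidx, c(pi$Gh, pi$Gw, E, N))
  t0 <- conv_bn(ctx, "tr.proj0", G)
  t1 <- conv_bn(ctx, "tr.up1", ag_up2(t0))
  t2 <- conv_bn(ctx, "tr.up2", ag_up2(t1))
  list(t0, t1, t2)
}

grid_index <- function(Tn, E, N, Gh, Gw) {
  key <- paste("gx", Tn, E, N, Gh, Gw, sep = "_")
  hit <- .ag$cache[[key]]
  if (!is.null(hit)) return(hit)
  # target (gh, gw, e, n) <- X[(n-1)*Tn + (gh + (gw-1)*Gh), e]; X is (Tn*N x E)
  gh <- rep(seq_len(Gh), times = Gw * E * N)
  gw <- rep(rep(seq_len(Gw), each = Gh), times = E * N)
  e <- rep(rep(seq_len(E), each = Gh * Gw), times = N)
  n <- rep(seq_len(N), each = Gh * Gw * E)
  r <- (n - 1L) * Tn + gh + (gw - 1L) * Gh
  idx <- r + (e - 1L) * (Tn * N)
  .ag$cache[[key]] <- idx
  idx
}

# ---- CNN branch ------------------------------------------------------------

fw_basic_block <- function(ctx, name, x, stride) {
  y <- conv_bn(ctx, paste0(name, ".c1"), x, stride = stride)
  y <- conv_bn(ctx, paste0(name, ".c2"), y, act = FALSE)
  sc <- if (!is.null(ctx$P[[paste0(name, ".down.w")]])) {
    conv_bn(ctx, paste0(name, ".down"), x, stride = stride, act = FALSE)
  } else {
    x
  }
  ag_relu(ag_add(y, sc))
}

fw_cnn <- function(ctx, x) {
  cfg <- ctx$cfg
  s <- conv_bn(ctx, "cnn.stem", x, stride = 2L)          # 1/2
  feats <- vector("list", 3)
  h <- s
  for (st in 1:3) {
    for (bl in seq_len(cfg$cnn_blocks[st])) {
      h <- fw_basic_block(ctx, paste0("cnn.s", st, ".b", bl), h,
                          stride = if (bl == 1L) 2L else 1L)
    }
    feats[[st]] <- h                                     # 1/4, 1/8, 1/16
  }
  r0 <- conv_bn(ctx, "cnn.proj0", feats[[3]])
  u1 <- ag_up2(r0)
  if (cfg$skip_fusion) u1 <- ag_concat_c(u1, feats[[2]])
  r1 <- conv_bn(ctx, "cnn.up1", u1)
  u2 <- ag_up2(r1)
  if (cfg$skip_fusion) u2 <- ag_concat_c(u2, feats[[1]])
  r2 <- conv_bn(ctx, "cnn.up2", u2)
  list(r0, r1, r2)
}

# ---- numeric wrappers ------------------------------------------------------

#' Run the transformer branch
#'
#' Patch-embeds the batch, applies the pre-norm transformer blocks and two
#' upsample+conv stages, returning the three-level feature pyramid (scales
#' 1/16, 1/8, 1/4 of the input; channels per the model's `dims`).
#'
#' @param model a `mugen_model` built with a transformer branch.
#' @param x image array (H, W, C) or batch (H, W, C, N), H and W divisible
#'   by 16 and matching the model's configured input size.
#' @return list of three arrays `t0`, `t1`, `t2`.
#' @export
transformer_encode <- function(model, x) {
  if (!has_tb(model$config)) stop("this model was built without a transformer branch")
  x <- as_image_batch(x)
  ctx <- forward_ctx(model, training = FALSE)
  py <- fw_transformer(ctx, ag_const(x))
  list(t0 = py[[1]]$val, t1 = py[[2]]$val, t2 = py[[3]]$val)
}

#' Run the CNN branch
#'
#' Residual-convolution encoder downsampling to 1/16 scale followed by two
#' bilinear upsample + conv stages (optionally fused with encoder skips),
#' emitting a pyramid shaped exactly like [transformer_encode()].
#'
#' @inheritParams transformer_encode
#' @param model a `mugen_model`.
#' @return list of three arrays `r0`, `r1`, `r2`.
#' @export
cnn_encode <- function(model, x) {
  x <- as_image_batch(x)
  ctx <- forward_ctx(model, training = FALSE)
  py <- fw_cnn(ctx, ag_const(x))
  list(r0 = py[[1]]$val, r1 = py[[2]]$val, r2 = py[[3]]$val)
}
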