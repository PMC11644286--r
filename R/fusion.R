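# Mugen fusion (SE on the transformer features, max-pool-only channel
# attention on the CNN features, residual combination), additive attention
# gates, and the progressive decoder.

fw_se <- function(ctx, pre, x) {
  P <- ctx$P
  s <- ag_gavgpool(x)                                   # (C, N)
  h <- ag_leakyrelu(ag_linear(ag_t2(s), P[[paste0(pre, "se1.w")]],
                              P[[paste0(pre, "se1.b")]]))
  g <- ag_sigmoid(ag_linear(h, P[[paste0(pre, "se2.w")]],
                            P[[paste0(pre, "se2.b")]]))
  list(out = ag_chan_gate(x, ag_t2(g)), gates = g)
}

fw_ca <- function(ctx, pre, x) {
  P <- ctx$P
  s <- ag_gmaxpool(x)                                   # max-pool only
  h <- ag_leakyrelu(ag_linear(ag_t2(s), P[[paste0(pre, "ca1.w")]],
                              P[[paste0(pre, "ca1.b")]]))
  g <- ag_sigmoid(ag_linear(h, P[[paste0(pre, "ca2.w")]],
                            P[[paste0(pre, "ca2.b")]]))
  list(out = ag_chan_gate(x, ag_t2(g)), gates = g)
}

# one fusion level; t may be NULL for CNN-only ablations
fw_fuse <- function(ctx, level, t, r) {
  cfg <- ctx$cfg
  pre <- paste0("fuse", level, ".")
  th <- if (!is.null(t) && has_se(cfg)) fw_se(ctx, pre, t)$out else t
  rh <- if (has_ca(cfg)) fw_ca(ctx, pre, r)$out else r
  if (!is.null(t)) {
    att_in <- ag_concat_c(th, rh)
    raw_in <- ag_concat_c(t, r)
  } else {
    att_in <- rh
    raw_in <- r
  }
  a <- conv_bn(ctx, paste0(pre, "proj"), att_in)
  s <- ag_conv2d(raw_in, ctx$P[[paste0(pre, "skip.w")]],
                 ctx$P[[paste0(pre, "skip.b")]], 1L, 0L)
  ag_add(a, s)
}

fw_ag <- function(ctx, name, g, x) {
  dg <- dim(g$val); dx <- dim(x$val)
  if (all(2L * dg[1:2] == dx[1:2])) {
    g <- ag_up2(g)
  } else if (!all(dg[1:2] == dx[1:2])) {
    stop(sprintf("attention gate scale mismatch: gate %dx%d vs input %dx%d",
                 dg[1], dg[2], dx[1], dx[2]))
  }
  P <- ctx$P
  q <- ag_relu(ag_add(
    ag_conv2d(g, P[[paste0(name, ".wg.w")]], P[[paste0(name, ".wg.b")]], 1L, 0L),
    ag_conv2d(x, P[[paste0(name, ".wx.w")]], P[[paste0(name, ".wx.b")]], 1L, 0L)))
  alpha <- ag_sigmoid(ag_conv2d(q, P[[paste0(name, ".psi.w")]],
                                P[[paste0(name, ".psi.b")]], 1L, 0L))
  list(out = ag_spatial_gate(x, alpha), alpha = alpha)
}

fw_decode <- function(ctx, y1, y2, y3) {
  d1 <- dim(y1$val); d2 <- dim(y2$val); d3 <- dim(y3$val)
  if (!all(2L * d1[1:2] == d2[1:2]) || !all(2L * d2[1:2] == d3[1:2])) {
    stop("decoder expects fused maps on a 1/16, 1/8, 1/4 scale ladder")
  }
  z1 <- conv_bn(ctx, "dec.up1", ag_up2(y1))             # 1/8
  a2 <- fw_ag(ctx, "dec.ag2", z1, y2)
  z2 <- conv_bn(ctx, "dec.up2", ag_up2(a2$out))         # 1/4
  a3 <- fw_ag(ctx, "dec.ag3", z2, y3)
  z3 <- conv_bn(ctx, "dec.up3", ag_up2(a3$out))         # 1/2
  zl <- ag_conv2d(ag_up2(z3), ctx$P[["head.z.w"]],
                  ctx$P[["head.z.b"]], 1L, 0L)          # full, 1 channel
  list(z1 = z1, z2 = z2, z3 = z3, zlogit = zl, zout = ag_sigmoid(zl),
       alpha2 = a2$alpha, alpha3 = a3$alpha)
}

head_logits <- function(ctx, name, feat) {
  h <- ag_conv2d(feat, ctx$P[[paste0(name, ".w")]],
                 ctx$P[[paste0(name, ".b")]], 1L, 0L)
  ag_up2(ag_up2(h))                                     # 1/4 -> full
}

fw_full <- function(ctx, x) {
  cfg <- ctx$cfg
  rr <- fw_cnn(ctx, x)
  tt <- if (has_tb(cfg)) fw_transformer(ctx, x) else list(NULL, NULL, NULL)
  ys <- lapply(1:3, function(i) fw_fuse(ctx, i, tt[[i]], rr[[i]]))
  dec <- fw_decode(ctx, ys[[1]], ys[[2]], ys[[3]])
  sr_l <- head_logits(ctx, "head.r", rr[[3]])
  st_l <- if (has_tb(cfg)) head_logits(ctx, "head.t", tt[[3]]) else NULL
  list(zout = dec$zout, zlogit = dec$zlogit,
       st = if (!is.null(st_l)) ag_sigmoid(st_l) else NULL, st_logit = st_l,
       sr = ag_sigmoid(sr_l), sr_logit = sr_l,
       dec = dec, pyr_t = tt, pyr_r = rr, ys = ys)
}

# ---- numeric wrappers ------------------------------------------------------

fusion_prefix <- function(level) {
  stopifnot(level %in% 1:3)
  paste0("fuse", level, ".")
}

#' Squeeze-and-excitation channel attention
#'
#' Global average squeeze, two-layer bottleneck (C/r then C) and sigmoid
#' channel gates, applied to the transformer-branch feature map of the given
#' fusion level.
#'
#' @param model a `mugen_model` with SE fusion (complete ablation).
#' @param level fusion level 1..3 (scales 1/16, 1/8, 1/4).
#' @param x feature array (H, W, C, N) with C equal to the level's dim.
#' @return list with `out` (gated features, same shape) and `gates`
#'   ((N, C) matrix of values strictly in (0,1)).
#' @export
se_attention <- function(model, level, x) {
  if (!has_se(model$config)) stop("model has no SE fusion (ablation without it)")
  ctx <- forward_ctx(model)
  z <- fw_se(ctx, fusion_prefix(level), ag_const(x))
  list(out = z$out$val, gates = z$gates$val)
}

#' Max-pool-only channel attention
#'
#' Like SE but the squeeze is a global max-pool (no average pooling), which
#' emphasizes pixel-level edge evidence; applied to the CNN-branch feature
#' map of the given fusion level.
#'
#' @inheritParams se_attention
#' @return list with `out` and `gates` as in [se_attention()].
#' @export
channel_attention <- function(model, level, x) {
  if (!has_ca(model$config)) stop("model has no channel-attention gate (ablation without it)")
  ctx <- forward_ctx(model)
  z <- fw_ca(ctx, fusion_prefix(level), ag_const(x))
  list(out = z$out$val, gates = z$gates$val)
}

#' Fuse a transformer / CNN feature pair
#'
#' Applies SE attention to the transformer features and max-pool channel
#' attention to the CNN features (per the model's ablation), projects the
#' concatenated attended maps with a conv+BN+ReLU, and adds a 1x1 residual
#' projection of the raw concatenation. Zeroing the learned projection
#' reduces the output to the residual path exactly.
#'
#' @inheritParams se_attention
#' @param t transformer feature array (NULL for CNN-only ablations).
#' @param r CNN feature array of the same shape.
#' @return fused feature array with the level's channel count.
#' @export
mugen_fuse <- function(model, level, t, r) {
  if (!is.null(t) && !all(dim(t) == dim(r))) {
    stop(sprintf("fusion shape mismatch: t %s vs r %s",
                 paste(dim(t), collapse = "x"), paste(dim(r), collapse = "x")))
  }
  if (is.null(t) && has_tb(model$config)) {
    stop("this model fuses two branches; supply the transformer features")
  }
  ctx <- forward_ctx(model)
  tn <- if (is.null(t)) NULL else ag_const(t)
  fw_fuse(ctx, level, tn, ag_const(r))$val
}

#' Additive attention gate
#'
#' Computes per-pixel attention coefficients
#' `alpha = sigmoid(psi(relu(Wg g + Wx x)))` from a coarse gating map `g`
#' (upsampled x2 internally when it is one scale coarser than `x`) and gates
#' the finer map: `out = alpha * x`.
#'
#' @param model a `mugen_model`.
#' @param stage decoder stage, 2 or 3.
#' @param g gating feature array; same spatial size as `x` or exactly half.
#' @param x finer feature array to be gated.
#' @return list with `out` (gated map, shape of `x`) and `alpha`
#'   (H, W, 1, N) coefficients strictly in (0,1).
#' @export
attention_gate <- function(model, stage, g, x) {
  stopifnot(stage %in% c(2L, 3L))
  ctx <- forward_ctx(model)
  z <- fw_ag(ctx, paste0("dec.ag", stage), ag_const(g), ag_const(x))
  list(out = z$out$val, alpha = z$alpha$val)
}

#' Decode fused pyramid maps to a full-resolution probability map
#'
#' Progressive attention-gated decoding: `z1 = upconv(y1)` (1/8), `z2 =
#' upconv(AG(z1, y2))` (1/4), `z3 = upconv(AG(z2, y3))` (1/2), and the final
#' sigmoid head at full resolution.
#'
#' @param model a `mugen_model`.
#' @param y1,y2,y3 fused feature arrays at 1/16, 1/8, 1/4 scale.
#' @return list with arrays `z1`, `z2`, `z3`, `zout` (H, W, 1, N in
#'   \[0,1\]) and the gate coefficient maps `alpha2`, `alpha3`.
#' @export
mugen_decode <- function(model, y1, y2, y3) {
  ctx <- forward_ctx(model)
  z <- fw_decode(ctx, ag_const(y1), ag_const(y2), ag_const(y3))
  list(z1 = z$z1$val, z2 = z$z2$val, z3 = z$z3$val, zout = z$zout$val,
       alpha2 = z$alpha2$val, alpha3 = z$alpha3$val)
}

#' Full forward pass
#'
#' Runs both branch encoders, the three fusion levels and the decoder.
#' Besides the final map `zout`, two deep-supervision side maps are
#' produced: `st` (1-channel head on the finest transformer map, absent in
#' CNN-only ablations) and `sr` (same on the CNN map), both upsampled to
#' full resolution and passed through a sigmoid; `sz` is `zout`.
#'
#' @param model a `mugen_model`.
#' @param x image array (H, W, C) or batch (H, W, C, N) at the model's
#'   input size.
#' @return list with `zout`, `st` (or NULL), `sr`, `sz` probability arrays
#'   (H, W, 1, N), plus `pyramid_t`, `pyramid_r` and decoder internals.
#' @export
mugen_forward <- function(model, x) {
  x <- as_image_batch(x)
  ctx <- forward_ctx(model)
  o <- fw_full(ctx, ag_const(x))
  list(zout = o$zout$val,
       st = if (!is.null(o$st)) o$st$val else NULL,
       sr = o$sr$val,
       sz = o$zout$val,
       pyramid_t = lapply(o$pyr_t, function(n) if (is.null(n)) NULL else n$val),
       pyramid_r = lapply(o$pyr_r, function(n) n$val),
       z1 = o$dec$z1$val, z2 = o$dec$z2$val, z3 = o$dec$z3$val,
       alpha2 = o$dec$alpha2$val, alpha3 = o$dec$alpha3$val)
}
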