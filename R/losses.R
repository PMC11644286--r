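#' Loss configuration
#'
#' The training loss per supervised output is `L = L_IoUw + n * L_BCEw`, a
#' boundary-weighted soft IoU term plus `n` times the boundary-weighted
#' binary cross-entropy, with `n = 6/5` so pixel-level constraints carry
#' slightly more weight than the global overlap term. The total loss over
#' the three supervised outputs is `alpha*L(G,S_t) + beta*L(G,S_r) +
#' gamma*L(G,S_z)` with unit weights by default.
#'
#' @param n IoU/BCE mixing hyperparameter (default 6/5).
#' @param alpha,beta,gamma per-output weights of the total loss.
#' @param weight_kernel odd window size of the boundary weight map.
#' @param weight_gain amplification of the boundary weighting.
#' @param eps numerical floor.
#' @return list of class `loss_config`.
#' @export
loss_config <- function(n = 6 / 5, alpha = 1, beta = 1, gamma = 1,
                        weight_kernel = 31L, weight_gain = 5, eps = 1e-8) {
  stopifnot(n >= 0, alpha >= 0, beta >= 0, gamma >= 0,
            weight_kernel >= 3, weight_kernel %% 2 == 1, weight_gain >= 0)
  structure(list(n = n, alpha = alpha, beta = beta, gamma = gamma,
                 weight_kernel = as.integer(weight_kernel),
                 weight_gain = weight_gain, eps = eps),
            class = "loss_config")
}

# box mean over a k x k window, averaging only over in-image pixels so that
# locally constant masks give a mean exactly equal to the mask value
box_mean_valid <- function(g, k) {
  H <- nrow(g); W <- ncol(g)
  pad <- (k - 1L) %/% 2L
  Pm <- matrix(0, H + 1L, W + 1L)
  Pm[-1L, -1L] <- t(apply(apply(g, 2, cumsum), 1, cumsum))
  r1 <- pmax(1L, seq_len(H) - pad); r2 <- pmin(H, seq_len(H) + pad)
  c1 <- pmax(1L, seq_len(W) - pad); c2 <- pmin(W, seq_len(W) + pad)
  sums <- Pm[r2 + 1L, c2 + 1L, drop = FALSE] - Pm[r1, c2 + 1L, drop = FALSE] -
    Pm[r2 + 1L, c1, drop = FALSE] + Pm[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts
}

#' Boundary weight map
#'
#' `w = 1 + gain * |mean_window(G) - G|`: 1 wherever the ground truth is
#' locally constant over the window, rising toward `1 + gain` next to mask
#' boundaries, so that hard boundary pixels dominate the weighted losses.
#'
#' @param gt binary matrix.
#' @param cfg a [loss_config()] providing window size and gain.
#' @return numeric matrix with minimum 1.
#' @export
boundary_weight_map <- function(gt, cfg = loss_config()) {
  gt <- as.matrix(gt)
  if (!all(gt %in% c(0, 1))) stop("ground truth must be binary")
  1 + cfg$weight_gain * abs(box_mean_valid(gt, cfg$weight_kernel) - gt)
}

check_loss_inputs <- function(pred, gt, w = NULL) {
  pred <- as.matrix(pred); gt <- as.matrix(gt)
  if (!all(dim(pred) == dim(gt))) {
    stop(sprintf("resolution mismatch: prediction %dx%d vs ground truth %dx%d (up-sample the prediction first)",
                 nrow(pred), ncol(pred), nrow(gt), ncol(gt)))
  }
  if (any(pred < 0) || any(pred > 1)) stop("predictions must lie in [0, 1]")
  if (!all(gt %in% c(0, 1))) stop("ground truth must be binary")
  if (!is.null(w) && !all(dim(as.matrix(w)) == dim(gt))) {
    stop("weight map shape must match the ground truth")
  }
  list(pred = pred, gt = gt, w = if (is.null(w)) NULL else as.matrix(w))
}

#' Weighted binary cross-entropy
#'
#' `sum(w * [-g log p - (1-g) log(1-p)]) / sum(w)`; normalizing by the total
#' weight makes the weighting scale-free (a constant weight map gives
#' exactly the unweighted BCE).
#'
#' @param pred probability matrix in \[0,1\].
#' @param gt binary matrix.
#' @param w weight map (e.g. from [boundary_weight_map()]).
#' @param cfg a [loss_config()].
#' @return scalar loss.
#' @export
weighted_bce <- function(pred, gt, w, cfg = loss_config()) {
  z <- check_loss_inputs(pred, gt, w)
  p <- pmin(pmax(z$pred, cfg$eps), 1 - cfg$eps)
  sum(z$w * (-z$gt * log(p) - (1 - z$gt) * log(1 - p))) / sum(z$w)
}

#' Weighted soft IoU loss
#'
#' `1 - sum(w p g) / sum(w (p + g - p g))`, the differentiable weighted IoU;
#' eps-guarded so an empty ground truth with an all-zero prediction scores 0.
#'
#' @inheritParams weighted_bce
#' @return scalar loss in \[0,1\].
#' @export
weighted_iou <- function(pred, gt, w, cfg = loss_config()) {
  z <- check_loss_inputs(pred, gt, w)
  inter <- sum(z$w * z$pred * z$gt)
  union <- sum(z$w * (z$pred + z$gt - z$pred * z$gt))
  1 - (inter + cfg$eps) / (union + cfg$eps)
}

#' Per-output training loss
#'
#' Builds the boundary weight map from the ground truth and returns the
#' weighted IoU and BCE components together with their combination
#' `L = L_IoUw + n * L_BCEw`.
#'
#' @inheritParams weighted_bce
#' @return named numeric vector c(iou, bce, total).
#' @export
branch_loss <- function(pred, gt, cfg = loss_config()) {
  z <- check_loss_inputs(pred, gt)
  w <- boundary_weight_map(z$gt, cfg)
  li <- weighted_iou(z$pred, z$gt, w, cfg)
  lb <- weighted_bce(z$pred, z$gt, w, cfg)
  c(iou = li, bce = lb, total = li + cfg$n * lb)
}

#' Deep-supervision total loss
#'
#' `L_total = alpha*L(G,S_t) + beta*L(G,S_r) + gamma*L(G,S_z)` over the
#' transformer side map, CNN side map and final map. A NULL side map (e.g.
#' in an ablation without the transformer branch) contributes nothing.
#'
#' @param s_t,s_r,s_z probability matrices at ground-truth resolution
#'   (NULL allowed).
#' @param gt binary matrix.
#' @param cfg a [loss_config()].
#' @return list of class `loss_breakdown`: `per_output` (named list of
#'   c(iou, bce, total)) and `total`.
#' @export
total_loss <- function(s_t, s_r, s_z, gt, cfg = loss_config()) {
  outs <- list(s_t = s_t, s_r = s_r, s_z = s_z)
  wts <- c(s_t = cfg$alpha, s_r = cfg$beta, s_z = cfg$gamma)
  per <- list()
  tot <- 0
  for (nm in names(outs)) {
    if (is.null(outs[[nm]])) next
    l <- branch_loss(outs[[nm]], gt, cfg)
    if (any(!is.finite(l))) stop("non-finite loss component for output ", nm)
    per[[nm]] <- l
    tot <- tot + wts[[nm]] * l[["total"]]
  }
  structure(list(per_output = per, total = tot), class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  for (nm in names(x$per_output)) {
    l <- x$per_output[[nm]]
    cat(sprintf("  %-3s L_IoUw %.4f  L_BCEw %.4f  L %.4f\n",
                nm, l[["iou"]], l[["bce"]], l[["total"]]))
  }
  cat(sprintf("  total %.4f\n", x$total))
  invisible(x)
}

# ---- graph-side loss (used by the trainer) ---------------------------------

# pred_logit: (H, W, 1, N) node; gt, w: arrays matching its layout. Returns a
# scalar node: the weighted soft-IoU plus n times the weighted BCE, with the
# whole batch pooled as one weighted sum (identical to the numeric
# branch_loss for a single image).
g_branch_loss <- function(pred_logit, gt, w, cfg) {
  p <- ag_sigmoid(pred_logit)
  pc <- ag_clamp(p, cfg$eps, 1 - cfg$eps)
  ga <- array(gt, dim(pred_logit$val))
  wa <- array(w, dim(pred_logit$val))
  ce <- ag_add(ag_cmul(ag_log(pc), -ga * wa),
               ag_cmul(ag_log(ag_clamp(ag_cadd(ag_neg(p), 1), cfg$eps, 1 - cfg$eps)),
                       -(1 - ga) * wa))
  sw <- sum(wa)
  lb <- ag_cmul(ag_sum(ce), 1 / sw)
  inter <- ag_sum(ag_cmul(p, wa * ga))
  un_p <- ag_sum(ag_cmul(p, wa * (1 - ga)))
  uc <- sum(wa * ga)
  ratio <- ag_sdiv(ag_cadd(inter, cfg$eps), ag_cadd(un_p, uc + cfg$eps))
  li <- ag_cadd(ag_neg(ratio), 1)
  list(loss = ag_add(li, ag_cmul(lb, cfg$n)),
       iou = as.numeric(li$val), bce = as.numeric(lb$val))
}
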