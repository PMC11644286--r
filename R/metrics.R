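#' Metric configuration
#'
#' Constants used by the segmentation evaluation suite. Defaults follow the
#' usual saliency-metric settings: uniform pixel weighting (`f_omega = 1`),
#' precision-biased F-measure (`f_beta = 1/2`, entering as beta^2 = 1/4),
#' equal object/region and foreground/background mixing in the S-measure
#' (`s_alpha = s_mu = 0.5`, `s_lambda = 1`).
#'
#' @param f_omega pixel-weight exponent of the weighted F-measure; only the
#'   uniform case 1 is implemented.
#' @param f_beta precision/recall trade-off beta of the F-measure.
#' @param s_alpha mixing weight between the object-aware and region-aware
#'   S-measure terms.
#' @param s_mu mixing weight between foreground and background object terms.
#' @param s_lambda dispersion penalty of the object term.
#' @param bin_threshold cut in (0,1) used to binarize probability maps for
#'   Dice/IoU.
#' @param eps numerical floor added to denominators.
#' @return a list of class `metric_config`.
#' @export
metric_config <- function(f_omega = 1, f_beta = 0.5, s_alpha = 0.5,
                          s_mu = 0.5, s_lambda = 1,
                          bin_threshold = 0.5, eps = 1e-8) {
  stopifnot(is.finite(f_omega), is.finite(f_beta), is.finite(s_alpha),
            is.finite(s_mu), is.finite(s_lambda), is.finite(eps),
            bin_threshold > 0, bin_threshold < 1)
  if (f_omega != 1) {
    stop("only the uniform pixel weighting f_omega = 1 is implemented")
  }
  structure(list(f_omega = f_omega, f_beta = f_beta, s_alpha = s_alpha,
                 s_mu = s_mu, s_lambda = s_lambda,
                 bin_threshold = bin_threshold, eps = eps),
            class = "metric_config")
}

check_pair <- function(pred, gt, binary_pred = FALSE) {
  pred <- as.matrix(pred)
  gt <- as.matrix(gt)
  if (!all(dim(pred) == dim(gt))) {
    stop(sprintf("shape mismatch: prediction %dx%d vs ground truth %dx%d",
                 nrow(pred), ncol(pred), nrow(gt), ncol(gt)))
  }
  if (!all(gt %in% c(0, 1))) stop("ground truth must be strictly binary (0/1)")
  if (any(pred < 0) || any(pred > 1)) stop("prediction values must lie in [0, 1]")
  if (binary_pred && !all(pred %in% c(0, 1))) {
    stop("prediction must be binarized before set-based metrics")
  }
  list(pred = pred, gt = gt)
}

#' Soft confusion counts between a probability map and a binary mask
#'
#' Pixelwise products of the continuous prediction `D` and ground truth `G`:
#' `tp = sum(D*G)`, `tn = sum((1-D)*(1-G))`, `fp = sum(D*(1-G))`,
#' `fn = sum((1-D)*G)`. The four counts always sum to the pixel count.
#'
#' @param pred numeric matrix in \[0,1\].
#' @param gt binary matrix of the same shape.
#' @return list of class `confusion_counts` with elements tp, tn, fp, fn.
#' @export
confusion_counts <- function(pred, gt) {
  z <- check_pair(pred, gt)
  structure(list(tp = sum(z$pred * z$gt),
                 tn = sum((1 - z$pred) * (1 - z$gt)),
                 fp = sum(z$pred * (1 - z$gt)),
                 fn = sum((1 - z$pred) * z$gt)),
            class = "confusion_counts")
}

#' Precision and recall from confusion counts
#'
#' Guarded so that empty denominators yield 0 (with a warning) rather than NaN.
#'
#' @param counts a `confusion_counts` object (or list with tp/fp/fn).
#' @param eps numerical floor.
#' @return named numeric vector c(precision, recall).
#' @export
precision_recall <- function(counts, eps = 1e-8) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp <= eps || tp + fn <= eps) {
    if (tp + fp <= eps && tp + fn <= eps) {
      warning("no positive predictions and no positive ground truth; returning 0")
    }
  }
  p <- if (tp + fp > eps) tp / (tp + fp) else 0
  r <- if (tp + fn > eps) tp / (tp + fn) else 0
  c(precision = p, recall = r)
}

#' Dice coefficient of two binary masks
#'
#' `2|A∩B| / (|A|+|B|)`; by convention two empty masks score 1.
#'
#' @param pred binary matrix (binarize probability maps first).
#' @param gt binary matrix of the same shape.
#' @return Dice score in \[0,1\].
#' @export
dice <- function(pred, gt) {
  z <- check_pair(pred, gt, binary_pred = TRUE)
  denom <- sum(z$pred) + sum(z$gt)
  if (denom == 0) {
    message("both masks empty; dice = 1 by convention")
    return(1)
  }
  2 * sum(z$pred * z$gt) / denom
}

#' Intersection over union of two binary masks
#'
#' `|A∩B| / |A∪B|`; two empty masks score 1. The batch mean of this quantity
#' is the usual mIoU.
#'
#' @inheritParams dice
#' @return IoU score in \[0,1\].
#' @export
iou <- function(pred, gt) {
  z <- check_pair(pred, gt, binary_pred = TRUE)
  inter <- sum(z$pred * z$gt)
  uni <- sum(z$pred) + sum(z$gt) - inter
  if (uni == 0) {
    message("both masks empty; iou = 1 by convention")
    return(1)
  }
  inter / uni
}

#' Mean absolute error between a probability map and a binary mask
#'
#' @inheritParams confusion_counts
#' @return MAE in \[0,1\], computed on the continuous prediction.
#' @export
mae <- function(pred, gt) {
  z <- check_pair(pred, gt)
  mean(abs(z$pred - z$gt))
}

#' Weighted F-measure
#'
#' `(1+beta^2) P R / (beta^2 P + R)` with precision and recall taken from the
#' soft confusion counts of the continuous prediction. With the uniform pixel
#' weighting (omega = 1) the weighted precision/recall reduce to the plain
#' ones. Returns 0 when both precision and recall vanish.
#'
#' @inheritParams confusion_counts
#' @param cfg a [metric_config()].
#' @return score in \[0,1\].
#' @export
fbeta_weighted <- function(pred, gt, cfg = metric_config()) {
  pr <- suppressWarnings(precision_recall(confusion_counts(pred, gt), cfg$eps))
  b2 <- cfg$f_beta^2
  num <- (1 + b2) * pr[["precision"]] * pr[["recall"]]
  den <- b2 * pr[["precision"]] + pr[["recall"]]
  if (den <= cfg$eps) return(0)
  min(max(num / den, 0), 1)
}

s_object_term <- function(x, s_lambda) {
  # 2*xbar / (xbar^2 + 1 + 2*lambda*sd); sd over a region with < 2 pixels is 0
  xbar <- mean(x)
  sdx <- if (length(x) > 1) stats::sd(x) else 0
  2 * xbar / (xbar^2 + 1 + 2 * s_lambda * sdx)
}

s_ssim_q <- function(p, g, eps) {
  p <- as.vector(p)
  g <- as.vector(g)
  n <- length(p)
  if (n == 0) return(1)
  x <- mean(p); y <- mean(g)
  if (n > 1) {
    sx <- stats::var(p); sy <- stats::var(g); sxy <- stats::cov(p, g)
  } else {
    sx <- 0; sy <- 0; sxy <- 0
  }
  a <- 4 * x * y * sxy
  b <- (x^2 + y^2) * (sx + sy)
  if (a != 0) a / (b + eps) else if (b == 0) 1 else 0
}

#' Structure measure (S-measure)
#'
#' Structural similarity between a continuous foreground map and a binary
#' ground truth: `S = alpha*S0 + (1-alpha)*Sr`. The object-aware term S0
#' mixes a foreground score (mean/dispersion of the prediction over ground
#' truth foreground) and the mirrored background score; the region-aware term
#' Sr cuts both maps into four quadrants at the ground-truth centroid and
#' averages an SSIM-style similarity per quadrant with weights proportional
#' to quadrant pixel area. Degenerate ground truths fall back to the mean of
#' the prediction: all-background gives `1 - mean(pred)`, all-foreground gives
#' `mean(pred)`. The result is clamped to \[0,1\].
#'
#' @inheritParams fbeta_weighted
#' @return score in \[0,1\].
#' @export
s_measure <- function(pred, gt, cfg = metric_config()) {
  z <- check_pair(pred, gt)
  pred <- z$pred; gt <- z$gt
  y <- mean(gt)
  if (y == 0) return(min(max(1 - mean(pred), 0), 1))
  if (y == 1) return(min(max(mean(pred), 0), 1))

  fg <- pred[gt == 1]
  bg <- 1 - pred[gt == 0]
  s0 <- cfg$s_mu * s_object_term(fg, cfg$s_lambda) +
    (1 - cfg$s_mu) * s_object_term(bg, cfg$s_lambda)

  H <- nrow(gt); W <- ncol(gt)
  area <- sum(gt)
  ridx <- row(gt); cidx <- col(gt)
  cy <- min(max(round(sum(ridx * gt) / area), 1), H)
  cx <- min(max(round(sum(cidx * gt) / area), 1), W)
  rs1 <- seq_len(cy); rs2 <- setdiff(seq_len(H), rs1)
  cs1 <- seq_len(cx); cs2 <- setdiff(seq_len(W), cs1)
  w1 <- (cx * cy) / (W * H)
  w2 <- ((W - cx) * cy) / (W * H)
  w3 <- (cx * (H - cy)) / (W * H)
  w4 <- 1 - w1 - w2 - w3
  q <- function(rs, cs) s_ssim_q(pred[rs, cs], gt[rs, cs], cfg$eps)
  sr <- w1 * q(rs1, cs1) + w2 * q(rs1, cs2) + w3 * q(rs2, cs1) + w4 * q(rs2, cs2)

  min(max(cfg$s_alpha * s0 + (1 - cfg$s_alpha) * sr, 0), 1)
}

#' Enhanced alignment measure (E-measure)
#'
#' Both maps are centered by their global means (`phi = X - mean(X)`), then
#' the pixelwise alignment `2*phi_GT*phi_FM / (phi_GT^2 + phi_FM^2)` is
#' averaged over the image (eps-guarded) and clamped to \[0,1\]. If both maps
#' are constant the score is 1 when they are equal and 0 otherwise.
#'
#' @inheritParams fbeta_weighted
#' @return score in \[0,1\].
#' @export
e_measure <- function(pred, gt, cfg = metric_config()) {
  z <- check_pair(pred, gt)
  phi_g <- z$gt - mean(z$gt)
  phi_f <- z$pred - mean(z$pred)
  if (max(abs(phi_g)) < cfg$eps && max(abs(phi_f)) < cfg$eps) {
    return(as.numeric(max(abs(z$pred - z$gt)) < cfg$eps))
  }
  xi <- 2 * phi_g * phi_f / (phi_g^2 + phi_f^2 + cfg$eps)
  min(max(mean(xi), 0), 1)
}

#' Evaluate a set of prediction / ground-truth pairs
#'
#' Computes the six segmentation metrics per image (Dice and IoU on the
#' prediction binarized at `cfg$bin_threshold`; MAE, weighted F, S and E on
#' the continuous map) and their arithmetic means.
#'
#' @param pairs a list; each element is a list or pair `list(pred, gt)`.
#' @param cfg a [metric_config()].
#' @return an object of class `eval_report`: list with `per_image`
#'   (data.frame) and `means` (named numeric vector mDice, mIoU, MAE, Fbw,
#'   Sm, Em).
#' @export
evaluate_pairs <- function(pairs, cfg = metric_config()) {
  if (length(pairs) == 0) stop("empty evaluation set")
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    pred <- as.matrix(p[[1]])
    gt <- as.matrix(p[[2]])
    predb <- (pred >= cfg$bin_threshold) * 1
    data.frame(
      id = i,
      dice = suppressMessages(dice(predb, gt)),
      iou = suppressMessages(iou(predb, gt)),
      mae = mae(pred, gt),
      fbw = fbeta_weighted(pred, gt, cfg),
      sm = s_measure(pred, gt, cfg),
      em = e_measure(pred, gt, cfg)
    )
  })
  per_image <- do.call(rbind, rows)
  means <- c(mDice = mean(per_image$dice), mIoU = mean(per_image$iou),
             MAE = mean(per_image$mae), Fbw = mean(per_image$fbw),
             Sm = mean(per_image$sm), Em = mean(per_image$em))
  structure(list(per_image = per_image, means = means), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Segmentation evaluation over %d image(s)\n", nrow(x$per_image)))
  m <- x$means
  cat(sprintf("  mDice %.4f  mIoU %.4f  MAE %.4f  Fbw %.4f  Sm %.4f  Em %.4f\n",
              m["mDice"], m["mIoU"], m["MAE"], m["Fbw"], m["Sm"], m["Em"]))
  invisible(x)
}
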