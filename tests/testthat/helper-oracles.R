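# Independent, deliberately naive reference implementations used as oracles.
# Everything here is written with explicit per-pixel loops so it shares no
# code path with the package's vectorized implementations.

oracle_confusion <- function(pred, gt) {
  tp <- 0; tn <- 0; fp <- 0; fn <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      d <- pred[i, j]; g <- gt[i, j]
      tp <- tp + d * g
      tn <- tn + (1 - d) * (1 - g)
      fp <- fp + d * (1 - g)
      fn <- fn + (1 - d) * g
    }
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

oracle_dice <- function(pred, gt) {
  inter <- 0; a <- 0; b <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      inter <- inter + pred[i, j] * gt[i, j]
      a <- a + pred[i, j]; b <- b + gt[i, j]
    }
  }
  if (a + b == 0) return(1)
  2 * inter / (a + b)
}

oracle_iou <- function(pred, gt) {
  inter <- 0; uni <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      inter <- inter + pred[i, j] * gt[i, j]
      uni <- uni + max(pred[i, j], gt[i, j])
    }
  }
  if (uni == 0) return(1)
  inter / uni
}

oracle_mae <- function(pred, gt) {
  s <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) s <- s + abs(pred[i, j] - gt[i, j])
  }
  s / (nrow(pred) * ncol(pred))
}

oracle_fbw <- function(pred, gt, beta = 0.5, eps = 1e-8) {
  cc <- oracle_confusion(pred, gt)
  p <- if (cc$tp + cc$fp > eps) cc$tp / (cc$tp + cc$fp) else 0
  r <- if (cc$tp + cc$fn > eps) cc$tp / (cc$tp + cc$fn) else 0
  den <- beta^2 * p + r
  if (den <= eps) return(0)
  min(max((1 + beta^2) * p * r / den, 0), 1)
}

oracle_emeasure <- function(pred, gt, eps = 1e-8) {
  h <- nrow(pred); w <- ncol(pred)
  mg <- 0; mf <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    mg <- mg + gt[i, j]; mf <- mf + pred[i, j]
  }
  mg <- mg / (h * w); mf <- mf / (h * w)
  # degenerate: both maps constant
  cg <- TRUE; cf <- TRUE
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (abs(gt[i, j] - mg) >= eps) cg <- FALSE
    if (abs(pred[i, j] - mf) >= eps) cf <- FALSE
  }
  if (cg && cf) {
    same <- TRUE
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if (abs(pred[i, j] - gt[i, j]) >= eps) same <- FALSE
    }
    return(as.numeric(same))
  }
  s <- 0
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      pg <- gt[i, j] - mg
      pf <- pred[i, j] - mf
      s <- s + 2 * pg * pf / (pg * pg + pf * pf + eps)
    }
  }
  min(max(s / (h * w), 0), 1)
}

# Loop-style transliteration of the published structure-measure algorithm
# (object term over foreground/background, region term over the four
# quadrants cut at the ground-truth centroid, SSIM-like per quadrant with
# pixel-area weights, fallbacks for degenerate ground truths).
oracle_smeasure <- function(pred, gt, alpha = 0.5, mu = 0.5, lambda = 1,
                            eps = 1e-8) {
  h <- nrow(gt); w <- ncol(gt)
  y <- mean(gt)
  if (y == 0) return(min(max(1 - mean(pred), 0), 1))
  if (y == 1) return(min(max(mean(pred), 0), 1))

  obj <- function(vals) {
    m <- mean(vals)
    s <- if (length(vals) > 1) sd(vals) else 0
    2 * m / (m * m + 1 + 2 * lambda * s)
  }
  fgv <- c(); bgv <- c()
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (gt[i, j] == 1) fgv <- c(fgv, pred[i, j]) else bgv <- c(bgv, 1 - pred[i, j])
  }
  s0 <- mu * obj(fgv) + (1 - mu) * obj(bgv)

  area <- sum(gt)
  sy <- 0; sx <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    sy <- sy + i * gt[i, j]; sx <- sx + j * gt[i, j]
  }
  cy <- min(max(round(sy / area), 1), h)
  cx <- min(max(round(sx / area), 1), w)

  ssim_q <- function(pq, gq) {
    n <- length(pq)
    if (n == 0) return(1)
    mx <- mean(pq); my <- mean(gq)
    if (n > 1) {
      vx <- sum((pq - mx)^2) / (n - 1)
      vy <- sum((gq - my)^2) / (n - 1)
      vxy <- sum((pq - mx) * (gq - my)) / (n - 1)
    } else {
      vx <- 0; vy <- 0; vxy <- 0
    }
    a <- 4 * mx * my * vxy
    b <- (mx^2 + my^2) * (vx + vy)
    if (a != 0) a / (b + eps) else if (b == 0) 1 else 0
  }
  r1 <- 1:cy; r2 <- if (cy < h) (cy + 1):h else integer(0)
  c1 <- 1:cx; c2 <- if (cx < w) (cx + 1):w else integer(0)
  q1 <- ssim_q(as.vector(pred[r1, c1]), as.vector(gt[r1, c1]))
  q2 <- ssim_q(as.vector(pred[r1, c2]), as.vector(gt[r1, c2]))
  q3 <- ssim_q(as.vector(pred[r2, c1]), as.vector(gt[r2, c1]))
  q4 <- ssim_q(as.vector(pred[r2, c2]), as.vector(gt[r2, c2]))
  w1 <- cx * cy / (w * h)
  w2 <- (w - cx) * cy / (w * h)
  w3 <- cx * (h - cy) / (w * h)
  w4 <- 1 - w1 - w2 - w3
  sr <- w1 * q1 + w2 * q2 + w3 * q3 + w4 * q4
  min(max(alpha * s0 + (1 - alpha) * sr, 0), 1)
}

# central-difference numerical gradient
num_grad <- function(f, v, eps = 1e-5) {
  g <- numeric(length(v))
  for (i in seq_along(v)) {
    v1 <- v; v1[i] <- v1[i] + eps
    v2 <- v; v2[i] <- v2[i] - eps
    g[i] <- (f(v1) - f(v2)) / (2 * eps)
  }
  g
}

# random prediction / ground-truth pair generators
random_pair <- function(h = 16, w = 16, blobby = TRUE) {
  pred <- matrix(runif(h * w), h, w)
  if (blobby) {
    gt <- matrix(0, h, w)
    cy <- sample(h, 1); cx <- sample(w, 1); r <- runif(1, 2, max(h, w) / 2)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if ((i - cy)^2 + (j - cx)^2 <= r^2) gt[i, j] <- 1
    }
  } else {
    gt <- matrix(rbinom(h * w, 1, runif(1, 0.2, 0.8)), h, w)
  }
  list(pred = pred, gt = gt)
}

# small in-memory synthetic training set
make_batch <- function(n, seed_base = 100, size = 64) {
  x <- array(0, c(size, size, 3, n))
  y <- array(0, c(size, size, n))
  for (i in seq_len(n)) {
    s <- generate_sample(polyp_scene_spec(seed = seed_base + i,
                                          height = size, width = size))
    x[, , , i] <- s$image
    y[, , i] <- s$mask
  }
  list(x = x, y = y)
}
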