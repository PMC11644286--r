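# Deterministic generator of polyp-like image/mask pairs: bright, reddish,
# Fourier-deformed elliptical blobs on a smoothly textured mucosa-like
# background, with optionally blurred boundaries and additive noise. Not
# photorealistic -- it exists so the whole pipeline is testable offline.

#' Synthetic polyp scene specification
#'
#' @param seed integer; the same spec always reproduces bit-identical output.
#' @param height,width canvas size in pixels.
#' @param n_blobs number of polyp blobs (0 gives a pure background scene).
#' @param radius_range c(min, max) base radius in pixels; the deformed
#'   radius stays within about -25%/+25% of the base (Fourier perturbation
#'   up to 12% plus axis ratios in \[0.85, 1.18\]).
#' @param boundary_softness Gaussian blur sd (pixels) applied to the blob
#'   interior in the image (the mask stays hard binary).
#' @param fg_bg_contrast intensity lift of blob interiors over background.
#' @param noise_sd additive Gaussian pixel noise sd.
#' @param texture_scale wavelength (pixels) of the background mottling.
#' @return list of class `polyp_scene_spec`.
#' @export
polyp_scene_spec <- function(seed = 1L, height = 64L, width = 64L,
                             n_blobs = 1L, radius_range = c(6, 16),
                             boundary_softness = 1.5, fg_bg_contrast = 0.35,
                             noise_sd = 0.03, texture_scale = 12) {
  stopifnot(height >= 1, width >= 1, n_blobs >= 0,
            length(radius_range) == 2, radius_range[1] <= radius_range[2],
            boundary_softness >= 0, noise_sd >= 0, texture_scale > 0)
  structure(list(seed = as.integer(seed), height = as.integer(height),
                 width = as.integer(width), n_blobs = as.integer(n_blobs),
                 radius_range = radius_range,
                 boundary_softness = boundary_softness,
                 fg_bg_contrast = fg_bg_contrast, noise_sd = noise_sd,
                 texture_scale = texture_scale),
            class = "polyp_scene_spec")
}

gaussian_blur <- function(x, sd) {
  if (sd <= 0) return(x)
  blur1 <- function(n) {
    r <- ceiling(3 * sd)
    B <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      w <- stats::dnorm(j - i, sd = sd)
      B[i, j] <- w / sum(w)
    }
    B
  }
  blur1(nrow(x)) %*% x %*% t(blur1(ncol(x)))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

draw_blob <- function(H, W, radius_range) {
  cy <- stats::runif(1, 0.25, 0.75) * H
  cx <- stats::runif(1, 0.25, 0.75) * W
  r0 <- stats::runif(1, radius_range[1], radius_range[2])
  s <- stats::runif(1, 0.85, 1.18)            # axis ratio
  phi <- stats::runif(1, 0, 2 * pi)           # orientation
  ak <- stats::runif(4, 0, 0.12 / (1:4))      # Fourier radius perturbation
  ph <- stats::runif(4, 0, 2 * pi)
  dy <- matrix(seq_len(H) - cy, H, W)
  dx <- matrix(rep(seq_len(W) - cx, each = H), H, W)
  u <- cos(phi) * dx + sin(phi) * dy
  v <- -sin(phi) * dx + cos(phi) * dy
  uu <- u / s
  vv <- v * s
  rad <- sqrt(uu^2 + vv^2)
  th <- atan2(vv, uu)
  rb <- r0 * (1 + ak[1] * cos(th + ph[1]) + ak[2] * cos(2 * th + ph[2]) +
                ak[3] * cos(3 * th + ph[3]) + ak[4] * cos(4 * th + ph[4]))
  (rad <= rb) * 1
}

#' Generate one synthetic polyp scene
#'
#' @param spec a [polyp_scene_spec()].
#' @return list with `image` (H x W x 3 array in \[0,1\]) and `mask`
#'   (binary H x W matrix).
#' @export
generate_sample <- function(spec) {
  stopifnot(inherits(spec, "polyp_scene_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width

  # textured background
  gh <- max(2L, round(H / spec$texture_scale))
  gw <- max(2L, round(W / spec$texture_scale))
  grid <- matrix(stats::runif(gh * gw, -1, 1), gh, gw)
  tex <- bilinear_resize(array(grid, c(gh, gw, 1L, 1L)), H, W)[, , 1, 1]
  bg <- 0.45 + 0.08 * tex

  mask <- matrix(0, H, W)
  if (spec$n_blobs > 0) {
    for (b in seq_len(spec$n_blobs)) {
      mask <- pmax(mask, draw_blob(H, W, spec$radius_range))
    }
    if (sum(mask) == 0) warning("all blobs clipped outside the canvas; mask is empty")
  }

  soft <- gaussian_blur(mask, spec$boundary_softness)
  gray <- bg + spec$fg_bg_contrast * soft
  if (spec$noise_sd > 0) gray <- gray + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
  image <- array(0, c(H, W, 3L))
  image[, , 1] <- clamp01(gray + 0.10 * soft)   # reddish foreground tint
  image[, , 2] <- clamp01(gray * 0.85)
  image[, , 3] <- clamp01(gray * 0.78)
  list(image = image, mask = mask)
}

sample_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) %% 2147483647 * 48271 + i * 16807) %% 2147483647) + 1L
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` image/mask PNG pairs (`img_%04d.png`, `mask_%04d.png`) plus a
#' `manifest.csv` assigning train/validation/test splits at 7:2:1 by a
#' seeded shuffle. Each sample draws from its own random stream derived
#' from `(base_seed, index)`, so generation is order-independent and
#' re-running with the same base seed reproduces every byte.
#'
#' @param n number of pairs (at least 10).
#' @param out_dir output directory (created if missing).
#' @param base_seed integer seed for sample streams and the split shuffle.
#' @param spec template [polyp_scene_spec()]; its seed field is overridden
#'   per sample.
#' @return the manifest data.frame (id, file_image, file_mask, split, seed),
#'   invisibly also written as CSV.
#' @export
generate_dataset <- function(n, out_dir, base_seed = 1L,
                             spec = polyp_scene_spec()) {
  if (n < 10) stop("need at least 10 samples for a 7:2:1 split")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- sample_seed(base_seed, i)
    s <- generate_sample(sp)
    fi <- sprintf("img_%04d.png", i)
    fm <- sprintf("mask_%04d.png", i)
    png::writePNG(s$image, file.path(out_dir, fi))
    png::writePNG(s$mask, file.path(out_dir, fm))
    rows[[i]] <- data.frame(id = i, file_image = fi, file_mask = fm,
                            seed = sp$seed)
  }
  manifest <- do.call(rbind, rows)
  set.seed(base_seed)
  perm <- sample.int(n)
  n_train <- floor(0.7 * n)
  n_val <- floor(0.2 * n)
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  split[perm[n_train + seq_len(n_val)]] <- "val"
  split[perm[(n_train + n_val + 1):n]] <- "test"
  manifest$split <- split
  manifest <- manifest[, c("id", "file_image", "file_mask", "split", "seed")]
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
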