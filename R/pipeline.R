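# Training / evaluation / prediction orchestration: dataset IO, run
# configuration, the Adam training loop over the deep-supervision loss, and
# the ablation harness.

#' Run configuration
#'
#' Collects protocol settings. The `"paper"` preset follows the published
#' protocol (256x192 inputs, Adam, learning rate 1e-4, batch 16, 30
#' epochs); the `"desk"` preset is sized for CPU runs on small synthetic
#' scenes (64x64, full batch 8, learning rate 1e-3, 20 epochs).
#'
#' @param preset `"desk"` or `"paper"`.
#' @param ablation model variant, see [mugen_config()].
#' @param input_size c(H, W), divisible by 16; preset default if NULL.
#' @param batch_size minibatch size; preset default if NULL.
#' @param lr Adam learning rate; preset default if NULL.
#' @param epochs training epochs; preset default if NULL.
#' @param seed integer seed governing weight init, splits and batch order.
#' @param loss a [loss_config()].
#' @param metrics a [metric_config()].
#' @param model_args named list of extra [mugen_config()] overrides.
#' @return list of class `run_config`.
#' @export
run_config <- function(preset = c("desk", "paper"),
                       ablation = c("complete", "backbone",
                                    "backbone_tb", "backbone_cb"),
                       input_size = NULL, batch_size = NULL, lr = NULL,
                       epochs = NULL, seed = 1L, loss = loss_config(),
                       metrics = metric_config(), model_args = list()) {
  preset <- match.arg(preset)
  ablation <- match.arg(ablation)
  def <- if (preset == "desk") {
    list(batch_size = 8L, lr = 1e-3, epochs = 20L)
  } else {
    list(batch_size = 16L, lr = 1e-4, epochs = 30L)
  }
  cfg <- list(preset = preset, ablation = ablation,
              batch_size = as.integer(batch_size %||% def$batch_size),
              lr = lr %||% def$lr,
              epochs = as.integer(epochs %||% def$epochs),
              seed = as.integer(seed), loss = loss, metrics = metrics)
  stopifnot(cfg$batch_size >= 1, cfg$lr >= 0, cfg$epochs >= 0)
  cfg$model <- do.call(mugen_config,
                       c(list(preset = preset, ablation = ablation,
                              input_size = input_size), model_args))
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys map to [run_config()] arguments; `loss:` and `metrics:`
#' sub-maps override [loss_config()] / [metric_config()] fields, and
#' `model:` holds extra [mugen_config()] overrides.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("loss", "metrics", "model"))]
  if (!is.null(y$loss)) args$loss <- do.call(loss_config, y$loss)
  if (!is.null(y$metrics)) args$metrics <- do.call(metric_config, y$metrics)
  if (!is.null(y$model)) args$model_args <- y$model
  do.call(run_config, args)
}

# ---- image IO --------------------------------------------------------------

nearest_resize <- function(x, Hout, Wout) {
  H <- nrow(x); W <- ncol(x)
  ri <- pmin(pmax(round((seq_len(Hout) - 0.5) * H / Hout + 0.5), 1), H)
  ci <- pmin(pmax(round((seq_len(Wout) - 0.5) * W / Wout + 0.5), 1), W)
  x[ri, ci, drop = FALSE]
}

#' Read an RGB image as a normalized array
#'
#' PNG (or matrix-like) input is converted to (H, W, 3) in \[0,1\] and
#' bilinearly resized to the target size when given.
#'
#' @param path PNG file.
#' @param size optional c(H, W) target.
#' @return (H, W, 3) array.
#' @export
read_image <- function(path, size = NULL) {
  x <- png::readPNG(path)
  if (is.matrix(x)) x <- array(rep(x, 3), c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 1L) x <- array(rep(x, 3), c(dim(x)[1:2], 3L))
  if (!is.null(size) && !all(dim(x)[1:2] == size)) {
    x <- bilinear_resize(array(x, c(dim(x), 1L)), size[1], size[2])[, , , 1]
  }
  x
}

#' Read a binary mask
#'
#' 8-bit grayscale PNG; pixels brighter than 127 map to 1. Resizing (when
#' `size` is given) is nearest-neighbour so labels never bleed.
#'
#' @param path PNG file.
#' @param size optional c(H, W) target.
#' @return binary (H, W) matrix.
#' @export
read_mask <- function(path, size = NULL) {
  x <- png::readPNG(path)
  if (!is.matrix(x)) x <- x[, , 1]
  if (!is.null(size) && !all(dim(x) == size)) x <- nearest_resize(x, size[1], size[2])
  (x > 127 / 255) * 1
}

#' Load an image/mask dataset and split it
#'
#' Pairs `img_*.png` with `mask_*.png` by name. If the directory holds a
#' `manifest.csv` (as written by [generate_dataset()]) its split column is
#' used; otherwise a seeded shuffle assigns train/val/test at 7:2:1.
#'
#' @param dir dataset directory.
#' @param cfg a [run_config()] (input size, seed).
#' @return list with elements `train`, `val`, `test`; each holds `x`
#'   (H, W, 3, N image array), `y` (H, W, N binary array) and `ids`.
#' @export
load_dataset <- function(dir, cfg = run_config()) {
  size <- cfg$model$input_size
  man_path <- file.path(dir, "manifest.csv")
  if (file.exists(man_path)) {
    man <- utils::read.csv(man_path, stringsAsFactors = FALSE)
  } else {
    imgs <- sort(list.files(dir, pattern = "^img_.*\\.png$"))
    masks <- sub("^img_", "mask_", imgs)
    missing <- !file.exists(file.path(dir, masks))
    if (any(missing)) {
      stop("unpaired image files (no matching mask): ",
           paste(imgs[missing], collapse = ", "))
    }
    if (length(imgs) == 0) stop("no img_*.png files found in ", dir)
    n <- length(imgs)
    set.seed(cfg$seed)
    perm <- sample.int(n)
    n_train <- floor(0.7 * n); n_val <- floor(0.2 * n)
    split <- character(n)
    split[perm[seq_len(n_train)]] <- "train"
    split[perm[n_train + seq_len(n_val)]] <- "val"
    split[perm[seq.int(n_train + n_val + 1, length.out = n - n_train - n_val)]] <- "test"
    man <- data.frame(id = seq_len(n), file_image = imgs, file_mask = masks,
                      split = split)
  }
  load_split <- function(rows) {
    n <- nrow(rows)
    if (n == 0) return(NULL)
    x <- array(0, c(size[1], size[2], 3L, n))
    y <- array(0, c(size[1], size[2], n))
    for (i in seq_len(n)) {
      x[, , , i] <- read_image(file.path(dir, rows$file_image[i]), size)
      y[, , i] <- read_mask(file.path(dir, rows$file_mask[i]), size)
    }
    list(x = x, y = y, ids = rows$id)
  }
  list(train = load_split(man[man$split == "train", , drop = FALSE]),
       val = load_split(man[man$split == "val", , drop = FALSE]),
       test = load_split(man[man$split == "test", , drop = FALSE]))
}

# ---- training --------------------------------------------------------------

clone_model <- function(model) {
  bn <- lapply(model$bn, function(st) {
    e <- new.env(parent = emptyenv())
    e$mean <- st$mean
    e$var <- st$var
    e
  })
  structure(list(config = model$config, params = model$params, bn = bn,
                 seed = model$seed), class = "mugen_model")
}

batch_weight_maps <- function(y, cfg_loss) {
  d <- dim(y)
  w <- array(1, d)
  for (i in seq_len(d[3])) w[, , i] <- boundary_weight_map(y[, , i], cfg_loss)
  w
}

#' Train the segmentation network
#'
#' Full training loop: seeded shuffling into minibatches, forward pass,
#' reverse-mode gradients of the deep-supervision loss, and Adam updates.
#' Per-step loss components are logged; after each epoch the validation
#' split (when present) is evaluated and the best checkpoint by validation
#' mDice is retained.
#'
#' @param data a dataset list as returned by [load_dataset()], or a list
#'   with at least `train = list(x, y)`.
#' @param config a [run_config()].
#' @param model optionally a pre-built or pre-trained `mugen_model` to
#'   continue from.
#' @param checkpoint optional path; the best model is saved there with
#'   [save_checkpoint()].
#' @param verbose print per-epoch progress.
#' @return object of class `mugen_fit`: the final and best models, the
#'   per-step `history` and per-epoch `epochs` data.frames.
#' @export
mugen_fit <- function(data, config = run_config(), model = NULL,
                      checkpoint = NULL, verbose = FALSE) {
  stopifnot(!is.null(data$train))
  x <- data$train$x
  y <- data$train$y
  n <- dim(x)[4]
  lcfg <- config$loss
  if (is.null(model)) model <- mugen_model(config$model, seed = config$seed)
  adam_m <- lapply(model$params, function(p) array(0, .dim(p)))
  adam_v <- adam_m
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  step <- 0L
  history <- list()
  epoch_rows <- list()
  best <- list(mdice = -Inf, model = NULL, epoch = 0L)
  set.seed(config$seed)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_losses <- c()
    ep_dice <- c()
    for (bt in batches) {
      xb <- x[, , , bt, drop = FALSE]
      yb <- y[, , bt, drop = FALSE]
      wb <- batch_weight_maps(yb, lcfg)
      ctx <- forward_ctx(model, training = TRUE, trainable = TRUE)
      out <- fw_full(ctx, ag_const(xb))
      lz <- g_branch_loss(out$zlogit, yb, wb, lcfg)
      lr_ <- g_branch_loss(out$sr_logit, yb, wb, lcfg)
      lt <- if (!is.null(out$st_logit)) g_branch_loss(out$st_logit, yb, wb, lcfg) else NULL
      comps <- c(s_t = if (is.null(lt)) NA_real_ else as.numeric(lt$loss$val),
                 s_r = as.numeric(lr_$loss$val), s_z = as.numeric(lz$loss$val))
      if (any(!is.finite(comps[!is.na(comps)]))) {
        bad <- names(comps)[!is.finite(comps) & !is.na(comps)]
        stop("non-finite training loss for output(s): ", paste(bad, collapse = ", "))
      }
      total <- ag_cmul(lz$loss, lcfg$gamma)
      total <- ag_add(total, ag_cmul(lr_$loss, lcfg$beta))
      if (!is.null(lt)) total <- ag_add(total, ag_cmul(lt$loss, lcfg$alpha))
      ag_backward(total)
      step <- step + 1L
      for (nm in names(model$params)) {
        g <- ctx$P[[nm]]$grad
        if (is.null(g)) next
        adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
        adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g * g
        mh <- adam_m[[nm]] / (1 - b1^step)
        vh <- adam_v[[nm]] / (1 - b2^step)
        upd <- model$params[[nm]] - config$lr * mh / (sqrt(vh) + adam_eps)
        dim(upd) <- dim(model$params[[nm]])
        model$params[[nm]] <- upd
      }
      zb <- out$zout$val
      bdice <- vapply(seq_along(bt), function(i) {
        suppressMessages(dice((zb[, , 1, i] >= 0.5) * 1, yb[, , i]))
      }, numeric(1))
      ep_dice <- c(ep_dice, bdice)
      ep_losses <- c(ep_losses, as.numeric(total$val))
      history[[length(history) + 1L]] <- data.frame(
        step = step, epoch = epoch,
        loss = as.numeric(total$val),
        iou_z = lz$iou, bce_z = lz$bce,
        iou_r = lr_$iou, bce_r = lr_$bce,
        iou_t = if (is.null(lt)) NA_real_ else lt$iou,
        bce_t = if (is.null(lt)) NA_real_ else lt$bce)
    }
    val_mdice <- NA_real_
    if (!is.null(data$val)) {
      vr <- evaluate_model(model, data$val$x, data$val$y, config$metrics)
      val_mdice <- unname(vr$means["mDice"])
    }
    track <- if (is.finite(val_mdice)) val_mdice else mean(ep_dice)
    if (track > best$mdice) {
      best <- list(mdice = track, model = clone_model(model), epoch = epoch)
    }
    epoch_rows[[epoch]] <- data.frame(
      epoch = epoch, loss = mean(ep_losses),
      train_mdice = mean(ep_dice), val_mdice = val_mdice)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  train mDice %.4f  val mDice %s",
                      epoch, mean(ep_losses), mean(ep_dice),
                      ifelse(is.na(val_mdice), "-", sprintf("%.4f", val_mdice))))
    }
  }
  if (is.null(best$model)) best <- list(mdice = NA_real_, model = clone_model(model), epoch = 0L)
  if (!is.null(checkpoint)) save_checkpoint(best$model, checkpoint)
  structure(list(model = model, best_model = best$model,
                 best_epoch = best$epoch,
                 history = do.call(rbind, history),
                 epochs = do.call(rbind, epoch_rows),
                 config = config),
            class = "mugen_fit")
}

#' Evaluate a model on an image/mask array pair
#'
#' Runs inference in chunks and scores each image with the six-metric
#' suite; predictions with IoU > 0.5 are flagged as valid detections.
#'
#' @param model a `mugen_model`.
#' @param x (H, W, 3, N) image array.
#' @param y (H, W, N) binary mask array.
#' @param cfg a [metric_config()].
#' @param out_csv optional path for a per-image CSV (plus a final mean row).
#' @param chunk inference chunk size.
#' @return an `eval_report` whose `per_image` has a `valid` column.
#' @export
evaluate_model <- function(model, x, y, cfg = metric_config(),
                           out_csv = NULL, chunk = 8L) {
  n <- dim(x)[4]
  pairs <- vector("list", n)
  for (s in seq.int(1L, n, by = chunk)) {
    ix <- s:min(s + chunk - 1L, n)
    z <- mugen_forward(model, x[, , , ix, drop = FALSE])$zout
    for (j in seq_along(ix)) {
      pairs[[ix[j]]] <- list(z[, , 1, j], y[, , ix[j]])
    }
  }
  rep <- evaluate_pairs(pairs, cfg)
  rep$per_image$valid <- rep$per_image$iou > 0.5
  if (!is.null(out_csv)) {
    per <- rep$per_image
    mean_row <- data.frame(id = NA, dice = rep$means[["mDice"]],
                           iou = rep$means[["mIoU"]], mae = rep$means[["MAE"]],
                           fbw = rep$means[["Fbw"]], sm = rep$means[["Sm"]],
                           em = rep$means[["Em"]], valid = NA)
    utils::write.csv(rbind(per, mean_row), out_csv, row.names = FALSE)
  }
  rep
}

#' Predict segmentation masks for image files
#'
#' Reads each image, resizes to the model input, runs the forward pass and
#' resizes the probability map back to the original resolution. When
#' `out_dir` is given, writes `<name>_prob.png` and `<name>_mask.png`.
#'
#' @param object a `mugen_model` (or `mugen_fit`, which uses its best model).
#' @param paths character vector of image files.
#' @param out_dir optional output directory.
#' @param threshold binarization cut for the mask output.
#' @param ... unused.
#' @return named list of probability matrices (invisibly when writing).
#' @export
predict.mugen_model <- function(object, paths, out_dir = NULL,
                                threshold = 0.5, ...) {
  size <- object$config$input_size
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  for (p in paths) {
    x0 <- tryCatch(png::readPNG(p), error = function(e) NULL)
    if (is.null(x0)) {
      warning("cannot read image: ", p)
      next
    }
    orig <- dim(x0)[1:2]
    x <- read_image(p, size)
    z <- mugen_forward(object, array(x, c(size[1], size[2], 3L, 1L)))$zout[, , 1, 1]
    zf <- bilinear_resize(array(z, c(size[1], size[2], 1L, 1L)),
                          orig[1], orig[2])[, , 1, 1]
    nm <- sub("\\.png$", "", basename(p))
    res[[nm]] <- zf
    if (!is.null(out_dir)) {
      png::writePNG(zf, file.path(out_dir, paste0(nm, "_prob.png")))
      png::writePNG((zf >= threshold) * 1, file.path(out_dir, paste0(nm, "_mask.png")))
    }
  }
  if (is.null(out_dir)) res else invisible(res)
}

#' @export
predict.mugen_fit <- function(object, paths, ...) {
  predict.mugen_model(object$best_model, paths, ...)
}

#' @export
print.mugen_fit <- function(x, ...) {
  ep <- x$epochs
  cat(sprintf("mugen_fit: %d epoch(s), %d step(s)\n", nrow(ep), nrow(x$history)))
  cat(sprintf("  final loss %.4f, train mDice %.4f\n",
              ep$loss[nrow(ep)], ep$train_mdice[nrow(ep)]))
  if (any(is.finite(ep$val_mdice))) {
    cat(sprintf("  best val mDice %.4f (epoch %d)\n",
                max(ep$val_mdice, na.rm = TRUE), x$best_epoch))
  }
  invisible(x)
}

#' @export
summary.mugen_fit <- function(object, ...) {
  print(object)
  print(object$model)
  invisible(object$epochs)
}

#' @export
plot.mugen_fit <- function(x, ...) {
  ep <- x$epochs
  graphics::par(mfrow = c(1, 2))
  graphics::plot(ep$epoch, ep$loss, type = "b", xlab = "epoch",
                 ylab = "training loss", main = "loss")
  graphics::plot(ep$epoch, ep$train_mdice, type = "b", xlab = "epoch",
                 ylab = "mDice", ylim = c(0, 1), main = "overlap")
  if (any(is.finite(ep$val_mdice))) {
    graphics::lines(ep$epoch, ep$val_mdice, type = "b", col = 2)
    graphics::legend("bottomright", legend = c("train", "val"),
                     col = c(1, 2), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Ablation harness
#'
#' Trains and evaluates the four model variants (backbone, backbone + TB,
#' backbone + CB, complete) under an identical seed and protocol and
#' returns a table of parameter counts and overlap metrics.
#'
#' @param data dataset list from [load_dataset()].
#' @param config base [run_config()]; its `ablation` field is overridden.
#' @param epochs training epochs per variant (smoke default 1).
#' @param out_csv optional CSV path.
#' @param verbose print progress.
#' @return data.frame with one row per configuration: parameters, mDice,
#'   mIoU and weighted F on the evaluation split (val when present,
#'   training otherwise).
#' @export
ablation_suite <- function(data, config = run_config(), epochs = 1L,
                           out_csv = NULL, verbose = FALSE) {
  variants <- c("backbone", "backbone_tb", "backbone_cb", "complete")
  rows <- vector("list", length(variants))
  for (i in seq_along(variants)) {
    cfg <- run_config(preset = config$preset, ablation = variants[i],
                      input_size = config$model$input_size,
                      batch_size = config$batch_size, lr = config$lr,
                      epochs = as.integer(epochs), seed = config$seed,
                      loss = config$loss, metrics = config$metrics)
    fit <- mugen_fit(data, cfg, verbose = verbose)
    ev <- if (!is.null(data$val)) {
      evaluate_model(fit$best_model, data$val$x, data$val$y, config$metrics)
    } else {
      evaluate_model(fit$best_model, data$train$x, data$train$y, config$metrics)
    }
    rows[[i]] <- data.frame(config = variants[i],
                            parameters = n_parameters(fit$model),
                            mdice = unname(ev$means["mDice"]),
                            miou = unname(ev$means["mIoU"]),
                            fbw = unname(ev$means["Fbw"]))
  }
  tab <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(tab, out_csv, row.names = FALSE)
  tab
}
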