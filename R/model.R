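#' Network configuration
#'
#' Builds the configuration for the parallel CNN / transformer segmentation
#' network. Two presets are provided: `"desk"`, a width-reduced model sized
#' for CPU experiments on small synthetic scenes (embedding 64, 4 heads,
#' depth 4, pyramid channels 64/32/16), and `"paper"`, which mirrors the
#' published geometry (256x192 input, ViT-B/16 transformer shape, a
#' ResNet-34 layout CNN encoder, pyramid channels 256/128/64).
#'
#' The four ablation variants select which parts are instantiated:
#' `"complete"` (both branches, SE and channel attention in the fusion),
#' `"backbone"` (CNN encoder with plain fusion/decoder), `"backbone_tb"`
#' (adds the transformer branch, fusion by plain projection) and
#' `"backbone_cb"` (CNN branch with the max-pool channel-attention gate).
#'
#' @param preset `"desk"` or `"paper"`.
#' @param ablation one of `"complete"`, `"backbone"`, `"backbone_tb"`,
#'   `"backbone_cb"`.
#' @param input_size integer c(H, W); both divisible by 16. Defaults to
#'   64x64 (desk) or 192x256 (paper, i.e. 256x192 images width x height).
#' @param in_channels image channels (3 for RGB).
#' @param ... named overrides of any configuration field (e.g. `embed_dim`,
#'   `depth`, `n_heads`, `cnn_widths`, `cnn_blocks`, `dims`, `d3`,
#'   `reduction`, `skip_fusion`, `patch`).
#' @return list of class `mugen_config`.
#' @export
mugen_config <- function(preset = c("desk", "paper"),
                         ablation = c("complete", "backbone",
                                      "backbone_tb", "backbone_cb"),
                         input_size = NULL, in_channels = 3L, ...) {
  preset <- match.arg(preset)
  ablation <- match.arg(ablation)
  cfg <- if (preset == "desk") {
    list(patch = 16L, embed_dim = 64L, depth = 4L, n_heads = 4L,
         mlp_ratio = 4L, cnn_stem = 16L, cnn_widths = c(16L, 32L, 64L),
         cnn_blocks = c(1L, 1L, 1L), dims = c(64L, 32L, 16L), d3 = 8L,
         reduction = 8L, skip_fusion = TRUE,
         input_size = c(64L, 64L))
  } else {
    list(patch = 16L, embed_dim = 768L, depth = 12L, n_heads = 12L,
         mlp_ratio = 4L, cnn_stem = 64L, cnn_widths = c(64L, 128L, 256L),
         cnn_blocks = c(3L, 4L, 6L), dims = c(256L, 128L, 64L), d3 = 32L,
         reduction = 16L, skip_fusion = TRUE,
         input_size = c(192L, 256L))
  }
  if (!is.null(input_size)) cfg$input_size <- as.integer(input_size)
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop("unknown configuration field: ", nm)
    cfg[[nm]] <- dots[[nm]]
  }
  cfg$preset <- preset
  cfg$ablation <- ablation
  cfg$in_channels <- as.integer(in_channels)
  H <- cfg$input_size[1]; W <- cfg$input_size[2]
  if (H %% 16L != 0L || W %% 16L != 0L) {
    stop(sprintf("input size %dx%d must be divisible by 16", H, W))
  }
  if (any(cfg$dims %% cfg$reduction != 0L)) {
    stop("every pyramid channel dim must be divisible by the reduction ratio")
  }
  if (cfg$embed_dim %% cfg$n_heads != 0L) {
    stop("embed_dim must be divisible by n_heads")
  }
  structure(cfg, class = "mugen_config")
}

has_tb <- function(cfg) cfg$ablation %in% c("complete", "backbone_tb")
has_se <- function(cfg) cfg$ablation == "complete"
has_ca <- function(cfg) cfg$ablation %in% c("complete", "backbone_cb")

# ---- parameter builders ----------------------------------------------------

mk_new <- function() {
  mk <- new.env(parent = emptyenv())
  mk$p <- list()
  mk$bn <- integer()
  mk
}

add_conv <- function(mk, name, k, cin, cout, bn = TRUE) {
  sd <- sqrt(2 / (k * k * cin))
  mk$p[[paste0(name, ".w")]] <- array(stats::rnorm(k * k * cin * cout, 0, sd),
                                      c(k, k, cin, cout))
  mk$p[[paste0(name, ".b")]] <- numeric(cout)
  if (bn) {
    mk$p[[paste0(name, ".g")]] <- rep(1, cout)
    mk$p[[paste0(name, ".bb")]] <- numeric(cout)
    mk$bn[[name]] <- cout
  }
  invisible(mk)
}

add_lin <- function(mk, name, din, dout, sd = sqrt(2 / din)) {
  mk$p[[paste0(name, ".w")]] <- matrix(stats::rnorm(din * dout, 0, sd), din, dout)
  mk$p[[paste0(name, ".b")]] <- numeric(dout)
  invisible(mk)
}

add_ln <- function(mk, name, d) {
  mk$p[[paste0(name, ".g")]] <- rep(1, d)
  mk$p[[paste0(name, ".bb")]] <- numeric(d)
  invisible(mk)
}

build_params <- function(cfg) {
  mk <- mk_new()
  E <- cfg$embed_dim
  D <- cfg$dims
  Cin <- cfg$in_channels
  H <- cfg$input_size[1]; W <- cfg$input_size[2]
  P <- cfg$patch

  if (has_tb(cfg)) {
    Tn <- (H %/% P) * (W %/% P)
    add_lin(mk, "tr.patch", P * P * Cin, E, sd = sqrt(1 / (P * P * Cin)))
    mk$p[["tr.pos"]] <- matrix(stats::rnorm(Tn * E, 0, 0.02), Tn, E)
    for (l in seq_len(cfg$depth)) {
      b <- paste0("tr.l", l, ".")
      add_ln(mk, paste0(b, "ln1"), E)
      add_lin(mk, paste0(b, "q"), E, E, sd = sqrt(1 / E))
      add_lin(mk, paste0(b, "k"), E, E, sd = sqrt(1 / E))
      add_lin(mk, paste0(b, "v"), E, E, sd = sqrt(1 / E))
      add_lin(mk, paste0(b, "o"), E, E, sd = sqrt(1 / E))
      add_ln(mk, paste0(b, "ln2"), E)
      add_lin(mk, paste0(b, "m1"), E, cfg$mlp_ratio * E)
      add_lin(mk, paste0(b, "m2"), cfg$mlp_ratio * E, E, sd = sqrt(1 / (cfg$mlp_ratio * E)))
    }
    add_ln(mk, "tr.lnf", E)
    add_conv(mk, "tr.proj0", 1L, E, D[1])
    add_conv(mk, "tr.up1", 3L, D[1], D[2])
    add_conv(mk, "tr.up2", 3L, D[2], D[3])
    add_conv(mk, "head.t", 1L, D[3], 1L, bn = FALSE)
  }

  # CNN branch (always present)
  ws <- cfg$cnn_widths
  add_conv(mk, "cnn.stem", 3L, Cin, cfg$cnn_stem)
  cin <- cfg$cnn_stem
  for (s in 1:3) {
    for (bl in seq_len(cfg$cnn_blocks[s])) {
      b <- paste0("cnn.s", s, ".b", bl, ".")
      stride <- if (bl == 1L) 2L else 1L
      cout <- ws[s]
      add_conv(mk, paste0(b, "c1"), 3L, cin, cout)
      add_conv(mk, paste0(b, "c2"), 3L, cout, cout)
      if (stride != 1L || cin != cout) add_conv(mk, paste0(b, "down"), 1L, cin, cout)
      cin <- cout
    }
  }
  add_conv(mk, "cnn.proj0", 1L, ws[3], D[1])
  up1_in <- D[1] + if (cfg$skip_fusion) ws[2] else 0L
  up2_in <- D[2] + if (cfg$skip_fusion) ws[1] else 0L
  add_conv(mk, "cnn.up1", 3L, up1_in, D[2])
  add_conv(mk, "cnn.up2", 3L, up2_in, D[3])
  add_conv(mk, "head.r", 1L, D[3], 1L, bn = FALSE)

  # Mugen fusion modules, one per pyramid level
  for (i in 1:3) {
    C <- D[i]
    b <- paste0("fuse", i, ".")
    Cr <- C %/% cfg$reduction
    if (has_se(cfg)) {
      add_lin(mk, paste0(b, "se1"), C, Cr)
      add_lin(mk, paste0(b, "se2"), Cr, C)
    }
    if (has_ca(cfg)) {
      add_lin(mk, paste0(b, "ca1"), C, Cr)
      add_lin(mk, paste0(b, "ca2"), Cr, C)
    }
    fin <- if (has_tb(cfg)) 2L * C else C
    add_conv(mk, paste0(b, "proj"), 3L, fin, C)
    add_conv(mk, paste0(b, "skip"), 1L, fin, C, bn = FALSE)
  }

  # attention-gated decoder
  add_conv(mk, "dec.up1", 3L, D[1], D[2])
  f2 <- max(D[2] %/% 2L, 4L)
  add_conv(mk, "dec.ag2.wg", 1L, D[2], f2, bn = FALSE)
  add_conv(mk, "dec.ag2.wx", 1L, D[2], f2, bn = FALSE)
  add_conv(mk, "dec.ag2.psi", 1L, f2, 1L, bn = FALSE)
  add_conv(mk, "dec.up2", 3L, D[2], D[3])
  f3 <- max(D[3] %/% 2L, 4L)
  add_conv(mk, "dec.ag3.wg", 1L, D[3], f3, bn = FALSE)
  add_conv(mk, "dec.ag3.wx", 1L, D[3], f3, bn = FALSE)
  add_conv(mk, "dec.ag3.psi", 1L, f3, 1L, bn = FALSE)
  add_conv(mk, "dec.up3", 3L, D[3], cfg$d3)
  add_conv(mk, "head.z", 1L, cfg$d3, 1L, bn = FALSE)

  mk
}

#' Construct a segmentation network with randomly initialized weights
#'
#' @param config a [mugen_config()].
#' @param seed integer seed for the weight initialization.
#' @return object of class `mugen_model`: configuration, named parameter
#'   arrays, and batch-norm running statistics.
#' @examples
#' m <- mugen_model(mugen_config("desk"), seed = 1)
#' print(m)
#' @export
mugen_model <- function(config = mugen_config(), seed = 1L) {
  stopifnot(inherits(config, "mugen_config"))
  set.seed(seed)
  mk <- build_params(config)
  bn <- list()
  for (nm in names(mk$bn)) {
    st <- new.env(parent = emptyenv())
    st$mean <- numeric(mk$bn[[nm]])
    st$var <- rep(1, mk$bn[[nm]])
    bn[[nm]] <- st
  }
  structure(list(config = config, params = mk$p, bn = bn, seed = seed),
            class = "mugen_model")
}

#' Number of trainable parameters
#' @param model a `mugen_model`.
#' @param by_component if TRUE, return a named vector per component prefix.
#' @return integer count (or named vector).
#' @export
n_parameters <- function(model, by_component = FALSE) {
  sizes <- vapply(model$params, length, numeric(1))
  if (!by_component) return(sum(sizes))
  comp <- sub("^([a-z]+)\\..*$", "\\1", names(sizes))
  tapply(sizes, comp, sum)
}

#' @export
print.mugen_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("mugen_model [%s preset, %s] %dx%d input\n",
              cfg$preset, cfg$ablation, cfg$input_size[1], cfg$input_size[2]))
  cat(sprintf("  pyramid channels %s, decoder %d, reduction %d\n",
              paste(cfg$dims, collapse = "/"), cfg$d3, cfg$reduction))
  if (has_tb(cfg)) {
    cat(sprintf("  transformer: dim %d, %d heads, depth %d, patch %d\n",
                cfg$embed_dim, cfg$n_heads, cfg$depth, cfg$patch))
  }
  cat(sprintf("  parameters: %s\n", format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
summary.mugen_model <- function(object, ...) {
  comp <- n_parameters(object, by_component = TRUE)
  print(object)
  cat("  by component:\n")
  for (nm in names(comp)) {
    cat(sprintf("    %-6s %s\n", nm, format(comp[[nm]], big.mark = ",")))
  }
  invisible(comp)
}

#' Save / load a model checkpoint
#'
#' Checkpoints are the model object serialized with `saveRDS`; loading
#' restores parameters, batch-norm statistics and configuration exactly.
#'
#' @param model a `mugen_model`.
#' @param path file path.
#' @return `load_checkpoint` returns the restored `mugen_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mugen_model"))
  # materialize bn environments into plain lists for serialization
  bn <- lapply(model$bn, function(st) list(mean = st$mean, var = st$var))
  obj <- list(config = unclass(model$config), params = model$params,
              bn = bn, seed = model$seed)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  bn <- lapply(obj$bn, function(st) {
    e <- new.env(parent = emptyenv())
    e$mean <- st$mean
    e$var <- st$var
    e
  })
  structure(list(config = structure(obj$config, class = "mugen_config"),
                 params = obj$params, bn = bn, seed = obj$seed),
            class = "mugen_model")
}
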