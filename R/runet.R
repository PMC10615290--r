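#' RUNet configuration
#'
#' Hyper-parameters of the residual encoder-decoder restoration network:
#' `depth` pooling stages (each halves the spatial size), residual
#' Conv-BN-ReLU blocks with tensor-addition skips, sub-pixel (pixel
#' shuffle) 2x upscaling in the expansive path, and a pixel + perceptual
#' training loss. Input spatial sizes must be divisible by `2^depth`.
#'
#' @param depth Number of pooling stages (default 4).
#' @param base_channels Channel width of the first stage (default 32).
#' @param loss_weights Named list `list(pixel =, perceptual =)`;
#'   non-negative, not both zero.
#' @param epochs Training epochs (default 50).
#' @param batch_size Mini-batch size (default 8).
#' @param learning_rate Adam step size (default 1e-4).
#' @param seed Integer seed for weight init and batch shuffling.
#' @param perceptual_seed Seed of the fixed random feature extractor used
#'   by the perceptual loss term.
#' @return A `runet_config`.
#' @export
runet_config <- function(depth = 4L, base_channels = 32L,
                         loss_weights = list(pixel = 1.0, perceptual = 0.1),
                         epochs = 50L, batch_size = 8L,
                         learning_rate = 1e-4, seed = 1L,
                         perceptual_seed = 727L) {
  if (depth < 1L) stop_invalid("depth must be >= 1")
  if (base_channels < 1L) stop_invalid("base_channels must be >= 1")
  lw <- loss_weights
  if (is.null(lw$pixel) || is.null(lw$perceptual) ||
      lw$pixel < 0 || lw$perceptual < 0 ||
      (lw$pixel == 0 && lw$perceptual == 0))
    stop_invalid("loss weights must be non-negative and not both zero")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 loss_weights = lapply(lw[c("pixel", "perceptual")],
                                       as.numeric),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = as.numeric(learning_rate),
                 seed = as.integer(seed),
                 perceptual_seed = as.integer(perceptual_seed)),
            class = "runet_config")
}

#' Residual Conv-BN-ReLU block (standalone)
#'
#' `output = inner(x) + x` with `inner = Conv -> BN -> ReLU -> Conv -> BN`;
#' spatial shape is preserved, and a 1x1 projection aligns channels when
#' the block's channel count differs from the input's.
#'
#' @param x Tensor of dim (H, W, C) or (H, W, C, N).
#' @param params Block parameters from [residual_block_params()].
#' @param training Use batch (TRUE) or running (FALSE) BN statistics.
#' @return Tensor of the same spatial shape with the block's channels.
#' @export
residual_block <- function(x, params, training = FALSE) {
  was3 <- length(dim(x)) == 3L
  if (was3) dim(x) <- c(dim(x), 1L)
  out <- resblock_fw(params, x, training)$out
  if (was3) dim(out) <- dim(out)[1:3]
  out
}

#' @rdname residual_block
#' @param c_in Input channel count.
#' @param channels Block channel count.
#' @param seed Seed for weight initialization.
#' @export
residual_block_params <- function(c_in, channels, seed = 1L) {
  local_rng(seed)
  resblock_init(c_in, channels)
}

#' Sub-pixel upscaling (pixel shuffle)
#'
#' Deterministic channel-to-space rearrangement
#' `(H, W, C r^2) -> (H r, W r, C)`: a bijective permutation of the
#' entries, the standard upsampling step of sub-pixel convolution.
#'
#' @param x Tensor of dim (H, W, C) or (H, W, C, N); channel count must be
#'   divisible by `r^2`.
#' @param r Integer upscale factor.
#' @return The rearranged tensor.
#' @export
subpixel_upscale <- function(x, r) {
  r <- as.integer(r)
  if (r < 1L) stop_invalid("r must be >= 1")
  was3 <- length(dim(x)) == 3L
  if (was3) dim(x) <- c(dim(x), 1L)
  out <- pixel_shuffle(x, r)
  if (was3) dim(out) <- dim(out)[1:3]
  out
}

#' Build an RUNet restoration model
#'
#' Encoder of `depth` stages (residual block, 2x mean pooling, channel
#' doubling), a residual bottleneck, and a symmetric decoder using
#' sub-pixel 2x upscaling with encoder-to-decoder skip additions; a final
#' 3x3 conv maps back to one channel, added to the input as a global
#' residual. Weight initialization is fully seeded.
#'
#' @param config A `runet_config`.
#' @return A `runet_model` with untrained weights and empty history.
#' @export
build_runet <- function(config = runet_config()) {
  stopifnot(inherits(config, "runet_config"))
  local_rng(config$seed)
  B <- config$base_channels
  D <- config$depth
  # levels are NAMED: every parameter-tree traversal (Adam, checkpoint
  # serialization) iterates names(), so unnamed lists would be skipped
  enc <- setNames(vector("list", D), paste0("level", seq_len(D)))
  dec <- setNames(vector("list", D), paste0("level", seq_len(D)))
  for (d in seq_len(D)) {
    cd <- B * 2^(d - 1)
    enc[[d]] <- list(rb = resblock_init(cd, cd),
                     down = conv_init(cd, 2 * cd))
    dec[[d]] <- list(up = conv_init(2 * cd, 4 * cd),
                     rb = resblock_init(cd, cd))
  }
  # zero-initialized head + global residual start the network at the
  # identity mapping, the standard warm start for restoration models
  params <- list(stem = conv_init(1L, B), enc = enc,
                 bott = resblock_init(B * 2^D, B * 2^D),
                 dec = dec, head = conv_zero(B, 1L))
  local_rng(config$perceptual_seed)
  perc <- list(c1 = conv_init(1L, 8L), c2 = conv_init(8L, 8L))
  structure(list(config = config, params = params, perceptual = perc,
                 history = data.frame(epoch = integer(),
                                      train_loss = numeric(),
                                      val_loss = numeric())),
            class = "runet_model")
}

check_input_size <- function(model, d) {
  div <- 2^model$config$depth
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop_invalid(sprintf(
      "input spatial size %dx%d must be divisible by 2^depth = %d",
      d[1], d[2], div))
}

runet_fw <- function(model, x, training = FALSE) {
  d <- dim(x)
  check_input_size(model, d)
  p <- model$params
  D <- model$config$depth
  cache <- list()
  f <- conv_fw(p$stem, x)
  cache$stem <- f$cache
  h <- f$out
  skips <- vector("list", D)
  cache$enc <- vector("list", D)
  for (dd in seq_len(D)) {
    rb <- resblock_fw(p$enc[[dd]]$rb, h, training)
    p$enc[[dd]]$rb <- rb$params
    skips[[dd]] <- rb$out
    pl <- avgpool_fw(rb$out)
    dn <- conv_fw(p$enc[[dd]]$down, pl$out)
    cache$enc[[dd]] <- list(rb = rb$cache, pool = pl$cache, down = dn$cache)
    h <- dn$out
  }
  bt <- resblock_fw(p$bott, h, training)
  p$bott <- bt$params
  cache$bott <- bt$cache
  h <- bt$out
  cache$dec <- vector("list", D)
  for (dd in rev(seq_len(D))) {
    up <- conv_fw(p$dec[[dd]]$up, h)
    sh <- pixel_shuffle(up$out, 2L)
    a <- sh + skips[[dd]]
    rb <- resblock_fw(p$dec[[dd]]$rb, a, training)
    p$dec[[dd]]$rb <- rb$params
    cache$dec[[dd]] <- list(up = up$cache, rb = rb$cache)
    h <- rb$out
  }
  hd <- conv_fw(p$head, h)
  cache$head <- hd$cache
  model$params <- p
  list(out = x + hd$out, cache = cache, model = model)
}

runet_bw <- function(model, cache, dout) {
  p <- model$params
  D <- model$config$depth
  grads <- list(
    enc = setNames(vector("list", D), paste0("level", seq_len(D))),
    dec = setNames(vector("list", D), paste0("level", seq_len(D))))
  gh <- conv_bw(p$head, cache$head, dout)
  grads$head <- gh$grads
  dh <- gh$dx
  dskips <- vector("list", D)
  for (dd in seq_len(D)) {
    rb <- resblock_bw(p$dec[[dd]]$rb, cache$dec[[dd]]$rb, dh)
    dskips[[dd]] <- rb$dx
    dup_out <- pixel_unshuffle(rb$dx, 2L)
    up <- conv_bw(p$dec[[dd]]$up, cache$dec[[dd]]$up, dup_out)
    grads$dec[[dd]] <- list(up = up$grads, rb = rb$grads)
    dh <- up$dx
  }
  bt <- resblock_bw(p$bott, cache$bott, dh)
  grads$bott <- bt$grads
  dh <- bt$dx
  for (dd in rev(seq_len(D))) {
    dn <- conv_bw(p$enc[[dd]]$down, cache$enc[[dd]]$down, dh)
    dpool <- avgpool_bw(cache$enc[[dd]]$pool, dn$dx)
    drb_out <- dpool + dskips[[dd]]
    rb <- resblock_bw(p$enc[[dd]]$rb, cache$enc[[dd]]$rb, drb_out)
    grads$enc[[dd]] <- list(rb = rb$grads, down = dn$grads)
    dh <- rb$dx
  }
  st <- conv_bw(p$stem, cache$stem, dh)
  grads$stem <- st$grads
  list(dx = st$dx + dout, grads = grads)   # global residual adds dout
}

#' Restoration training loss
#'
#' `weights$pixel * mean(|pred - target|) + weights$perceptual * MSE`
#' between feature maps of a fixed, seeded, randomly initialized shallow
#' convolutional extractor applied to both images. Inputs are expected on
#' the \[0, 1\] scale.
#'
#' @param pred,target Tensors of identical dim (H, W) / (H, W, 1, N).
#' @param weights Named list with `pixel` and `perceptual` weights.
#' @param perceptual Extractor parameters (e.g. `model$perceptual`);
#'   required when the perceptual weight is nonzero.
#' @param grad Also return the gradient with respect to `pred`.
#' @return Scalar loss, or `list(loss, dpred)` when `grad = TRUE`.
#' @export
runet_loss <- function(pred, target,
                       weights = list(pixel = 1, perceptual = 0.1),
                       perceptual = NULL, grad = FALSE) {
  if (is.matrix(pred)) dim(pred) <- c(dim(pred), 1L, 1L)
  if (is.matrix(target)) dim(target) <- c(dim(target), 1L, 1L)
  if (!identical(dim(pred), dim(target)))
    stop_invalid("pred and target shapes differ")
  n <- length(pred)
  diff <- pred - target
  loss <- weights$pixel * mean(abs(diff))
  dpred <- if (grad) weights$pixel * sign(diff) / n else NULL
  if (weights$perceptual > 0) {
    if (is.null(perceptual))
      stop_invalid("perceptual extractor parameters required")
    fp <- perceptual_features(perceptual, pred)
    ft <- perceptual_features(perceptual, target)
    fdiff <- fp$out - ft$out
    loss <- loss + weights$perceptual * mean(fdiff^2)
    if (grad) {
      dfeat <- weights$perceptual * 2 * fdiff / length(fdiff)
      dpred <- dpred + perceptual_backprop(perceptual, fp, dfeat)
    }
  }
  if (grad) list(loss = loss, dpred = dpred) else loss
}

# fixed extractor: conv(1->8) -> ReLU -> 2x2 mean pool -> conv(8->8) -> ReLU
perceptual_features <- function(perc, x) {
  f1 <- conv_fw(perc$c1, x)
  r1 <- relu_fw(f1$out)
  p1 <- avgpool_fw(r1$out)
  f2 <- conv_fw(perc$c2, p1$out)
  r2 <- relu_fw(f2$out)
  list(out = r2$out, cache = list(c1 = f1$cache, r1 = r1$cache,
                                  p1 = p1$cache, c2 = f2$cache,
                                  r2 = r2$cache))
}

perceptual_backprop <- function(perc, fw, dfeat) {
  d <- relu_bw(fw$cache$r2, dfeat)
  g2 <- conv_bw(perc$c2, fw$cache$c2, d)
  d <- avgpool_bw(fw$cache$p1, g2$dx)
  d <- relu_bw(fw$cache$r1, d)
  g1 <- conv_bw(perc$c1, fw$cache$c1, d)
  g1$dx
}

adam_init <- function(params)
  list(m = tree_apply_grads(params, params, function(p, g, path) p * 0),
       v = tree_apply_grads(params, params, function(p, g, path) p * 0),
       t = 0L)

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  state$m <- tree_update(state$m, grads, function(m, g) beta1 * m +
                           (1 - beta1) * g)
  state$v <- tree_update(state$v, grads, function(v, g) beta2 * v +
                           (1 - beta2) * g^2)
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  params <- tree_apply3(params, state$m, state$v, function(p, m, v)
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps))
  list(params = params, state = state)
}

tree_update <- function(a, b, f) {
  rec <- function(p, g) {
    if (inherits(p, c("conv_params", "bn_params", "proj_params"))) {
      for (nm in trainable_names(p)) p[[nm]] <- f(p[[nm]], g[[nm]])
      p
    } else if (is.list(p)) {
      for (nm in names(p)) p[[nm]] <- rec(p[[nm]], g[[nm]])
      p
    } else p
  }
  rec(a, b)
}

tree_apply3 <- function(a, b, c, f) {
  rec <- function(p, m, v) {
    if (inherits(p, c("conv_params", "bn_params", "proj_params"))) {
      for (nm in trainable_names(p)) p[[nm]] <- f(p[[nm]], m[[nm]], v[[nm]])
      p
    } else if (is.list(p)) {
      for (nm in names(p)) p[[nm]] <- rec(p[[nm]], m[[nm]], v[[nm]])
      p
    } else p
  }
  rec(a, b, c)
}

images_to_tensor <- function(imgs) {
  mats <- lapply(imgs, function(im) as_pixels(im) / 255)
  d <- dim(mats[[1]])
  array(unlist(mats), dim = c(d[1], d[2], 1L, length(mats)))
}

#' Train the restoration network
#'
#' Mini-batch Adam on the pixel + perceptual loss for up to
#' `config$epochs` epochs, recording per-epoch training and validation
#' loss and retaining the weights with minimum validation loss (the
#' initial weights when `epochs = 0`). Fully reproducible given the
#' config seed.
#'
#' @param model A `runet_model`.
#' @param data A `paired_dataset` (see [make_paired_dataset()]) or a list
#'   with `sparse`, `dense` image lists and `split` index sets.
#' @param factor Which sparse factor of the dataset to train on (defaults
#'   to the first).
#' @param verbose Print per-epoch losses.
#' @return The trained `runet_model` with populated `history`.
#' @export
train_runet <- function(model, data, factor = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "runet_model"))
  pairs <- dataset_pairs(data, factor)
  tr <- data$split$train
  va <- data$split$val
  if (length(tr) == 0L) stop_invalid("empty training split")
  cfg <- model$config
  xs <- images_to_tensor(pairs$sparse)
  ys <- images_to_tensor(pairs$dense)
  check_input_size(model, dim(xs))
  local_rng(cfg$seed + 1L)
  opt <- adam_init(model$params)
  best <- list(val = Inf, params = model$params)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(tr)
    nb <- ceiling(length(ord) / cfg$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      idx <- ord[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size,
                                                    length(ord))]
      x <- xs[, , , idx, drop = FALSE]
      y <- ys[, , , idx, drop = FALSE]
      fw <- runet_fw(model, x, training = TRUE)
      model <- fw$model               # BN running stats advance
      l <- runet_loss(fw$out, y, cfg$loss_weights, model$perceptual,
                      grad = TRUE)
      if (!is.finite(l$loss)) stop("non-finite training loss; aborting")
      bw <- runet_bw(model, fw$cache, l$dpred)
      st <- adam_step(model$params, bw$grads, opt, cfg$learning_rate)
      model$params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + l$loss * length(idx)
    }
    ep_loss <- ep_loss / length(ord)
    vl <- if (length(va) > 0) {
      # chunked so validation never holds full-resolution caches for the
      # whole split at once
      tot <- 0
      for (b0 in seq(1, length(va), by = cfg$batch_size)) {
        idx <- va[b0:min(b0 + cfg$batch_size - 1, length(va))]
        fwv <- runet_fw(model, xs[, , , idx, drop = FALSE],
                        training = FALSE)
        tot <- tot + length(idx) *
          runet_loss(fwv$out, ys[, , , idx, drop = FALSE],
                     cfg$loss_weights, model$perceptual)
      }
      tot / length(va)
    } else NA_real_
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %d: train %.5f val %.5f", ep, ep_loss, vl))
    if (is.finite(vl) && vl < best$val) best <- list(val = vl,
                                                     params = model$params)
  }
  if (is.finite(best$val)) model$params <- best$params
  model$history <- hist
  model
}

#' Restore a sparse-array B-mode image
#'
#' Normalizes to \[0, 1\], runs the network in inference mode (BN running
#' statistics), and rescales to a clamped 8-bit frame of the same shape.
#'
#' @param object A `runet_model`.
#' @param sparse A `bmode_image` or integer matrix in \[0, 255\].
#' @param ... Unused.
#' @return A `bmode_image` when given one, else an integer matrix.
#' @export
predict.runet_model <- function(object, sparse, ...) {
  px <- as_pixels(sparse)
  x <- array(px / 255, dim = c(dim(px), 1L, 1L))
  out <- runet_fw(object, x, training = FALSE)$out
  res <- matrix(as.integer(floor(pmin(pmax(out[, , 1, 1], 0), 1) * 255 +
                                   0.5)), nrow(px), ncol(px))
  if (inherits(sparse, "bmode_image")) {
    sparse$pixels <- res
    sparse$provenance$restored <- TRUE
    sparse
  } else res
}

#' Save / load a model checkpoint (HDF5)
#'
#' Weights (including BN running statistics), the fixed perceptual
#' extractor, config and training history are stored; loading followed by
#' prediction is bit-identical to the pre-save model.
#'
#' @param model A `runet_model`.
#' @param path Checkpoint `.h5` path.
#' @return `path` invisibly (save); a `runet_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  leaves <- c(tree_leaves(list(params = model$params)),
              tree_leaves(list(perceptual = model$perceptual)))
  rhdf5::h5createGroup(path, "weights")
  made <- "weights"
  for (nm in names(leaves)) {
    ds <- paste0("weights", gsub("/+", "/", nm))
    parts <- strsplit(ds, "/")[[1]]
    for (k in seq_len(length(parts) - 1L)[-1]) {
      grp <- paste(parts[seq_len(k)], collapse = "/")
      if (!grp %in% made) {
        rhdf5::h5createGroup(path, grp)
        made <- c(made, grp)
      }
    }
    rhdf5::h5write(leaves[[nm]], path, ds)
  }
  cfg <- model$config
  rhdf5::h5createGroup(path, "config")
  for (nm in setdiff(names(cfg), "loss_weights"))
    rhdf5::h5write(cfg[[nm]], path, paste0("config/", nm))
  rhdf5::h5write(as.numeric(unlist(cfg$loss_weights)), path,
                 "config/loss_weights")
  rhdf5::h5createGroup(path, "history")
  rhdf5::h5write(model$history$epoch, path, "history/epoch")
  rhdf5::h5write(model$history$train_loss, path, "history/train_loss")
  rhdf5::h5write(model$history$val_loss, path, "history/val_loss")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  lw <- as.numeric(rhdf5::h5read(path, "config/loss_weights"))
  cfg <- runet_config(
    depth = as.integer(rhdf5::h5read(path, "config/depth")),
    base_channels = as.integer(rhdf5::h5read(path, "config/base_channels")),
    loss_weights = list(pixel = lw[1], perceptual = lw[2]),
    epochs = as.integer(rhdf5::h5read(path, "config/epochs")),
    batch_size = as.integer(rhdf5::h5read(path, "config/batch_size")),
    learning_rate = as.numeric(rhdf5::h5read(path, "config/learning_rate")),
    seed = as.integer(rhdf5::h5read(path, "config/seed")),
    perceptual_seed = as.integer(rhdf5::h5read(path,
                                               "config/perceptual_seed")))
  model <- build_runet(cfg)
  fill <- function(p, path_prefix) {
    if (inherits(p, c("conv_params", "bn_params", "proj_params"))) {
      for (nm in names(p)) {
        v <- rhdf5::h5read(path, paste0(path_prefix, "/", nm))
        if (!is.null(dim(p[[nm]]))) dim(v) <- dim(p[[nm]])
        else v <- as.numeric(v)
        p[[nm]] <- v
      }
      p
    } else if (is.list(p)) {
      for (nm in names(p)) p[[nm]] <- fill(p[[nm]],
                                           paste0(path_prefix, "/", nm))
      p
    } else p
  }
  model$params <- fill(model$params, "weights/params")
  model$perceptual <- fill(model$perceptual, "weights/perceptual")
  model$history <- data.frame(
    epoch = as.integer(rhdf5::h5read(path, "history/epoch")),
    train_loss = as.numeric(rhdf5::h5read(path, "history/train_loss")),
    val_loss = as.numeric(rhdf5::h5read(path, "history/val_loss")))
  rhdf5::h5closeAll()
  model
}
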