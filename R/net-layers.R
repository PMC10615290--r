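# Minimal conv-net layer zoo with hand-written backprop. Tensors are R
# arrays of dim (H, W, C, N); conv kernels are 3x3, stride 1, padding 1
# (C++ im2col + BLAS gemm). Only what the restoration network needs.

conv_init <- function(c_in, c_out) {
  w <- array(rnorm(9 * c_in * c_out, sd = sqrt(2 / (9 * c_in))),
             dim = c(3, 3, c_in, c_out))
  structure(list(w = w, b = numeric(c_out)), class = "conv_params")
}

conv_zero <- function(c_in, c_out)
  structure(list(w = array(0, c(3, 3, c_in, c_out)), b = numeric(c_out)),
            class = "conv_params")

conv_fw <- function(p, x) {
  out <- conv2d_fw(x, p$w, p$b)
  list(out = out, cache = x)
}

conv_bw <- function(p, cache, dout) {
  g <- conv2d_bw(cache, p$w, dout)
  list(dx = g$dx, grads = structure(list(w = g$dw, b = g$db),
                                    class = "conv_params"))
}

bn_init <- function(c) {
  structure(list(gamma = rep(1, c), beta = numeric(c),
                 run_mean = numeric(c), run_var = rep(1, c)),
            class = "bn_params")
}

# batch statistics over (H, W, N) per channel; running stats for inference
bn_fw <- function(p, x, training, eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  hw <- d[1] * d[2]
  m <- matrix(x, nrow = hw)                 # cols indexed by (c, n)
  cidx <- rep(seq_len(d[3]), times = d[4])
  if (training) {
    cm <- colMeans(m)
    mu <- as.numeric(tapply(cm, cidx, mean))
    cv <- colMeans(m^2)
    ex2 <- as.numeric(tapply(cv, cidx, mean))
    va <- pmax(ex2 - mu^2, 0)
    p$run_mean <- (1 - momentum) * p$run_mean + momentum * mu
    p$run_var <- (1 - momentum) * p$run_var + momentum * va
  } else {
    mu <- p$run_mean
    va <- p$run_var
  }
  invstd <- 1 / sqrt(va + eps)
  xhat <- sweep(m, 2, mu[cidx], "-")
  xhat <- sweep(xhat, 2, invstd[cidx], "*")
  y <- sweep(xhat, 2, p$gamma[cidx], "*")
  y <- sweep(y, 2, p$beta[cidx], "+")
  out <- array(y, dim = d)
  list(out = out, params = p,
       cache = list(xhat = xhat, invstd = invstd, cidx = cidx, dim = d,
                    training = training))
}

bn_bw <- function(p, cache, dout) {
  d <- cache$dim
  hw <- d[1] * d[2]
  dm <- matrix(dout, nrow = hw)
  cidx <- cache$cidx
  xhat <- cache$xhat
  colsum_by_c <- function(mat) {
    cs <- colSums(mat)
    as.numeric(tapply(cs, cidx, sum))
  }
  dgamma <- colsum_by_c(dm * xhat)
  dbeta <- colsum_by_c(dm)
  m_count <- hw * d[4]
  dxhat <- sweep(dm, 2, p$gamma[cidx], "*")
  if (cache$training) {
    sum_dxhat <- colsum_by_c(dxhat)
    sum_dxhat_xhat <- colsum_by_c(dxhat * xhat)
    t2 <- sweep(dxhat * m_count, 2, sum_dxhat[cidx], "-")
    t3 <- xhat * rep(sum_dxhat_xhat[cidx], each = hw)
    dx <- sweep(t2 - t3, 2, cache$invstd[cidx] / m_count, "*")
  } else {
    dx <- sweep(dxhat, 2, cache$invstd[cidx], "*")
  }
  list(dx = array(dx, dim = d),
       grads = structure(list(gamma = dgamma, beta = dbeta,
                              run_mean = numeric(length(dgamma)),
                              run_var = numeric(length(dgamma))),
                         class = "bn_params"))
}

relu_fw <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bw <- function(cache, dout) dout * cache

# 2x2 mean pooling; halves spatial size
avgpool_fw <- function(x) {
  d <- dim(x)
  io <- seq(1, d[1], by = 2); ie <- io + 1
  jo <- seq(1, d[2], by = 2); je <- jo + 1
  out <- (x[io, jo, , , drop = FALSE] + x[ie, jo, , , drop = FALSE] +
            x[io, je, , , drop = FALSE] + x[ie, je, , , drop = FALSE]) / 4
  list(out = out, cache = d)
}

avgpool_bw <- function(cache, dout) {
  d <- cache
  dx <- array(0, d)
  g <- dout / 4
  io <- seq(1, d[1], by = 2); jo <- seq(1, d[2], by = 2)
  dx[io, jo, , ] <- g
  dx[io + 1, jo, , ] <- g
  dx[io, jo + 1, , ] <- g
  dx[io + 1, jo + 1, , ] <- g
  dx
}

# channel-to-space rearrangement (H, W, C r^2, N) -> (rH, rW, C, N);
# input channel (c-1) r^2 + (di-1) r + dj feeds output phase (di, dj).
pixel_shuffle <- function(x, r) {
  d <- dim(x)
  if (d[3] %% (r * r) != 0L)
    stop_invalid("channel count not divisible by r^2")
  if (r == 1L) return(x)
  cout <- d[3] %/% (r * r)
  out <- array(0, c(d[1] * r, d[2] * r, cout, d[4]))
  for (c in seq_len(cout)) {
    for (di in seq_len(r)) {
      for (dj in seq_len(r)) {
        k <- (c - 1L) * r * r + (di - 1L) * r + dj
        out[seq(di, d[1] * r, by = r), seq(dj, d[2] * r, by = r), c, ] <-
          x[, , k, ]
      }
    }
  }
  out
}

pixel_unshuffle <- function(y, r) {
  d <- dim(y)
  if (d[1] %% r != 0L || d[2] %% r != 0L)
    stop_invalid("spatial size not divisible by r")
  if (r == 1L) return(y)
  x <- array(0, c(d[1] %/% r, d[2] %/% r, d[3] * r * r, d[4]))
  for (c in seq_len(d[3])) {
    for (di in seq_len(r)) {
      for (dj in seq_len(r)) {
        k <- (c - 1L) * r * r + (di - 1L) * r + dj
        x[, , k, ] <- y[seq(di, d[1], by = r), seq(dj, d[2], by = r), c, ]
      }
    }
  }
  x
}

# 1x1 channel projection used only when a residual block must match
# channel counts: y = x . P  (per pixel)
proj_init <- function(c_in, c_out) {
  structure(list(p = matrix(rnorm(c_in * c_out, sd = sqrt(1 / c_in)),
                            c_in, c_out)), class = "proj_params")
}

proj_fw <- function(p, x) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  y <- m %*% p$p
  out <- aperm(array(y, c(d[1], d[2], d[4], ncol(p$p))), c(1, 2, 4, 3))
  list(out = out, cache = list(m = m, dim = d))
}

proj_bw <- function(p, cache, dout) {
  d <- cache$dim
  dm <- matrix(aperm(dout, c(1, 2, 4, 3)), ncol = ncol(p$p))
  dx_m <- dm %*% t(p$p)
  dx <- aperm(array(dx_m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, grads = structure(list(p = t(cache$m) %*% dm),
                                  class = "proj_params"))
}

# residual block: Conv -> BN -> ReLU -> Conv -> BN, plus identity skip
resblock_init <- function(c_in, channels) {
  p <- list(c1 = conv_init(c_in, channels), b1 = bn_init(channels),
            c2 = conv_init(channels, channels), b2 = bn_init(channels))
  if (c_in != channels) p$proj <- proj_init(c_in, channels)
  structure(p, class = "resblock_params")
}

resblock_fw <- function(p, x, training) {
  f1 <- conv_fw(p$c1, x)
  f2 <- bn_fw(p$b1, f1$out, training)
  p$b1 <- f2$params
  f3 <- relu_fw(f2$out)
  f4 <- conv_fw(p$c2, f3$out)
  f5 <- bn_fw(p$b2, f4$out, training)
  p$b2 <- f5$params
  if (!is.null(p$proj)) {
    fp <- proj_fw(p$proj, x)
    sk <- fp$out
    pc <- fp$cache
  } else {
    sk <- x
    pc <- NULL
  }
  list(out = f5$out + sk, params = p,
       cache = list(c1 = f1$cache, b1 = f2$cache, r1 = f3$cache,
                    c2 = f4$cache, b2 = f5$cache, proj = pc))
}

resblock_bw <- function(p, cache, dout) {
  g5 <- bn_bw(p$b2, cache$b2, dout)
  g4 <- conv_bw(p$c2, cache$c2, g5$dx)
  dr <- relu_bw(cache$r1, g4$dx)
  g2 <- bn_bw(p$b1, cache$b1, dr)
  g1 <- conv_bw(p$c1, cache$c1, g2$dx)
  dx <- g1$dx
  grads <- list(c1 = g1$grads, b1 = g2$grads, c2 = g4$grads, b2 = g5$grads)
  if (!is.null(p$proj)) {
    gp <- proj_bw(p$proj, cache$proj, dout)
    dx <- dx + gp$dx
    grads$proj <- gp$grads
  } else {
    dx <- dx + dout
  }
  list(dx = dx, grads = structure(grads, class = "resblock_params"))
}

# --- parameter-tree utilities (Adam skips BN running stats) -----------------

trainable_names <- function(p) {
  if (inherits(p, "bn_params")) c("gamma", "beta") else names(p)
}

tree_apply_grads <- function(params, grads, fun) {
  # fun(param_leaf, grad_leaf, path) -> new param leaf
  rec <- function(p, g, path) {
    if (inherits(p, c("conv_params", "bn_params", "proj_params"))) {
      for (nm in trainable_names(p))
        p[[nm]] <- fun(p[[nm]], g[[nm]], paste0(path, "/", nm))
      p
    } else if (is.list(p)) {
      for (nm in names(p)) p[[nm]] <- rec(p[[nm]], g[[nm]],
                                          paste0(path, "/", nm))
      p
    } else p
  }
  rec(params, grads, "")
}

tree_leaves <- function(params) {
  out <- list()
  rec <- function(p, path) {
    if (inherits(p, c("conv_params", "bn_params", "proj_params"))) {
      for (nm in names(p))
        out[[paste0(path, "/", nm)]] <<- p[[nm]]
    } else if (is.list(p)) {
      for (nm in names(p)) rec(p[[nm]], paste0(path, "/", nm))
    }
  }
  rec(params, "")
  out
}
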