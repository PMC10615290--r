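# Shared fixtures and independent reference implementations. The
# reference code here is deliberately naive (scalar loops, closed forms)
# so it exercises none of the package's vectorized/compiled paths.

small_array <- function(n = 8L, pitch = 0.4e-3)
  make_linear_array(n, pitch, 28e6, 0.6)

short_seq <- function(angles = c(-5, 0, 5))
  plane_wave_sequence(angles_deg = angles)

# strict 8-neighborhood local maxima (row, col) of a matrix
local_maxima <- function(e) {
  n <- nrow(e); m <- ncol(e)
  inner <- e[2:(n - 1), 2:(m - 1)]
  res <- inner > e[1:(n - 2), 2:(m - 1)] & inner > e[3:n, 2:(m - 1)] &
    inner > e[2:(n - 1), 1:(m - 2)] & inner > e[2:(n - 1), 3:m] &
    inner > e[1:(n - 2), 1:(m - 2)] & inner > e[3:n, 3:m] &
    inner > e[1:(n - 2), 3:m] & inner > e[3:n, 1:(m - 2)]
  which(res, arr.ind = TRUE) + 1L
}

# 4-connected component count of a logical mask (naive flood fill)
n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (!mask[q] || lab[q] != 0L) next
      lab[q] <- cur
      i <- (q - 1L) %% nrow(mask) + 1L
      j <- (q - 1L) %/% nrow(mask) + 1L
      if (i > 1) queue <- c(queue, q - 1L)
      if (i < nrow(mask)) queue <- c(queue, q + 1L)
      if (j > 1) queue <- c(queue, q - nrow(mask))
      if (j < ncol(mask)) queue <- c(queue, q + nrow(mask))
    }
  }
  cur
}

# naive delay-and-sum reference: per-pixel, per-element scalar loop over
# the same complex-baseband traces the package beamformer consumes
naive_das <- function(rf, angle_index, grid, array, upsample = 4L) {
  fs <- rf$sampling_rate * upsample
  f0 <- array$center_freq
  tr <- t(matrix(rf$traces[angle_index, , ], nrow = array$n_elements))
  bb <- sparus:::analytic_baseband(tr, rf$sampling_rate, f0, upsample,
                                   rf$t0)
  th <- rf$sequence$angles_deg[angle_index] * pi / 180
  c0 <- rf$sequence$sound_speed
  gx <- seq(grid$lateral_extent[1], grid$lateral_extent[2],
            length.out = grid$n_cols)
  gz <- seq(grid$depth_range[1], grid$depth_range[2],
            length.out = grid$n_rows)
  idx <- which(array$active_mask)
  na <- length(idx)
  wall <- numeric(array$n_elements)
  wall[idx] <- if (na == 1) 1 else
    0.5 * (1 - cos(2 * pi * (seq_len(na) - 1) / (na - 1)))
  img <- matrix(0 + 0i, grid$n_rows, grid$n_cols)
  for (j in seq_len(grid$n_cols)) {
    for (i in seq_len(grid$n_rows)) {
      acc <- 0 + 0i
      for (e in idx) {
        tau <- (gz[i] * cos(th) + gx[j] * sin(th)) / c0 +
          sqrt((gx[j] - array$element_positions[e])^2 + gz[i]^2) / c0
        fi <- (tau - rf$t0) * fs
        k <- floor(fi)
        if (k < 0 || k >= nrow(bb) - 1) next
        fr <- fi - k
        v <- (1 - fr) * bb[k + 1, e] + fr * bb[k + 2, e]
        acc <- acc + wall[e] * v * exp(2i * pi * f0 * tau)
      }
      img[i, j] <- acc
    }
  }
  img
}

# zero the inner path of a residual block so it computes the identity
zeroed_resblock <- function(c_in, channels, seed = 1L) {
  p <- residual_block_params(c_in, channels, seed)
  p$c1$w[] <- 0; p$c1$b[] <- 0
  p$c2$w[] <- 0; p$c2$b[] <- 0
  p
}
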