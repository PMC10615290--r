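#' Reconstruction image grid
#'
#' Cartesian pixel grid for beamforming: rows index depth (increasing
#' downward), columns index lateral position (left to right). Defaults
#' match the 512 x 512 frame over the dense aperture (+-4.48 mm lateral,
#' 0.5-15 mm depth).
#'
#' @param n_rows,n_cols Pixel counts.
#' @param lateral_extent Length-2 lateral bounds in meters.
#' @param depth_range Length-2 depth bounds in meters.
#' @return An `image_grid`.
#' @export
image_grid <- function(n_rows = 512L, n_cols = 512L,
                       lateral_extent = c(-4.48e-3, 4.48e-3),
                       depth_range = c(0.5e-3, 15e-3)) {
  if (n_rows < 2L || n_cols < 2L) stop_invalid("grid needs >= 2 pixels/axis")
  if (diff(lateral_extent) <= 0 || diff(depth_range) <= 0)
    stop_invalid("grid extents must be increasing")
  if (depth_range[1] <= 0) stop_invalid("depths must be positive")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 lateral_extent = as.numeric(lateral_extent),
                 depth_range = as.numeric(depth_range)),
            class = "image_grid")
}

grid_lateral <- function(grid)
  seq(grid$lateral_extent[1], grid$lateral_extent[2],
      length.out = grid$n_cols)

grid_depth <- function(grid)
  seq(grid$depth_range[1], grid$depth_range[2], length.out = grid$n_rows)

#' Pixel spacing of a grid
#' @param grid An `image_grid`.
#' @return c(depth, lateral) spacing in meters.
#' @export
grid_spacing <- function(grid)
  c(depth = diff(grid$depth_range) / (grid$n_rows - 1),
    lateral = diff(grid$lateral_extent) / (grid$n_cols - 1))

#' Two-way plane-wave delay for a pixel
#'
#' `tau_tx + tau_rx` with `tau_tx = (z cos(theta) + x sin(theta)) / c`
#' (plane wave timed to t = 0 at the array-plane center) and
#' `tau_rx = sqrt((x - element_x)^2 + z^2) / c`.
#'
#' @param angle Steering angle in radians.
#' @param pixel c(lateral, depth) in meters; depth > 0.
#' @param element_x Receive element lateral position, meters.
#' @param c Sound speed in m/s.
#' @return Delay in seconds.
#' @export
pixel_delay <- function(angle, pixel, element_x, c = 1480) {
  if (c <= 0) stop_invalid("sound speed must be positive")
  x <- pixel[1]; z <- pixel[2]
  if (z <= 0) stop_invalid("pixel depth must be positive")
  (z * cos(angle) + x * sin(angle)) / c +
    sqrt((x - element_x)^2 + z^2) / c
}

#' Analytic signal along the time axis
#'
#' Hilbert-transform based one-sided spectrum; input is a real matrix with
#' time along rows, one trace per column.
#' @param x Real matrix (n_samples x n_traces).
#' @return Complex matrix of the same shape.
#' @export
analytic_signal <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  mvfft(mvfft(x) * h, inverse = TRUE) / n
}

# analytic signal, band-limited r-fold upsampling and baseband
# demodulation in one padded-FFT pipeline (padding to a power of two for
# FFT speed; the traces are quiescent at the window end)
analytic_baseband <- function(tr, fs, f0, r, t0) {
  n <- nrow(tr)
  N <- stats::nextn(n, 2)
  X <- rbind(tr, matrix(0, N - n, ncol(tr)))
  Z <- mvfft(X)
  h <- numeric(N)
  h[1] <- 1
  h[2:(N / 2)] <- 2
  h[N / 2 + 1] <- 1
  big <- matrix(0 + 0i, N * r, ncol(tr))
  big[1:(N / 2 + 1), ] <- Z[1:(N / 2 + 1), ] * h[1:(N / 2 + 1)]
  fine <- mvfft(big, inverse = TRUE)[seq_len(n * r), , drop = FALSE] / N
  tfine <- t0 + (seq_len(n * r) - 1) / (fs * r)
  fine * exp(-2i * pi * f0 * tfine)
}

#' Hanning apodization over the active aperture
#'
#' Symmetric window with zero endpoints spanning the active elements only;
#' returns one weight per physical element (zero where inactive).
#' @param array A `transducer_array`.
#' @return Numeric weight vector of length `n_elements`.
#' @export
hanning_apodization <- function(array) {
  w <- numeric(array$n_elements)
  idx <- which(array$active_mask)
  na <- length(idx)
  w[idx] <- if (na == 1L) 1 else
    0.5 * (1 - cos(2 * pi * (seq_len(na) - 1) / (na - 1)))
  w
}

#' Delay-and-sum beamforming for one steering angle
#'
#' Sums analytic-signal samples of each active element at its two-way
#' pixel delay (linear sub-sample interpolation; delays outside the RF
#' window contribute zero), weighted by a Hanning window spanning the
#' active aperture. Receive-side apodization only.
#'
#' @param rf An `rf_channel_data`.
#' @param angle_index 1-based index into the sequence's angle list.
#' @param grid An `image_grid`.
#' @param array Optional array override; defaults to the one stored in
#'   `rf`. Its active mask selects the receive aperture.
#' @param upsample Band-limited upsampling factor applied to the complex
#'   baseband traces before linear interpolation (4 keeps interpolation
#'   error ~-45 dB at 62.5 MHz sampling).
#' @return Complex matrix (n_rows x n_cols).
#' @export
das_single_angle <- function(rf, angle_index, grid, array = rf$array,
                             upsample = 4L) {
  stopifnot(inherits(rf, "rf_channel_data"), inherits(grid, "image_grid"))
  n_ang <- dim(rf$traces)[1]
  if (angle_index < 1L || angle_index > n_ang)
    stop_invalid("angle_index out of range")
  if (dim(rf$traces)[2] != array$n_elements)
    stop_invalid("rf does not match array")
  c0 <- rf$sequence$sound_speed
  fs <- rf$sampling_rate
  n_samp <- dim(rf$traces)[3]
  max_delay <- 2 * grid$depth_range[2] / c0 +
    max(abs(grid$lateral_extent)) / c0
  if (rf$t0 + (n_samp - 1) / fs < 2 * grid$depth_range[2] / c0)
    stop_invalid("grid deeper than RF window")
  # (samples x elements) real block -> analytic signal -> complex baseband
  tr <- t(matrix(rf$traces[angle_index, , ], nrow = array$n_elements))
  f0 <- array$center_freq
  bb <- analytic_baseband(tr, fs, f0, as.integer(upsample), rf$t0)
  fs <- fs * upsample
  w <- hanning_apodization(array)
  das_angle(bb, array$element_positions, w, rf$t0, fs,
            rf$sequence$angles_deg[angle_index] * pi / 180,
            grid_lateral(grid), grid_depth(grid), c0, f0)
}

#' Coherent compounding over steering angles
#'
#' Arithmetic mean of per-angle complex images.
#' @param per_angle_images Non-empty list of congruent complex matrices.
#' @return Complex matrix.
#' @export
compound_angles <- function(per_angle_images) {
  if (length(per_angle_images) == 0L) stop_invalid("empty image list")
  d <- dim(per_angle_images[[1]])
  for (im in per_angle_images)
    if (!identical(dim(im), d)) stop_invalid("image shape mismatch")
  Reduce(`+`, per_angle_images) / length(per_angle_images)
}

# beamform one RF block against several receive apertures, computing the
# per-angle baseband traces once (make_paired_dataset hot path)
beamform_multi <- function(rf, grid, arrays, dynamic_range_db = 50,
                           upsample = 4L) {
  f0 <- rf$array$center_freq
  fs <- rf$sampling_rate
  n_ang <- dim(rf$traces)[1]
  acc <- lapply(arrays, function(a) 0)
  for (ai in seq_len(n_ang)) {
    tr <- t(matrix(rf$traces[ai, , ], nrow = rf$array$n_elements))
    bb <- analytic_baseband(tr, fs, f0, as.integer(upsample), rf$t0)
    for (k in seq_along(arrays)) {
      arr <- arrays[[k]]
      w <- hanning_apodization(arr)
      acc[[k]] <- acc[[k]] + das_angle(
        bb, arr$element_positions, w, rf$t0, fs * upsample,
        rf$sequence$angles_deg[ai] * pi / 180,
        grid_lateral(grid), grid_depth(grid), rf$sequence$sound_speed, f0)
    }
  }
  lapply(acc, function(img) to_bmode(img / n_ang, dynamic_range_db,
                                     grid = grid,
                                     provenance = rf$provenance))
}

#' Beamform all angles and compound
#'
#' Convenience wrapper: per-angle delay-and-sum followed by coherent
#' compounding and 8-bit log compression.
#' @param rf An `rf_channel_data`.
#' @param grid An `image_grid`.
#' @param array Optional receive-array override.
#' @param dynamic_range_db Display dynamic range in dB.
#' @return A `bmode_image`.
#' @export
beamform <- function(rf, grid = image_grid(), array = rf$array,
                     dynamic_range_db = 50) {
  n_ang <- dim(rf$traces)[1]
  imgs <- lapply(seq_len(n_ang), function(a)
    das_single_angle(rf, a, grid, array))
  to_bmode(compound_angles(imgs), dynamic_range_db, grid = grid,
           provenance = rf$provenance)
}

#' Envelope detection and log compression to 8-bit
#'
#' `dB = 20 log10(|img| / max |img|)`, clipped to `[-DR, 0]` and mapped
#' linearly to `[0, 255]` (half-up rounding; the brightest pixel of a
#' non-zero frame maps to 255). An all-zero input yields an all-zero frame
#' flagged in provenance.
#'
#' @param compounded Complex (or real) matrix.
#' @param dynamic_range_db Positive dynamic range in dB.
#' @param grid Optional `image_grid` carried for physical pixel spacing.
#' @param provenance Free-form list.
#' @return A `bmode_image` with integer `pixels` in `[0, 255]`.
#' @export
to_bmode <- function(compounded, dynamic_range_db = 50, grid = NULL,
                     provenance = list()) {
  if (dynamic_range_db <= 0) stop_invalid("dynamic range must be positive")
  env <- Mod(compounded)
  mx <- max(env)
  if (mx == 0) {
    px <- matrix(0L, nrow(env), ncol(env))
    provenance$all_zero <- TRUE
  } else {
    db <- 20 * log10(pmax(env / mx, 10^(-dynamic_range_db / 20 - 2)))
    db <- pmin(pmax(db, -dynamic_range_db), 0)
    px <- matrix(as.integer(floor(255 * (db + dynamic_range_db) /
                                    dynamic_range_db + 0.5)),
                 nrow(env), ncol(env))
  }
  structure(list(pixels = px, grid = grid,
                 dynamic_range_db = dynamic_range_db,
                 provenance = provenance), class = "bmode_image")
}

#' Predicted lateral offset of a grating lobe
#'
#' For an on-axis scatterer at `depth`, the order-`k` grating lobe of an
#' aperture with effective pitch `p` appears at lateral offset
#' `depth * tan(asin(k * lambda / p))`, with `lambda = c / f0`. When
#' `k * lambda >= p` no real lobe exists and a
#' `sparus_no_grating_lobe` error is signaled.
#'
#' @param array A `transducer_array` (its active mask sets the effective
#'   pitch).
#' @param c Sound speed, m/s.
#' @param depth Depth of the on-axis target, meters.
#' @param order Grating-lobe order (>= 1).
#' @return Lateral offset in meters.
#' @export
grating_lobe_offset <- function(array, c = 1480, depth = 10e-3, order = 1L) {
  if (order < 1L) stop_invalid("order must be >= 1")
  lam <- c / array$center_freq
  p <- effective_pitch(array)
  s <- order * lam / p
  if (s >= 1)
    stop(structure(class = c("sparus_no_grating_lobe", "error", "condition"),
                   list(message = sprintf(
                     "order %d lobe is evanescent (k lambda / pitch = %.3f >= 1)",
                     order, s), call = sys.call())))
  depth * tan(asin(s))
}

#' Write / read an 8-bit B-mode frame as grayscale PNG
#' @param img A `bmode_image`.
#' @param path PNG path.
#' @return `path` invisibly (writer); a `bmode_image` (reader).
#' @export
write_bmode_png <- function(img, path) {
  png::writePNG(img$pixels / 255, path)
  invisible(path)
}

#' @rdname write_bmode_png
#' @param grid,dynamic_range_db Metadata to attach on read.
#' @export
read_bmode_png <- function(path, grid = NULL, dynamic_range_db = 50) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  structure(list(pixels = matrix(as.integer(round(m * 255)), nrow(m)),
                 grid = grid, dynamic_range_db = dynamic_range_db,
                 provenance = list(source = path)), class = "bmode_image")
}
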