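#' Trace length needed to beamform a grid
#'
#' Number of RF samples required so every pixel of `grid` lies inside the
#' trace window for all angles and elements (worst-case path plus pulse
#' tail). Pass the result as `n_samples` to [simulate_rf()] when the
#' imaging grid is deeper than the phantom's deepest scatterer.
#'
#' @param grid An `image_grid`.
#' @param array A `transducer_array`.
#' @param seq A `plane_wave_sequence`.
#' @return Integer sample count.
#' @export
rf_samples_for <- function(grid, array, seq = plane_wave_sequence()) {
  c0 <- seq$sound_speed
  sig <- pulse_sigma_t(array$center_freq, array$frac_bandwidth)
  zmax <- grid$depth_range[2]
  xmax <- max(abs(grid$lateral_extent))
  half_ap <- max(abs(array$element_positions))
  tau <- max(abs(sin(seq$angles_deg * pi / 180))) * xmax / c0 + zmax / c0 +
    sqrt((xmax + half_ap)^2 + zmax^2) / c0
  # 32 extra samples absorb the anti-alias filter's ringing tail
  as.integer(ceiling((tau + 4.5 * sig) * seq$sampling_rate) + 34)
}

#' Simulate plane-wave RF channel data
#'
#' Single-scattering time-of-flight model: for each steering angle, active
#' receive element and scatterer, an echo
#' `reflectivity * pulse(t - tau)` is added to that element's trace, with
#' `tau = (z cos(theta) + x sin(theta))/c + dist(element, scatterer)/c`
#' (ideal plane-wave transmit referenced to t = 0 at the array plane
#' center). Inactive elements produce identically zero traces. No
#' attenuation or time-gain compensation is applied; an optional cosine
#' element-directivity factor is off by default.
#'
#' @param phantom A `phantom`.
#' @param array A `transducer_array` (its `active_mask` governs both
#'   transmit and receive).
#' @param seq A `plane_wave_sequence` (checked against the array's
#'   Nyquist requirement).
#' @param n_samples Trace length; computed from the deepest scatterer when
#'   `NULL`. If supplied but too short for the deepest scatterer, an error
#'   names the required length.
#' @param directivity Apply a cosine obliquity factor per element.
#' @param antialias Model the DAQ's anti-alias filtering: echoes use the
#'   excitation pulse convolved with a zero-phase raised-cosine low pass
#'   (rolloff 0.8-1.0 of the Nyquist frequency), precomputed on a fine
#'   table. The default `TRUE` matches real converters; without it the
#'   36.4 MHz band edge of the 28 MHz / 0.6-bw pulse folds across the
#'   31.25 MHz Nyquist limit and sets an aliasing sidelobe floor near
#'   -25 dB.
#' @return An `rf_channel_data` with `traces` of dim
#'   `(n_angles, n_elements, n_samples)`, `t0 = 0`, `sampling_rate`, and
#'   provenance configs.
#' @export
simulate_rf <- function(phantom, array, seq = plane_wave_sequence(),
                        n_samples = NULL, directivity = FALSE,
                        antialias = TRUE) {
  stopifnot(inherits(phantom, "phantom"), inherits(array, "transducer_array"),
            inherits(seq, "plane_wave_sequence"))
  check_sequence_for_array(seq, array)
  c0 <- seq$sound_speed
  fs <- seq$sampling_rate
  sig <- pulse_sigma_t(array$center_freq, array$frac_bandwidth)
  ang <- seq$angles_deg * pi / 180
  x <- phantom$positions[, 1]; z <- phantom$positions[, 2]
  half_ap <- max(abs(array$element_positions))
  # worst-case arrival over angles/elements plus pulse tail
  tau_max <- max(vapply(ang, function(a)
    max((z * cos(a) + x * sin(a)) / c0 +
          sqrt((abs(x) + half_ap)^2 + z^2) / c0), numeric(1)))
  need <- ceiling((tau_max + 4.5 * sig) * fs) + 2L
  if (is.null(n_samples)) {
    n_samples <- as.integer(need)
  } else if (n_samples < need) {
    stop_invalid(sprintf(
      "n_samples = %d cannot hold the deepest scatterer; need >= %d",
      as.integer(n_samples), as.integer(need)))
  }
  if (antialias) {
    tab <- filtered_pulse_table(array$center_freq, array$frac_bandwidth, fs)
    traces <- rf_synthesize_tab(x, z, phantom$reflectivities,
                                array$element_positions,
                                as.integer(array$active_mask), ang,
                                c0, fs, 0, as.integer(n_samples),
                                tab$table, tab$dt, tab$t0,
                                isTRUE(directivity))
  } else {
    traces <- rf_synthesize(x, z, phantom$reflectivities,
                            array$element_positions,
                            as.integer(array$active_mask), ang,
                            c0, fs, 0, as.integer(n_samples),
                            array$center_freq, sig, isTRUE(directivity))
  }
  structure(list(traces = traces, t0 = 0, sampling_rate = fs,
                 array = array, sequence = seq,
                 provenance = phantom$metadata),
            class = "rf_channel_data")
}

# The converter anti-alias response: the excitation pulse filtered by a
# zero-phase raised-cosine low pass (rolloff 0.8-1.0 of the target
# Nyquist), tabulated on a fine grid so echoes can be synthesized
# directly at the decimated rate by table lookup (exact by linearity and
# shift invariance). Memoized per (f0, bw, fs).
.pulse_tables <- new.env(parent = emptyenv())

filtered_pulse_table <- function(center_freq, frac_bandwidth, fs) {
  key <- paste(center_freq, frac_bandwidth, fs)
  hit <- get0(key, envir = .pulse_tables)
  if (!is.null(hit)) return(hit)
  ov <- 64L
  dt <- 1 / (fs * ov)
  M <- 16384L
  tt <- (seq_len(M) - M / 2) * dt
  p <- excitation_pulse(tt, center_freq, frac_bandwidth)
  f <- (0:(M - 1)) * (fs * ov) / M
  f <- pmin(f, fs * ov - f)
  nyq <- fs / 2
  H <- ifelse(f <= 0.8 * nyq, 1,
              ifelse(f >= nyq, 0,
                     0.5 * (1 + cos(pi * (f - 0.8 * nyq) / (0.2 * nyq)))))
  pf <- Re(fft(fft(p) * H, inverse = TRUE) / M)
  # truncate at -60 dB: tails below that sit under the beamformer's
  # ~-45 dB interpolation floor and only inflate synthesis cost
  keep <- which(abs(pf) > max(abs(pf)) * 1e-3)
  out <- list(table = pf[keep[1]:keep[length(keep)]], dt = dt,
              t0 = tt[keep[1]])
  assign(key, out, envir = .pulse_tables)
  out
}

#' Write / read RF channel data (HDF5)
#'
#' Datasets `/traces`, `/t0`, `/sampling_rate`, with groups `/array` and
#' `/sequence` mirroring the configuration fields.
#' @param rf An `rf_channel_data`.
#' @param path Output `.h5` path.
#' @return `path`, invisibly (writer); an `rf_channel_data` (reader).
#' @export
write_rf_h5 <- function(rf, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(rf$traces, path, "traces")
  rhdf5::h5write(rf$t0, path, "t0")
  rhdf5::h5write(rf$sampling_rate, path, "sampling_rate")
  rhdf5::h5createGroup(path, "array")
  a <- rf$array
  rhdf5::h5write(a$n_elements, path, "array/n_elements")
  rhdf5::h5write(a$pitch, path, "array/pitch")
  rhdf5::h5write(a$center_freq, path, "array/center_freq")
  rhdf5::h5write(a$frac_bandwidth, path, "array/frac_bandwidth")
  rhdf5::h5write(as.integer(a$active_mask), path, "array/active_mask")
  rhdf5::h5createGroup(path, "sequence")
  s <- rf$sequence
  rhdf5::h5write(s$angles_deg, path, "sequence/angles_deg")
  rhdf5::h5write(s$sound_speed, path, "sequence/sound_speed")
  rhdf5::h5write(s$sampling_rate, path, "sequence/sampling_rate")
  rhdf5::h5write(s$prf, path, "sequence/prf")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_rf_h5
#' @export
read_rf_h5 <- function(path) {
  arr <- make_linear_array(
    n_elements = as.integer(rhdf5::h5read(path, "array/n_elements")),
    pitch = as.numeric(rhdf5::h5read(path, "array/pitch")),
    center_freq = as.numeric(rhdf5::h5read(path, "array/center_freq")),
    frac_bandwidth = as.numeric(rhdf5::h5read(path, "array/frac_bandwidth")))
  arr$active_mask <- as.logical(rhdf5::h5read(path, "array/active_mask"))
  sq <- plane_wave_sequence(
    angles_deg = as.numeric(rhdf5::h5read(path, "sequence/angles_deg")),
    sound_speed = as.numeric(rhdf5::h5read(path, "sequence/sound_speed")),
    sampling_rate = as.numeric(rhdf5::h5read(path, "sequence/sampling_rate")),
    prf = as.numeric(rhdf5::h5read(path, "sequence/prf")))
  out <- structure(list(
    traces = rhdf5::h5read(path, "traces"),
    t0 = as.numeric(rhdf5::h5read(path, "t0")),
    sampling_rate = as.numeric(rhdf5::h5read(path, "sampling_rate")),
    array = arr, sequence = sq, provenance = list()),
    class = "rf_channel_data")
  rhdf5::h5closeAll()
  out
}
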