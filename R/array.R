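#' @useDynLib sparus, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft mvfft rnorm runif sd qt pt cor t.test setNames
NULL

stop_invalid <- function(...) {
  stop(structure(class = c("sparus_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Linear transducer array
#'
#' Builds a uniformly pitched linear array centered on x = 0, with all
#' elements active. The defaults describe a 128-element, 70 um pitch,
#' 28 MHz high-frequency probe with a -6 dB fractional bandwidth of 0.6.
#'
#' @param n_elements Number of physical elements (>= 2).
#' @param pitch Center-to-center element spacing in meters.
#' @param center_freq Transmit center frequency in Hz.
#' @param frac_bandwidth -6 dB fractional bandwidth (0 < bw < 2).
#' @return A `transducer_array` with element positions (meters, symmetric
#'   about 0), an all-`TRUE` `active_mask`, and the geometry fields.
#' @export
#' @examples
#' arr <- make_linear_array()
#' diff(range(arr$element_positions))  # 8.89 mm aperture
make_linear_array <- function(n_elements = 128L, pitch = 70e-6,
                              center_freq = 28e6, frac_bandwidth = 0.6) {
  if (length(n_elements) != 1L || n_elements < 2L)
    stop_invalid("n_elements must be a single count >= 2")
  if (pitch <= 0) stop_invalid("pitch must be positive")
  if (center_freq <= 0) stop_invalid("center_freq must be positive")
  if (frac_bandwidth <= 0 || frac_bandwidth >= 2)
    stop_invalid("frac_bandwidth must lie in (0, 2)")
  n_elements <- as.integer(n_elements)
  pos <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  structure(list(
    n_elements = n_elements,
    pitch = pitch,
    center_freq = center_freq,
    frac_bandwidth = frac_bandwidth,
    active_mask = rep(TRUE, n_elements),
    element_positions = pos
  ), class = "transducer_array")
}

#' Sparse aperture by regular decimation
#'
#' Keeps every `factor`-th element (offset by `phase`) active and turns the
#' rest off, enlarging the effective pitch to `factor * pitch`: factor 2 on
#' the 70 um array yields the 64-channel / 140 um configuration, factor 8
#' the 16-channel / 560 um configuration. Geometry is unchanged; only the
#' active mask is modified (elements are off on both transmit and receive).
#'
#' @param array A `transducer_array`.
#' @param factor Decimation factor (1 = identity).
#' @param phase Index offset of the first kept element (0-based).
#' @return The array with an updated `active_mask` and an
#'   `effective_pitch` field.
#' @export
decimate_aperture <- function(array, factor, phase = 0L) {
  stopifnot(inherits(array, "transducer_array"))
  if (factor < 1L || factor > array$n_elements)
    stop_invalid("factor must lie in [1, n_elements]")
  if (phase < 0L || phase >= factor)
    stop_invalid("phase must lie in [0, factor)")
  # decimate the sequence of currently ACTIVE elements, so repeated
  # decimations compose: x2 then x2 equals x4
  act <- which(array$active_mask)
  idx0 <- seq_along(act) - 1L                     # 0-based active index
  keep <- act[(idx0 - as.integer(phase)) %% as.integer(factor) == 0L]
  if (length(keep) == 0L)
    stop_invalid("decimation leaves no active element")
  mask <- logical(array$n_elements)
  mask[keep] <- TRUE
  array$active_mask <- mask
  array$effective_pitch <- effective_pitch(array)
  array
}

#' Effective pitch of the active aperture
#'
#' Spacing between consecutive active elements; equals
#' `pitch * factor` for a keep-every-`factor` mask.
#' @param array A `transducer_array`.
#' @return Effective pitch in meters.
#' @export
effective_pitch <- function(array) {
  pos <- array$element_positions[array$active_mask]
  if (length(pos) < 2L) return(array$pitch)
  d <- diff(sort(pos))
  if (max(d) - min(d) > 1e-12)
    warning("active mask is irregular; returning mean spacing")
  mean(d)
}

n_active <- function(array) sum(array$active_mask)

#' Plane-wave transmit sequence
#'
#' Steering angles for coherent compounding. The default is 7 angles
#' evenly spaced over \[-15, 15\] degrees, sampled at 62.5 MHz.
#'
#' @param angles_deg Strictly increasing steering angles in degrees.
#' @param sound_speed Speed of sound in m/s (water at ~20 C by default).
#' @param sampling_rate A/D sample rate in Hz.
#' @param prf Pulse repetition frequency in Hz (metadata only).
#' @return A `plane_wave_sequence`.
#' @export
plane_wave_sequence <- function(angles_deg = seq(-15, 15, length.out = 7),
                                sound_speed = 1480, sampling_rate = 62.5e6,
                                prf = 5e3) {
  if (length(angles_deg) < 1L || any(diff(angles_deg) <= 0) &&
      length(angles_deg) > 1L)
    stop_invalid("angles must be strictly increasing")
  if (sound_speed <= 0) stop_invalid("sound_speed must be positive")
  if (sampling_rate <= 0) stop_invalid("sampling_rate must be positive")
  structure(list(
    angles_deg = as.numeric(angles_deg),
    sound_speed = sound_speed,
    sampling_rate = sampling_rate,
    prf = prf
  ), class = "plane_wave_sequence")
}

# The DAQ ceiling (62.5 MHz) undersamples the -6 dB band edge of a
# 28 MHz / 0.6-bw probe (36.4 MHz > 31.25 MHz Nyquist); that is the
# hardware reality, so only carrier Nyquist is enforced here.
check_sequence_for_array <- function(seq, array) {
  if (seq$sampling_rate < 2 * array$center_freq)
    stop_invalid(sprintf(
      "sampling_rate %.3g Hz below carrier Nyquist 2 f0 = %.3g Hz",
      seq$sampling_rate, 2 * array$center_freq))
  invisible(TRUE)
}

#' Gaussian-modulated excitation pulse
#'
#' Cosine carrier at `center_freq` under a Gaussian envelope whose -6 dB
#' (half-amplitude) spectral full width equals
#' `frac_bandwidth * center_freq`. Peak amplitude 1 at t = 0.
#'
#' @param t Time in seconds (vectorized).
#' @param center_freq Carrier frequency in Hz.
#' @param frac_bandwidth Fractional -6 dB bandwidth (> 0).
#' @return Pulse amplitude at `t`.
#' @export
excitation_pulse <- function(t, center_freq = 28e6, frac_bandwidth = 0.6) {
  if (frac_bandwidth <= 0) stop_invalid("frac_bandwidth must be positive")
  sig <- pulse_sigma_t(center_freq, frac_bandwidth)
  exp(-0.5 * (t / sig)^2) * cos(2 * pi * center_freq * t)
}

# envelope exp(-t^2/(2 s^2)) has amplitude spectrum exp(-2 pi^2 s^2 f^2);
# half-amplitude full width bw*f0  =>  s = sqrt(2 ln 2) / (pi bw f0)
pulse_sigma_t <- function(center_freq, frac_bandwidth) {
  sqrt(2 * log(2)) / (pi * frac_bandwidth * center_freq)
}
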