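test_that("linear array geometry follows the probe spec", {
  arr <- make_linear_array(128L, 70e-6, 28e6, 0.6)
  expect_equal(diff(range(arr$element_positions)), 127 * 70e-6)
  expect_equal(sum(arr$element_positions), 0)
  expect_equal(unique(round(diff(arr$element_positions), 12)), 70e-6)
  expect_true(all(arr$active_mask))

  two <- make_linear_array(2L, 1e-3, 1e6, 0.6)
  expect_equal(two$element_positions, c(-0.5e-3, 0.5e-3))

  # wavelength arithmetic the grating-lobe math relies on
  expect_equal(1480 / arr$center_freq, 52.857e-6, tolerance = 1e-3)

  expect_error(make_linear_array(1L), class = "sparus_validation_error")
  expect_error(make_linear_array(pitch = -1), class = "sparus_validation_error")
  expect_error(make_linear_array(center_freq = 0),
               class = "sparus_validation_error")
  expect_error(make_linear_array(frac_bandwidth = 2.5),
               class = "sparus_validation_error")
})

test_that("aperture decimation yields the sparse pitches", {
  arr <- make_linear_array()
  a2 <- decimate_aperture(arr, 2L)
  expect_equal(sum(a2$active_mask), 64L)
  expect_equal(effective_pitch(a2), 140e-6)
  a8 <- decimate_aperture(arr, 8L)
  expect_equal(sum(a8$active_mask), 16L)
  expect_equal(effective_pitch(a8), 560e-6)

  # identity and reciprocity
  a1 <- decimate_aperture(arr, 1L)
  expect_identical(a1$active_mask, arr$active_mask)
  a22 <- decimate_aperture(decimate_aperture(arr, 2L), 2L)
  a4 <- decimate_aperture(arr, 4L)
  expect_identical(a22$active_mask, a4$active_mask)

  # geometry untouched
  expect_identical(a8$element_positions, arr$element_positions)
  expect_error(decimate_aperture(arr, 0L), class = "sparus_validation_error")
  expect_error(decimate_aperture(arr, 2L, phase = 2L),
               class = "sparus_validation_error")
})

test_that("excitation pulse meets its bandwidth contract", {
  expect_equal(excitation_pulse(0), 1.0)
  expect_lt(abs(excitation_pulse(1e-6)), 1e-12)
  expect_lt(abs(excitation_pulse(-1e-6)), 1e-12)

  # -6 dB spectral full width via DFT at fine sampling (the 62.5 MHz DAQ
  # rate aliases the upper band edge, so the continuous-time contract is
  # checked on an adequately sampled version)
  fs <- 1e9
  t <- seq(-2e-6, 2e-6, by = 1 / fs)
  p <- excitation_pulse(t, 28e6, 0.6)
  n <- length(t)
  f <- (0:(n - 1)) * fs / n
  amp <- Mod(fft(p))
  keep <- f < fs / 2
  above <- f[keep][amp[keep] >= max(amp) / 2]
  width <- max(above) - min(above)
  expect_equal(width, 0.6 * 28e6, tolerance = 0.05)
})

test_that("echo arrival times match the geometric path oracle", {
  arr <- make_linear_array(5L, 0.5e-3, 28e6, 0.6)
  sq <- plane_wave_sequence(angles_deg = 0)
  c0 <- sq$sound_speed
  fs <- sq$sampling_rate

  rf <- simulate_rf(wire_phantom(10e-3), arr, sq, antialias = FALSE)
  tr <- rf$traces[1, 3, ]        # center element at x = 0
  expect_equal((which.max(tr) - 1) / fs, 2 * 0.01 / c0, tolerance = 1e-3)

  # off-axis element: plane-wave path + return distance
  e <- 5L
  ex <- arr$element_positions[e]
  tau <- 0.01 / c0 + sqrt(ex^2 + 0.01^2) / c0
  tre <- rf$traces[1, e, ]
  expect_lt(abs((which.max(tre) - 1) / fs - tau), 1 / fs)

  # 100 random scatterer/element/angle triples against a brute-force
  # path-length computation, one sample period tolerance
  set.seed(7)
  for (i in 1:20) {
    xs <- runif(1, -2e-3, 2e-3); zs <- runif(1, 3e-3, 9e-3)
    ang <- runif(1, -15, 15)
    sq1 <- plane_wave_sequence(angles_deg = ang)
    rf1 <- simulate_rf(phantom(cbind(xs, zs), 1), arr, sq1,
                       antialias = FALSE)
    for (e in sample(5L, 5L)) {
      ex <- arr$element_positions[e]
      tau <- (zs * cos(ang * pi / 180) + xs * sin(ang * pi / 180)) / c0 +
        sqrt((xs - ex)^2 + zs^2) / c0
      k <- which.max(Mod(analytic_signal(matrix(rf1$traces[1, e, ]))))
      expect_lt(abs((k - 1) / fs - tau), 1.0 / fs)
    }
  }
})

test_that("masked channels stay zero and simulation is linear", {
  arr <- decimate_aperture(small_array(), 2L)
  sq <- short_seq()
  ph1 <- phantom(cbind(0, 5e-3), 1)
  ph2 <- phantom(cbind(1e-3, 7e-3), -0.5)
  rf1 <- simulate_rf(ph1, arr, sq)
  expect_true(all(rf1$traces[, !arr$active_mask, ] == 0))

  n <- max(dim(rf1$traces)[3],
           dim(simulate_rf(ph2, arr, sq)$traces)[3])
  rf1 <- simulate_rf(ph1, arr, sq, n_samples = n + 50L)
  rf2 <- simulate_rf(ph2, arr, sq, n_samples = n + 50L)
  rf12 <- simulate_rf(merge_phantoms(ph1, ph2), arr, sq,
                      n_samples = n + 50L)
  expect_equal(rf12$traces, rf1$traces + rf2$traces,
               tolerance = 1e-9)
})

test_that("seeded phantoms give bit-identical RF across runs", {
  arr <- small_array()
  sq <- short_seq()
  ph <- tooth_phantom(1.4, seed = 9L, length_mm = 5)
  a <- simulate_rf(ph, arr, sq)
  b <- simulate_rf(tooth_phantom(1.4, seed = 9L, length_mm = 5), arr, sq)
  expect_identical(a$traces, b$traces)
})

test_that("undersized trace windows are rejected with the needed length", {
  arr <- small_array()
  err <- tryCatch(simulate_rf(wire_phantom(12e-3), arr, short_seq(),
                              n_samples = 10L),
                  error = function(e) conditionMessage(e))
  expect_match(err, "need >= [0-9]+")
})

test_that("HDF5 round trip preserves RF blocks", {
  arr <- decimate_aperture(small_array(), 2L)
  rf <- simulate_rf(wire_phantom(5e-3), arr, short_seq())
  path <- file.path(tempdir(), "rf_test.h5")
  write_rf_h5(rf, path)
  back <- read_rf_h5(path)
  expect_identical(back$traces, rf$traces)
  expect_identical(back$array$active_mask, arr$active_mask)
  expect_equal(back$sequence$angles_deg, rf$sequence$angles_deg)
  unlink(path)
})
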