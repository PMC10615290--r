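test_that("wire phantom is a single deterministic scatterer", {
  ph <- wire_phantom(10e-3)
  expect_equal(nrow(ph$positions), 1L)
  expect_equal(ph$positions[1, ], c(0, 0.01))
  expect_equal(ph$reflectivities, 1)
  expect_identical(wire_phantom(10e-3), wire_phantom(10e-3))
})

test_that("a dense-array wire image has one -6 dB component", {
  arr <- make_linear_array()
  sq <- plane_wave_sequence()
  grid <- image_grid(96L, 96L, c(-1.5e-3, 1.5e-3), c(8.5e-3, 11.5e-3))
  rf <- simulate_rf(wire_phantom(10e-3), arr, sq,
                    n_samples = rf_samples_for(grid, arr, sq))
  img <- beamform(rf, grid)
  mask <- img$pixels >= 255 * (1 - 6 / img$dynamic_range_db)
  expect_equal(n_components(mask), 1L)
})

test_that("tooth phantoms honor construction and determinism", {
  ph <- tooth_phantom(1.41, seed = 3L)
  expect_equal(measure_thickness(ph$metadata$scene), 1.41)
  expect_identical(tooth_phantom(1.41, seed = 3L)$positions, ph$positions)
  expect_false(identical(tooth_phantom(1.41, seed = 4L)$positions,
                         ph$positions))
  expect_error(tooth_phantom(5), class = "sparus_validation_error")

  grid <- image_grid(32L, 32L, c(-3e-3, 3e-3), c(1e-3, 9e-3))
  with_mask <- tooth_phantom(1.4, seed = 3L, grid = grid)
  expect_named(with_mask$region_masks, "gingiva")
  expect_equal(dim(with_mask$region_masks$gingiva), c(32L, 32L))
  expect_gt(sum(with_mask$region_masks$gingiva), 0)
})

test_that("speckle counts scale with density like a Poisson draw", {
  count_speckle <- function(density, seed) {
    ph <- tooth_phantom(1.4, seed = seed, density = density)
    sc <- ph$metadata$scene
    n_interface <- nrow(sparus:::resample_polyline(sc$tooth_curve,
                                                   1480 / 28e6 / 2)) +
      nrow(sparus:::resample_polyline(sc$gingiva_curve, 1480 / 28e6 / 2))
    nrow(ph$positions) - n_interface
  }
  set.seed(10)
  for (seed in c(21L, 22L, 23L)) {
    ph <- tooth_phantom(1.4, seed = seed)
    area <- abs(sparus:::polygon_area(
      sparus:::gingiva_polygon(ph$metadata$scene))) * 1e6
    lam <- 40 * area
    n <- count_speckle(40, seed)
    expect_lt(abs(n - lam), 3 * sqrt(lam) + 1)
  }
})

test_that("negative controls have the advertised structure", {
  ph <- negative_control_phantom("noise", seed = 5L)
  expect_identical(negative_control_phantom("noise", seed = 5L)$positions,
                   ph$positions)
  expect_null(ph$region_masks)
  expect_error(negative_control_phantom("tendon"))

  # anechoic lumen: mean B-mode intensity inside the ellipse under 25%
  # of the surrounding speckle mean
  ves <- negative_control_phantom("vessel", seed = 6L)
  arr <- make_linear_array()
  grid <- image_grid(64L, 64L, c(-3e-3, 3e-3), c(1e-3, 9e-3))
  rf <- simulate_rf(ves, arr, plane_wave_sequence(),
                    n_samples = rf_samples_for(grid, arr,
                                               plane_wave_sequence()))
  img <- beamform(rf, grid)
  el <- ves$metadata$ellipse
  gx <- seq(-3e-3, 3e-3, length.out = 64)
  gz <- seq(1e-3, 9e-3, length.out = 64)
  px <- outer(gz * 0, gx, `+`); pz <- outer(gz, gx * 0, `+`)
  inside <- ((px - el["cx"]) / (0.7 * el["rx"]))^2 +
    ((pz - el["cz"]) / (0.7 * el["rz"]))^2 < 1
  ring <- !inside & (((px - el["cx"]) / (1.6 * el["rx"]))^2 +
                       ((pz - el["cz"]) / (1.6 * el["rz"]))^2 < 1)
  expect_lt(mean(img$pixels[inside]), 0.25 * mean(img$pixels[ring]))
})

test_that("thickness measurement is geometric and rigid-motion safe", {
  sc <- tooth_scene(1.2, curvature = 0)
  # constant-offset region: same reading anywhere past the ramp
  expect_equal(measure_thickness(sc, 2), 1.2)
  expect_equal(measure_thickness(sc, 3.5), 1.2)

  sc2 <- tooth_scene(1.73)
  rot <- function(scene, deg) {
    th <- deg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    scene$tooth_curve <- scene$tooth_curve %*% R
    scene$gingiva_curve <- scene$gingiva_curve %*% R
    scene
  }
  expect_lt(abs(measure_thickness(rot(sc2, 10)) -
                  measure_thickness(sc2)), 0.02)
  expect_error(measure_thickness(sc, 40), class = "sparus_validation_error")
})

test_that("paired datasets align apertures and split 80/20", {
  sp <- split_indices(400L, 0L, seed = 2L)
  expect_length(sp$train, 320L)
  expect_length(sp$val, 80L)
  expect_length(intersect(sp$train, sp$val), 0L)

  sp2 <- split_indices(300L, 50L, seed = 2L)
  expect_equal(sp2$test, 251:300)
  expect_length(sp2$train, 200L)
  expect_length(sp2$val, 50L)

  grid <- image_grid(32L, 32L, c(-2e-3, 2e-3), c(1e-3, 6e-3))
  ds <- make_paired_dataset(2L, factors = c(1L, 8L), seed = 31L,
                            grid = grid)
  expect_length(ds$dense, 2L)
  expect_named(ds$sparse, c("1", "8"))
  # factor-1 member is the dense member bit for bit
  expect_identical(ds$sparse[["1"]][[1]]$pixels, ds$dense[[1]]$pixels)
  expect_identical(ds$sparse[["1"]][[2]]$pixels, ds$dense[[2]]$pixels)
  # artifacts present for real decimation on speckle scenes
  for (i in 1:2)
    expect_lt(ssim(ds$dense[[i]], ds$sparse[["8"]][[i]]), 1)

  # pure function of (seed, configs)
  ds2 <- make_paired_dataset(2L, factors = c(1L, 8L), seed = 31L,
                             grid = grid)
  expect_identical(lapply(ds$dense, `[[`, "pixels"),
                   lapply(ds2$dense, `[[`, "pixels"))

  # HDF5 round trip
  path <- file.path(tempdir(), "pairs_test.h5")
  write_dataset_h5(ds, path)
  back <- read_dataset_h5(path)
  expect_identical(back$dense[[1]]$pixels, ds$dense[[1]]$pixels)
  expect_identical(back$sparse[["8"]][[2]]$pixels,
                   ds$sparse[["8"]][[2]]$pixels)
  expect_equal(back$split, lapply(ds$split, as.integer))
  unlink(path)
})
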