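#' 80/20 train/validation split over the non-test pool
#'
#' Deterministic shuffled split: the last `n_test` indices form the test
#' set; the remaining pool is split 80% train / 20% validation.
#'
#' @param n Total number of pairs.
#' @param n_test Pairs reserved for testing (taken from the end).
#' @param seed Shuffling seed.
#' @param train_fraction Fraction of the non-test pool used for training.
#' @return List of integer index vectors `train`, `val`, `test`.
#' @export
split_indices <- function(n, n_test = 0L, seed = 1L, train_fraction = 0.8) {
  if (n_test >= n) stop_invalid("n_test must leave a non-empty pool")
  pool <- seq_len(n - n_test)
  local_rng(seed)
  pool <- sample(pool)
  n_train <- round(train_fraction * length(pool))
  list(train = sort(pool[seq_len(n_train)]),
       val = sort(pool[-seq_len(n_train)]),
       test = if (n_test > 0) (n - n_test + 1L):n else integer())
}

#' Generate a paired sparse/dense B-mode dataset
#'
#' For each seeded phantom (tooth/gingiva scenes with thicknesses drawn
#' uniformly over the plausible 0.9-2.0 mm range, by default), simulates
#' RF once and beamforms once per aperture configuration: the dense
#' 128-channel array plus each requested decimation factor. Pairs are
#' pixel-aligned by construction and the whole dataset is a pure function
#' of `(seed, configs)`.
#'
#' @param n_pairs Number of phantoms (>= 1).
#' @param factors Integer decimation factors (e.g. `c(2, 8)`).
#' @param seed Master seed.
#' @param grid An `image_grid` (use a 2^k size for network training).
#' @param array Dense `transducer_array`.
#' @param seq A `plane_wave_sequence`.
#' @param n_test Pairs reserved as the held-out test split.
#' @param dynamic_range_db Log-compression dynamic range.
#' @param phantom_fun Called as `phantom_fun(i, seed_i)`; defaults to
#'   seeded [tooth_phantom()] draws.
#' @return A `paired_dataset`: `dense` (list of `bmode_image`),
#'   `sparse` (named list by factor of lists), `split`, `thicknesses`,
#'   `seed`.
#' @export
make_paired_dataset <- function(n_pairs, factors = c(2L, 8L), seed = 1L,
                                grid = image_grid(
                                  128L, 128L,
                                  lateral_extent = c(-3.2e-3, 3.2e-3),
                                  depth_range = c(1e-3, 7.4e-3)),
                                array = make_linear_array(),
                                seq = plane_wave_sequence(),
                                n_test = 0L, dynamic_range_db = 50,
                                phantom_fun = NULL) {
  if (n_pairs < 1L) stop_invalid("n_pairs must be >= 1")
  factors <- as.integer(factors)
  arrays <- lapply(factors, function(f) decimate_aperture(array, f))
  local_rng(seed)
  thick <- runif(n_pairs, 0.9, 2.0)
  seeds <- sample.int(2^30, n_pairs)
  dense <- vector("list", n_pairs)
  sparse <- setNames(lapply(factors, function(f) vector("list", n_pairs)),
                     as.character(factors))
  n_samp <- rf_samples_for(grid, array, seq)
  for (i in seq_len(n_pairs)) {
    ph <- if (is.null(phantom_fun)) {
      # 5 mm tooth surface starting 1.4-2.2 mm deep fits the default
      # 128 x 128 training grid (depth 1-7.4 mm)
      tooth_phantom(thick[i], seed = seeds[i], length_mm = 5,
                    margin_z = c(1.4e-3, 2.2e-3))
    } else {
      phantom_fun(i, seeds[i])
    }
    rf <- simulate_rf(ph, array, seq)
    rf <- pad_rf(rf, n_samp)      # cover the whole grid depth
    # receive masks select the apertures; transmit is the ideal plane
    # wave, so one RF block and one baseband prep serve every aperture
    imgs <- beamform_multi(rf, grid, c(list(array), arrays),
                           dynamic_range_db)
    dense[[i]] <- imgs[[1]]
    for (k in seq_along(factors)) sparse[[k]][[i]] <- imgs[[k + 1]]
  }
  structure(list(dense = dense, sparse = sparse, factors = factors,
                 split = split_indices(n_pairs, n_test, seed),
                 thicknesses = thick, seed = seed, grid = grid),
            class = "paired_dataset")
}

# zero-pad traces in time so the window covers at least n_samples
pad_rf <- function(rf, n_samples) {
  d <- dim(rf$traces)
  if (d[3] >= n_samples) return(rf)
  padded <- array(0, c(d[1], d[2], n_samples))
  padded[, , seq_len(d[3])] <- rf$traces
  rf$traces <- padded
  rf
}

# normalize `data` into aligned sparse/dense lists for one factor
dataset_pairs <- function(data, factor = NULL) {
  if (inherits(data, "paired_dataset")) {
    f <- if (is.null(factor)) names(data$sparse)[1] else as.character(factor)
    if (!f %in% names(data$sparse))
      stop_invalid("requested factor not present in dataset")
    list(sparse = data$sparse[[f]], dense = data$dense)
  } else {
    list(sparse = data$sparse, dense = data$dense)
  }
}

#' Write / read a paired dataset (HDF5)
#'
#' Stores dense and per-factor sparse image stacks as 8-bit integer
#' datasets plus the split indices and seed.
#' @param data A `paired_dataset`.
#' @param path Output `.h5` path.
#' @return `path` invisibly (writer); a `paired_dataset` (reader).
#' @export
write_dataset_h5 <- function(data, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  stack <- function(imgs) {
    d <- dim(imgs[[1]]$pixels)
    array(unlist(lapply(imgs, `[[`, "pixels")),
          dim = c(d[1], d[2], length(imgs)))
  }
  rhdf5::h5write(stack(data$dense), path, "dense")
  rhdf5::h5createGroup(path, "sparse")
  for (f in names(data$sparse))
    rhdf5::h5write(stack(data$sparse[[f]]), path, paste0("sparse/f", f))
  rhdf5::h5createGroup(path, "split")
  for (nm in names(data$split))
    rhdf5::h5write(as.integer(data$split[[nm]]), path,
                   paste0("split/", nm))
  rhdf5::h5write(data$thicknesses, path, "thicknesses")
  rhdf5::h5write(as.integer(data$seed), path, "seed")
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_dataset_h5
#' @export
read_dataset_h5 <- function(path) {
  unstack <- function(a) {
    lapply(seq_len(dim(a)[3]), function(i)
      structure(list(pixels = matrix(as.integer(a[, , i]), dim(a)[1]),
                     grid = NULL, dynamic_range_db = 50,
                     provenance = list(source = path)),
                class = "bmode_image"))
  }
  dense <- unstack(rhdf5::h5read(path, "dense"))
  snames <- rhdf5::h5ls(path)
  sgroups <- snames$name[snames$group == "/sparse"]
  sparse <- setNames(
    lapply(sgroups, function(g)
      unstack(rhdf5::h5read(path, paste0("sparse/", g)))),
    sub("^f", "", sgroups))
  split <- list(
    train = as.integer(rhdf5::h5read(path, "split/train")),
    val = as.integer(rhdf5::h5read(path, "split/val")),
    test = as.integer(rhdf5::h5read(path, "split/test")))
  out <- structure(list(
    dense = dense, sparse = sparse,
    factors = as.integer(names(sparse)),
    split = split,
    thicknesses = as.numeric(rhdf5::h5read(path, "thicknesses")),
    seed = as.integer(rhdf5::h5read(path, "seed")), grid = NULL),
    class = "paired_dataset")
  rhdf5::h5closeAll()
  out
}
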