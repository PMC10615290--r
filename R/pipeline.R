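# configuration schema: defaults mirror the study hardware (128 elements,
# 70 um pitch, 28 MHz, 7 plane waves over +-15 deg, 62.5 MHz sampling,
# 50 epochs, 80/20 split)
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "sparus-run",
    log_level = "info",
    array = list(n_elements = 128L, pitch = 70e-6, center_freq = 28e6,
                 frac_bandwidth = 0.6),
    sequence = list(n_angles = 7L, angle_span_deg = c(-15, 15),
                    angles_deg = NULL,
                    sound_speed = 1480, sampling_rate = 62.5e6, prf = 5e3),
    grid = list(n_rows = 512L, n_cols = 512L,
                lateral_extent = c(-4.48e-3, 4.48e-3),
                depth_range = c(0.5e-3, 15e-3)),
    runet = list(depth = 4L, base_channels = 32L, epochs = 50L,
                 batch_size = 8L, learning_rate = 1e-4,
                 loss_pixel = 1.0, loss_perceptual = 0.1),
    dataset = list(n_pairs = 10L, factors = c(2L, 8L), n_test = 0L,
                   train_fraction = 0.8),
    metrics = list(dynamic_range_db = 50, i_max = 255L)
  )
}

config_checks <- list(
  "array.n_elements" = function(v) v >= 2,
  "array.pitch" = function(v) is.numeric(v) && v > 0,
  "array.center_freq" = function(v) is.numeric(v) && v > 0,
  "array.frac_bandwidth" = function(v) v > 0 && v < 2,
  "sequence.n_angles" = function(v) v >= 1,
  "sequence.sound_speed" = function(v) v > 0,
  "sequence.sampling_rate" = function(v) v > 0,
  "grid.n_rows" = function(v) v >= 2,
  "grid.n_cols" = function(v) v >= 2,
  "runet.depth" = function(v) v >= 1,
  "runet.base_channels" = function(v) v >= 1,
  "runet.epochs" = function(v) v >= 0,
  "runet.learning_rate" = function(v) v > 0,
  "dataset.n_pairs" = function(v) v >= 1,
  "dataset.train_fraction" = function(v) v > 0 && v < 1,
  "metrics.dynamic_range_db" = function(v) v > 0
)

#' Validate and complete a run configuration
#'
#' Injects the default hardware/training constants into a possibly partial
#' raw mapping (e.g. parsed YAML), rejects unknown keys naming their
#' location, and aggregates range violations into a single error report.
#' A sequence given as an angle span expands to `n_angles` evenly spaced
#' entries.
#'
#' @param raw Named list (possibly nested, possibly empty).
#' @return A validated `run_config`.
#' @export
validate_config <- function(raw = list()) {
  def <- default_config()
  problems <- character()
  merge <- function(d, r, path) {
    for (nm in names(r)) {
      p <- if (nzchar(path)) paste0(path, ".", nm) else nm
      if (!nm %in% names(d)) {
        problems <<- c(problems, paste0("unknown key: ", p))
      } else if (is.list(d[[nm]]) && !is.null(names(d[[nm]]))) {
        d[[nm]] <- merge(d[[nm]], r[[nm]], p)
      } else {
        d[[nm]] <- r[[nm]]
      }
    }
    d
  }
  cfg <- merge(def, raw, "")
  for (key in names(config_checks)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    ok <- tryCatch(isTRUE(config_checks[[key]](v)), error = function(e) FALSE)
    if (!ok) problems <- c(problems, paste0("invalid value for ", key))
  }
  if (length(problems) > 0)
    stop_invalid("configuration errors:\n  ",
                 paste(problems, collapse = "\n  "))
  # an explicit angle list (e.g. from a serialized config) wins over the
  # span expansion
  if (is.null(cfg$sequence$angles_deg))
    cfg$sequence$angles_deg <- seq(cfg$sequence$angle_span_deg[1],
                                   cfg$sequence$angle_span_deg[2],
                                   length.out = cfg$sequence$n_angles)
  structure(cfg, class = "run_config")
}

#' Read / write run configurations as YAML
#' @param path YAML file path.
#' @return A validated `run_config` (reader); `path` invisibly (writer).
#' @export
read_config_yaml <- function(path) validate_config(yaml::read_yaml(path))

#' @rdname read_config_yaml
#' @param config A `run_config` or raw mapping.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Per-stage seed derivation
#'
#' Fans the global seed out into named streams so that adding a stage
#' never perturbs the draws of earlier stages. Plain multiplicative hash
#' of the stage name folded with the global seed, kept below 2^31.
#'
#' @param global_seed Integer master seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483629
  as.integer((h + as.numeric(global_seed) * 2654435761) %% 2147483629 + 1)
}

config_objects <- function(config) {
  arr <- make_linear_array(config$array$n_elements, config$array$pitch,
                           config$array$center_freq,
                           config$array$frac_bandwidth)
  sq <- plane_wave_sequence(config$sequence$angles_deg,
                            config$sequence$sound_speed,
                            config$sequence$sampling_rate,
                            config$sequence$prf)
  gr <- image_grid(config$grid$n_rows, config$grid$n_cols,
                   config$grid$lateral_extent, config$grid$depth_range)
  list(array = arr, sequence = sq, grid = gr)
}

#' Run pipeline stages
#'
#' Executes the requested stages in order (`simulate` -> `beamform` ->
#' `train` -> `predict` -> `evaluate`), writing artifacts (HDF5 datasets,
#' PNG frames, model checkpoints, CSV metric tables) under the config's
#' output directory, and returns a manifest listing every written file
#' with its MD5 content hash. Deterministic stages reproduce identical
#' hashes on re-runs with the same config. A stage whose upstream
#' artifact is missing fails with an error naming the absent stage.
#'
#' @param config A `run_config`.
#' @param stages Character vector of stage names.
#' @return The manifest data.frame (`stage`, `path`, `md5`), invisibly
#'   written to `manifest.json` as well.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "beamform", "train",
                                    "predict", "evaluate")) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  obj <- config_objects(config)
  manifest <- data.frame(stage = character(), path = character(),
                         md5 = character())
  note <- function(stage, path) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, path = path, md5 = unname(tools::md5sum(path))))
  }
  log_msg <- function(...) {
    if (identical(config$log_level, "info")) message(...)
    cat(format(Sys.time(), "%H:%M:%S "), paste0(...), "\n",
        file = file.path(out, "run.log"), append = TRUE)
  }
  ds_path <- file.path(out, "pairs.h5")
  model_path <- file.path(out, "model.h5")

  if ("simulate" %in% stages || "beamform" %in% stages) {
    # simulate + beamform happen jointly per phantom (RF reuse); the
    # simulate stage persists the first phantom's RF for inspection
    log_msg("simulate/beamform: ", config$dataset$n_pairs, " pairs")
    data <- make_paired_dataset(
      config$dataset$n_pairs, config$dataset$factors,
      seed = stage_seed(config$seed, "simulate"),
      grid = obj$grid, array = obj$array, seq = obj$sequence,
      n_test = config$dataset$n_test,
      dynamic_range_db = config$metrics$dynamic_range_db)
    if ("simulate" %in% stages) {
      local_rng(stage_seed(config$seed, "simulate"))
      th <- runif(1, 0.9, 2.0)
      sd1 <- sample.int(2^30, 1)
      rf <- simulate_rf(tooth_phantom(th, seed = sd1), obj$array,
                        obj$sequence)
      write_rf_h5(rf, file.path(out, "rf_pair001.h5"))
      note("simulate", file.path(out, "rf_pair001.h5"))
    }
    if ("beamform" %in% stages) {
      write_dataset_h5(data, ds_path)
      note("beamform", ds_path)
      png1 <- file.path(out, "dense_pair001.png")
      write_bmode_png(data$dense[[1]], png1)
      note("beamform", png1)
    }
  }
  if ("train" %in% stages) {
    if (!file.exists(ds_path))
      stop_invalid("missing upstream artifact for 'train': ",
                   "run the 'beamform' stage first (", ds_path, ")")
    data <- read_dataset_h5(ds_path)
    cfg <- runet_config(
      depth = config$runet$depth,
      base_channels = config$runet$base_channels,
      loss_weights = list(pixel = config$runet$loss_pixel,
                          perceptual = config$runet$loss_perceptual),
      epochs = config$runet$epochs, batch_size = config$runet$batch_size,
      learning_rate = config$runet$learning_rate,
      seed = stage_seed(config$seed, "train"))
    model <- build_runet(cfg)
    log_msg("train: ", cfg$epochs, " epochs on ",
            length(data$split$train), " pairs")
    model <- train_runet(model, data)
    save_checkpoint(model, model_path)
    note("train", model_path)
  }
  if ("predict" %in% stages || "evaluate" %in% stages) {
    if (!file.exists(model_path))
      stop_invalid("missing upstream artifact for 'predict': ",
                   "run the 'train' stage first (", model_path, ")")
    if (!file.exists(ds_path))
      stop_invalid("missing upstream artifact for 'predict': ",
                   "run the 'beamform' stage first (", ds_path, ")")
    model <- load_checkpoint(model_path)
    data <- read_dataset_h5(ds_path)
    pairs <- dataset_pairs(data)
    idx <- if (length(data$split$test) > 0) data$split$test else
      data$split$val
    preds <- lapply(idx, function(i) predict(model, pairs$sparse[[i]]))
    if ("predict" %in% stages) {
      pp <- file.path(out, "pred_first.png")
      write_bmode_png(preds[[1]], pp)
      note("predict", pp)
    }
    if ("evaluate" %in% stages) {
      tab <- evaluate_pairs(pairs$dense[idx], pairs$sparse[idx], preds)
      csv <- file.path(out, "metrics.csv")
      utils::write.csv(tab, csv, row.names = FALSE)
      note("evaluate", csv)
      log_msg(sprintf(
        "evaluate: mean SSIM %.3f -> %.3f, MSE %.0f -> %.0f, PSNR %.1f -> %.1f",
        mean(tab$ssim_in), mean(tab$ssim_pred), mean(tab$mse_in),
        mean(tab$mse_pred), mean(tab$psnr_in), mean(tab$psnr_pred)))
    }
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(manifest)
}
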