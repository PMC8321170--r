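#' Build a pipeline run configuration
#'
#' A run is either self-contained (a `phantom_spec` provides the test
#' volume and its gold standard, plus a separate training phantom drawn
#' with a distinct derived seed, mirroring the separation between the
#' studies used to train the classifier and those used to test the
#' segmentation) or driven by real inputs (`volume`, optional `gold`,
#' and an ROI mask or box).  Exactly one of `phantom` / `volume` must be
#' given.
#'
#' @param phantom a [phantom_spec] for self-contained runs.
#' @param volume,gold,roi NIfTI paths for real-data runs (`roi` may also
#'   be given as `roi_box = c(i0, j0, k0, i1, j1, k1)`, 1-based
#'   inclusive).
#' @param model path to a serialized `da_model` JSON
#'   (see [write_da_model()]); when given, the sampling and training
#'   stages are skipped — the classifier needs to be trained only once
#'   and can then drive any number of segmentations.
#' @param roi_box integer vector of length 6 (alternative to `roi`).
#' @param roi_margin bounding-box margin in voxels for phantom-mode ROIs
#'   (default 4).
#' @param params an [as_params].
#' @param k,gamma classifier cross-validation folds and ridge strength.
#' @param frac seed-region threshold fraction (default 0.4).
#' @param ellipsoid_scale semi-axis multiplier for the initialization.
#' @param seed master seed; all stage seeds derive from it.
#' @param hd_units Hausdorff units in the report.
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = NULL, volume = NULL, gold = NULL,
                       model = NULL,
                       roi = NULL, roi_box = NULL, roi_margin = 4L,
                       params = as_params(), k = 5, gamma = NULL,
                       frac = 0.4, ellipsoid_scale = 2.6, seed = 1,
                       hd_units = "voxel") {
  if (is.null(phantom) == is.null(volume))
    stopf("exactly one of `phantom` (a phantom_spec) or `volume` (a NIfTI path) must be given")
  structure(list(phantom = phantom, volume = volume, gold = gold,
                 model = model, roi = roi, roi_box = roi_box,
                 roi_margin = as.integer(roi_margin), params = params,
                 k = k, gamma = gamma, frac = frac,
                 ellipsoid_scale = ellipsoid_scale, seed = as.integer(seed),
                 hd_units = hd_units),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML schema mirrors [run_config()]: top-level keys `seed`, `k`,
#' `gamma`, `frac`, `ellipsoid_scale`, `roi_margin`, `hd_units`, an
#' optional `params` block (fields of [as_params()]), and either a
#' `phantom` block (fields of [phantom_spec()], with `geom` nested) or
#' `volume`/`gold`/`roi`/`roi_box` paths.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- do.call(as_params, y$params %||% list())
  phantom <- if (!is.null(y$phantom)) do.call(phantom_spec, y$phantom)
  args <- y[setdiff(names(y), c("params", "phantom"))]
  do.call(run_config, c(list(phantom = phantom, params = params), args))
}

box_mask <- function(box, grid) {
  box <- as.integer(box)
  lo <- pmax(box[1:3], 1L)
  hi <- pmin(box[4:6], grid$shape)
  out <- array(0, grid$shape)
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  binary_mask(out, grid = grid)
}

#' Run the full segmentation pipeline
#'
#' Executes phantom generation (or volume loading), window sampling,
#' classifier training with stratified k-fold cross-validation,
#' whole-volume tissue classification, ellipsoid initialization from the
#' ROI, active-surface segmentation, and (when a gold standard exists)
#' evaluation.  Every intermediate artifact is written to `out_dir`
#' together with the resolved seed, so identical configurations yield
#' byte-identical outputs.
#'
#' @param config a [run_config] (or a YAML path).
#' @param out_dir output directory (created if needed).
#' @param verbose print per-stage progress.
#' @return Invisibly, a list with the in-memory artifacts: `volume`,
#'   `gold`, `model`, `cv`, `maps`, `roi`, `init` (ellipsoid),
#'   `segmentation`, `report`, and `paths`.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  paths <- list()
  stage <- "inputs"
  on_fail <- function(e) {
    stopf("pipeline stage '%s' failed: %s (artifacts so far: %s)", stage,
          conditionMessage(e),
          if (length(paths)) paste(unlist(paths), collapse = ", ") else "none")
  }
  tryCatch({
    if (!is.null(config$phantom)) {
      stage <- "phantom"
      spec_test <- config$phantom
      spec_test$seed <- config$seed
      ph <- generate_phantom(spec_test)
      vol <- ph$volume; gold <- ph$gold
      spec_train <- spec_test
      spec_train$seed <- config$seed + 1000L
      ph_train <- generate_phantom(spec_train)
      train_vol <- ph_train$volume; train_gold <- ph_train$gold
      paths$volume <- file.path(out_dir, "volume.nii.gz")
      paths$gold <- file.path(out_dir, "gold.nii.gz")
      write_volume(vol, paths$volume)
      write_volume(gold, paths$gold)
      roi <- roi_around(gold, config$roi_margin)
    } else {
      stage <- "inputs"
      vol <- read_volume(config$volume)
      gold <- if (!is.null(config$gold)) read_mask(config$gold)
      train_vol <- vol
      train_gold <- gold
      if (is.null(train_gold) && is.null(config$model))
        stopf("real-data runs need either a gold mask to train on or a pretrained model")
      roi <- if (!is.null(config$roi)) read_mask(config$roi)
             else if (!is.null(config$roi_box)) box_mask(config$roi_box, vol$grid)
             else stopf("an ROI (mask path or roi_box) is required")
    }
    if (is.null(config$model)) {
      say("sampling 3x3x3 windows")
      stage <- "sampling"
      samples <- extract_samples(train_vol, train_gold)
      stage <- "training"
      say("training DA classifier (k = %d folds)", config$k)
      cv <- da_kfold_cv(samples, k = config$k, gamma = config$gamma,
                        seed = config$seed + 1L)
      model <- da_train(samples, gamma = config$gamma,
                        seed = config$seed + 2L)
      paths$model <- file.path(out_dir, "model.json")
      write_da_model(model, paths$model)
    } else {
      stage <- "training"
      say("loading pretrained model %s", config$model)
      model <- read_da_model(config$model)
      cv <- NULL
      samples <- NULL
    }
    stage <- "classification"
    say("classifying volume")
    maps <- classify_volume(model, vol)
    stage <- "presegmentation"
    mx <- find_max_voxel(vol, roi)
    seed_m <- seed_region(vol, roi, frac = config$frac)
    ell <- fit_ellipsoid(seed_m, scale = config$ellipsoid_scale,
                         max_voxel = mx)
    phi0 <- ellipsoid_to_levelset(ell, vol$grid)
    stage <- "segmentation"
    say("evolving active surface")
    seg <- segment_surface(vol, maps, phi0, config$params)
    paths$mask <- file.path(out_dir, "mask.nii.gz")
    write_volume(seg$mask, paths$mask)
    paths$history <- file.path(out_dir, "history.csv")
    utils::write.csv(seg$history, paths$history, row.names = FALSE)
    stage <- "evaluation"
    report <- list(seed = config$seed,
                   converged = seg$converged, flag = seg$flag,
                   iterations = nrow(seg$history),
                   classifier = if (is.null(cv)) {
                     list(pretrained = config$model,
                          heldout = as.list(model$heldout))
                   } else {
                     list(cv_mean = as.list(cv$mean),
                          cv_sd = as.list(cv$sd), k = cv$k,
                          heldout = as.list(model$heldout))
                   },
                   class_counts = if (!is.null(samples))
                     as.list(class_counts(samples)))
    if (!is.null(gold)) {
      ev <- evaluate_masks(seg$mask, gold, hd_units = config$hd_units)
      report$segmentation <- ev
    }
    paths$report <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, paths$report, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
    paths$config <- file.path(out_dir, "config.json")
    cfg_dump <- config
    cfg_dump$params <- unclass(cfg_dump$params)
    cfg_dump$phantom <- if (!is.null(config$phantom)) {
      p <- unclass(config$phantom); p$grid <- unclass(p$grid); p
    }
    jsonlite::write_json(unclass(cfg_dump), paths$config, digits = NA,
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    say("done: %s", out_dir)
    invisible(list(volume = vol, gold = gold, model = model, cv = cv,
                   maps = maps, roi = roi, init = ell,
                   segmentation = seg, report = report, paths = paths))
  }, error = on_fail)
}
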