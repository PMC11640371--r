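# End-to-end orchestration: data (synthetic or user image-folder),
# fluorescence preprocessing + resize, balancing augmentation, frozen
# feature extraction, head training (softmax and/or gradient-boosted
# trees), evaluation, and artifact writing. Every stage is seeded from the
# single config seed, so a run is reproducible from its recorded config.

#' Pipeline configuration
#'
#' Builds the full nested configuration with defaults; any element can be
#' overridden by passing a nested list. Defaults mirror the study setting
#' the pipeline emulates: synthetic five-class data at 1125 x 1264 raw
#' resolution, fluorescence preprocessing (alpha 2, blue suppression on),
#' resize to 700 x 600 (width x height), balanced augmentation of the
#' training split only, tiny frozen backbones of both families,
#' concatenation fusion with the basic head, and both classification heads.
#'
#' @param overrides Nested list merged over the defaults.
#' @param work_dir Working directory for data and artifacts.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(overrides = list(), work_dir = tempfile("run"),
                            seed = 1) {
  defaults <- list(
    seed = seed,
    work_dir = work_dir,
    data = list(source = "synthetic", dir = NULL, n_per_class = 100L,
                raw_width = 1125L, raw_height = 1264L, test_fraction = 0.15),
    preprocess = list(alpha = 2.0, suppress_blue = TRUE, colormap = "none",
                      width = 700L, height = 600L),
    augment = list(balance = TRUE, policy = NULL),
    backbones = list(families = c("mobilenet_v2_like",
                                  "efficientnet_b0_like"),
                     scale = "tiny", input_norm = "zscore"),
    model = list(variant = "basic", fusion_mode = "concat", hidden = 128L,
                 extended_units = 850L),
    head = "both",
    gbt = list(eta = 0.3, lambda = 1, n_rounds = 50L, max_depth = 3L,
               representation = "penultimate"),
    train = list(epochs = 15L, lr = 1e-3, batch_size = 32L,
                 val_fraction = 0.1)
  )
  cfg <- utils::modifyList(defaults, overrides)
  stopifnot(cfg$preprocess$width >= 1, cfg$preprocess$height >= 1,
            is.numeric(cfg$seed), length(cfg$seed) == 1L,
            cfg$head %in% c("softmax", "gbt", "both"))
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys override [pipeline_config()] defaults.
#' @param work_dir,seed Fallbacks when the file does not set them.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, work_dir = tempfile("run"), seed = 1) {
  overrides <- yaml::read_yaml(path)
  if (!is.null(overrides$work_dir)) work_dir <- overrides$work_dir
  if (!is.null(overrides$seed)) seed <- overrides$seed
  pipeline_config(overrides, work_dir = work_dir, seed = seed)
}

#' Build a manifest from a class-per-subdirectory image folder
#'
#' @param dir Directory whose immediate subdirectories are class labels
#'   containing PNG/JPEG images.
#' @param test_fraction Stratified held-out fraction.
#' @param seed Split seed.
#' @return A manifest data frame (`path`, `label`, `split`, `source`).
#' @export
read_image_folder <- function(dir, test_fraction = 0.15, seed = 1) {
  labs <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  if (length(labs) == 0L) stop("no class subdirectories under ", dir,
                               call. = FALSE)
  rows <- lapply(labs, function(lab) {
    paths <- list.files(file.path(dir, lab), full.names = TRUE,
                        pattern = "\\.(png|jpe?g)$", ignore.case = TRUE)
    if (length(paths) == 0L) return(NULL)
    n_test <- round(test_fraction * length(paths))
    split <- rep("train", length(paths))
    if (n_test > 0) {
      idx <- withr::with_seed(seed + match(lab, labs),
                              sample.int(length(paths), n_test))
      split[idx] <- "test"
    }
    data.frame(path = paths, label = lab, split = split, source = "folder",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "root") <- dir
  out
}

#' Save / load a fusion model
#'
#' JSON serialization preserving full double precision.
#'
#' @param model A [build_fusion_model()] object.
#' @param path File path.
#' @return `path` invisibly; `read_fusion_model()` restores the model.
#' @export
write_fusion_model <- function(model, path) {
  stopifnot(inherits(model, "fusion_model"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(jsonlite::serializeJSON(unclass(model), digits = 17), path)
  invisible(path)
}

#' @rdname write_fusion_model
#' @export
read_fusion_model <- function(path) {
  obj <- jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE),
                                         collapse = "\n"))
  structure(obj, class = "fusion_model")
}

stage_msg <- function(stage, t0, detail) {
  message(sprintf("[%s] %5.1fs  %s", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  detail))
}

preprocess_manifest <- function(manifest, cfg, out_dir) {
  fl_cfg <- fluorescence_config(cfg$preprocess$alpha,
                                cfg$preprocess$suppress_blue,
                                cfg$preprocess$colormap)
  out <- manifest
  out$path <- file.path(out_dir, manifest$label,
                        sub("\\.[^.]+$", ".png", basename(manifest$path)))
  for (i in seq_len(nrow(manifest))) {
    img <- read_image(manifest$path[i])
    img <- fluorescence_simulate(img, fl_cfg)
    img <- resize_image(img, cfg$preprocess$width, cfg$preprocess$height)
    write_image(img, out$path[i])
  }
  attr(out, "root") <- out_dir
  out
}

#' Run the full classification pipeline
#'
#' Stages, in order: data acquisition (synthetic generation or image-folder
#' loading), fluorescence preprocessing and resize, training-split
#' balancing by augmentation, frozen dual-backbone feature extraction with
#' global average pooling, fusion-head training (Adam, categorical
#' cross-entropy), optional gradient-boosted-tree head on deep features,
#' and held-out evaluation. Artifacts (manifests, history, model
#' checkpoints, JSON reports, and a reproducibility record) are written
#' under `config$work_dir`.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`: `reports` (per head),
#'   `report` (the primary head's report), `history`, `manifests`, `models`,
#'   `config`, `timings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  work <- config$work_dir
  dir.create(work, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tick <- function(stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }

  # 1. data
  if (identical(config$data$source, "synthetic")) {
    gp <- generator_params(n_per_class = config$data$n_per_class,
                           raw_width = config$data$raw_width,
                           raw_height = config$data$raw_height,
                           seed = config$seed,
                           test_fraction = config$data$test_fraction)
    manifest_raw <- generate_dataset(gp, file.path(work, "raw"))
  } else {
    manifest_raw <- read_image_folder(config$data$dir,
                                      config$data$test_fraction, config$seed)
  }
  tick("data")
  stage_msg("data", t0, sprintf("%d images, %d classes", nrow(manifest_raw),
                                length(unique(manifest_raw$label))))

  # 2. preprocessing (fluorescence simulation + resize)
  manifest <- preprocess_manifest(manifest_raw, config,
                                  file.path(work, "processed"))
  tick("preprocess")
  stage_msg("preprocess", t0,
            sprintf("resized to %d x %d (w x h)", config$preprocess$width,
                    config$preprocess$height))

  # 3. balancing augmentation (training split only)
  if (isTRUE(config$augment$balance)) {
    policy <- build_policy(config$augment$policy)
    manifest <- balance_training_set(manifest, policy, config$seed + 5L,
                                     out_dir = file.path(work, "augmented"))
  }
  utils::write.csv(manifest, file.path(work, "manifest.csv"),
                   row.names = FALSE)
  tick("augment")
  stage_msg("augment", t0,
            sprintf("train %d / test %d", sum(manifest$split == "train"),
                    sum(manifest$split == "test")))

  # 4. frozen backbones + pooled features
  bb <- list(
    build_backbone(config$backbones$families[1], config$backbones$scale,
                   config$seed + 1L, config$backbones$input_norm),
    build_backbone(config$backbones$families[2], config$backbones$scale,
                   config$seed + 2L, config$backbones$input_norm)
  )
  tr_man <- manifest[manifest$split == "train", , drop = FALSE]
  te_man <- manifest[manifest$split == "test", , drop = FALSE]
  if (nrow(tr_man) == 0L) stop("[features] training split is empty",
                               call. = FALSE)
  feats_tr <- manifest_features(bb, tr_man)
  feats_te <- if (nrow(te_man) > 0L) manifest_features(bb, te_man) else NULL
  tick("features")
  stage_msg("features", t0,
            sprintf("pooled %d + %d channels", bb[[1]]$output_channels,
                    bb[[2]]$output_channels))

  # 5. fusion head (always trained: the boosted head consumes its features)
  model <- build_fusion_model(bb[[1]]$output_channels,
                              bb[[2]]$output_channels,
                              num_classes = length(feats_tr$levels),
                              variant = config$model$variant,
                              fusion_mode = config$model$fusion_mode,
                              seed = config$seed + 3L,
                              hidden = config$model$hidden,
                              extended_units = config$model$extended_units)
  trained <- train_head(model, bb, epochs = config$train$epochs,
                        seed = config$seed + 4L,
                        batch_size = config$train$batch_size,
                        lr = config$train$lr,
                        val_fraction = config$train$val_fraction,
                        features = feats_tr)
  model <- trained$model
  tick("train")
  if (nrow(trained$history) > 0) {
    stage_msg("train", t0, sprintf("final train acc %.3f",
                                   trained$history$acc[nrow(trained$history)]))
  }

  reports <- list()
  models <- list(backbones = bb, fusion = model)
  if (!is.null(feats_te)) {
    truth <- te_man$label
    if (config$head %in% c("softmax", "both")) {
      probs <- predict_proba_features(model, feats_te$a, feats_te$b)
      pred <- feats_tr$levels[max.col(probs, ties.method = "first")]
      reports$softmax <- evaluate_predictions(truth, pred,
                                              labels = feats_tr$levels)
    }
    if (config$head %in% c("gbt", "both")) {
      rep_fn <- function(f) {
        if (config$gbt$representation == "penultimate") {
          head_forward(model, f$a, f$b, training = FALSE)$penultimate
        } else {
          head_forward(model, f$a, f$b, training = FALSE)$probs
        }
      }
      gbt_cfg <- gbt_config(eta = config$gbt$eta, lambda = config$gbt$lambda,
                            n_rounds = config$gbt$n_rounds,
                            max_depth = config$gbt$max_depth,
                            seed = config$seed + 6L)
      ens <- fit_gbt(rep_fn(feats_tr),
                     factor(feats_tr$levels[feats_tr$labels],
                            levels = feats_tr$levels), gbt_cfg)
      pred_g <- predict_gbt(ens, rep_fn(feats_te), type = "class")
      reports$gbt <- evaluate_predictions(truth, pred_g,
                                          labels = feats_tr$levels)
      models$gbt <- ens
    }
  }
  tick("evaluate")

  # 6. artifacts + reproducibility record
  art <- file.path(work, "artifacts")
  dir.create(art, showWarnings = FALSE)
  utils::write.csv(trained$history, file.path(art, "history.csv"),
                   row.names = FALSE)
  save_backbone(bb[[1]], file.path(art, "backbone_a.json"))
  save_backbone(bb[[2]], file.path(art, "backbone_b.json"))
  write_fusion_model(model, file.path(art, "fusion_model.json"))
  if (!is.null(models$gbt)) write_gbt(models$gbt, file.path(art, "gbt.json"))
  for (nm in names(reports)) {
    write_eval_report(reports[[nm]], file.path(art, paste0("report_", nm,
                                                           ".json")))
  }
  record <- list(config = unclass(config), seed = config$seed,
                 r_version = R.version.string,
                 package_version = tryCatch(
                   as.character(utils::packageVersion("fundusfusion")),
                   error = function(e) "dev"),
                 timestamp = format(Sys.time(), tz = "UTC"))
  writeLines(jsonlite::toJSON(record, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, null = "null"),
             file.path(art, "run_record.json"))
  tick("artifacts")

  primary <- if (config$head == "softmax") reports$softmax else reports$gbt
  structure(list(reports = reports, report = primary,
                 history = trained$history,
                 manifests = list(raw = manifest_raw, final = manifest),
                 models = models, config = config, timings = timings),
            class = "pipeline_result")
}

#' Compare model configurations under a shared budget
#'
#' Runs each configuration (which must agree on training epochs, so the
#' comparison is at equal budget) and assembles one macro-metric row per
#' model in the standard comparison layout.
#'
#' @param configs Named list of [pipeline_config()] objects.
#' @return A list with `table` (data frame: model, sensitivity,
#'   specificity, accuracy, f1) and `results` (the full pipeline results).
#' @export
compare_models <- function(configs) {
  stopifnot(length(configs) >= 2, !is.null(names(configs)))
  epochs <- vapply(configs, function(cf) as.integer(cf$train$epochs),
                   integer(1))
  if (length(unique(epochs)) != 1L) {
    stop("all configurations must train for the same number of epochs ",
         "(got ", paste(epochs, collapse = ", "), ")", call. = FALSE)
  }
  results <- lapply(configs, run_pipeline)
  reports <- lapply(results, function(r) r$report)
  list(table = comparison_table(reports), results = results)
}
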