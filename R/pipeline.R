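PIPELINE_DEFAULTS <- function() list(
  input = NULL,                # path to an on-disk image set; NULL = simulate
  out_dir = "ifcml_out",
  simulate = TRUE,
  counts = c(Int = 300, Pro = 38, Meta = 16, Ana = 15, Telo = 25),
  debris_frac = 0, doublet_frac = 0, defocus_frac = 0, defocus_sigma = 3,
  frame_size = 64, noise_sd = 0.01,
  tile_capacity = 1000,
  grms_min = "AUTO", area_min = 50, area_max = 460, aspect_min = 0.2,
  min_area = 9,
  n_rings = 4, n_wedges = 8,
  granularity_max = 8, granularity_bg = 10,
  glcm_dc = 3, glcm_levels = 8,
  exclude_patterns = c("Orientation", "Location", "Center"),
  algorithm = "gradient_boosting",
  hyperparams = list(),
  cap = 100, k_folds = 10,
  seed = 42)

#' Pipeline configuration
#'
#' Every stage parameter of the end-to-end protocol in one validated
#' list. Unknown keys are rejected; every field has a documented default
#' (see the package vignette). Set `input` to a directory written by
#' [write_imageset()] to analyse real data, or leave `simulate = TRUE`
#' to run on the default synthetic population.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `ifc_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- PIPELINE_DEFAULTS()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(!nzchar(names(over)))))
    stop("all configuration overrides must be named", call. = FALSE)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, over)
  stopifnot(cfg$cap >= 1, cfg$k_folds >= 2, cfg$tile_capacity >= 1)
  structure(cfg, class = "ifc_pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file of key-value overrides.
#' @return An `ifc_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$counts)) vals$counts <- unlist(vals$counts)
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline
#'
#' Executes the three-step protocol end to end — (optionally) simulate,
#' tile into montages, QC-gate, segment, extract features, build the
#' undersampled training set, train, cross-validate, score all remaining
#' cells, evaluate and rank features — writing every stage artifact under
#' `config$out_dir`: the image-set container, montage TIFFs and slot
#' maps, `qc.csv`, `features.csv` (+ registry JSON), `confusion.csv`,
#' `evaluation.json`, `top_features.csv` and `pipeline.log`. Identical
#' configuration and seed give identical artifacts.
#'
#' @param config An [pipeline_config()] object.
#' @param truth Optional ground-truth tibble (`cell_id, phase`) when
#'   `input` is used and the manifest has no labels.
#' @return Invisibly, a list with the main in-memory results: `images`,
#'   `truth`, `qc`, `features`, `training_set`, `model`, `cv` (the
#'   cross-validated `ifc_evaluation`), `scores`, `test_eval` (test-set
#'   evaluation, when labels allow), `ranking`.
#' @export
run_pipeline <- function(config = pipeline_config(), truth = NULL) {
  stopifnot(inherits(config, "ifc_pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "pipeline.log")
  cat("", file = log_path)
  logf <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s", stage, sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  stage <- "simulate"
  res <- tryCatch({
    if (isTRUE(config$simulate) && is.null(config$input)) {
      pop <- generate_population(simulation_config(
        counts = config$counts, debris_frac = config$debris_frac,
        doublet_frac = config$doublet_frac, defocus_frac = config$defocus_frac,
        defocus_sigma = config$defocus_sigma, frame_size = config$frame_size,
        noise_sd = config$noise_sd, seed = config$seed))
      images <- pop$images
      truth <- pop$truth
      write_imageset(images, file.path(out, "imageset"))
      readr::write_csv(truth, file.path(out, "ground_truth.csv"))
      logf(stage, "simulated %d cells (seed %d)", length(images), config$seed)
    } else {
      stage <- "load"
      images <- read_imageset(config$input)
      if (is.null(truth)) {
        truth <- tibble::tibble(cell_id = cell_ids(images),
                                phase = cell_labels(images),
                                contaminant = "none")
      }
      logf(stage, "loaded %d cells from %s", length(images), config$input)
    }

    stage <- "tile"
    tiles <- pack_montages(images, config$tile_capacity)
    write_montages(tiles, file.path(out, "montages"))
    logf(stage, "%d tile(s), capacity %d", length(tiles), config$tile_capacity)

    stage <- "segment"
    masks <- segment_imageset(images, min_area = config$min_area)
    logf(stage, "%d masks, %d empty", length(masks),
         sum(vapply(masks, function(m) !any(m), logical(1))))

    stage <- "qc"
    qc <- apply_gates(images, masks, gate_config(
      grms_min = config$grms_min, area_min = config$area_min,
      area_max = config$area_max, aspect_min = config$aspect_min))
    write_qc_result(qc, file.path(out, "qc.csv"))
    logf(stage, "kept %d / %d", length(qc$kept_ids), length(images))
    kept <- subset_imageset(images, qc$kept_ids)

    stage <- "features"
    features <- extract_feature_table(
      kept, masks, n_rings = config$n_rings, n_wedges = config$n_wedges,
      granularity_max = config$granularity_max,
      granularity_bg = config$granularity_bg,
      glcm_dc = config$glcm_dc, glcm_levels = config$glcm_levels)
    write_feature_table(features, file.path(out, "features.csv"))
    logf(stage, "%d cells x %d features", nrow(features), ncol(features) - 2L)
    filtered <- filter_features(features, config$exclude_patterns)

    stage <- "train"
    labels <- stats::setNames(truth$phase, truth$cell_id)[filtered$cell_id]
    ts <- build_training_set(labels, cap = config$cap, seed = config$seed)
    model <- train_classifier(ts, filtered, config$algorithm,
                              config$hyperparams, seed = config$seed)
    logf(stage, "%s on %d cells (cap %d)", config$algorithm,
         length(ts$cell_ids), config$cap)

    stage <- "evaluate"
    cv <- cross_validate(ts, filtered, config$algorithm, config$hyperparams,
                         k = config$k_folds, seed = config$seed)
    scores <- score_all(model, filtered)
    test_eval <- NULL
    test_truth <- labels[scores$cell_id]
    if (nrow(scores) && !anyNA(test_truth)) {
      test_eval <- confusion_matrix_pct(
        as.character(test_truth), scores$predicted,
        note = sprintf("test set: %d cells outside the training set",
                       nrow(scores)))
    }
    write_evaluation(cv, file.path(out, "confusion.csv"))
    readr::write_csv(scores, file.path(out, "predictions.csv"))
    logf(stage, "CV macro TPR %.2f%%; scored %d held-out cells",
         glance(cv)$macro_tpr, nrow(scores))

    stage <- "rank"
    ranking <- rank_features(model)
    readr::write_csv(as.data.frame(ranking), file.path(out, "top_features.csv"))
    logf(stage, "top feature: %s", ranking$feature[1])

    list(images = images, truth = truth, qc = qc, features = features,
         training_set = ts, model = model, cv = cv, scores = scores,
         test_eval = test_eval, ranking = ranking)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Write an evaluation report as CSV plus JSON
#' @param x An `ifc_evaluation`.
#' @param path CSV output path (confusion matrix in table layout); a JSON
#'   report with TPRs and support is written next to it.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(x, path) {
  df <- cbind(data.frame(True = rownames(x$confusion)),
              as.data.frame(round(x$confusion, 2)))
  readr::write_csv(df, path)
  jsonlite::write_json(
    list(tpr = as.list(round(x$tpr, 2)), support = as.list(x$support),
         macro_tpr = glance(x)$macro_tpr, note = x$note),
    sub("\\.csv$", ".json", path), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
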