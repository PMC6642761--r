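#' Pipeline configuration
#'
#' Collects every tunable of the extraction + evaluation chain in one
#' validated list. Defaults are the study settings: `k = 4` windows,
#' adaptive tolerance `T = 0.06`, channels-only trajectory space,
#' `sigma = 0.90` cumulative-eigenvalue precision, centred projection,
#' random-forest backend, stratified 10-fold cross-validation.
#'
#' @param input Input path (Bonn-dialect parent directory with one
#'   subdirectory per class, or a CSV per class), or `NULL` to simulate.
#' @param format `"bonn"` or `"csv"`.
#' @param k Windows per record.
#' @param T Adaptive tolerance percentage.
#' @param space Trajectory space, `"channels"` or `"time"`.
#' @param time_scale Time-coordinate scale for `"time"` space.
#' @param sigma Cumulative eigenvalue fraction for component selection.
#' @param center Centre before projection.
#' @param classifier Backend id: `"rf"`, `"knn"`, `"svm"`, `"dt"`.
#' @param hyperparameters Named list passed to the backend.
#' @param folds Cross-validation fold count.
#' @param seed Integer seed for folds (and simulation when no input).
#' @param fold_safe_pca Refit PCA inside each training fold.
#' @param synth A [synthetic_config()] used when `input` is `NULL`.
#' @param out_dir Output directory for the `cmd_*` runners.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, format = c("bonn", "csv"),
                            k = 4L, T = 0.06,
                            space = c("channels", "time"), time_scale = 1,
                            sigma = 0.90, center = TRUE,
                            classifier = c("rf", "knn", "svm", "dt"),
                            hyperparameters = list(),
                            folds = 10L, seed = 1L,
                            fold_safe_pca = FALSE,
                            synth = synthetic_config(seed = seed),
                            out_dir = ".") {
  format <- match.arg(format)
  space <- match.arg(space)
  classifier <- match.arg(classifier)
  stopifnot(k >= 1L, T >= 0, sigma > 0, sigma <= 1, folds >= 2L)
  structure(list(input = input, format = format, k = as.integer(k), T = T,
                 space = space, time_scale = time_scale, sigma = sigma,
                 center = center, classifier = classifier,
                 hyperparameters = hyperparameters,
                 folds = as.integer(folds), seed = as.integer(seed),
                 fold_safe_pca = fold_safe_pca, synth = synth,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; keys under `synth:`
#' are passed to [synthetic_config()]. Flags given in `overrides` win
#' over file values.
#'
#' @param path YAML file path.
#' @param overrides Named list of overriding values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals[names(overrides)] <- overrides
  synth_args <- vals$synth
  vals$synth <- NULL
  if (!is.null(synth_args))
    vals$synth <- do.call(synthetic_config, synth_args)
  do.call(pipeline_config, vals)
}

load_records <- function(cfg) {
  if (is.null(cfg$input)) return(generate_dataset(cfg$synth))
  if (cfg$format == "bonn") {
    dirs <- list.dirs(cfg$input, recursive = FALSE)
    dirs <- sort(dirs, method = "radix")
    if (length(dirs) == 0L)
      stop("no class subdirectories under ", cfg$input, call. = FALSE)
    lapply(seq_along(dirs), function(i)
      read_bonn_set(dirs[i], class_label = i))
  } else {
    files <- Sys.glob(file.path(cfg$input, "*.csv"))
    files <- sort(files, method = "radix")
    if (length(files) == 0L)
      stop("no CSV files under ", cfg$input, call. = FALSE)
    lapply(seq_along(files), function(i)
      read_matrix(files[i], class_label = i))
  }
}

#' Run the full extraction + evaluation pipeline
#'
#' Loads (or simulates) the class records, builds the DP sample set,
#' fits PCA and projects to the feature set, and cross-validates the
#' configured backend. The resolved configuration is embedded in the
#' returned report.
#'
#' @param cfg A [pipeline_config()].
#' @param records Optional pre-loaded list of [eeg_record]s (skips input
#'   loading).
#' @return A list with `records`, `samples` (`dp_sample_set`), `model`
#'   (`dp_pca_model`), `features` (`dp_feature_set`), `report`
#'   (`evaluation_report`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), records = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(records)) records <- load_records(cfg)
  samples <- build_sample_set(records, k = cfg$k, T = cfg$T,
                              space = cfg$space,
                              time_scale = cfg$time_scale)
  model <- fit_pca(samples, sigma = cfg$sigma)
  features <- project_features(samples, model, center = cfg$center)
  spec <- do.call(classifier_spec,
                  c(list(backend = cfg$classifier), cfg$hyperparameters))
  folds <- stratified_folds(samples$labels, k = cfg$folds, seed = cfg$seed)
  report <- cross_validate(features, spec, folds,
                           fold_safe_pca = cfg$fold_safe_pca,
                           samples = if (cfg$fold_safe_pca) samples,
                           sigma = cfg$sigma, center = cfg$center)
  report$parameters <- c(report$parameters,
                         list(pipeline = cfg[c("k", "T", "space",
                                               "time_scale", "sigma",
                                               "center", "classifier",
                                               "fold_safe_pca")]))
  list(records = records, samples = samples, model = model,
       features = features, report = report)
}

#' Tolerance sweep summary
#'
#' Rebuilds the DP sample set for each value of `T` and reports the
#' retained counts and compression, the exploration used to fix the
#' working tolerance (the study swept 0.01..0.1 in steps of 0.01).
#'
#' @param records List of [eeg_record]s.
#' @param T_values Tolerances to sweep (default `seq(0.01, 0.1, 0.01)`).
#' @inheritParams build_sample_set
#' @return data.frame with one row per `T`: `T`, `n_total`, `n_original`,
#'   `compression_pct`.
#' @export
sweep_tolerance <- function(records, T_values = seq(0.01, 0.1, by = 0.01),
                            k = 4L, space = c("channels", "time"),
                            time_scale = 1) {
  space <- match.arg(space)
  rows <- lapply(T_values, function(tv) {
    ss <- build_sample_set(records, k = k, T = tv, space = space,
                           time_scale = time_scale)
    data.frame(T = tv, n_total = nrow(ss$data),
               n_original = ss$n_original,
               compression_pct = 100 * ss$compression)
  })
  do.call(rbind, rows)
}
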