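#' Stratified k-fold assignments
#'
#' Within each class, samples are shuffled by a seeded RNG and dealt
#' round-robin to the folds, so per-class counts across folds differ by at
#' most one. With `stratified = FALSE` the pooled samples are shuffled and
#' dealt regardless of class (so `k = n` gives leave-one-out).
#'
#' @param labels Per-sample class labels.
#' @param k Fold count (default 10).
#' @param seed Integer RNG seed (mandatory, recorded in reports).
#' @param stratified Stratify by class (default TRUE).
#' @return An object of class `fold_split`: list with `k`, `assignments`
#'   (per-sample fold id in 1..k), `seed`, `stratified`.
#' @export
stratified_folds <- function(labels, k = 10L, seed, stratified = TRUE) {
  n <- length(labels)
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2", call. = FALSE)
  if (k > n) stop("k cannot exceed the number of samples", call. = FALSE)
  if (missing(seed) || !is.numeric(seed))
    stop("a numeric seed is required", call. = FALSE)
  counts <- table(labels)
  if (stratified && any(counts < k))
    warning("some classes have fewer than k samples; ",
            "their folds will not all be populated")
  assignments <- integer(n)
  rng <- local_rng(seed)
  if (stratified) {
    start <- 0L
    for (lv in names(counts)) {
      idx <- which(as.character(labels) == lv)
      idx <- idx[rng$sample_int(length(idx))]
      # continue dealing across classes so fold sizes stay balanced
      assignments[idx] <- ((start + seq_along(idx) - 1L) %% k) + 1L
      start <- start + length(idx)
    }
  } else {
    idx <- rng$sample_int(n)
    assignments[idx] <- ((seq_len(n) - 1L) %% k) + 1L
  }
  structure(list(k = k, assignments = assignments,
                 seed = as.integer(seed), stratified = stratified),
            class = "fold_split")
}

# Seeded RNG scoped to this object; does not disturb the global stream.
local_rng <- function(seed) {
  state <- NULL
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    if (is.null(state)) set.seed(seed) else assign(".Random.seed", state,
                                                   globalenv())
    out <- f()
    state <<- get(".Random.seed", globalenv())
    out
  }
  list(sample_int = function(n) with_state(function() sample.int(n)))
}

#' Cross-validate a classifier on a feature set
#'
#' For each fold, fits the backend on the remaining folds, predicts the
#' held-out fold, and computes the full metric suite (per-class
#' sensitivity, FPR, specificity, OCA, kappa, one-vs-rest AUC) from the
#' fold's confusion matrix. Aggregates are the mean and sample standard
#' deviation (n - 1) across folds.
#'
#' With `fold_safe_pca = TRUE` the PCA model is refitted inside each
#' training split and both splits are projected with it -- the
#' leakage-free variant; `samples` must then be the `dp_sample_set` and
#' `sigma` / `center` give the PCA settings. The default (`FALSE`)
#' evaluates the features as given, i.e. the model fitted once on the
#' full sample set.
#'
#' @param features A `dp_feature_set` (ignored when `fold_safe_pca`).
#' @param spec A [classifier_spec()].
#' @param folds A [stratified_folds()] split over the same samples.
#' @param fold_safe_pca Refit PCA within each training fold.
#' @param samples `dp_sample_set`, required when `fold_safe_pca`.
#' @param sigma,center PCA settings for the fold-safe mode.
#' @return An object of class `evaluation_report`: list with `per_fold`
#'   (one entry per fold: `fold`, `n_test`, `confusion` matrix, `se`,
#'   `fpr`, `sp` per class, `oca`, `kappa`, `po`, `pe`, `auc` per class,
#'   `auc_overall`), `aggregate` (mean and sd per metric), `class_order`,
#'   `parameters`.
#' @export
cross_validate <- function(features = NULL, spec, folds, fold_safe_pca = FALSE,
                           samples = NULL, sigma = 0.90, center = TRUE) {
  stopifnot(inherits(spec, "classifier_spec"),
            inherits(folds, "fold_split"))
  if (fold_safe_pca) {
    if (!inherits(samples, "dp_sample_set"))
      stop("fold_safe_pca = TRUE requires the dp_sample_set in `samples`",
           call. = FALSE)
    labels <- samples$labels
    n <- nrow(samples$data)
  } else {
    stopifnot(inherits(features, "dp_feature_set"))
    labels <- features$labels
    n <- nrow(features$features)
  }
  if (length(folds$assignments) != n)
    stop("fold split does not match the sample count", call. = FALSE)
  lev <- sort(unique(labels))
  y <- factor(labels, levels = lev)
  backend <- make_backend(spec)
  per_fold <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    test <- which(folds$assignments == f)
    train <- which(folds$assignments != f)
    if (length(test) == 0L) next
    if (fold_safe_pca) {
      model_f <- fit_pca(samples$data[train, , drop = FALSE], sigma = sigma)
      Xtr <- project_features(samples$data[train, , drop = FALSE], model_f,
                              center = center)$features
      Xte <- project_features(samples$data[test, , drop = FALSE], model_f,
                              center = center)$features
    } else {
      Xtr <- features$features[train, , drop = FALSE]
      Xte <- features$features[test, , drop = FALSE]
    }
    ytr <- droplevels(y[train])
    if (nlevels(ytr) < nlevels(y))
      warning(sprintf("fold %d: class absent from training split", f))
    model <- tryCatch(backend$fit(Xtr, ytr), error = function(e)
      stop(sprintf("backend '%s' failed on fold %d: %s", spec$backend, f,
                   conditionMessage(e)), call. = FALSE))
    pred <- as.character(backend$predict(model, Xte))
    sc_raw <- backend$scores(model, Xte)
    # align score columns to the global class order; absent classes get 0
    sc <- matrix(0, nrow = length(test), ncol = length(lev),
                 dimnames = list(NULL, as.character(lev)))
    common <- intersect(colnames(sc_raw), colnames(sc))
    sc[, common] <- as.matrix(sc_raw)[, common]
    cm <- confusion_matrix(as.character(y[test]), pred,
                           levels = as.character(lev))
    m <- as_cm(cm)
    total <- sum(m)
    po <- sum(diag(m)) / total
    pe <- sum((rowSums(m) / total) * (colSums(m) / total))
    auc <- auc_one_vs_rest(sc, as.character(y[test]))
    per_fold[[f]] <- list(
      fold = f, n_test = length(test), confusion = m,
      se = suppressWarnings(sensitivity(cm)), fpr = fpr(cm),
      sp = specificity(cm), oca = oca(cm),
      kappa = kappa_statistic(cm), po = po, pe = pe,
      auc = as.numeric(auc), auc_overall = attr(auc, "overall"))
  }
  per_fold <- per_fold[!vapply(per_fold, is.null, logical(1))]
  agg <- aggregate_folds(per_fold, as.character(lev))
  structure(
    list(per_fold = per_fold, aggregate = agg,
         class_order = lev,
         parameters = list(
           backend = spec$backend,
           hyperparameters = spec$hyperparameters,
           folds = folds$k, seed = folds$seed,
           stratified = folds$stratified,
           fold_safe_pca = fold_safe_pca,
           sigma = if (fold_safe_pca) sigma else
             if (!is.null(features$model)) features$model$sigma else NA,
           q = if (!fold_safe_pca && !is.null(features$model))
             features$model$q else NA)),
    class = "evaluation_report")
}

# mean +/- sample sd (n-1) across folds; NA metrics excluded per entry
aggregate_folds <- function(per_fold, lev) {
  scalar <- function(name) {
    v <- vapply(per_fold, function(x) x[[name]], numeric(1))
    v <- v[!is.na(v)]
    list(mean = mean(v), sd = stats::sd(v))
  }
  perclass <- function(name) {
    m <- do.call(rbind, lapply(per_fold, `[[`, name))
    list(mean = apply(m, 2L, mean, na.rm = TRUE),
         sd = apply(m, 2L, stats::sd, na.rm = TRUE))
  }
  list(oca = scalar("oca"), kappa = scalar("kappa"),
       auc_overall = scalar("auc_overall"),
       se = perclass("se"), fpr = perclass("fpr"), sp = perclass("sp"),
       auc = perclass("auc"), class_order = lev)
}

#' @export
print.evaluation_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<evaluation_report> %s backend, %d folds (seed %d)\n",
              x$parameters$backend, length(x$per_fold), x$parameters$seed))
  cat(sprintf("  OCA   %.2f +/- %.2f %%\n", a$oca$mean, a$oca$sd))
  cat(sprintf("  kappa %.4f +/- %.4f\n", a$kappa$mean, a$kappa$sd))
  cat(sprintf("  AUC   %.4f +/- %.4f\n", a$auc_overall$mean,
              a$auc_overall$sd))
  cls <- a$class_order
  for (i in seq_along(cls))
    cat(sprintf("  class %s: Se %.2f%%  Sp %.2f%%  FPR %.2f%%\n",
                cls[i], a$se$mean[i], a$sp$mean[i], a$fpr$mean[i]))
  invisible(x)
}
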