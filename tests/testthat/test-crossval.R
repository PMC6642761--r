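# small separable two-class feature set used across blocks
make_separable <- function(n_per = 30L, seed = 9L) {
  withr::with_seed(seed, {
    F <- rbind(matrix(rnorm(n_per * 2, mean = 0), n_per, 2),
               matrix(rnorm(n_per * 2, mean = 8), n_per, 2))
  })
  structure(list(features = F,
                 labels = rep(1:2, each = n_per), model = NULL),
            class = "dp_feature_set")
}

test_that("stratified folds balance every class to within one sample", {
  labels <- rep(c("A", "B"), each = 4)
  fs <- stratified_folds(labels, k = 2L, seed = 1L)
  for (f in 1:2) {
    got <- table(labels[fs$assignments == f])
    expect_equal(unname(c(got)), c(2L, 2L))
  }
  withr::with_seed(10, {
    labels2 <- sample(rep(1:3, times = c(17, 23, 9)))
  })
  fs2 <- stratified_folds(labels2, k = 5L, seed = 77L)
  expect_setequal(unique(fs2$assignments), 1:5)
  for (cl in 1:3) {
    per_fold <- tabulate(fs2$assignments[labels2 == cl], 5L)
    expect_lte(max(per_fold) - min(per_fold), 1L)
  }
})

test_that("fold assignment is a pure function of labels and seed", {
  labels <- rep(1:3, times = c(12, 15, 9))
  a <- stratified_folds(labels, k = 4L, seed = 42L)$assignments
  b <- stratified_folds(labels, k = 4L, seed = 42L)$assignments
  expect_identical(a, b)
  c <- stratified_folds(labels, k = 4L, seed = 43L)$assignments
  expect_false(identical(a, c))
})

test_that("unstratified k = n dealing gives leave-one-out folds", {
  labels <- seq_len(8)
  fs <- stratified_folds(labels, k = 8L, seed = 3L, stratified = FALSE)
  expect_equal(sort(tabulate(fs$assignments, 8L)), rep(1L, 8))
})

test_that("fold argument errors and warnings fire", {
  labels <- rep(1:2, each = 5)
  expect_error(stratified_folds(labels, k = 1L, seed = 1L), ">= 2")
  expect_error(stratified_folds(labels, k = 11L, seed = 1L), "exceed")
  expect_error(stratified_folds(labels, k = 5L), "seed")
  expect_warning(stratified_folds(rep(1:2, times = c(2, 8)), k = 4L,
                                  seed = 1L), "fewer than k")
})

test_that("separable classes are classified perfectly by every backend", {
  features <- make_separable()
  folds <- stratified_folds(features$labels, k = 5L, seed = 2L)
  for (backend in c("rf", "knn", "svm", "dt")) {
    rep <- cross_validate(features, classifier_spec(backend), folds)
    expect_equal(rep$aggregate$oca$mean, 100,
                 info = backend)
    expect_equal(unname(rep$aggregate$fpr$mean), c(0, 0), info = backend)
    expect_equal(rep$aggregate$kappa$mean, 1, info = backend)
  }
})

test_that("per-fold bookkeeping is consistent and recomputable", {
  features <- make_separable(n_per = 20L, seed = 21L)
  folds <- stratified_folds(features$labels, k = 4L, seed = 5L)
  rep <- cross_validate(features, classifier_spec("dt"), folds)
  expect_length(rep$per_fold, 4L)
  tot <- vapply(rep$per_fold, function(x) sum(x$confusion), numeric(1))
  expect_equal(tot, vapply(1:4, function(f)
    sum(folds$assignments == f), numeric(1)))
  expect_equal(sum(tot), 40)
  # aggregate mean equals the hand average of per-fold values
  expect_equal(rep$aggregate$oca$mean,
               mean(vapply(rep$per_fold, `[[`, numeric(1), "oca")))
  expect_equal(rep$aggregate$kappa$sd,
               sd(vapply(rep$per_fold, `[[`, numeric(1), "kappa")))
  # OCA equals the class-size-weighted mean of sensitivities
  for (pf in rep$per_fold) {
    rs <- rowSums(pf$confusion)
    expect_equal(pf$oca, sum(pf$se * rs) / sum(rs))
  }
})

test_that("permuted labels score at chance level", {
  withr::with_seed(1234, {
    F <- matrix(rnorm(300 * 3), 300, 3)
    labels <- rep(1:3, each = 100)
    features <- structure(list(features = F, labels = sample(labels),
                               model = NULL), class = "dp_feature_set")
  })
  folds <- stratified_folds(features$labels, k = 10L, seed = 6L)
  rep <- cross_validate(features, classifier_spec("knn"), folds)
  expect_gt(rep$aggregate$oca$mean, 23)
  expect_lt(rep$aggregate$oca$mean, 43)
  expect_gt(rep$aggregate$kappa$mean, -0.15)
  expect_lt(rep$aggregate$kappa$mean, 0.15)
})

test_that("fold-safe PCA refits inside each training split", {
  rec1 <- make_record(n = 120L, p = 4L, class_label = 1L, seed = 61L)
  rec2 <- eeg_record(make_record(n = 120L, p = 4L, seed = 62L)$data + 6,
                     class_label = 2L)
  samples <- build_sample_set(list(rec1, rec2), k = 2L, T = 0.02)
  folds <- stratified_folds(samples$labels, k = 3L, seed = 8L)
  rep <- cross_validate(spec = classifier_spec("knn"), folds = folds,
                        fold_safe_pca = TRUE, samples = samples,
                        sigma = 0.9)
  expect_length(rep$per_fold, 3L)
  expect_true(rep$parameters$fold_safe_pca)
  expect_gt(rep$aggregate$oca$mean, 90)
  expect_error(cross_validate(spec = classifier_spec("knn"), folds = folds,
                              fold_safe_pca = TRUE), "dp_sample_set")
})

test_that("the kernel cost heuristic scales with the training set", {
  withr::with_seed(14, {
    X <- matrix(rnorm(40), 20, 2)
    C <- svm_cost_heuristic(X)
    # direct evaluation of N / sum K(x_i, xbar)
    xbar <- colMeans(X)
    K <- (drop(X %*% xbar) / 2)^3
    expect_equal(C, 20 / sum(K))
    rep <- cross_validate(make_separable(),
                          classifier_spec("svm", cost = "heuristic"),
                          stratified_folds(rep(1:2, each = 30), k = 3L,
                                           seed = 4L))
    expect_gt(rep$aggregate$oca$mean, 85)
  })
})
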