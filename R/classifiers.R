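#' Classifier backend specification
#'
#' The evaluation harness treats classifiers as pluggable backends behind
#' a fit / predict / scores contract; the learning algorithms themselves
#' are delegated to established implementations:
#' \describe{
#'   \item{`"rf"`}{random forest via \pkg{randomForest} (500 trees).}
#'   \item{`"knn"`}{k-nearest neighbour via \pkg{class} (k = 1,
#'     Euclidean distance); scores are the one-hot vote of the winner.}
#'   \item{`"svm"`}{polynomial-kernel support vector machine via
#'     \pkg{e1071} (one-against-one pairwise voting, probability model
#'     for scores). Set `cost = "heuristic"` to use the kernel-based
#'     cost rule `C = N / sum_i K(x_i, xbar)` evaluated at the training
#'     mean `xbar` (see [svm_cost_heuristic()]).}
#'   \item{`"dt"`}{C4.5-style decision tree via \pkg{rpart}.}
#' }
#'
#' @param backend One of `"rf"`, `"knn"`, `"svm"`, `"dt"`.
#' @param ... Backend hyperparameters (e.g. `ntree`, `k`, `cost`,
#'   `degree`), passed through to the underlying implementation.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(backend = c("rf", "knn", "svm", "dt"), ...) {
  backend <- match.arg(backend)
  structure(list(backend = backend, hyperparameters = list(...)),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- if (length(x$hyperparameters))
    paste(names(x$hyperparameters),
          vapply(x$hyperparameters, format, character(1)),
          sep = "=", collapse = ", ") else "defaults"
  cat(sprintf("<classifier_spec> %s (%s)\n", x$backend, hp))
  invisible(x)
}

#' Kernel-based SVM cost heuristic
#'
#' Sets the SVM regularisation parameter from the training data as
#' `C = N / sum_i K(x_i, xbar)` where `xbar` is the training mean and `K`
#' the polynomial kernel `(gamma * <u, v> + coef0)^degree`. This scales
#' the error/complexity trade-off by the typical kernel magnitude of the
#' training set.
#'
#' @param X Training feature matrix.
#' @param degree,gamma,coef0 Polynomial kernel parameters; `gamma`
#'   defaults to `1 / ncol(X)` as in \pkg{e1071}.
#' @return Positive scalar cost.
#' @export
svm_cost_heuristic <- function(X, degree = 3, gamma = 1 / ncol(X),
                               coef0 = 0) {
  X <- as.matrix(X)
  xbar <- colMeans(X)
  kv <- (gamma * drop(X %*% xbar) + coef0)^degree
  s <- sum(kv)
  if (!is.finite(s) || s <= 0)
    stop("kernel sum is not positive; heuristic cost undefined",
         call. = FALSE)
  nrow(X) / s
}

# Internal: instantiate the fit/predict/scores closure triple for a spec.
# fit(X, y) -> model object; predict(model, X) -> factor labels;
# scores(model, X) -> matrix n x c with colnames = class levels,
# rows summing to ~1.
make_backend <- function(spec) {
  hp <- spec$hyperparameters
  arg <- function(name, default) if (!is.null(hp[[name]])) hp[[name]] else default
  switch(
    spec$backend,
    rf = list(
      fit = function(X, y) {
        randomForest::randomForest(x = X, y = y,
                                   ntree = arg("ntree", 500L),
                                   mtry = arg("mtry",
                                              max(1L, floor(sqrt(ncol(X))))))
      },
      predict = function(model, X) stats::predict(model, X),
      scores = function(model, X)
        stats::predict(model, X, type = "prob")),
    knn = list(
      fit = function(X, y) list(X = X, y = y, k = arg("k", 1L)),
      predict = function(model, X)
        class::knn(model$X, X, model$y, k = model$k),
      scores = function(model, X) {
        pred <- class::knn(model$X, X, model$y, k = model$k, prob = TRUE)
        lev <- levels(model$y)
        pwin <- attr(pred, "prob")  # winning-class vote fraction
        s <- matrix((1 - pwin) / max(1L, length(lev) - 1L),
                    nrow = length(pred), ncol = length(lev),
                    dimnames = list(NULL, lev))
        s[cbind(seq_along(pred), as.integer(pred))] <- pwin
        s
      }),
    svm = list(
      fit = function(X, y) {
        cost <- arg("cost", 1)
        degree <- arg("degree", 3)
        gamma <- arg("gamma", 1 / ncol(X))
        coef0 <- arg("coef0", 0)
        if (identical(cost, "heuristic"))
          cost <- svm_cost_heuristic(X, degree = degree, gamma = gamma,
                                     coef0 = coef0)
        e1071::svm(x = X, y = y, kernel = "polynomial", degree = degree,
                   gamma = gamma, coef0 = coef0, cost = cost,
                   probability = TRUE)
      },
      predict = function(model, X) stats::predict(model, X),
      scores = function(model, X) {
        pr <- stats::predict(model, X, probability = TRUE)
        s <- attr(pr, "probabilities")
        s[, model$levels[model$levels %in% colnames(s)], drop = FALSE]
      }),
    dt = list(
      fit = function(X, y) {
        df <- as.data.frame(X)
        df$.class <- y
        rpart::rpart(.class ~ ., data = df, method = "class",
                     control = rpart::rpart.control(
                       cp = arg("cp", 0.01), minsplit = arg("minsplit", 20L)))
      },
      predict = function(model, X)
        stats::predict(model, as.data.frame(X), type = "class"),
      scores = function(model, X)
        stats::predict(model, as.data.frame(X), type = "prob")),
    stop("unknown backend: ", spec$backend, call. = FALSE))
}
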