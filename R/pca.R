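#' Fit PCA on a DP sample set
#'
#' Principal component analysis of the retained samples: the covariance
#' matrix is `(1/n) * sum_i (x_i - mu)(x_i - mu)^T` (population form; the
#' normalisation cancels in the eigenvalue ratios used for component
#' selection) and is eigendecomposed symmetrically. Eigenpairs are sorted
#' by descending eigenvalue and each eigenvector's sign is fixed so that
#' its largest-magnitude entry is positive, making feature files
#' reproducible across platforms.
#'
#' @param samples A `dp_sample_set` or a numeric matrix (rows = samples).
#' @param sigma Cumulative eigenvalue fraction in (0, 1] for component
#'   selection (default 0.90).
#'
#' @return An object of class `dp_pca_model`: list with `mean`,
#'   `eigenvalues` (descending, clamped to >= 0 at tolerance
#'   `1e-8 * lambda_1`), `eigenvectors` (p x p, columns aligned with
#'   eigenvalues), `sigma`, `q` (selected component count), `n_fit`.
#' @export
fit_pca <- function(samples, sigma = 0.90) {
  X <- if (inherits(samples, "dp_sample_set")) samples$data
       else as.matrix(samples)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 samples to fit PCA", call. = FALSE)
  if (!all(is.finite(X))) stop("non-finite values in sample set", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / n
  eg <- eigen(C, symmetric = TRUE)
  lambda <- eg$values
  U <- eg$vectors
  # numerical negatives are clamped; anything below -tol is a real problem
  tol <- 1e-8 * max(lambda[1], 0)
  if (any(lambda < -tol - 1e-300))
    warning("covariance eigenvalues below -tol; clamping")
  lambda <- pmax(lambda, 0)
  # deterministic sign: largest-|entry| of each column made positive
  for (j in seq_len(p)) {
    w <- which.max(abs(U[, j]))
    if (U[w, j] < 0) U[, j] <- -U[, j]
  }
  # an all-zero spectrum (all rows identical) leaves nothing to select;
  # keep one component rather than failing the fit
  q <- if (sum(lambda) == 0) 1L else select_components(lambda, sigma)
  structure(list(mean = mu, eigenvalues = lambda, eigenvectors = U,
                 sigma = sigma, q = q, n_fit = n),
            class = "dp_pca_model")
}

#' @export
print.dp_pca_model <- function(x, ...) {
  p <- length(x$eigenvalues)
  expl <- sum(x$eigenvalues[seq_len(x$q)]) / sum(x$eigenvalues)
  cat(sprintf(
    "<dp_pca_model> p = %d, q = %d at sigma = %g (%.2f%% variance), n = %d\n",
    p, x$q, x$sigma, 100 * expl, x$n_fit))
  invisible(x)
}

#' Select the number of principal components
#'
#' Smallest `q` whose leading eigenvalues account for at least a fraction
#' `sigma` of the total variance:
#' `q = min { q : sum_{i<=q} lambda_i / sum_{i<=p} lambda_i >= sigma }`.
#'
#' @param eigenvalues Nonnegative eigenvalues in descending order.
#' @param sigma Target cumulative fraction in (0, 1].
#' @return Positive integer `q`.
#' @export
#' @examples
#' select_components(c(5, 3, 1, 1), 0.9)  # 3
select_components <- function(eigenvalues, sigma = 0.90) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0 || sigma > 1)
    stop("sigma must be in (0, 1]", call. = FALSE)
  if (any(eigenvalues < 0))
    stop("eigenvalues must be nonnegative", call. = FALSE)
  total <- sum(eigenvalues)
  if (total == 0) stop("degenerate spectrum: all eigenvalues zero",
                       call. = FALSE)
  if (is.unsorted(rev(eigenvalues)))
    stop("eigenvalues must be in descending order", call. = FALSE)
  which(cumsum(eigenvalues) / total >= sigma - 1e-12)[1]
}

#' Project samples onto the selected principal components
#'
#' Computes the q-dimensional feature set `(X - 1 mu^T) U_q` (centred,
#' the default) or the literal uncentred product `X U_q`. Centring only
#' shifts every feature by a constant, which no downstream classifier is
#' sensitive to, but it makes the usual PCA identities (zero-mean,
#' variance = eigenvalue) hold on the fitting data.
#'
#' @param samples A `dp_sample_set` or numeric matrix with the model's `p`
#'   columns.
#' @param model A `dp_pca_model`.
#' @param center Subtract the model mean before projecting (default TRUE).
#' @param q Number of components (default `model$q`).
#' @param labels Per-row labels; taken from `samples` when it is a
#'   `dp_sample_set`.
#'
#' @return An object of class `dp_feature_set`: list with `features`
#'   (n x q), `labels`, `model`.
#' @export
project_features <- function(samples, model, center = TRUE, q = model$q,
                             labels = NULL) {
  stopifnot(inherits(model, "dp_pca_model"))
  X <- if (inherits(samples, "dp_sample_set")) samples$data
       else as.matrix(samples)
  if (is.null(labels) && inherits(samples, "dp_sample_set"))
    labels <- samples$labels
  p <- length(model$mean)
  if (ncol(X) != p)
    stop(sprintf("sample dimension %d does not match model p = %d",
                 ncol(X), p), call. = FALSE)
  q <- as.integer(q)
  if (q < 1L || q > p) stop("q must be in 1..p", call. = FALSE)
  if (center) X <- sweep(X, 2L, model$mean)
  F <- X %*% model$eigenvectors[, seq_len(q), drop = FALSE]
  colnames(F) <- paste0("f", seq_len(q))
  structure(list(features = F,
                 labels = if (is.null(labels))
                   rep(NA_integer_, nrow(F)) else labels,
                 model = model),
            class = "dp_feature_set")
}

#' @export
print.dp_feature_set <- function(x, ...) {
  cat(sprintf("<dp_feature_set> %d samples x %d features, %d classes\n",
              nrow(x$features), ncol(x$features),
              length(unique(x$labels[!is.na(x$labels)]))))
  invisible(x)
}

#' Serialize / restore a PCA model as JSON
#'
#' @param model A `dp_pca_model`.
#' @param path Output JSON path.
#' @return `path` (write) / a `dp_pca_model` (read).
#' @export
write_pca_model <- function(model, path) {
  stopifnot(inherits(model, "dp_pca_model"))
  jsonlite::write_json(
    list(mean = model$mean, eigenvalues = model$eigenvalues,
         eigenvectors = model$eigenvectors, sigma = model$sigma,
         q = model$q, n_fit = model$n_fit),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_pca_model
#' @export
read_pca_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = obj$mean, eigenvalues = obj$eigenvalues,
                 eigenvectors = obj$eigenvectors, sigma = obj$sigma,
                 q = as.integer(obj$q), n_fit = as.integer(obj$n_fit)),
            class = "dp_pca_model")
}
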