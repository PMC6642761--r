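#' Confusion matrix for multiclass predictions
#'
#' @param truth True class labels.
#' @param predicted Predicted class labels.
#' @param levels Class order; defaults to the sorted union of both.
#' @return A `confusion_matrix`: c x c integer matrix, rows = true class,
#'   columns = predicted class, with `class_order` attribute.
#' @export
confusion_matrix <- function(truth, predicted, levels = NULL) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  if (is.null(levels)) levels <- sort(unique(c(truth, predicted)))
  cm <- table(factor(truth, levels = levels),
              factor(predicted, levels = levels))
  m <- matrix(as.integer(cm), nrow = length(levels),
              dimnames = list(true = as.character(levels),
                              predicted = as.character(levels)))
  structure(m, class_order = levels, class = c("confusion_matrix", "matrix"))
}

as_cm <- function(cm) {
  m <- unclass(as.matrix(cm))
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square",
                               call. = FALSE)
  if (sum(m) == 0) stop("empty confusion matrix", call. = FALSE)
  m
}

#' Per-class sensitivity (recall), in percent
#'
#' `Se_i = 100 * cm[i, i] / rowsum_i`: true positives of class i over the
#' actual positives of class i. A class with no cases in the evaluated set
#' has undefined sensitivity and is reported as `NA` with a warning.
#'
#' @param cm A confusion matrix (rows = true class).
#' @return Named numeric vector of percentages.
#' @export
sensitivity <- function(cm) {
  m <- as_cm(cm)
  rs <- rowSums(m)
  out <- ifelse(rs > 0, 100 * diag(m) / rs, NA_real_)
  if (anyNA(out))
    warning("class absent from evaluated set; sensitivity undefined (NA)")
  names(out) <- rownames(m)
  out
}

#' Overall classification accuracy, in percent
#'
#' `OCA = 100 * trace / total`: correct decisions over all cases.
#'
#' @param cm A confusion matrix.
#' @return Scalar percentage.
#' @export
oca <- function(cm) {
  m <- as_cm(cm)
  100 * sum(diag(m)) / sum(m)
}

#' Per-class false positive rate, in percent
#'
#' `FPR_i = 100 * (colsum_i - cm[i, i]) / (total - rowsum_i)`: negatives
#' of class i detected as class i, over all negatives of class i.
#'
#' @param cm A confusion matrix.
#' @return Named numeric vector of percentages.
#' @export
fpr <- function(cm) {
  m <- as_cm(cm)
  neg <- sum(m) - rowSums(m)
  out <- ifelse(neg > 0, 100 * (colSums(m) - diag(m)) / neg, NA_real_)
  names(out) <- rownames(m)
  out
}

#' Per-class specificity, in percent
#'
#' The complement of the false positive rate: `Sp_i = 100 - FPR_i`.
#'
#' @param cm A confusion matrix.
#' @return Named numeric vector of percentages.
#' @export
specificity <- function(cm) 100 - fpr(cm)

#' Cohen's kappa
#'
#' Chance-corrected agreement `(Po - Pe) / (1 - Pe)` with observed
#' agreement `Po = trace / total` and expected agreement
#' `Pe = sum_i (rowsum_i / total)(colsum_i / total)`. In the degenerate
#' single-cell case `Pe = 1`, kappa is 1 when agreement is total and 0
#' otherwise.
#'
#' @param cm A confusion matrix.
#' @return Scalar in [-1, 1].
#' @export
#' @examples
#' kappa_statistic(matrix(c(2, 1, 1, 2), 2))  # 1/3
kappa_statistic <- function(cm) {
  m <- as_cm(cm)
  total <- sum(m)
  po <- sum(diag(m)) / total
  pe <- sum((rowSums(m) / total) * (colSums(m) / total))
  if (abs(1 - pe) < 1e-15) return(if (po >= 1 - 1e-15) 1 else 0)
  (po - pe) / (1 - pe)
}

#' One-vs-rest AUC per class
#'
#' Rank-based (Mann-Whitney) AUC of each class's score column for that
#' class's samples against all others, with midranks for ties; equal
#' scores therefore give 0.5. The `overall` attribute is the
#' class-frequency-weighted mean over the defined per-class values. A
#' class with zero positives or zero negatives has undefined AUC (`NA`).
#'
#' @param scores n x c matrix of per-class scores; column order must match
#'   `sort(unique(labels))` or the matrix's own `colnames`.
#' @param labels True class labels, length n.
#' @return Named numeric vector of per-class AUC in [0, 1] with attribute
#'   `overall`.
#' @export
auc_one_vs_rest <- function(scores, labels) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(labels))
    stop("scores rows must match labels length", call. = FALSE)
  lev <- if (!is.null(colnames(scores))) colnames(scores)
         else as.character(sort(unique(labels)))
  if (ncol(scores) != length(lev))
    stop("scores must have one column per class", call. = FALSE)
  labels <- as.character(labels)
  out <- vapply(seq_along(lev), function(j) {
    pos <- labels == lev[j]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(scores[, j])  # midranks for ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  names(out) <- lev
  wt <- vapply(lev, function(l) sum(labels == l), numeric(1))
  ok <- !is.na(out)
  attr(out, "overall") <- if (any(ok))
    sum(out[ok] * wt[ok]) / sum(wt[ok]) else NA_real_
  out
}
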