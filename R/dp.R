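#' Trajectory view of a time window
#'
#' A window of a multichannel record is treated as an ordered polyline of
#' d-dimensional points. In `"channels"` space (the default) point `t` is
#' the p-vector of channel amplitudes at sample `t`, so distances are pure
#' amplitude distances in R^p. In `"time"` space each point additionally
#' carries the coordinate `(t - 1) * time_scale`, making the sample index
#' part of the geometry; this is available for sensitivity analysis.
#'
#' @param segm An `eeg_segment` from [segment_record()], or a numeric
#'   matrix of points (rows in trajectory order).
#' @param space `"channels"` (d = p) or `"time"` (d = p + 1).
#' @param time_scale Positive scale applied to the sample-index coordinate
#'   in `"time"` space.
#'
#' @return An object of class `dp_trajectory`: list with `points`
#'   (N x d matrix), `n`, `space`, `time_scale`.
#' @export
make_trajectory <- function(segm, space = c("channels", "time"),
                            time_scale = 1) {
  space <- match.arg(space)
  m <- if (inherits(segm, "eeg_segment")) segm$data else as.matrix(segm)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("trajectory needs at least 2 points", call. = FALSE)
  if (!all(is.finite(m))) stop("non-finite trajectory values", call. = FALSE)
  if (space == "time") {
    if (!is.numeric(time_scale) || length(time_scale) != 1L || time_scale <= 0)
      stop("time_scale must be a single positive number", call. = FALSE)
    m <- cbind(m, (seq_len(nrow(m)) - 1) * time_scale)
  }
  structure(list(points = m, n = nrow(m), space = space,
                 time_scale = if (space == "time") time_scale else NA_real_),
            class = "dp_trajectory")
}

traj_points <- function(x) {
  if (inherits(x, "dp_trajectory")) x$points else as.matrix(x)
}

#' Total path length of a trajectory
#'
#' Sum of Euclidean distances between consecutive points; the "overall
#' distance" that the adaptive tolerance is a percentage of.
#'
#' @param traj A `dp_trajectory` or a numeric matrix of points.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' path_length(rbind(c(0, 0), c(3, 4)))  # 5
path_length <- function(traj) {
  m <- traj_points(traj)
  if (nrow(m) < 2L) return(0)
  d <- diff(m)
  sum(sqrt(rowSums(d * d)))
}

#' Adaptive simplification tolerance
#'
#' The tolerance is set per window as a percentage of the window's total
#' path length: `epsilon = (T / 100) * path_length(traj)`. A single `T`
#' therefore adapts the absolute tolerance to each window's amplitude and
#' roughness, which is why windows of the same record get different epsilon.
#'
#' @param traj A `dp_trajectory` or point matrix.
#' @param T Nonnegative percentage-like scalar (the study default is 0.06).
#' @return A list of class `dp_tolerance` with `T`, `epsilon`,
#'   `path_length`.
#' @export
tolerance_from_T <- function(traj, T) {
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T < 0)
    stop("T must be a single nonnegative number", call. = FALSE)
  pl <- path_length(traj)
  structure(list(T = T, epsilon = (T / 100) * pl, path_length = pl),
            class = "dp_tolerance")
}

#' Perpendicular distance from a point to a line
#'
#' Distance from `P` to the infinite line through `A` and `B`; when
#' `A == B` the line degenerates and the plain Euclidean distance
#' `||P - A||` is returned (EEG windows can start and end at equal
#' values, so the fallback is mandatory).
#'
#' @param P,A,B Numeric vectors of equal dimension.
#' @return Nonnegative scalar.
#' @export
#' @examples
#' perpendicular_distance(c(3, 4), c(0, 0), c(6, 0))  # 4
perpendicular_distance <- function(P, A, B) {
  if (length(P) != length(A) || length(A) != length(B))
    stop("P, A, B must have the same dimension", call. = FALSE)
  drop(perp_dist_block(matrix(P, nrow = 1L), A, B))
}

# Distances of each row of M to the line through A and B (vectorised).
perp_dist_block <- function(M, A, B) {
  v <- B - A
  vv <- sum(v * v)
  W <- sweep(M, 2L, A)
  if (vv == 0) return(sqrt(rowSums(W * W)))
  t <- drop(W %*% v) / vv
  R <- W - outer(t, v)
  sqrt(rowSums(R * R))
}

#' Douglas-Peucker retained indices
#'
#' Iterative (explicit-stack) simplification: the first and last points are
#' always retained; for the span between two retained endpoints, the
#' intermediate point of maximum perpendicular distance to the line through
#' the endpoints is found (ties broken by the smallest index). If that
#' maximum is strictly less than `epsilon` all intermediates are dropped,
#' otherwise the span is split at the maximiser and both halves are
#' processed. Note the strict comparison: at `epsilon = 0` nothing is
#' dropped, not even exactly collinear interior points (0 < 0 is false).
#'
#' The explicit stack avoids recursion-depth failures on windows of 10^3
#' and more points; a plain recursive version gives identical output and is
#' used as a cross-check in the test suite.
#'
#' @param traj A `dp_trajectory` or point matrix.
#' @param epsilon Nonnegative tolerance in the trajectory's units.
#' @return Strictly increasing integer vector of 1-based retained indices,
#'   always containing 1 and N.
#' @export
#' @examples
#' zig <- rbind(c(0, 0), c(1, 1), c(2, 0), c(3, 1), c(4, 0))
#' dp_indices(zig, 0.7)  # 1 2 5
dp_indices <- function(traj, epsilon) {
  m <- traj_points(traj)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
        epsilon < 0)
    stop("epsilon must be a single nonnegative number", call. = FALSE)
  n <- nrow(m)
  if (n < 2L) stop("trajectory needs at least 2 points", call. = FALSE)
  keep <- logical(n)
  keep[c(1L, n)] <- TRUE
  # stack of index spans [i, j], i < j, endpoints already kept
  stack_i <- integer(64L); stack_j <- integer(64L)
  stack_i[1L] <- 1L; stack_j[1L] <- n
  top <- 1L
  while (top > 0L) {
    i <- stack_i[top]; j <- stack_j[top]; top <- top - 1L
    if (j - i < 2L) next
    mid <- (i + 1L):(j - 1L)
    d <- perp_dist_block(m[mid, , drop = FALSE], m[i, ], m[j, ])
    w <- which.max(d)          # first maximum = smallest index tie-break
    if (d[w] < epsilon) next   # drop all intermediates
    split <- mid[w]
    keep[split] <- TRUE
    if (top + 2L > length(stack_i)) {
      stack_i <- c(stack_i, integer(length(stack_i)))
      stack_j <- c(stack_j, integer(length(stack_j)))
    }
    stack_i[top + 1L] <- i; stack_j[top + 1L] <- split
    stack_i[top + 2L] <- split; stack_j[top + 2L] <- j
    top <- top + 2L
  }
  which(keep)
}

#' Extract the representative samples of one window
#'
#' Composes [make_trajectory()], [tolerance_from_T()] and [dp_indices()]
#' and returns the retained rows in channel space (the time coordinate, if
#' used for the geometry, is not part of the output samples).
#'
#' @param segm An `eeg_segment`.
#' @param T Adaptive tolerance percentage (default 0.06).
#' @inheritParams make_trajectory
#' @return An object of class `dp_sample`: list with `retained` (1-based
#'   indices into the window), `samples` (retained rows, n_j x p),
#'   `tolerance` (the `dp_tolerance` used), `max_deviation` (largest
#'   perpendicular distance among dropped points, 0 if none dropped),
#'   `segment_index`, `class_label`.
#' @export
extract_segment_samples <- function(segm, T = 0.06,
                                    space = c("channels", "time"),
                                    time_scale = 1) {
  stopifnot(inherits(segm, "eeg_segment"))
  space <- match.arg(space)
  traj <- make_trajectory(segm, space = space, time_scale = time_scale)
  tol <- tolerance_from_T(traj, T)
  idx <- dp_indices(traj, tol$epsilon)
  max_dev <- 0
  if (length(idx) < traj$n) {
    # deviation of each dropped point to its covering retained chord
    devs <- unlist(lapply(seq_len(length(idx) - 1L), function(s) {
      i <- idx[s]; j <- idx[s + 1L]
      if (j - i < 2L) return(numeric(0))
      perp_dist_block(traj$points[(i + 1L):(j - 1L), , drop = FALSE],
                      traj$points[i, ], traj$points[j, ])
    }))
    if (length(devs)) max_dev <- max(devs)
  }
  structure(
    list(retained = idx,
         samples = segm$data[idx, , drop = FALSE],
         tolerance = tol, max_deviation = max_dev,
         segment_index = segm$segment_index,
         class_label = segm$class_label),
    class = "dp_sample")
}

#' Build the stacked DP sample set over all classes
#'
#' Segments every class record into `k` windows, simplifies each window
#' under the adaptive tolerance, and stacks the retained rows class by
#' class (windows in time order within a class). The result is the
#' labelled n_total x p matrix that PCA is fitted on, together with
#' per-row provenance and the achieved compression.
#'
#' @param records List of [eeg_record]s, one per class, all with the same
#'   number of channels.
#' @param k Windows per record (default 4).
#' @param T Adaptive tolerance percentage (default 0.06).
#' @inheritParams make_trajectory
#'
#' @return An object of class `dp_sample_set`: list with `data`
#'   (n_total x p), `labels` (per-row class id), `provenance`
#'   (data.frame class / segment / t_index, `t_index` 1-based within the
#'   window), `per_segment` (data.frame class / segment / n_original /
#'   n_retained / epsilon / path_length), `n_original` (sum of record
#'   lengths) and `compression` (fraction of points removed,
#'   `1 - n_total / n_original`).
#' @export
build_sample_set <- function(records, k = 4L, T = 0.06,
                             space = c("channels", "time"),
                             time_scale = 1) {
  space <- match.arg(space)
  if (length(records) < 1L) stop("need at least one record", call. = FALSE)
  ps <- vapply(records, function(r) ncol(r$data), integer(1))
  if (length(unique(ps)) != 1L)
    stop("records have mismatched channel counts: ",
         paste(ps, collapse = ", "), call. = FALSE)
  blocks <- list(); labels <- integer(0)
  prov_class <- integer(0); prov_seg <- integer(0); prov_t <- integer(0)
  per_seg <- list()
  n_original <- 0L
  for (rec in records) {
    n_original <- n_original + nrow(rec$data)
    for (segm in segment_record(rec, k)) {
      smp <- extract_segment_samples(segm, T = T, space = space,
                                     time_scale = time_scale)
      blocks[[length(blocks) + 1L]] <- smp$samples
      nj <- length(smp$retained)
      labels <- c(labels, rep.int(rec$class_label, nj))
      prov_class <- c(prov_class, rep.int(rec$class_label, nj))
      prov_seg <- c(prov_seg, rep.int(segm$segment_index, nj))
      prov_t <- c(prov_t, smp$retained)
      per_seg[[length(per_seg) + 1L]] <- data.frame(
        class = rec$class_label, segment = segm$segment_index,
        n_original = segm$n, n_retained = nj,
        epsilon = smp$tolerance$epsilon,
        path_length = smp$tolerance$path_length)
    }
  }
  data <- do.call(rbind, blocks)
  rownames(data) <- NULL
  structure(
    list(data = data, labels = labels,
         provenance = data.frame(class = prov_class, segment = prov_seg,
                                 t_index = prov_t),
         per_segment = do.call(rbind, per_seg),
         n_original = n_original,
         compression = 1 - nrow(data) / n_original,
         parameters = list(k = as.integer(k), T = T, space = space,
                           time_scale = time_scale)),
    class = "dp_sample_set")
}

#' @export
print.dp_sample_set <- function(x, ...) {
  cat(sprintf(paste0("<dp_sample_set> %d retained samples x %d channels ",
                     "(%d classes, %.2f%% reduction)\n"),
              nrow(x$data), ncol(x$data), length(unique(x$labels)),
              100 * x$compression))
  invisible(x)
}
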