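#' Split a record into fixed-size nonoverlapping time windows
#'
#' EEG is nonstationary over minutes but approximately stationary over short
#' windows, so each class record is cut into `k` contiguous nonoverlapping
#' windows ("Segms") before simplification. The first `k - 1` windows have
#' length `floor(N_total / k)` and the last absorbs the remainder, so a
#' 4097-sample record at `k = 4` yields lengths (1024, 1024, 1024, 1025).
#'
#' @param record An [eeg_record].
#' @param k Number of windows (default 4).
#'
#' @return A list of `k` objects of class `eeg_segment`, each a list with
#'   `data` (the window's rows), `start` (1-based index of the first row in
#'   the parent record), `n`, `segment_index`, `class_label`.
#' @export
#' @examples
#' rec <- eeg_record(matrix(rnorm(20), 10, 2))
#' lengths <- vapply(segment_record(rec, 3), function(s) s$n, integer(1))
#' lengths  # 3 3 4
segment_record <- function(record, k = 4L) {
  stopifnot(inherits(record, "eeg_record"))
  k <- as.integer(k)
  if (is.na(k) || k <= 0L) stop("k must be a positive integer", call. = FALSE)
  n_total <- nrow(record$data)
  if (2L * k > n_total)
    stop(sprintf("record too short for %d segments (%d samples; need >= %d)",
                 k, n_total, 2L * k), call. = FALSE)
  base <- n_total %/% k
  lens <- rep(base, k)
  lens[k] <- n_total - base * (k - 1L)
  starts <- cumsum(c(1L, lens[-k]))
  lapply(seq_len(k), function(j) {
    rows <- seq.int(starts[j], length.out = lens[j])
    structure(
      list(data = record$data[rows, , drop = FALSE],
           start = starts[j], n = lens[j],
           segment_index = j, class_label = record$class_label),
      class = "eeg_segment")
  })
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> #%d of class %d: rows %d..%d (%d x %d)\n",
              x$segment_index, x$class_label, x$start, x$start + x$n - 1L,
              x$n, ncol(x$data)))
  invisible(x)
}
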