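#' Multichannel EEG record
#'
#' Bundles a time-by-channel amplitude matrix with its sampling rate and a
#' class label. This is the unit the whole pipeline operates on: one record
#' per class set (e.g. one Bonn set read as 100 "channels").
#'
#' @param data Numeric matrix, rows = time samples, columns = channels.
#'   All values must be finite and there must be at least 2 rows.
#' @param fs Sampling rate in Hz. Default 173.61, the rate of the Bonn
#'   epilepsy database.
#' @param class_label Small integer category id for the record.
#' @param source_id Free-text provenance string.
#'
#' @return An object of class `eeg_record`: a list with elements `data`,
#'   `fs`, `class_label`, `source_id`.
#' @export
#' @examples
#' rec <- eeg_record(matrix(rnorm(40), 20, 2), class_label = 1)
#' dim(rec$data)
eeg_record <- function(data, fs = 173.61, class_label = 1L,
                       source_id = "") {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 2L)
    stop("record must have at least 2 time samples", call. = FALSE)
  if (ncol(data) < 1L)
    stop("record must have at least 1 channel", call. = FALSE)
  if (!all(is.finite(data)))
    stop("record contains non-finite values (NaN/Inf/NA)", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number", call. = FALSE)
  structure(
    list(data = data, fs = fs, class_label = as.integer(class_label),
         source_id = as.character(source_id)),
    class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %d samples x %d channels, fs = %g Hz, class = %d\n",
              nrow(x$data), ncol(x$data), x$fs, x$class_label))
  if (nzchar(x$source_id)) cat("  source:", x$source_id, "\n")
  invisible(x)
}

#' @export
dim.eeg_record <- function(x) dim(x$data)

as_record_matrix <- function(x) {
  if (inherits(x, "eeg_record")) x$data else as.matrix(x)
}
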