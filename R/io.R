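#' Read a Bonn-dialect class set
#'
#' Reads a directory of single-column ASCII text files, one amplitude value
#' per line and one file per channel -- the on-disk layout of the Bonn
#' epilepsy database sets A--E (100 files of ~4097 samples at 173.61 Hz).
#' Files are taken in ascending lexicographic filename order; column `j` of
#' the result is the j-th sorted file. Amplitudes are read as doubles even
#' when the files hold 12-bit ADC integers, so there is a single numeric
#' path downstream. The reader accepts any common length (distributions of
#' the Bonn data carry 4096 or 4097 samples per channel) and never truncates.
#'
#' @param directory Path to a directory of channel files.
#' @param class_label Integer class id to attach to the record.
#' @param fs Sampling rate in Hz (default 173.61).
#' @param pattern Optional filename regexp passed to [list.files()].
#'
#' @return An [eeg_record] with `p` = number of files and `N_total` = common
#'   line count.
#' @export
read_bonn_set <- function(directory, class_label = 1L, fs = 173.61,
                          pattern = NULL) {
  if (!dir.exists(directory))
    stop("directory not found: ", directory, call. = FALSE)
  files <- list.files(directory, pattern = pattern, full.names = TRUE)
  files <- files[!dir.exists(files)]
  files <- sort(files, method = "radix")
  if (length(files) == 0L)
    stop("no channel files in ", directory, call. = FALSE)
  cols <- vector("list", length(files))
  for (i in seq_along(files)) {
    vals <- tryCatch(scan(files[i], what = double(), quiet = TRUE),
                     error = function(e) e)
    if (inherits(vals, "error")) {
      # rescan line by line to report the offending line
      lines <- readLines(files[i], warn = FALSE)
      bad <- which(is.na(suppressWarnings(as.numeric(lines))) &
                     nzchar(trimws(lines)))[1]
      stop(sprintf("non-numeric value in %s at line %d",
                   basename(files[i]), if (is.na(bad)) -1L else bad),
           call. = FALSE)
    }
    cols[[i]] <- vals
  }
  lens <- lengths(cols)
  if (length(unique(lens)) != 1L) {
    ref <- as.integer(names(which.max(table(lens))))
    off <- which(lens != ref)[1]
    stop(sprintf(
      "ragged channel set: %s has %d samples, expected %d",
      basename(files[off]), lens[off], ref), call. = FALSE)
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- basename(files)
  eeg_record(mat, fs = fs, class_label = class_label,
             source_id = normalizePath(directory))
}

#' Write a record as a Bonn-dialect directory
#'
#' Inverse of [read_bonn_set()]: one text file per channel, one value per
#' line. Channel files are named `chan001.txt`, `chan002.txt`, ... so that
#' lexicographic order preserves the column order.
#'
#' @param record An [eeg_record].
#' @param directory Output directory, created if necessary.
#' @param digits Significant digits to keep (default 10).
#' @return The directory path, invisibly.
#' @export
write_bonn_set <- function(record, directory, digits = 10L) {
  stopifnot(inherits(record, "eeg_record"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- ncol(record$data)
  for (j in seq_len(p)) {
    f <- file.path(directory, sprintf("chan%03d.txt", j))
    writeLines(formatC(record$data[, j], digits = digits, format = "g"), f)
  }
  invisible(directory)
}

#' Read a delimited numeric matrix as a record
#'
#' @param path Path to a delimited text file; rows = time samples,
#'   columns = channels.
#' @param delimiter Field delimiter (default `","`).
#' @param class_label Integer class id.
#' @param header Logical; skip a single header row when `TRUE`.
#' @param fs Sampling rate in Hz.
#' @return An [eeg_record].
#' @export
read_matrix <- function(path, delimiter = ",", class_label = 1L,
                        header = FALSE, fs = 173.61) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, sep = delimiter, header = header,
                      colClasses = "numeric"),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) stop("empty file: ", path, call. = FALSE)
  eeg_record(as.matrix(df), fs = fs, class_label = class_label,
             source_id = path)
}

#' Write a record (or matrix) as delimited text
#'
#' @param x An [eeg_record] or numeric matrix.
#' @param path Output file path.
#' @param delimiter Field delimiter (default `","`).
#' @param digits Significant digits (default 10, so that a write/read
#'   round trip is an identity well beyond single precision).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path, delimiter = ",", digits = 10L) {
  m <- as_record_matrix(x)
  utils::write.table(signif(m, digits), path, sep = delimiter,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a feature table as CSV
#'
#' Writes features as columns `f1..fq` followed by a final `label` column,
#' the flat format consumed by external classifier tooling.
#'
#' @param features A `dp_feature_set` (see [project_features()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  stopifnot(inherits(features, "dp_feature_set"))
  if (nrow(features$features) == 0L)
    stop("empty feature set", call. = FALSE)
  df <- as.data.frame(features$features)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$label <- features$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a DP sample set as CSV
#'
#' Columns `ch1..chp`, `label`, `class`, `segment`, `t_index`; `t_index`
#' is the 0-based time index of the retained row within its window.
#'
#' @param samples A `dp_sample_set` (see [build_sample_set()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_set <- function(samples, path) {
  stopifnot(inherits(samples, "dp_sample_set"))
  df <- as.data.frame(samples$data)
  names(df) <- paste0("ch", seq_len(ncol(df)))
  df$label <- samples$labels
  df$class <- samples$provenance$class
  df$segment <- samples$provenance$segment
  df$t_index <- samples$provenance$t_index - 1L
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read an evaluation report as JSON
#'
#' The JSON document holds per-fold confusion matrices and metrics, the
#' aggregate mean +/- sd table, and the full parameter set (including
#' seeds) that produced it.
#'
#' @param report An `evaluation_report` from [cross_validate()].
#' @param path Output JSON path.
#' @return `path` (write) / an `evaluation_report`-shaped list (read),
#'   invisibly for the writer.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  class(out) <- "evaluation_report"
  out
}
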