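# Independent reference implementations used as oracles, plus fixture
# helpers. Kept deliberately naive: the recursive simplifier mirrors the
# textbook description point for point and shares no code with the
# production stack-based version beyond perpendicular_distance().

# Recursive Douglas-Peucker: returns sorted 1-based retained indices.
dp_recursive_oracle <- function(m, epsilon) {
  n <- nrow(m)
  rec <- function(i, j) {
    if (j - i < 2L) return(c(i, j))
    dmax <- -Inf
    split <- -1L
    for (t in (i + 1L):(j - 1L)) {
      d <- perpendicular_distance(m[t, ], m[i, ], m[j, ])
      if (d > dmax) {          # strict >: first max = smallest index
        dmax <- d
        split <- t
      }
    }
    if (dmax < epsilon) return(c(i, j))
    sort(unique(c(rec(i, split), rec(split, j))))
  }
  rec(1L, n)
}

# Brute-force path length (scalar loop, no vectorisation).
path_length_oracle <- function(m) {
  total <- 0
  for (i in seq_len(nrow(m) - 1L))
    total <- total + sqrt(sum((m[i + 1L, ] - m[i, ])^2))
  total
}

# Random trajectory: N points in d dimensions, integer-ish values so
# exact ties at the maximum deviation actually occur.
random_trajectory <- function(n, d, quantized = TRUE) {
  m <- matrix(stats::rnorm(n * d, sd = 3), n, d)
  if (quantized) m <- round(m, 1)
  m
}

# Small record with known content.
make_record <- function(n = 32L, p = 2L, class_label = 1L, seed = 7L) {
  withr::with_seed(seed,
    eeg_record(matrix(stats::rnorm(n * p), n, p),
               class_label = class_label))
}

# A tiny Bonn-dialect directory fixture; returns its path.
make_bonn_dir <- function(values_by_channel, dir = withr::local_tempdir(
                            .local_envir = parent.frame())) {
  for (i in seq_along(values_by_channel))
    writeLines(as.character(values_by_channel[[i]]),
               file.path(dir, sprintf("ch%02d.txt", i)))
  dir
}
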