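zigzag <- rbind(c(0, 0), c(1, 1), c(2, 0), c(3, 1), c(4, 0))

test_that("trajectory construction in channel and time-augmented space", {
  rec <- eeg_record(matrix(1:8, 4, 2))
  segm <- segment_record(rec, 1L)[[1]]
  tr <- make_trajectory(segm)
  expect_equal(dim(tr$points), c(4L, 2L))
  tt <- make_trajectory(segm, space = "time", time_scale = 1)
  expect_equal(dim(tt$points), c(4L, 3L))
  expect_equal(unname(tt$points[, 3]), c(0, 1, 2, 3))
  expect_equal(unname(make_trajectory(segm, space = "time",
                                      time_scale = 0.5)$points[, 3]),
               c(0, 0.5, 1, 1.5))
  expect_error(make_trajectory(segm, space = "time", time_scale = 0),
               "time_scale")
})

test_that("path length matches hand values and a loop oracle", {
  expect_equal(path_length(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(path_length(rbind(c(0, 0), c(1, 0), c(1, 1))), 2)
  withr::with_seed(31, {
    m <- matrix(rnorm(300), 100, 3)
    expect_equal(path_length(m), path_length_oracle(m), tolerance = 1e-12)
  })
})

test_that("adaptive tolerance is T percent of the path length", {
  tol <- tolerance_from_T(rbind(c(0, 0), c(3, 4)), T = 10)
  expect_s3_class(tol, "dp_tolerance")
  expect_equal(tol$epsilon, 0.5)
  expect_equal(tol$path_length, 5)
  expect_equal(tolerance_from_T(zigzag, T = 0)$epsilon, 0)
  expect_error(tolerance_from_T(zigzag, T = -1), "nonnegative")
})

test_that("perpendicular distance to a line, with degenerate fallback", {
  expect_equal(perpendicular_distance(c(1, 1), c(0, 0), c(2, 2)), 0)
  expect_equal(perpendicular_distance(c(3, 4), c(0, 0), c(6, 0)), 4)
  expect_equal(perpendicular_distance(c(1, 2), c(0, 0), c(4, 2)),
               6 / sqrt(20), tolerance = 1e-12)
  expect_equal(perpendicular_distance(c(3, 4), c(0, 0), c(0, 0)), 5)
  expect_error(perpendicular_distance(c(1, 2, 3), c(0, 0), c(1, 1)),
               "dimension")
  # projection-residual oracle in higher dimension
  withr::with_seed(8, {
    for (i in 1:20) {
      A <- rnorm(4); B <- rnorm(4); P <- rnorm(4)
      v <- B - A
      t <- sum((P - A) * v) / sum(v * v)
      expect_equal(perpendicular_distance(P, A, B),
                   sqrt(sum((P - A - t * v)^2)), tolerance = 1e-12)
    }
  })
})

test_that("dp_indices reproduces hand-executed recursions", {
  expect_equal(dp_indices(rbind(c(0, 0), c(5, 5)), 3), c(1L, 2L))
  coll <- cbind(0:3, 0:3)
  expect_equal(dp_indices(coll, 0.1), c(1L, 4L))
  # first split at point 2 (D = 1); right-half deviations 2/sqrt(10) < 0.7
  expect_equal(dp_indices(zigzag, 0.7), c(1L, 2L, 5L))
  expect_equal(dp_indices(zigzag, 0.5), 1:5)
  expect_error(dp_indices(zigzag, -0.1), "nonnegative")
})

test_that("strict drop rule: epsilon = 0 retains every point", {
  expect_equal(dp_indices(zigzag, 0), 1:5)
  # even exactly-collinear interiors survive at epsilon = 0 (0 < 0 false)
  expect_equal(dp_indices(cbind(0:3, 0:3), 0), 1:4)
})

test_that("production simplifier equals the recursive oracle", {
  withr::with_seed(123, {
    for (i in 1:60) {
      n <- sample(3:30, 1)
      d <- sample(1:4, 1)
      m <- random_trajectory(n, d)
      eps <- runif(1, 0, 0.02 * path_length(m))
      expect_identical(dp_indices(m, eps), dp_recursive_oracle(m, eps))
    }
  })
})

test_that("every dropped point lies within epsilon of its covering chord", {
  withr::with_seed(99, {
    for (i in 1:40) {
      m <- random_trajectory(sample(5:40, 1), sample(1:3, 1))
      eps <- runif(1, 0.05, 2)
      idx <- dp_indices(m, eps)
      expect_equal(idx[1], 1L)
      expect_equal(idx[length(idx)], nrow(m))
      for (s in seq_len(length(idx) - 1L)) {
        i0 <- idx[s]; j0 <- idx[s + 1L]
        if (j0 - i0 < 2L) next
        for (t in (i0 + 1L):(j0 - 1L))
          expect_lt(perpendicular_distance(m[t, ], m[i0, ], m[j0, ]), eps)
      }
    }
  })
})

test_that("retained sets are nested as epsilon grows", {
  withr::with_seed(2024, {
    for (i in 1:40) {
      m <- random_trajectory(sample(5:40, 1), sample(1:3, 1))
      e1 <- runif(1, 0, 1)
      e2 <- e1 + runif(1, 0, 1)
      expect_true(all(dp_indices(m, e2) %in% dp_indices(m, e1)))
    }
  })
})

test_that("retained indices are invariant to translation and rotation", {
  withr::with_seed(55, {
    theta <- runif(5, 0, 2 * pi)
    for (th in theta) {
      m <- random_trajectory(25, 2, quantized = FALSE)
      eps <- runif(1, 0.1, 1)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      shift <- rnorm(2, sd = 10)
      m2 <- sweep(m %*% R, 2, -shift)
      expect_identical(dp_indices(m, eps), dp_indices(m2, eps))
    }
  })
})

test_that("segment extraction composes trajectory, tolerance and DP", {
  # collinear ramp: epsilon > 0, all interior deviations 0 -> endpoints only
  ramp <- eeg_record(cbind(1:16, 1:16))
  segm <- segment_record(ramp, 1L)[[1]]
  smp <- extract_segment_samples(segm, T = 5)
  expect_s3_class(smp, "dp_sample")
  expect_equal(smp$retained, c(1L, 16L))
  expect_gt(smp$tolerance$epsilon, 0)

  # degenerate constant window: path length 0 -> epsilon 0 -> strict
  # drop rule retains everything (0 < 0 is false)
  const <- segment_record(eeg_record(matrix(3, 16, 2)), 1L)[[1]]
  smp_const <- extract_segment_samples(const, T = 5)
  expect_equal(smp_const$tolerance$epsilon, 0)
  expect_equal(smp_const$retained, seq_len(16L))

  rec <- make_record(n = 40L, p = 2L, seed = 3L)
  segm <- segment_record(rec, 1L)[[1]]
  all_kept <- extract_segment_samples(segm, T = 0)
  expect_equal(all_kept$retained, seq_len(40L))
  expect_equal(all_kept$max_deviation, 0)

  some <- extract_segment_samples(segm, T = 2)
  expect_lt(length(some$retained), 40L)
  # retained rows equal the original rows exactly
  expect_identical(some$samples, segm$data[some$retained, , drop = FALSE])
  expect_gt(some$max_deviation, 0)
  expect_lt(some$max_deviation, some$tolerance$epsilon)
})

test_that("time-augmented extraction returns channel-space samples", {
  rec <- make_record(n = 30L, p = 3L, seed = 17L)
  segm <- segment_record(rec, 1L)[[1]]
  smp <- extract_segment_samples(segm, T = 1, space = "time",
                                 time_scale = 0.1)
  expect_equal(ncol(smp$samples), 3L)
  expect_identical(smp$samples, segm$data[smp$retained, , drop = FALSE])
})

test_that("sample sets stack classes in order with full provenance", {
  c1 <- eeg_record(cbind(1:8, 1:8), class_label = 1L)
  c2 <- eeg_record(cbind(8:1, 8:1), class_label = 2L)
  ss <- build_sample_set(list(c1, c2), k = 2L, T = 1)
  # collinear windows retain endpoints only: 2 per window, 2 windows, 2 classes
  expect_equal(nrow(ss$data), 8L)
  expect_equal(ss$labels, rep(c(1L, 2L), each = 4L))
  expect_equal(ss$provenance$segment, rep(rep(1:2, each = 2L), 2L))
  expect_equal(ss$provenance$t_index, rep(c(1L, 4L), 4L))
  expect_equal(ss$compression, 1 - 8 / 16)
  expect_equal(ss$per_segment$n_retained, rep(2L, 4))

  p_mismatch <- eeg_record(matrix(0, 8, 3), class_label = 3L)
  expect_error(build_sample_set(list(c1, p_mismatch)), "mismatched")
})

test_that("compression of collinear records follows the endpoint count", {
  k <- 3L
  recs <- lapply(1:2, function(i)
    eeg_record(cbind(i * (1:30), i * (1:30)), class_label = i))
  ss <- build_sample_set(recs, k = k, T = 0.5)
  expect_equal(ss$compression, 1 - (2 * k * 2) / 60)
})
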