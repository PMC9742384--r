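test_that("min-max normalization maps bounds affinely and clips test values", {
  sp <- normalization_spec(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(as.numeric(minmax_normalize(matrix(c(1, 2, 3)), sp)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(1, sp)[1, 1], 0)  # x = min -> n_min
  sp2 <- normalization_spec(matrix(c(10, 20), ncol = 1), n_min = 0, n_max = 4.45)
  expect_equal(as.numeric(minmax_normalize(matrix(c(10, 20)), sp2)), c(0, 4.45))
  # out-of-range values clip to the trained bounds
  expect_equal(as.numeric(minmax_normalize(matrix(c(-5, 25)), sp2)), c(0, 4.45))
})

test_that("degenerate features map to the range midpoint with a warning", {
  X <- cbind(a = c(1, 1, 1), b = c(0, 1, 2))
  expect_warning(sp <- normalization_spec(X), "degenerate")
  Xn <- minmax_normalize(X, sp)
  expect_equal(Xn[, 1], rep(0.5, 3))
  expect_equal(Xn[, 2], c(0, 0.5, 1))
})

test_that("normalization round-trips within 1e-9 for in-range values", {
  set.seed(1)
  X <- matrix(runif(60, -3, 7), 20, 3)
  sp <- normalization_spec(X)
  expect_lt(max(abs(denormalize(minmax_normalize(X, sp), sp) - X)), 1e-9)
})

test_that("receptive fields have 7 sigma-spaced points and the peak-density weight", {
  rf <- build_receptive_field(0.5, 0.1)
  expect_equal(rf$points, seq(0.2, 0.8, by = 0.1))
  expect_equal(rf$weight, 1 / (0.1 * sqrt(2 * pi)))  # ~3.9894
  expect_equal(rf$weight, dnorm(0.5, 0.5, 0.1))
  expect_equal(build_receptive_field(0, 1)$points, -3:3)
  # symmetric about mu: negate-and-reverse returns the original
  expect_equal(rev(2 * rf$mu - rf$points), rf$points)
  expect_error(build_receptive_field(0.5, 0), "sigma")
  expect_error(build_receptive_field(0.5, 0.1, n_points = 6), "odd")
})

test_that("full convolution equals the direct double-sum definition", {
  expect_equal(convolve_full(1, c(1, 2, 3)), c(1, 2, 3))
  expect_equal(convolve_full(c(1, 1), c(1, 1)), c(1, 2, 1))
  set.seed(42)
  for (rep in 1:5) {
    a <- rnorm(5); b <- rnorm(7)
    expect_equal(convolve_full(a, b), ref_convolve(a, b), tolerance = 1e-12)
    expect_length(convolve_full(a, b), 11)
  }
  expect_error(convolve_full(numeric(0), 1), "non-empty")
})

test_that("mossy-fiber count is n_features x n_per_feature with center dominance", {
  set.seed(2)
  X <- matrix(runif(80, 1, 9), 20, 4)
  enc <- fit_encoder(X)
  Xn <- minmax_normalize(X, enc$spec)
  e4 <- encode_instance(Xn[1, ], enc)
  expect_equal(nrow(e4), 28)  # 4 features x 7
  X3 <- X[, 1:3]
  enc3 <- fit_encoder(X3)
  e3 <- encode_instance(minmax_normalize(X3, enc3$spec)[1, ], enc3)
  expect_equal(nrow(e3), 21)  # 3 features x 7
  # per-feature currents are unimodal with the maximum at the center offset
  for (j in 1:4) {
    cur <- e4$current_pA[e4$feature == j]
    if (max(cur) > 0) {
      expect_equal(which.max(cur), 4)
      expect_true(all(diff(cur[1:4]) >= 0) && all(diff(cur[4:7]) <= 0))
    }
  }
  expect_true(all(e4$current_pA >= 0))
  # the center current follows the kernel-weight form w_j * mu
  j <- which.max(Xn[1, ])
  expect_equal(e4$current_pA[e4$feature == j & e4$offset == 0],
               enc$gain * (1 / (enc$sigma[j] * sqrt(2 * pi))) * Xn[1, j])
})

test_that("encoding is deterministic and the MF-count identity holds generally", {
  set.seed(3)
  for (d in c(1, 3, 6)) {
    for (npf in c(3, 7)) {
      X <- matrix(runif(10 * d), 10, d)
      enc <- fit_encoder(X, encoding_config(n_per_feature = npf))
      Xn <- minmax_normalize(X, enc$spec)
      a <- encode_instance(Xn[2, ], enc)
      b <- encode_instance(Xn[2, ], enc)
      expect_identical(a, b)
      expect_equal(nrow(a), d * npf)
    }
  }
})

test_that("gain calibration puts the largest training current at the target", {
  set.seed(4)
  X <- matrix(runif(40), 10, 4)
  enc <- fit_encoder(X, encoding_config(target_max_pA = 1200))
  Xn <- minmax_normalize(X, enc$spec)
  peak <- max(vapply(seq_len(10), function(i)
    max(encode_instance(Xn[i, ], enc)$current_pA), numeric(1)))
  expect_equal(peak, 1200, tolerance = 1e-9)
})

test_that("mossy-fiber spike trains follow their drive currents", {
  set.seed(5)
  X <- matrix(runif(40, 0, 1), 10, 4)
  enc <- fit_encoder(X)
  Xn <- minmax_normalize(X, enc$spec)
  e <- encode_instance(Xn[3, ], enc)
  trains <- mf_spike_trains(e, T = 300, dt = 0.1)
  expect_length(trains, 28)  # 28 in, 28 out
  counts <- lengths(trains)
  expect_true(all(counts[e$current_pA == 0] == 0))  # zero current, empty train
  # monotone: a larger current never yields fewer spikes
  ord <- order(e$current_pA)
  expect_true(all(diff(counts[ord]) >= 0))
})

test_that("datasets read from CSV round-trip features and labels", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(a = c(1, 2), b = c(3, 4), label = c("x", "y"))
  write.csv(df, f, row.names = FALSE)
  ds <- read_dataset(f)
  expect_equal(dim(ds$X), c(2L, 2L))
  expect_equal(ds$y, c("x", "y"))
  expect_error(read_dataset(f, label = "missing"), "not found")
})
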