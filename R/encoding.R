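# Gaussian receptive-field encoding of tabular features into mossy-fiber
# drive currents and spike trains.

#' Min-max normalization specification
#'
#' Computes per-feature bounds from a training table. Constant features are
#' flagged as degenerate and later mapped to the midpoint of the target range.
#'
#' @param X numeric matrix or data frame of raw training features.
#' @param n_min,n_max target range bounds (defaults 0 and 1).
#' @return an object of class `norm_spec`.
#' @export
normalization_spec <- function(X, n_min = 0, n_max = 1) {
  X <- as.matrix(X)
  if (n_max <= n_min) stop("n_max must exceed n_min")
  mins <- apply(X, 2, min); maxs <- apply(X, 2, max)
  degen <- maxs <= mins
  if (any(degen))
    warning("degenerate (constant) feature(s) mapped to range midpoint: ",
            paste(which(degen), collapse = ", "))
  structure(list(feature_min = mins, feature_max = maxs,
                 n_min = n_min, n_max = n_max, degenerate = degen),
            class = "norm_spec")
}

#' Min-max normalize features
#'
#' Affine per-feature map of raw values onto `[n_min, n_max]` using bounds
#' from [normalization_spec()] (training data only). Values outside the
#' training bounds are clipped so receptive fields stay inside the trained
#' code; degenerate features map to the range midpoint.
#'
#' @param X numeric matrix, data frame, or vector (one instance).
#' @param spec a `norm_spec` object.
#' @param clip clip out-of-range values to the target bounds (default TRUE).
#' @return normalized matrix with the same shape as `X` (vectors return a
#'   one-row matrix).
#' @export
#' @examples
#' sp <- normalization_spec(matrix(c(1, 2, 3), ncol = 1))
#' minmax_normalize(matrix(c(1, 2, 3), ncol = 1), sp)[, 1]  # 0 0.5 1
minmax_normalize <- function(X, spec, clip = TRUE) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  out <- X
  for (j in seq_len(ncol(X))) {
    if (spec$degenerate[j]) {
      out[, j] <- (spec$n_min + spec$n_max) / 2
    } else {
      z <- (X[, j] - spec$feature_min[j]) /
        (spec$feature_max[j] - spec$feature_min[j])
      out[, j] <- z * (spec$n_max - spec$n_min) + spec$n_min
    }
  }
  if (clip) out <- pmin(pmax(out, spec$n_min), spec$n_max)
  out
}

#' Invert min-max normalization
#'
#' @inheritParams minmax_normalize
#' @param Xn normalized matrix.
#' @return matrix on the original feature scale.
#' @export
denormalize <- function(Xn, spec) {
  if (is.null(dim(Xn))) Xn <- matrix(Xn, nrow = 1)
  Xn <- as.matrix(Xn)
  out <- Xn
  for (j in seq_len(ncol(Xn))) {
    z <- (Xn[, j] - spec$n_min) / (spec$n_max - spec$n_min)
    out[, j] <- z * (spec$feature_max[j] - spec$feature_min[j]) + spec$feature_min[j]
  }
  out
}

#' Gaussian receptive field around a normalized value
#'
#' Places `n_points` (default 7) sample positions at `mu + k * sigma` for
#' integer offsets `k` symmetric about zero, with kernel weight equal to the
#' normal density at its own mean, `1 / (sigma * sqrt(2 * pi))`.
#'
#' @param mu receptive-field center (normalized units).
#' @param sigma spread (normalized units), must be positive.
#' @param n_points number of sample positions (odd, default 7).
#' @return an object of class `receptive_field` with `mu`, `sigma`, `points`,
#'   `offsets` and `weight`.
#' @export
#' @examples
#' rf <- build_receptive_field(0.5, 0.1)
#' rf$points  # 0.2 0.3 ... 0.8
build_receptive_field <- function(mu, sigma, n_points = 7) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (n_points < 1 || n_points %% 2 == 0) stop("n_points must be a positive odd number")
  half <- (n_points - 1) / 2
  offsets <- seq(-half, half)
  structure(list(mu = mu, sigma = sigma, offsets = offsets,
                 points = mu + offsets * sigma,
                 weight = 1 / (sigma * sqrt(2 * pi))),
            class = "receptive_field")
}

#' Full (open) convolution of two sequences
#'
#' Direct-definition full convolution: the output has length
#' `length(a) + length(b) - 1` and entry `k` equals
#' `sum(a[i] * b[k - i + 1])` over valid `i`.
#'
#' @param a,b non-empty numeric vectors.
#' @return numeric vector of length `length(a) + length(b) - 1`.
#' @export
convolve_full <- function(a, b) {
  if (!length(a) || !length(b)) stop("inputs must be non-empty")
  stats::convolve(a, rev(b), type = "open")
}

#' Encoder configuration
#'
#' @param n_per_feature number of mossy-fiber units per feature (default 7).
#' @param sigma receptive-field spread; `NULL` (default) uses the standard
#'   deviation of the normalized training values of each feature, floored at
#'   `sigma_floor`.
#' @param sigma_floor lower bound for the data-driven spread (default 0.05).
#' @param gain current gain in pA per unit of raw encoded drive; `NULL`
#'   (default) calibrates the gain on the training set so the largest drive
#'   current equals `target_max_pA`.
#' @param target_max_pA calibration target for the maximum training-set drive
#'   current (default 1200 pA, which places the strongest-driven unit near
#'   100 Hz on the AdEx f-I curve while units encoding weak feature values
#'   stay below the ~350 pA rheobase and remain silent).
#' @param n_min,n_max normalization target range (defaults 0 and 1).
#' @return a list of class `encoding_config`.
#' @export
encoding_config <- function(n_per_feature = 7, sigma = NULL, sigma_floor = 0.05,
                            gain = NULL, target_max_pA = 1200,
                            n_min = 0, n_max = 1) {
  if (n_per_feature < 1) stop("n_per_feature must be >= 1")
  structure(list(n_per_feature = n_per_feature, sigma = sigma,
                 sigma_floor = sigma_floor, gain = gain,
                 target_max_pA = target_max_pA, n_min = n_min, n_max = n_max),
            class = "encoding_config")
}

#' Fit an encoder on training features
#'
#' Derives the normalization bounds, per-feature receptive-field spreads and
#' the current gain from training data only. The fitted encoder is then
#' applied unchanged to test instances (out-of-range values are clipped).
#'
#' @param X raw training feature matrix or data frame.
#' @param config an [encoding_config()].
#' @return an object of class `mf_encoder`.
#' @export
fit_encoder <- function(X, config = encoding_config()) {
  X <- as.matrix(X)
  spec <- normalization_spec(X, config$n_min, config$n_max)
  Xn <- minmax_normalize(X, spec)
  sigma <- if (is.null(config$sigma)) {
    pmax(apply(Xn, 2, stats::sd), config$sigma_floor)
  } else rep_len(config$sigma, ncol(X))
  enc <- structure(list(spec = spec, sigma = sigma, config = config, gain = 1),
                   class = "mf_encoder")
  if (is.null(config$gain)) {
    raw_max <- max(vapply(seq_len(nrow(Xn)), function(i) {
      max(encode_instance(Xn[i, ], enc)$current_pA)
    }, numeric(1)))
    enc$gain <- if (raw_max > 0) config$target_max_pA / raw_max else 1
  } else {
    enc$gain <- config$gain
  }
  enc
}

#' Encode one normalized instance into mossy-fiber drive currents
#'
#' Each feature value `mu` gets a Gaussian receptive field of
#' `n_per_feature` mossy-fiber units at positions `mu + k * sigma`. The unit
#' at offset `k` receives drive current
#' `gain * w_j * mu * exp(-k^2 / 2)`, where `w_j = 1/(sigma * sqrt(2*pi))` is
#' the kernel weight: the center unit receives the full `gain * w_j * mu` and
#' excitation falls off with the Gaussian profile, giving the center-surround
#' structure in which the central neuron is driven most strongly. Negative
#' drive is floored at zero. A full convolution of the kernel density samples
#' with the instance is computed and used as a non-emptiness guard on the
#' encoding.
#'
#' @param x_norm normalized feature vector (within the target range).
#' @param encoder a fitted [fit_encoder()] object.
#' @return a data frame of class `encoded_instance` with columns `mf_id`,
#'   `feature`, `offset` (integer, 0 at the center) and `current_pA`; the
#'   number of rows is `n_features * n_per_feature`.
#' @export
encode_instance <- function(x_norm, encoder) {
  x_norm <- as.numeric(x_norm)
  d <- length(x_norm)
  npf <- encoder$config$n_per_feature
  rows <- vector("list", d)
  for (j in seq_len(d)) {
    rf <- build_receptive_field(x_norm[j], encoder$sigma[j], npf)
    pdf_samples <- stats::dnorm(rf$points, mean = rf$mu, sd = rf$sigma)
    guard <- convolve_full(pdf_samples, x_norm)
    if (!length(guard)) stop("empty convolution matrix during encoding")
    current <- encoder$gain * rf$weight * x_norm[j] * exp(-rf$offsets^2 / 2)
    rows[[j]] <- data.frame(feature = j, offset = rf$offsets,
                            current_pA = pmax(current, 0))
  }
  out <- do.call(rbind, rows)
  out <- cbind(mf_id = seq_len(nrow(out)), out)
  class(out) <- c("encoded_instance", "data.frame")
  out
}

#' Simulate mossy-fiber spike trains from encoded drive currents
#'
#' Each mossy-fiber unit is an AdEx neuron (granule-cell parameter set by
#' default) driven by its constant encoded current.
#'
#' @param encoded an [encode_instance()] result.
#' @param T,dt simulation window and step (ms).
#' @param params AdEx parameters for the input units.
#' @return a list with one numeric spike-time vector per mossy fiber.
#' @export
mf_spike_trains <- function(encoded, T = 300, dt = 0.1,
                            params = adex_params("MF")) {
  n_steps <- round(T / dt)
  drive <- matrix(encoded$current_pA, nrow = nrow(encoded), ncol = n_steps)
  out <- .adex_integrate(params, drive, dt)
  apply(out$spikes, 1, function(s) which(s) * dt, simplify = FALSE)
}

#' Read a feature/label dataset from CSV or ARFF
#'
#' @param path file path; `.arff` files are read with `foreign::read.arff()`
#'   when the foreign package is installed, anything else with
#'   [utils::read.csv()] (header expected).
#' @param label name of the label column (default `"label"`).
#' @return a list with numeric feature matrix `X` and label vector `y`.
#' @export
read_dataset <- function(path, label = "label") {
  dat <- if (grepl("\\.arff$", path, ignore.case = TRUE)) {
    if (!requireNamespace("foreign", quietly = TRUE))
      stop("reading ARFF files requires the 'foreign' package")
    foreign::read.arff(path)
  } else {
    utils::read.csv(path)
  }
  if (!label %in% names(dat)) stop("label column '", label, "' not found")
  y <- dat[[label]]
  X <- as.matrix(dat[setdiff(names(dat), label)])
  storage.mode(X) <- "double"
  list(X = X, y = y)
}
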