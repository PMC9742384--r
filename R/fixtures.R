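# Seeded synthetic datasets with the statistical structure of the study's
# experiments, so every analysis runs offline.

#' Synthetic classification fixture
#'
#' Gaussian class-conditional features with balanced labels: class means are
#' equally spaced along the feature-space diagonal (every feature carries
#' the class signal, as in screening questionnaires where most items
#' correlate with the outcome), with consecutive means separated by
#' `separation * noise_sd`, and instances are the class mean plus isotropic
#' `N(0, noise_sd^2)` noise. Mirrors the scale of small tabular screening
#' datasets (a handful of features, tens to low hundreds of instances).
#'
#' @param n number of instances (must be at least `2 * k`).
#' @param d number of features.
#' @param k number of classes.
#' @param separation distance between class means in units of `noise_sd`
#'   (0 gives chance-level structure).
#' @param noise_sd within-class standard deviation.
#' @param seed RNG seed; fixtures are bit-reproducible from (parameters, seed).
#' @return a list of class `classification_fixture` with feature matrix `X`,
#'   integer labels `y` in `0:(k-1)`, and the generating parameters.
#' @export
#' @examples
#' fx <- make_classification(n = 20, d = 4, k = 2, separation = 3, seed = 1)
#' table(fx$y)
make_classification <- function(n, d, k = 2, separation = 3, noise_sd = 1,
                                seed = 1L) {
  if (n < 2 * k) stop("need at least 2 instances per class")
  if (d < 1) stop("d must be >= 1")
  set.seed(seed)
  u <- rep(1 / sqrt(d), d)  # unit diagonal direction
  offsets <- (seq_len(k) - (k + 1) / 2) * separation * noise_sd
  centers <- outer(offsets, u)
  y <- rep(seq_len(k) - 1L, length.out = n)
  X <- centers[y + 1L, , drop = FALSE] +
    matrix(stats::rnorm(n * d, 0, noise_sd), n, d)
  ord <- sample.int(n)
  colnames(X) <- paste0("f", seq_len(d))
  structure(list(X = X[ord, , drop = FALSE], y = y[ord],
                 n = n, d = d, k = k, separation = separation,
                 noise_sd = noise_sd, seed = seed),
            class = "classification_fixture")
}

#' Synthetic 6-DOF arm dataset
#'
#' Samples joint-angle vectors uniformly over the arm's admissible range and
#' keeps those whose forward kinematics lands inside the workspace cuboid,
#' emitting forward-kinematics-consistent (xyz, angles) pairs: ground truth
#' is available for every instance by construction.
#'
#' @param arm an [arm_model()].
#' @param n_points number of pairs to generate.
#' @param seed RNG seed.
#' @param max_tries rejection-sampling cap (default `1000 * n_points`).
#' @return a list of class `arm_fixture` with matrices `xyz` (`n_points` x 3,
#'   cm) and `angles` (`n_points` x 6, radians), the `arm`, and the `seed`.
#' @export
make_arm_dataset <- function(arm, n_points = 200, seed = 1L,
                             max_tries = 1000 * n_points) {
  if (n_points < 1) stop("n_points must be >= 1")
  set.seed(seed)
  lo <- arm$angle_range[1]; hi <- arm$angle_range[2]
  xyz <- matrix(NA_real_, n_points, 3)
  angles <- matrix(NA_real_, n_points, arm$n_joints)
  got <- 0L; tries <- 0L
  while (got < n_points) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("workspace appears unreachable: rejection sampling cap hit")
    th <- stats::runif(arm$n_joints, lo, hi)
    p <- forward_kinematics(th, arm)
    if (in_workspace(p, arm)) {
      got <- got + 1L
      xyz[got, ] <- p
      angles[got, ] <- th
    }
  }
  colnames(xyz) <- c("x", "y", "z")
  colnames(angles) <- paste0("theta", seq_len(arm$n_joints))
  structure(list(xyz = xyz, angles = angles, arm = arm, n_points = n_points,
                 seed = seed),
            class = "arm_fixture")
}

#' Extract a smooth short trajectory from an arm fixture
#'
#' Greedy nearest-neighbour ordering over the fixture points, restarted from
#' several seeds, returning the `k`-point path whose largest consecutive
#' spacing is smallest; errors if no path with spacing at most `max_spacing`
#' exists among the restarts.
#'
#' @param fixture an [make_arm_dataset()] result.
#' @param k number of trajectory points (default 4).
#' @param max_spacing maximum consecutive spacing (cm, default 10).
#' @param n_starts number of greedy restarts.
#' @return a list of class `arm_trajectory` with `xyz` (`k` x 3),
#'   `angles` (`k` x 6), point indices, and the consecutive `spacings`.
#' @export
make_trajectory <- function(fixture, k = 4, max_spacing = 10, n_starts = 10) {
  n <- fixture$n_points
  if (k > n) stop("k exceeds the number of fixture points")
  if (k < 1) stop("k must be >= 1")
  D <- as.matrix(stats::dist(fixture$xyz))
  best <- NULL; best_gap <- Inf
  for (s in seq_len(min(n_starts, n))) {
    path <- s
    while (length(path) < k) {
      cand <- setdiff(seq_len(n), path)
      nxt <- cand[which.min(D[path[length(path)], cand])]
      path <- c(path, nxt)
    }
    gap <- if (k > 1) max(D[cbind(path[-k], path[-1])]) else 0
    if (gap < best_gap) { best_gap <- gap; best <- path }
  }
  if (best_gap > max_spacing)
    stop("no path with consecutive spacing <= ", max_spacing, " cm found")
  spacings <- if (k > 1) D[cbind(best[-k], best[-1])] else numeric(0)
  structure(list(xyz = fixture$xyz[best, , drop = FALSE],
                 angles = fixture$angles[best, , drop = FALSE],
                 indices = best, spacings = spacings, arm = fixture$arm),
            class = "arm_trajectory")
}

#' Write a fixture to CSV
#'
#' Classification fixtures are written with a `label` column; arm fixtures
#' with columns `point_id`, `x`, `y`, `z`, `theta1..theta6`.
#'
#' @param fixture a `classification_fixture` or `arm_fixture`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_fixture_csv <- function(fixture, path) {
  df <- if (inherits(fixture, "classification_fixture")) {
    cbind(as.data.frame(fixture$X), label = fixture$y)
  } else if (inherits(fixture, "arm_fixture")) {
    cbind(point_id = seq_len(fixture$n_points),
          as.data.frame(fixture$xyz), as.data.frame(fixture$angles))
  } else stop("unsupported fixture type")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Split a fixture into training and test sets
#'
#' Seeded shuffle followed by a fractional split; the first `frac` of the
#' shuffled instances (rounded) form the training set.
#'
#' @param n number of instances.
#' @param frac training fraction (default 0.66).
#' @param seed RNG seed.
#' @return a list with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(n, frac = 0.66, seed = 1L) {
  set.seed(seed)
  ord <- sample.int(n)
  n_tr <- max(1L, round(frac * n))
  if (n_tr >= n) n_tr <- n - 1L
  list(train = ord[seq_len(n_tr)], test = ord[(n_tr + 1L):n])
}
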