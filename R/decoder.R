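# Rate-coded decoding of Purkinje spike trains through a small feed-forward
# sigmoid network (bin counts -> 2 hidden nodes -> 1 output).

#' Rate-code a spike train into bin counts
#'
#' @param times numeric spike times (ms) in `[0, T)`.
#' @param T window length (ms); must be an integer multiple of `bin_width`.
#' @param bin_width bin width (ms), default 50.
#' @return integer vector of length `T / bin_width`; entry `k` counts spikes
#'   in `[(k-1) * bin_width, k * bin_width)`. A spike on the terminal sample
#'   (exactly at `T`) is folded into the last bin so that the counts always
#'   sum to the train length.
#' @export
#' @examples
#' rate_code(c(10, 60, 110), T = 300)  # 1 1 1 0 0 0
rate_code <- function(times, T = 300, bin_width = 50) {
  B <- T / bin_width
  if (!isTRUE(all.equal(B, round(B))))
    stop("bin_width must divide T")
  B <- round(B)
  idx <- findInterval(times, seq(0, T, by = bin_width))
  idx[times == T] <- B
  tabulate(idx, nbins = B)
}

#' Initialize a decoder network
#'
#' A fixed-architecture feed-forward net: `n_input` bin counts, one hidden
#' layer of `n_hidden` (default 2) logistic nodes, one logistic output node.
#' Weights are drawn from `0.1 * N(0, 1)`; biases start at zero.
#'
#' @param n_input input size (number of time bins, default 6).
#' @param n_hidden hidden layer size (default 2).
#' @param seed RNG seed for the weight draw.
#' @return an object of class `decoder_net`.
#' @export
decoder_net <- function(n_input = 6, n_hidden = 2, seed = 1L) {
  set.seed(seed)
  structure(list(
    n_input = n_input, n_hidden = n_hidden,
    W1 = matrix(stats::rnorm(n_hidden * n_input, 0, 0.1), n_hidden, n_input),
    b1 = rep(0, n_hidden),
    w2 = stats::rnorm(n_hidden, 0, 0.1),
    b2 = 0, seed = seed
  ), class = "decoder_net")
}

.sigmoid <- function(s) 1 / (1 + exp(-s))

#' Decoder forward pass
#'
#' @param net a [decoder_net()].
#' @param counts numeric input vector (bin counts), length `net$n_input`.
#' @return a list with output `y` (strictly inside (0, 1) for finite
#'   weights), `hidden` activations, and the `input`; hidden activations are
#'   cached for the subsequent weight update.
#' @export
decoder_forward <- function(net, counts) {
  counts <- as.numeric(counts)
  if (length(counts) != net$n_input)
    stop("expected ", net$n_input, " inputs, got ", length(counts))
  h <- .sigmoid(as.numeric(net$W1 %*% counts) + net$b1)
  y <- .sigmoid(sum(net$w2 * h) + net$b2)
  list(y = y, hidden = h, input = counts)
}

#' Threshold a decoder output into a binary label
#'
#' Implemented exactly as specified by the decoding algorithm: label 1 when
#' `y <= 0.5`, else 0. The threshold is inverted with respect to the usual
#' sigmoid convention; the training pipeline therefore teaches each decoder
#' the *complement* of its label (see [decoder_backprop()]), so that the
#' inverted threshold recovers the label.
#'
#' @param y decoder output in (0, 1).
#' @return integer label, 0 or 1.
#' @export
classify_binary <- function(y) {
  as.integer(y <= 0.5)
}

#' Decode several Purkinje trains with per-output decoder nets
#'
#' @param nets list of [decoder_net()] objects, one per Purkinje cell.
#' @param trains list of spike-time vectors, aligned with `nets`.
#' @param T,bin_width rate-coding window and bin width (ms).
#' @return numeric vector of raw decoder outputs `y`, one per net. For
#'   multiclass classification take `which.max(1 - y)` (lowest index wins
#'   ties); for motor prediction the command value is `1 - y` (see
#'   [classify_binary()] for why readouts invert).
#' @export
decode_multi <- function(nets, trains, T = 300, bin_width = 50) {
  if (length(nets) != length(trains))
    stop("need one decoder net per spike train")
  vapply(seq_along(nets), function(i) {
    decoder_forward(nets[[i]], rate_code(trains[[i]], T, bin_width))$y
  }, numeric(1))
}

#' Pick the winning class from per-class decoder outputs
#'
#' @param y numeric vector of per-class decoder outputs.
#' @return 1-based index of the winning class, `which.max(1 - y)` with the
#'   lowest index winning ties.
#' @export
argmax_class <- function(y) {
  which.max(1 - y)
}

#' Serialize / restore a decoder net as JSON
#'
#' @param net a `decoder_net`.
#' @param path JSON file path.
#' @return `decoder_to_json()` returns the path invisibly;
#'   `decoder_from_json()` the restored net.
#' @export
decoder_to_json <- function(net, path) {
  jsonlite::write_json(unclass(net), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname decoder_to_json
#' @export
decoder_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$W1 <- matrix(unlist(x$W1), x$n_hidden, x$n_input)
  structure(x, class = "decoder_net")
}
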