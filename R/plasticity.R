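# Error-modulated plasticity: multiplicative updates at the spiking synapses
# and delta-rule backpropagation at the decoder.

#' Learning rates for the three plastic sites
#'
#' Defaults follow the published operating point: 0.1 at the mossy-to-granule
#' synapse, 0.35 at the granule-to-Purkinje (parallel-fiber) synapse, and
#' 0.15 at the decoder.
#'
#' @param lr_mf_grc,lr_grc_pc,lr_decoder positive learning rates.
#' @return a list of class `learning_rates`.
#' @export
learning_rates <- function(lr_mf_grc = 0.1, lr_grc_pc = 0.35, lr_decoder = 0.15) {
  if (any(c(lr_mf_grc, lr_grc_pc, lr_decoder) <= 0))
    stop("learning rates must be positive")
  structure(list(lr_mf_grc = lr_mf_grc, lr_grc_pc = lr_grc_pc,
                 lr_decoder = lr_decoder), class = "learning_rates")
}

#' Multiplicative error-driven weight update
#'
#' Applies `w <- w * (1 - lr * e)` to every entry. Zero error is a fixed
#' point, silenced synapses (`w = 0`) stay silenced, and signs are preserved
#' whenever `|lr * e| < 1`. If `|lr * e| >= 1` the error is clamped to
#' `0.95 / lr` in magnitude (with a warning) so the update can never flip a
#' weight's sign.
#'
#' @param W numeric weight matrix (or vector).
#' @param e scalar error; at the mossy-to-granule site this is the sensory
#'   error, at the granule-to-Purkinje site the motor error (the two coincide
#'   for classification).
#' @param lr positive learning rate.
#' @return the updated weights.
#' @export
#' @examples
#' update_spiking_weights(0.5, e = 1, lr = 0.1)  # 0.45
update_spiking_weights <- function(W, e, lr) {
  if (lr <= 0) stop("lr must be positive")
  if (!is.finite(e)) stop("error must be finite")
  if (abs(lr * e) >= 1) {
    warning("|lr * e| >= 1 would flip weight signs; error clamped")
    e <- sign(e) * 0.95 / lr
  }
  W * (1 - lr * e)
}

#' Decoder output-layer error signal
#'
#' The delta-rule error signal at the output node:
#' `e_s = (y - y') * y' * (1 - y')`.
#'
#' @param y training target.
#' @param y_hat decoder output in (0, 1).
#' @return numeric scalar.
#' @export
#' @examples
#' decoder_error_signal(1, 0.5)  # 0.125
decoder_error_signal <- function(y, y_hat) {
  (y - y_hat) * y_hat * (1 - y_hat)
}

# Per-instance gradient increments of the decoder delta rule.
# e_out is the output error signal (already includes the y'(1-y') factor);
# hidden deltas are e_out * w2_j * h_j (1 - h_j). .apply_decoder_update()
# takes one gradient-descent step on the squared output error.
.decoder_increments <- function(net, fwd, e_out) {
  h <- fwd$hidden
  delta_h <- e_out * net$w2 * h * (1 - h)
  list(dW1 = delta_h %*% t(fwd$input), db1 = delta_h,
       dw2 = e_out * h, db2 = e_out)
}

.apply_decoder_update <- function(net, inc, lr) {
  net$W1 <- net$W1 + lr * inc$dW1
  net$b1 <- net$b1 + lr * inc$db1
  net$w2 <- net$w2 + lr * inc$dw2
  net$b2 <- net$b2 + lr * inc$db2
  net
}

#' One decoder weight update from a (counts, target) pair
#'
#' The two-layer backpropagation delta rule: the output error signal is
#' `e_s = (y - y') y' (1 - y')`, hidden deltas are back-propagated as
#' `e_s * w * h (1 - h)`, and every weight takes one gradient-descent step
#' `w <- w + lr * delta * input`, so repeated updates on a fixed pair drive
#' `|y - y'|` monotonically down for small learning rates.
#'
#' When used with the inverted classification threshold
#' ([classify_binary()]: `y' <= 0.5` maps to label 1), the training pipeline
#' passes the *complement* `1 - label` as the decoder target, so the trained
#' output converges on the complement and the inverted threshold recovers
#' the label; the same complement convention gives the motor readout
#' `1 - y'` in trajectory mode.
#'
#' @param net a [decoder_net()].
#' @param counts input vector (bin counts).
#' @param y training target.
#' @param lr decoder learning rate (default 0.15).
#' @param e_out optional externally supplied output error signal; by default
#'   `decoder_error_signal(y, y')`. The trajectory trainer passes the motor
#'   error on the radian scale here.
#' @return the updated `decoder_net`.
#' @export
decoder_backprop <- function(net, counts, y, lr = 0.15, e_out = NULL) {
  fwd <- decoder_forward(net, counts)
  if (is.null(e_out)) e_out <- decoder_error_signal(y, fwd$y)
  .apply_decoder_update(net, .decoder_increments(net, fwd, e_out), lr)
}

#' Causal exponential kernel trace of a spike train
#'
#' `x(t) = sum over spikes t_f <= t of exp(-(t - t_f) / tau)`; the convolved
#' presynaptic trace used by the optional trace-based learning rule.
#'
#' @param times spike times (ms).
#' @param t evaluation time (ms).
#' @param tau kernel time constant (ms), default 10.
#' @return non-negative numeric scalar.
#' @export
kernel_trace <- function(times, t, tau = 10) {
  tf <- times[times <= t]
  if (!length(tf)) return(0)
  sum(exp(-(t - tf) / tau))
}

#' Trace-based weight increment (optional alternative rule)
#'
#' `delta_w = lambda * trace * e`, the kernel-convolved form of the
#' error-driven rule. Provided as an opt-in alternative to the default
#' multiplicative rule; it is linear in both the learning rate and the trace.
#'
#' @param trace convolved presynaptic trace (see [kernel_trace()]).
#' @param e error scalar (sensory error at the mossy-to-granule site, motor
#'   error at the granule-to-Purkinje site).
#' @param lambda learning rate.
#' @return weight increment(s).
#' @export
kernel_weight_update <- function(trace, e, lambda) {
  lambda * trace * e
}
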