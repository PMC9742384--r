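# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: plain scalar loops and
# homogeneous-transform matrices.

# Scalar-loop AdEx integrator (forward Euler, same model definition).
ref_adex <- function(params, I, T, dt, V0 = params$E_L, w0 = 0) {
  n_steps <- round(T / dt)
  I <- rep_len(I, n_steps)
  V <- V0; w <- w0
  spikes <- numeric(0)
  Vtr <- numeric(n_steps + 1); Vtr[1] <- V
  for (k in seq_len(n_steps)) {
    expo <- exp(min((V - params$V_T) / params$Delta_T, params$exp_clamp))
    dV <- (-params$g_L * (V - params$E_L) +
             params$g_L * params$Delta_T * expo + I[k] - w) / params$C
    dw <- (params$a * (V - params$E_L) - w) / params$tau_w
    V <- V + dt * dV
    w <- w + dt * dw
    if (V > params$spike_cut) {
      V <- params$V_r
      w <- w + params$b
      spikes <- c(spikes, k * dt)
    }
    Vtr[k + 1] <- V
  }
  list(spike_times = spikes, V = Vtr, w_final = w)
}

# Direct double-loop full convolution.
ref_convolve <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a))
    for (j in seq_along(b))
      out[i + j - 1] <- out[i + j - 1] + a[i] * b[j]
  out
}

# Forward kinematics through explicit 4x4 homogeneous transforms.
ref_fk <- function(angles, arm) {
  hrot <- function(axis, th) {
    R <- diag(4)
    c_ <- cos(th); s_ <- sin(th)
    R3 <- switch(axis,
                 x = rbind(c(1, 0, 0), c(0, c_, -s_), c(0, s_, c_)),
                 y = rbind(c(c_, 0, s_), c(0, 1, 0), c(-s_, 0, c_)),
                 z = rbind(c(c_, -s_, 0), c(s_, c_, 0), c(0, 0, 1)))
    R[1:3, 1:3] <- R3
    R
  }
  htrans <- function(x) { M <- diag(4); M[1, 4] <- x; M }
  M <- diag(4)
  for (i in seq_len(arm$n_joints))
    M <- M %*% hrot(arm$joint_axes[i], angles[i]) %*% htrans(arm$link_lengths_cm[i])
  as.numeric(M[1:3, 4])
}

# From-scratch sparseness index (independent arithmetic path).
ref_si <- function(v) {
  n <- length(v)
  num <- mean(v)^2
  den <- mean(v * v)
  (1 - num / den) / (1 - 1 / n)
}

# Analytic gradient of 0.5 * (y - y')^2 for the 6-2-1 decoder, written out
# by the chain rule; used to check decoder_backprop to machine precision.
ref_decoder_gradstep <- function(net, x, y, lr) {
  sig <- function(s) 1 / (1 + exp(-s))
  h <- sig(as.numeric(net$W1 %*% x) + net$b1)
  yp <- sig(sum(net$w2 * h) + net$b2)
  d_out <- (y - yp) * yp * (1 - yp)       # -dE/ds at the output node
  d_hid <- d_out * net$w2 * h * (1 - h)   # -dE/ds at each hidden node
  list(W1 = net$W1 + lr * (d_hid %*% t(x)),
       b1 = net$b1 + lr * d_hid,
       w2 = net$w2 + lr * d_out * h,
       b2 = net$b2 + lr * d_out,
       y = yp)
}

# Small mossy-fiber input: a few regular trains plus silence, for network
# tests that need deterministic presynaptic activity.
toy_mf_trains <- function(n_mf, T = 300) {
  lapply(seq_len(n_mf), function(i) {
    if (i %% 3 == 0) numeric(0) else seq(5 * i %% 17 + 1, T, by = 7 + (i %% 5))
  })
}
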