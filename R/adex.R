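# Adaptive exponential integrate-and-fire (AdEx) neurons for the three
# cerebellar cell types used throughout the package.

.adex_table <- list(
  GrC = list(C = 150, g_L = 10,   E_L = -70, Delta_T = 4, V_T = -50, tau_w = 13,  I = 350, a = 9,   b = 250),
  GoC = list(C = 500, g_L = 13.1, E_L = -58, Delta_T = 7, V_T = -54, tau_w = 8.7, I = 0,   a = -17, b = 1033),
  PC  = list(C = 100, g_L = 10,   E_L = -65, Delta_T = 2, V_T = -50, tau_w = 1,   I = 0,   a = -13, b = 260)
)

#' AdEx neuron parameters for a cerebellar cell type
#'
#' Returns the nine-parameter AdEx model for granule (GrC), Golgi (GoC) or
#' Purkinje (PC) cells, plus the reset voltage and spike-detection voltage.
#' Mossy-fiber input units (`"MF"`) reuse the granule-cell parameter set.
#'
#' The membrane potential `V` (mV) and adaptation current `w` (pA) evolve as
#' \deqn{C dV/dt = -g_L (V - E_L) + g_L \Delta_T \exp((V - V_T)/\Delta_T) + I - w}
#' \deqn{\tau_w dw/dt = a (V - E_L) - w}
#' and whenever `V` exceeds `spike_cut` (0 mV) a spike is recorded, `V` is
#' reset to `V_r` and `w` is incremented by `b`.
#'
#' @param cell_type one of `"GrC"`, `"GoC"`, `"PC"`, `"MF"`.
#' @param V_r reset potential (mV); defaults to the cell's resting potential
#'   `E_L`, which keeps the model within the published parameter set.
#' @param spike_cut spike detection voltage (mV), fixed at 0 by the reset rule.
#' @param exp_clamp cap on the exponential argument `(V - V_T)/Delta_T` so the
#'   spike-initiation term never overflows; any voltage beyond the clamped
#'   region triggers the reset branch on the same step.
#' @param ... named overrides for any of `C`, `g_L`, `E_L`, `Delta_T`, `V_T`,
#'   `tau_w`, `I`, `a`, `b` (units pF, nS, mV, mV, mV, ms, pA, nS, pA).
#' @return an object of class `adex_params`.
#' @export
#' @examples
#' p <- adex_params("GrC")
#' p$b  # spike-triggered adaptation increment, pA
adex_params <- function(cell_type = c("GrC", "GoC", "PC", "MF"),
                        V_r = NULL, spike_cut = 0, exp_clamp = 20, ...) {
  cell_type <- match.arg(cell_type)
  base <- .adex_table[[if (cell_type == "MF") "GrC" else cell_type]]
  dots <- list(...)
  bad <- setdiff(names(dots), names(base))
  if (length(bad)) stop("unknown AdEx parameter(s): ", paste(bad, collapse = ", "))
  base[names(dots)] <- dots
  p <- c(base, list(V_r = if (is.null(V_r)) base$E_L else V_r,
                    spike_cut = spike_cut, exp_clamp = exp_clamp,
                    cell_type = cell_type))
  with(p, {
    if (C <= 0 || g_L <= 0 || Delta_T <= 0 || tau_w <= 0)
      stop("C, g_L, Delta_T and tau_w must be positive")
    if (V_r >= spike_cut) stop("V_r must be below spike_cut")
  })
  structure(p, class = "adex_params")
}

#' @export
print.adex_params <- function(x, ...) {
  cat("AdEx parameters (", x$cell_type, ")\n", sep = "")
  flds <- c("C", "g_L", "E_L", "Delta_T", "V_T", "tau_w", "I", "a", "b", "V_r")
  cat(paste0("  ", flds, " = ", unlist(x[flds]), collapse = "\n"), "\n")
  invisible(x)
}

#' Initial neuron state
#'
#' @param params an [adex_params()] object.
#' @param V,w_adapt,t initial membrane potential (mV; default resting
#'   potential), adaptation current (pA) and time (ms).
#' @return a list with elements `V`, `w_adapt`, `t`.
#' @export
neuron_state <- function(params, V = params$E_L, w_adapt = 0, t = 0) {
  list(V = V, w_adapt = w_adapt, t = t)
}

# Vectorised forward-Euler integration of one homogeneous AdEx population.
# drive: N x n_steps matrix of injected current (pA). Spike at step k is
# assigned time k*dt. Returns the logical spike matrix and, optionally, the
# sampled voltage trace (n_steps + 1 columns, including t = 0; post-reset
# values are recorded so the trace never exceeds spike_cut).
.adex_integrate <- function(params, drive, dt, V0 = NULL, w0 = 0,
                            record_v = FALSE, record_w = FALSE) {
  n <- nrow(drive); n_steps <- ncol(drive)
  V <- if (is.null(V0)) rep(params$E_L, n) else rep_len(V0, n)
  w <- rep_len(w0, n)
  spikes <- matrix(FALSE, n, n_steps)
  Vtr <- if (record_v) matrix(NA_real_, n, n_steps + 1) else NULL
  wtr <- if (record_w) matrix(NA_real_, n, n_steps + 1) else NULL
  if (record_v) Vtr[, 1] <- V
  if (record_w) wtr[, 1] <- w
  gL <- params$g_L; EL <- params$E_L; DT <- params$Delta_T; VT <- params$V_T
  Cm <- params$C; tw <- params$tau_w; a <- params$a; b <- params$b
  Vr <- params$V_r; cut <- params$spike_cut; clamp <- params$exp_clamp
  for (k in seq_len(n_steps)) {
    expo <- exp(pmin((V - VT) / DT, clamp))
    dV <- (-gL * (V - EL) + gL * DT * expo + drive[, k] - w) / Cm
    dw <- (a * (V - EL) - w) / tw
    V <- V + dt * dV
    w <- w + dt * dw
    sp <- V > cut
    if (any(sp)) {
      V[sp] <- Vr
      w[sp] <- w[sp] + b
      spikes[, k] <- sp
    }
    if (record_v) Vtr[, k + 1] <- V
    if (record_w) wtr[, k + 1] <- w
  }
  list(spikes = spikes, V = Vtr, w = wtr, V_final = V, w_final = w, dt = dt)
}

#' Advance an AdEx neuron by one forward-Euler step
#'
#' @param state a [neuron_state()] list.
#' @param params an [adex_params()] object.
#' @param I_ext injected current (pA) during the step.
#' @param dt step size (ms), must be positive.
#' @return a list with the updated `state` and a logical `spiked`. Immediately
#'   after a reported spike `state$V` equals `params$V_r` exactly and the
#'   adaptation current has been incremented by `params$b`.
#' @export
adex_step <- function(state, params, I_ext, dt) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive and finite")
  if (!all(is.finite(c(state$V, state$w_adapt, I_ext))))
    stop("non-finite neuron state or input current")
  out <- .adex_integrate(params, matrix(I_ext, 1, 1), dt,
                         V0 = state$V, w0 = state$w_adapt)
  list(state = list(V = out$V_final, w_adapt = out$w_final, t = state$t + dt),
       spiked = out$spikes[1, 1])
}

#' Simulate a single AdEx neuron over a time window
#'
#' @param params an [adex_params()] object.
#' @param current injected current: a scalar (pA, held constant) or a vector
#'   with one value per time step.
#' @param T simulation length (ms); must be a multiple of `dt`.
#' @param dt integration step (ms), default 0.1.
#' @param V0,w0 initial membrane potential (default `E_L`) and adaptation
#'   current.
#' @return a list of class `adex_sim` with `spike_times` (ms, strictly
#'   increasing), `trace` (data frame `time_ms`, `V_mV` of length `T/dt + 1`),
#'   `w_final`, and the call parameters.
#' @export
#' @examples
#' sim <- simulate_neuron(adex_params("GrC"), current = 0, T = 50)
#' length(sim$spike_times)  # granule cells are quiescent without input
simulate_neuron <- function(params, current, T = 300, dt = 0.1,
                            V0 = NULL, w0 = 0) {
  n_steps <- T / dt
  if (!isTRUE(all.equal(n_steps, round(n_steps))))
    stop("T must be a multiple of dt")
  n_steps <- round(n_steps)
  drive <- matrix(rep_len(current, n_steps), nrow = 1)
  out <- .adex_integrate(params, drive, dt, V0 = V0, w0 = w0,
                         record_v = TRUE, record_w = TRUE)
  structure(list(
    spike_times = which(out$spikes[1, ]) * dt,
    trace = data.frame(time_ms = seq(0, T, by = dt), V_mV = out$V[1, ]),
    w_trace = out$w[1, ],
    w_final = out$w_final, V_final = out$V_final,
    params = params, T = T, dt = dt
  ), class = "adex_sim")
}

#' Write a voltage trace or spike train to CSV
#'
#' `write_trace_csv()` writes two columns (`time_ms`, `value`);
#' `write_spikes_csv()` writes a two-column spike file (`neuron_id`,
#' `time_ms`) for a list of spike trains.
#'
#' @param sim an `adex_sim` object (for traces) or a list of numeric spike-time
#'   vectors (for spike files).
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(sim, path) {
  utils::write.csv(data.frame(time_ms = sim$trace$time_ms, value = sim$trace$V_mV),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param trains a list of numeric spike-time vectors.
#' @export
write_spikes_csv <- function(trains, path) {
  ids <- rep(seq_along(trains), lengths(trains))
  utils::write.csv(data.frame(neuron_id = ids, time_ms = unlist(trains, use.names = FALSE)),
                   path, row.names = FALSE)
  invisible(path)
}
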