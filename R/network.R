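# Construction and simulation of the MF -> GrC/GoC -> PC spiking microcircuit.

#' Build the cerebellar network topology
#'
#' Layer sizes follow the circuit's convergence-divergence conventions: the
#' mossy-fiber count is `n_features * n_per_feature`, each mossy fiber maps
#' to 53 granule cells while each granule cell pools 4 mossy fibers, so
#' `N_GrC = ceiling(N_MF * 53 / 4)` (the ceiling reproduces both reference
#' network sizes, 371 granule cells for 28 mossy fibers and 279 for 21).
#' One Purkinje cell is created per output. Mossy-fiber-to-Golgi and
#' Golgi-to-granule weights are drawn uniformly from `w_range`; the
#' mossy-to-granule weights are uniform on the same range over exactly
#' `mf_per_grc` presynaptic mossy fibers sampled without replacement per
#' granule cell; granule-to-Purkinje weights start at `w_grc_pc_init` over
#' `grc_per_pc` presynaptic granule cells (all of them when the layer is
#' smaller).
#'
#' @param n_features number of input features.
#' @param n_per_feature mossy fibers per feature (default 7).
#' @param n_outputs number of Purkinje cells (one per output).
#' @param n_goc number of Golgi cells (default 1).
#' @param mf_per_grc presynaptic mossy fibers per granule cell (default 4,
#'   capped at `N_MF` for very small input layers; explicitly requesting
#'   more than `N_MF` is an error).
#' @param grc_per_pc presynaptic granule cells per Purkinje cell (default 48).
#' @param w_range range for the uniformly drawn weights (default 0.01-0.09).
#' @param w_grc_pc_init initial granule-to-Purkinje weight (default 0.01).
#' @param seed RNG seed for weight draws and presynaptic sampling.
#' @return an object of class `cisnn_topology`.
#' @export
#' @examples
#' topo <- build_topology(4, 7, 1, seed = 1)
#' topo$N_GrC  # 371
build_topology <- function(n_features, n_per_feature = 7, n_outputs = 1,
                           n_goc = 1, mf_per_grc = 4, grc_per_pc = 48,
                           w_range = c(0.01, 0.09), w_grc_pc_init = 0.01,
                           seed = 1L) {
  if (n_features < 1 || n_per_feature < 1 || n_outputs < 1)
    stop("n_features, n_per_feature and n_outputs must be >= 1")
  N_MF <- n_features * n_per_feature
  if (missing(mf_per_grc)) {
    mf_per_grc <- min(mf_per_grc, N_MF)
  } else if (mf_per_grc > N_MF) {
    stop("mf_per_grc exceeds the number of mossy fibers")
  }
  N_GrC <- ceiling(N_MF * 53 / 4)
  N_PC <- n_outputs
  set.seed(seed)
  W_mf_goc <- matrix(stats::runif(N_MF * n_goc, w_range[1], w_range[2]),
                     N_MF, n_goc)
  presyn_mf <- matrix(vapply(seq_len(N_GrC),
                             function(i) sort(sample.int(N_MF, mf_per_grc)),
                             integer(mf_per_grc)),
                      nrow = N_GrC, ncol = mf_per_grc, byrow = TRUE)
  W_mf_grc <- matrix(0, N_GrC, N_MF)
  for (i in seq_len(N_GrC))
    W_mf_grc[i, presyn_mf[i, ]] <- stats::runif(mf_per_grc, w_range[1], w_range[2])
  W_goc_grc <- matrix(stats::runif(n_goc * N_GrC, w_range[1], w_range[2]),
                      n_goc, N_GrC)
  k_pc <- min(grc_per_pc, N_GrC)
  presyn_grc <- matrix(vapply(seq_len(N_PC),
                              function(i) sort(sample.int(N_GrC, k_pc)),
                              integer(k_pc)),
                       nrow = N_PC, ncol = k_pc, byrow = TRUE)
  W_grc_pc <- matrix(0, N_PC, N_GrC)
  for (i in seq_len(N_PC)) W_grc_pc[i, presyn_grc[i, ]] <- w_grc_pc_init
  structure(list(
    N_MF = N_MF, N_GoC = n_goc, N_GrC = N_GrC, N_PC = N_PC,
    mf_per_grc = mf_per_grc, grc_per_pc = k_pc,
    presyn_mf = presyn_mf, presyn_grc = presyn_grc,
    W_mf_goc = W_mf_goc, W_mf_grc = W_mf_grc,
    W_goc_grc = W_goc_grc, W_grc_pc = W_grc_pc,
    rng_seed = seed
  ), class = "cisnn_topology")
}

#' @export
print.cisnn_topology <- function(x, ...) {
  cat(sprintf("cisnn topology: %d MF, %d GrC, %d GoC, %d PC (seed %d)\n",
              x$N_MF, x$N_GrC, x$N_GoC, x$N_PC, x$rng_seed))
  invisible(x)
}

#' Total number of spiking neurons in a topology
#'
#' @param topology a `cisnn_topology`.
#' @return integer count `N_MF + N_GrC + N_GoC + N_PC`.
#' @export
n_neurons <- function(topology) {
  with(topology, N_MF + N_GrC + N_GoC + N_PC)
}

#' Discrete spike indicator
#'
#' Discrete-time reading of the Dirac comb over a spike train: 1 if a spike
#' time falls in `[t, t + dt)`, else 0.
#'
#' @param train numeric spike times (ms).
#' @param t bin start (ms).
#' @param dt bin width (ms).
#' @return 0 or 1.
#' @export
spike_indicator <- function(train, t, dt) {
  as.integer(any(train >= t & train < t + dt))
}

# Spike-time lists -> binary indicator matrix (N x n_steps); spike at time s
# is assigned to step ceiling(s / dt), consistent with .adex_integrate.
.trains_to_indicator <- function(trains, T, dt) {
  n_steps <- round(T / dt)
  ind <- matrix(0, length(trains), n_steps)
  for (i in seq_along(trains)) {
    k <- round(trains[[i]] / dt)
    k <- k[k >= 1 & k <= n_steps]
    ind[i, k] <- 1
  }
  ind
}

#' Postsynaptic drive at one time step
#'
#' Weighted sum of presynaptic spike indicators, scaled by the synaptic gain.
#' Inhibitory contributions enter through negative weights.
#'
#' @param weights numeric weight vector (one entry per presynaptic train).
#' @param presyn_trains list of spike-time vectors aligned with `weights`.
#' @param t,dt time step start and width (ms).
#' @param gain synaptic gain (pA per unit weight), default
#'   [default_synaptic_gain()].
#' @return drive current (pA).
#' @export
psp_drive <- function(weights, presyn_trains, t, dt,
                      gain = default_synaptic_gain()) {
  ind <- vapply(presyn_trains, spike_indicator, integer(1), t = t, dt = dt)
  gain * sum(weights * ind)
}

#' Default synaptic gain
#'
#' Scale factor converting the dimensionless connection weights into injected
#' current (pA) during one integration step. Delta synapses act for a single
#' `dt = 0.1` ms step, so one presynaptic spike at weight `w` depolarises the
#' postsynaptic cell by `gain * w * dt / C`. The default (8e5 pA per unit
#' weight) makes a mossy-fiber volley at the mean weight (0.05) a powerful,
#' relay-like event (tens of mV, as at the biological mossy-to-granule
#' synapse); with the default encoder it places active granule cells in the
#' physiological 10-50 Hz band with sparse population participation, and
#' parallel-fiber-driven Purkinje cells in the 30-500 Hz band.
#'
#' @return numeric scalar.
#' @export
default_synaptic_gain <- function() 8e5

#' Simulate the cerebellar network
#'
#' Runs the layered simulation: Golgi cells are driven (excitatory) by all
#' mossy fibers, each granule cell by its sampled mossy fibers (excitatory)
#' minus the Golgi input (inhibitory), and each Purkinje cell by its sampled
#' granule cells. Every cell is integrated as an AdEx neuron with its cell
#' type's parameter set; within the network, cells receive synaptic current
#' only (the free-running baseline current of the single-neuron model is not
#' injected).
#'
#' @param topology a [build_topology()] result.
#' @param mf_trains list of `N_MF` spike-time vectors (from
#'   [mf_spike_trains()]).
#' @param T,dt simulation window and step (ms).
#' @param gain synaptic gain (pA per unit weight).
#' @param goc_inhibition set `FALSE` to silence the Golgi-to-granule synapse
#'   (used for inhibition-removal contrasts).
#' @return an object of class `cisnn_activity`: spike-time lists `mf`, `goc`,
#'   `grc`, `pc`, spike-count vectors per layer, and the simulation window.
#' @export
simulate_network <- function(topology, mf_trains, T = 300, dt = 0.1,
                             gain = default_synaptic_gain(),
                             goc_inhibition = TRUE) {
  if (length(mf_trains) != topology$N_MF)
    stop("expected ", topology$N_MF, " mossy-fiber trains, got ", length(mf_trains))
  mf_ind <- .trains_to_indicator(mf_trains, T, dt)
  sim <- .simulate_from_mf(topology, mf_ind, T, dt, gain, goc_inhibition)
  structure(list(
    mf = mf_trains,
    goc = .spike_matrix_to_trains(sim$goc_spikes, dt),
    grc = .spike_matrix_to_trains(sim$grc_spikes, dt),
    pc = .spike_matrix_to_trains(sim$pc_spikes, dt),
    counts = list(mf = lengths(mf_trains), goc = rowSums(sim$goc_spikes),
                  grc = rowSums(sim$grc_spikes), pc = rowSums(sim$pc_spikes)),
    T = T, dt = dt, gain = gain
  ), class = "cisnn_activity")
}

.spike_matrix_to_trains <- function(sp, dt) {
  apply(sp, 1, function(s) which(s) * dt, simplify = FALSE)
}

# Core layered pass used by simulate_network and by the training loops (which
# cache the mossy-fiber indicator and Golgi spikes across epochs: neither
# depends on the learned weights).
.simulate_from_mf <- function(topology, mf_ind, T, dt,
                              gain = default_synaptic_gain(),
                              goc_inhibition = TRUE, goc_spikes = NULL) {
  if (is.null(goc_spikes)) {
    goc_drive <- gain * (t(topology$W_mf_goc) %*% mf_ind)
    goc_spikes <- .adex_integrate(adex_params("GoC"), goc_drive, dt)$spikes
  }
  grc_drive <- gain * (topology$W_mf_grc %*% mf_ind)
  if (goc_inhibition)
    grc_drive <- grc_drive - gain * (t(topology$W_goc_grc) %*% (goc_spikes * 1))
  grc_spikes <- .adex_integrate(adex_params("GrC"), grc_drive, dt)$spikes
  pc_drive <- gain * (topology$W_grc_pc %*% (grc_spikes * 1))
  pc_spikes <- .adex_integrate(adex_params("PC"), pc_drive, dt)$spikes
  list(goc_spikes = goc_spikes, grc_spikes = grc_spikes, pc_spikes = pc_spikes)
}

#' Serialize / restore a topology as JSON
#'
#' @param topology a `cisnn_topology`.
#' @param path JSON file path.
#' @return `topology_to_json()` returns the path invisibly;
#'   `topology_from_json()` returns the restored `cisnn_topology`.
#' @export
topology_to_json <- function(topology, path) {
  jsonlite::write_json(unclass(topology), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname topology_to_json
#' @export
topology_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("presyn_mf", "presyn_grc", "W_mf_goc", "W_mf_grc",
               "W_goc_grc", "W_grc_pc"))
    x[[nm]] <- as.matrix(x[[nm]])
  structure(x, class = "cisnn_topology")
}
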