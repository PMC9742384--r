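# Trajectory prediction for the 6-DOF arm: per-point spiking networks map
# end-effector coordinates to joint angles, trained with the dual
# sensory/motor error.

# Encoder over the workspace cuboid: the normalization bounds come from the
# cuboid extents (not from data), with a constant receptive-field spread.
.workspace_encoder <- function(arm, config) {
  lo <- arm$workspace_center - arm$workspace_dims / 2
  hi <- arm$workspace_center + arm$workspace_dims / 2
  corners <- rbind(lo, hi)
  fit_encoder(corners, encoding_config(
    n_per_feature = config$n_per_feature,
    sigma = config$trajectory_sigma,
    target_max_pA = config$encoder_config$target_max_pA))
}

# Build the untrained per-point prediction network (21 MF, 279 GrC, 1 GoC,
# 6 PC by default) and its six decoders.
.point_model <- function(arm, config, encoder, seed) {
  topology <- build_topology(3, config$n_per_feature, arm$n_joints, seed = seed)
  decoders <- lapply(seq_len(arm$n_joints), function(k)
    decoder_net(n_input = round(config$T / config$bin_width), seed = seed + k))
  list(topology = topology, decoders = decoders, encoder = encoder, arm = arm)
}

#' Untrained per-point prediction model
#'
#' Instantiates the single-point prediction network: 3 coordinate features
#' at `n_per_feature` mossy fibers each, one Purkinje cell per joint, and a
#' workspace-bound encoder. With the defaults this is 21 MF + 279 GrC +
#' 1 GoC + 6 PC = 307 spiking neurons.
#'
#' @param arm an [arm_model()].
#' @param config a [run_config()].
#' @param seed RNG seed for the weight draws.
#' @return a point model usable with [predict_point()].
#' @export
point_prediction_model <- function(arm = arm_model(),
                                   config = run_config(mode = "trajectory"),
                                   seed = config$seed) {
  .point_model(arm, config, .workspace_encoder(arm, config), seed)
}

.point_forward <- function(model, prep, config) {
  out <- .forward_instance(prep, model$topology, model$decoders, config)
  raw <- 1 - out$y  # readouts invert the raw output; see classify_binary()
  angles <- normalize_angles(raw, model$arm)
  list(y = out$y, fwd = out$fwd, raw = raw, angles = angles,
       grc_counts = out$grc_counts, pc_counts = out$pc_counts)
}

#' Predict the joint angles reaching one target point
#'
#' Encodes the target coordinates (3 features at `n_per_feature` mossy
#' fibers each), runs the prediction network (21 MF, 279 GrC, 1 GoC, 6 PC
#' with the defaults -- 307 spiking neurons), decodes the six outputs,
#' maps them onto the joint-angle range and computes the realized
#' end-effector position by forward kinematics.
#'
#' @param target_xyz target position (cm); a target outside the workspace
#'   cuboid triggers a warning but is still predicted.
#' @param model a per-point model from [follow_trajectory()] (or an untrained
#'   one built internally).
#' @param arm an [arm_model()]; defaults to the model's arm.
#' @param config a [run_config()].
#' @return a list of class `trajectory_point` with `target_xyz`,
#'   `predicted_angles`, `realized_xyz` (forward kinematics of the predicted
#'   angles, always self-consistent) and the raw decoder outputs.
#' @export
predict_point <- function(target_xyz, model, arm = model$arm,
                          config = run_config(mode = "trajectory")) {
  if (!in_workspace(target_xyz, arm))
    warning("target lies outside the workspace cuboid")
  Xn <- minmax_normalize(target_xyz, model$encoder$spec)
  enc <- encode_instance(Xn[1, ], model$encoder)
  trains <- mf_spike_trains(enc, T = config$T, dt = config$dt)
  mf_ind <- .trains_to_indicator(trains, config$T, config$dt)
  goc_drive <- config$synaptic_gain * (t(model$topology$W_mf_goc) %*% mf_ind)
  goc_spikes <- .adex_integrate(adex_params("GoC"), goc_drive, config$dt)$spikes
  res <- .point_forward(model, list(mf_ind = mf_ind, goc_spikes = goc_spikes),
                        config)
  structure(list(target_xyz = as.numeric(target_xyz),
                 predicted_angles = res$angles,
                 realized_xyz = forward_kinematics(res$angles, arm),
                 raw_outputs = res$raw, y = res$y),
            class = "trajectory_point")
}

#' Trace a multi-point trajectory with per-point networks
#'
#' One independent prediction network is instantiated per target (307
#' spiking neurons each with the defaults, so a 4-point trajectory uses
#' 1,228), and each is trained on its point for up to `config$epochs`
#' epochs. Each epoch runs the network, decodes the six joint angles,
#' computes the dual errors -- the motor error (desired minus predicted
#' angle, radians) and the sensory error (target minus realized
#' end-effector position, cm) -- and applies one update: the sensory error
#' (coordinate mean) drives the multiplicative rule at the mossy-to-granule
#' weights, the per-joint motor error drives the corresponding
#' granule-to-Purkinje row, and the radian-scale motor error drives each
#' joint's decoder through the delta rule. The best epoch (smallest
#' maximum per-coordinate deviation) is kept per point.
#'
#' @param trajectory an [make_trajectory()] result (targets with their
#'   forward-kinematics-consistent desired angles).
#' @param config a [run_config()] (`mode = "trajectory"`).
#' @param share_weights start each point's network from the previous point's
#'   trained weights instead of a fresh draw (default FALSE, independent
#'   per-point networks).
#' @return a list of class `trajectory_run`: `points` (one
#'   `trajectory_point` per target, at the best epoch), `deviation` matrix
#'   (points x xyz, absolute target-minus-realized), `max_deviation_cm`,
#'   `n_neurons_total`, per-point training `history`, and the config.
#' @export
follow_trajectory <- function(trajectory, config = run_config(mode = "trajectory"),
                              share_weights = FALSE) {
  arm <- trajectory$arm
  k <- nrow(trajectory$xyz)
  if (k == 0)
    return(structure(list(points = list(),
                          deviation = matrix(numeric(0), 0, 3),
                          max_deviation_cm = NA_real_, n_neurons_total = 0L,
                          history = list(), config = config),
                     class = "trajectory_run"))
  encoder <- .workspace_encoder(arm, config)
  lr <- config$rates
  angle_span <- diff(arm$angle_range)
  points <- vector("list", k)
  histories <- vector("list", k)
  n_total <- 0L
  carry <- NULL
  for (p in seq_len(k)) {
    target <- trajectory$xyz[p, ]
    desired <- trajectory$angles[p, ]
    desired_norm <- (desired - arm$angle_range[1]) / angle_span
    model <- .point_model(arm, config, encoder, seed = config$seed + 101 * p)
    if (share_weights && !is.null(carry)) {
      model$topology <- carry$topology
      model$decoders <- carry$decoders
    }
    n_total <- n_total + n_neurons(model$topology)
    Xn <- minmax_normalize(target, encoder$spec)
    enc <- encode_instance(Xn[1, ], encoder)
    trains <- mf_spike_trains(enc, T = config$T, dt = config$dt)
    mf_ind <- .trains_to_indicator(trains, config$T, config$dt)
    goc_drive <- config$synaptic_gain * (t(model$topology$W_mf_goc) %*% mf_ind)
    goc_spikes <- .adex_integrate(adex_params("GoC"), goc_drive, config$dt)$spikes
    prep <- list(mf_ind = mf_ind, goc_spikes = goc_spikes)

    hist <- data.frame(epoch = integer(0), max_dev_cm = numeric(0),
                       mean_abs_es_cm = numeric(0), mean_abs_em_rad = numeric(0))
    best <- list(dev = Inf, model = model, epoch = 0L)
    record <- function(ep, res) {
      errs <- dual_errors(desired, res$angles, target, arm)
      dev <- max(abs(errs$e_s))
      hist[nrow(hist) + 1, ] <<- list(ep, dev, mean(abs(errs$e_s)),
                                      mean(abs(errs$e_m)))
      if (dev < best$dev) best <<- list(dev = dev, model = model, epoch = ep)
      errs
    }
    res <- .point_forward(model, prep, config)
    errs <- record(0L, res)
    if (config$epochs > 0) {
      for (ep in seq_len(config$epochs)) {
        # spiking sites take the dimensionless (normalized) errors -- the
        # multiplicative rule's sign-preservation bound |lr * e| < 1 holds
        # only for unit-scale errors: sensory error normalized by the
        # workspace extents (coordinate mean) at MF-GrC, per-joint motor
        # error on the 0-1 angle scale at the matching GrC-PC row
        e_s_scalar <- .clamp_e(mean(errs$e_s / arm$workspace_dims),
                               lr$lr_mf_grc)
        model$topology$W_mf_grc <-
          update_spiking_weights(model$topology$W_mf_grc, e_s_scalar,
                                 lr$lr_mf_grc)
        for (j in seq_len(arm$n_joints)) {
          e_m_j <- .clamp_e(errs$e_m[j] / angle_span, lr$lr_grc_pc)
          model$topology$W_grc_pc[j, ] <-
            update_spiking_weights(model$topology$W_grc_pc[j, ], e_m_j,
                                   lr$lr_grc_pc)
        }
        # decoders: delta rule toward the complement of the normalized
        # desired angle (readouts invert). The output delta is the plain
        # motor error on the radian scale -- the dual-error formulation's
        # linear error term, without the classification algorithm's
        # sigmoid-derivative factor
        for (j in seq_len(arm$n_joints)) {
          e_out <- angle_span * ((1 - desired_norm[j]) - res$y[j])
          inc <- .decoder_increments(model$decoders[[j]], res$fwd[[j]], e_out)
          model$decoders[[j]] <- .apply_decoder_update(model$decoders[[j]],
                                                       inc, lr$lr_decoder)
        }
        res <- .point_forward(model, prep, config)
        errs <- record(ep, res)
      }
    }
    carry <- best$model
    final <- .point_forward(best$model, prep, config)
    points[[p]] <- structure(list(
      target_xyz = as.numeric(target), desired_angles = as.numeric(desired),
      predicted_angles = final$angles,
      realized_xyz = forward_kinematics(final$angles, arm),
      raw_outputs = final$raw, y = final$y, best_epoch = best$epoch,
      model = best$model), class = "trajectory_point")
    histories[[p]] <- hist
  }
  deviation <- t(vapply(points, function(pt)
    abs(pt$target_xyz - pt$realized_xyz), numeric(3)))
  colnames(deviation) <- c("x", "y", "z")
  structure(list(points = points, deviation = deviation,
                 max_deviation_cm = max(deviation),
                 n_neurons_total = n_total, history = histories,
                 config = config),
            class = "trajectory_run")
}

# quiet clamp keeping |lr * e| < 1 (sign-preservation bound); the trainers
# count on update_spiking_weights() erroring only on non-finite input
.clamp_e <- function(e, lr) {
  if (abs(lr * e) >= 1) sign(e) * 0.95 / lr else e
}

#' @export
print.trajectory_run <- function(x, ...) {
  cat(sprintf("trajectory run: %d points, %d spiking neurons, max deviation %.2f cm\n",
              length(x$points), x$n_neurons_total,
              x$max_deviation_cm))
  invisible(x)
}

#' Summarise a trajectory run as JSON
#'
#' @param run a `trajectory_run`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
trajectory_report_json <- function(run, path) {
  jsonlite::write_json(list(
    n_points = length(run$points),
    n_neurons_total = run$n_neurons_total,
    max_deviation_cm = run$max_deviation_cm,
    deviation = as.data.frame(run$deviation),
    targets = lapply(run$points, `[[`, "target_xyz"),
    realized = lapply(run$points, `[[`, "realized_xyz"),
    seed = run$config$seed
  ), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
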