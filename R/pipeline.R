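# End-to-end supervised training and evaluation (classification mode), plus
# the run configuration shared by all modes.

#' Run configuration
#'
#' Collects every tunable of an end-to-end run. Defaults follow the model's
#' published operating point: 7 mossy fibers per feature, a 300 ms window at
#' 0.1 ms resolution, 50 ms rate-coding bins, learning rates 0.1 / 0.35 /
#' 0.15 at the three plastic sites, at most 50 epochs, and a 66% training
#' split.
#'
#' @param mode one of `"classify"`, `"trajectory"`, `"metrics"`, `"fixtures"`.
#' @param n_per_feature mossy fibers per feature.
#' @param T,dt simulation window and integration step (ms).
#' @param bin_width rate-coding bin (ms).
#' @param rates a [learning_rates()] object.
#' @param epochs maximum training epochs.
#' @param split training fraction for the train/test split.
#' @param seed master RNG seed; all randomness in a run derives from it.
#' @param synaptic_gain network synaptic gain (pA per unit weight).
#' @param encoder_config an [encoding_config()].
#' @param early_stop_tol stop when the epoch-to-epoch change in mean training
#'   error falls below this (default 1e-4).
#' @param trajectory_sigma receptive-field spread for workspace-encoded
#'   coordinates (default 0.1 normalized units).
#' @param capacity_interpretation formula-parse identifiers recorded with any
#'   capacity numbers.
#' @return a list of class `cisnn_config`.
#' @export
run_config <- function(mode = c("classify", "trajectory", "metrics", "fixtures"),
                       n_per_feature = 7, T = 300, dt = 0.1, bin_width = 50,
                       rates = learning_rates(), epochs = 50, split = 0.66,
                       seed = 1L, synaptic_gain = default_synaptic_gain(),
                       encoder_config = NULL, early_stop_tol = 1e-4,
                       trajectory_sigma = 0.1,
                       capacity_interpretation = c(kappa = "T_over_sqrt",
                                                   alpha = "lnln_over_2ln2")) {
  mode <- match.arg(mode)
  if (is.null(encoder_config))
    encoder_config <- encoding_config(n_per_feature = n_per_feature)
  stopifnot(T > 0, dt > 0, epochs >= 0, split > 0, split < 1)
  structure(list(mode = mode, n_per_feature = n_per_feature, T = T, dt = dt,
                 bin_width = bin_width, rates = rates, epochs = epochs,
                 split = split, seed = as.integer(seed),
                 synaptic_gain = synaptic_gain,
                 encoder_config = encoder_config,
                 early_stop_tol = early_stop_tol,
                 trajectory_sigma = trajectory_sigma,
                 capacity_interpretation = capacity_interpretation),
            class = "cisnn_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Scalar fields of the file override [run_config()] defaults; learning
#' rates may be given as `lr_mf_grc`, `lr_grc_pc`, `lr_decoder`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return a `cisnn_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  lr <- learning_rates(
    lr_mf_grc = raw$lr_mf_grc %||% 0.1,
    lr_grc_pc = raw$lr_grc_pc %||% 0.35,
    lr_decoder = raw$lr_decoder %||% 0.15)
  args <- raw[intersect(names(raw), setdiff(names(formals(run_config)),
                                            c("rates", "encoder_config")))]
  do.call(run_config, c(args, list(rates = lr)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Prepare the per-instance caches that do not depend on the learned weights:
# encoded currents, mossy-fiber spike indicators and Golgi spikes.
.prepare_instances <- function(X, encoder, topology, config) {
  Xn <- minmax_normalize(X, encoder$spec)
  n_steps <- round(config$T / config$dt)
  lapply(seq_len(nrow(Xn)), function(i) {
    enc <- encode_instance(Xn[i, ], encoder)
    trains <- mf_spike_trains(enc, T = config$T, dt = config$dt)
    mf_ind <- .trains_to_indicator(trains, config$T, config$dt)
    goc_drive <- config$synaptic_gain * (t(topology$W_mf_goc) %*% mf_ind)
    goc_spikes <- .adex_integrate(adex_params("GoC"), goc_drive, config$dt)$spikes
    list(mf_ind = mf_ind, goc_spikes = goc_spikes)
  })
}

# Forward pass for one prepared instance under the current weights.
# Returns decoder outputs and granule/Purkinje spike counts.
.forward_instance <- function(prep, topology, decoders, config) {
  sim <- .simulate_from_mf(topology, prep$mf_ind, config$T, config$dt,
                           gain = config$synaptic_gain,
                           goc_spikes = prep$goc_spikes)
  counts <- lapply(seq_len(topology$N_PC), function(k) {
    rate_code(which(sim$pc_spikes[k, ]) * config$dt, config$T, config$bin_width)
  })
  fwd <- lapply(seq_len(topology$N_PC), function(k)
    decoder_forward(decoders[[k]], counts[[k]]))
  list(y = vapply(fwd, `[[`, numeric(1), "y"), fwd = fwd, counts = counts,
       grc_counts = rowSums(sim$grc_spikes),
       pc_counts = rowSums(sim$pc_spikes))
}

# Decoder training targets per output for one instance: the *complement* of
# the label indicator (binary: second class -> 0, first class -> 1;
# multiclass one-vs-rest likewise), matching the inverted classification
# threshold (see classify_binary()).
.class_targets <- function(y_i, classes) {
  if (length(classes) == 2) {
    1 - as.numeric(y_i == classes[2])
  } else {
    1 - as.numeric(classes == y_i)
  }
}

.predict_label <- function(y_hat, classes) {
  if (length(classes) == 2) {
    classes[classify_binary(y_hat) + 1L]
  } else {
    classes[argmax_class(y_hat)]
  }
}

#' Train the cerebellum-inspired classifier
#'
#' Runs the full pipeline on a feature/label training set: fit the encoder,
#' build the spiking topology (one Purkinje cell and decoder for binary
#' labels, one per class otherwise), then per epoch encode - simulate -
#' decode every instance, adapting each decoder online after every instance
#' with the delta rule (toward the complement target, see
#' [decoder_backprop()]), while the two spiking sites receive one
#' multiplicative update per epoch from the accumulated mean error. Epoch
#' statistics are collected during the pass. Training stops early when the
#' mean absolute error changes by less than `config$early_stop_tol`, and the
#' best-epoch weights (lowest mean error) are kept.
#'
#' @param X training feature matrix or data frame.
#' @param y training labels (two or more classes).
#' @param config a [run_config()].
#' @return a list of class `cisnn_model` with the fitted `encoder`,
#'   `topology`, `decoders`, `classes`, `config`, and a `report` containing
#'   the resolved configuration, the per-epoch `history` (mean absolute
#'   error, training accuracy), granule-layer sparseness summaries before
#'   and after learning, and the epoch kept.
#' @export
train_model <- function(X, y, config = run_config()) {
  X <- as.matrix(X)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least two classes")
  n_out <- if (length(classes) == 2) 1L else length(classes)
  encoder <- fit_encoder(X, config$encoder_config)
  topology <- build_topology(ncol(X), config$n_per_feature, n_out,
                             seed = config$seed)
  decoders <- lapply(seq_len(n_out), function(k)
    decoder_net(n_input = round(config$T / config$bin_width),
                seed = config$seed + k))
  prep <- .prepare_instances(X, encoder, topology, config)
  n <- nrow(X)
  lr <- config$rates
  history <- data.frame(epoch = integer(0), mean_abs_error = numeric(0),
                        accuracy = numeric(0))
  best <- list(err = Inf, topology = topology, decoders = decoders, epoch = 0L)
  clamp_events <- 0L
  si_pre <- si_post <- NULL

  run_pass <- function(update) {
    # one pass over the training set; with update = TRUE each decoder is
    # adapted online after every instance, while the two spiking sites
    # receive one multiplicative update per epoch from the accumulated mean
    # error (classification uses a single error representation, so the
    # sensory and motor errors coincide)
    err_sum <- 0; correct <- 0; e_site <- 0
    grc_rates <- matrix(0, topology$N_GrC, n)
    for (i in seq_len(n)) {
      out <- .forward_instance(prep[[i]], topology, decoders, config)
      targets <- .class_targets(y[i], classes)
      errs <- targets - out$y
      err_sum <- err_sum + mean(abs(errs))
      e_site <- e_site + mean(errs)
      if (identical(.predict_label(out$y, classes), y[i])) correct <- correct + 1
      grc_rates[, i] <- out$grc_counts / (config$T / 1000)
      if (update) {
        for (k in seq_len(n_out)) {
          e_out <- decoder_error_signal(targets[k], out$y[k])
          inc <- .decoder_increments(decoders[[k]], out$fwd[[k]], e_out)
          decoders[[k]] <<- .apply_decoder_update(decoders[[k]], inc,
                                                  lr$lr_decoder)
        }
      }
    }
    if (update) {
      for (site in c("W_mf_grc", "W_grc_pc")) {
        lr_site <- if (site == "W_mf_grc") lr$lr_mf_grc else lr$lr_grc_pc
        e_use <- e_site / n
        if (abs(lr_site * e_use) >= 1) {
          clamp_events <<- clamp_events + 1L
          e_use <- sign(e_use) * 0.95 / lr_site
        }
        topology[[site]] <<- update_spiking_weights(topology[[site]],
                                                    e_use, lr_site)
      }
    }
    list(err = err_sum / n, acc = correct / n, grc_rates = grc_rates)
  }

  res <- run_pass(update = FALSE)
  history[1, ] <- list(0L, res$err, res$acc)
  si_pre <- sparseness_profile(res$grc_rates)
  ep_first_rates <- res$grc_rates
  best <- list(err = res$err, topology = topology, decoders = decoders,
               epoch = 0L)
  prev_err <- res$err
  last_rates <- res$grc_rates
  if (config$epochs > 0) {
    for (ep in seq_len(config$epochs)) {
      res <- run_pass(update = TRUE)
      history[nrow(history) + 1, ] <- list(ep, res$err, res$acc)
      last_rates <- res$grc_rates
      if (res$err < best$err)
        best <- list(err = res$err, topology = topology, decoders = decoders,
                     epoch = ep)
      if (abs(prev_err - res$err) < config$early_stop_tol) break
      prev_err <- res$err
    }
  }
  si_post <- sparseness_profile(last_rates)
  structure(list(
    encoder = encoder, topology = best$topology, decoders = best$decoders,
    classes = classes, config = config,
    report = list(history = history, best_epoch = best$epoch,
                  clamp_events = clamp_events,
                  # granule cells firing before learning but silent after
                  # (observed sparsification; recorded, not asserted)
                  n_grc_silenced = sum(rowSums(ep_first_rates) > 0 &
                                         rowSums(last_rates) == 0),
                  si_pre = si_pre, si_post = si_post,
                  si_mean_pre = mean(si_pre, na.rm = TRUE),
                  si_mean_post = mean(si_post, na.rm = TRUE),
                  seed = config$seed)
  ), class = "cisnn_model")
}

#' Predict labels with a trained model
#'
#' @param object a `cisnn_model`.
#' @param X feature matrix on the raw scale.
#' @param ... unused.
#' @return a list with `labels` and the raw decoder outputs `y_hat`
#'   (instances x outputs).
#' @export
predict.cisnn_model <- function(object, X, ...) {
  X <- as.matrix(X)
  config <- object$config
  prep <- .prepare_instances(X, object$encoder, object$topology, config)
  y_hat <- vapply(prep, function(p) {
    .forward_instance(p, object$topology, object$decoders, config)$y
  }, numeric(length(object$decoders)))
  y_hat <- if (is.null(dim(y_hat))) matrix(y_hat, ncol = 1) else t(y_hat)
  labels <- apply(y_hat, 1, .predict_label, classes = object$classes)
  list(labels = labels, y_hat = y_hat)
}

#' Evaluate a trained model on a test split
#'
#' Forward-only pass; accuracy is the fraction of correct labels and the
#' confusion counts sum to the test-set size.
#'
#' @param model a `cisnn_model`.
#' @param X,y test features and labels.
#' @return a list with `accuracy`, `confusion` (true x predicted table), and
#'   the predictions.
#' @export
evaluate_model <- function(model, X, y) {
  pred <- predict(model, X)
  lv <- as.character(model$classes)
  confusion <- table(factor(as.character(y), levels = lv),
                     factor(as.character(pred$labels), levels = lv),
                     dnn = c("true", "predicted"))
  list(accuracy = mean(pred$labels == y), confusion = confusion,
       predictions = pred$labels, y_hat = pred$y_hat)
}

#' Write a training history to CSV
#'
#' @param model a `cisnn_model`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_history_csv <- function(model, path) {
  utils::write.csv(model$report$history, path, row.names = FALSE)
  invisible(path)
}
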