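# Neural-network latency regressors: model builders, input preparation
# (250 Hz, 101-sample crop, per-trial standardization), training harness
# and prediction.

#' Training configuration for the neural-network regressors
#'
#' Adam with its default hyperparameters, mean-squared-error loss on the
#' latency target, batch size 128 and early stopping on the validation
#' loss with best-weight restoration.
#'
#' @param batch_size minibatch size.
#' @param max_epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param lr initial Adam learning rate.
#' @param val_fraction fraction of training trials held out for validation
#'   when no validation set is supplied.
#' @param lr_decay multiplicative learning-rate reduction applied at each
#'   schedule milestone; 1 keeps the rate constant.
#' @param lr_steps number of evenly spaced decay milestones across the
#'   run (stepped schedule; 2 gives thirds at `lr`, `lr*d`, `lr*d^2`).
#' @param seed seed for initialisation, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 128L, max_epochs = 100L,
                         patience = 10L, lr = 0.001, val_fraction = 0.2,
                         lr_decay = 0.5, lr_steps = 2L, seed = 42L) {
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr = lr,
                 val_fraction = val_fraction, lr_decay = lr_decay,
                 lr_steps = as.integer(lr_steps),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Input preparation shared by training and prediction
#'
#' @param srate_target sampling rate the networks operate at, Hz.
#' @param crop time window cropped to the network's input length, seconds;
#'   the default 0.248-0.652 s centres the 101-sample (at 250 Hz) input on
#'   the 0.300-0.600 s search window, leaving an equal margin on both
#'   sides so late and early components are truncated symmetrically.
#' @param n_samples network input length in samples.
#' @param search_window window used for the affine latency target scaling.
#' @return An object of class `nn_prep`.
#' @export
nn_prep <- function(srate_target = 250, crop = c(0.248, 0.652),
                    n_samples = 101L, search_window = c(0.300, 0.600)) {
  structure(list(srate_target = srate_target, crop = crop,
                 n_samples = as.integer(n_samples),
                 search_window = search_window), class = "nn_prep")
}

# epochs -> standardized [trials, channels, n_samples] array at 250 Hz
prepare_nn_array <- function(epochs, prep) {
  if (abs(epochs$srate - prep$srate_target) > 1e-9) {
    fac <- epochs$srate / prep$srate_target
    if (abs(fac - round(fac)) > 1e-9)
      stop("srate ", epochs$srate, " is not an integer multiple of ",
           prep$srate_target)
    epochs <- decimate_epochs(epochs, round(fac))
  }
  i0 <- time_to_sample(epochs, prep$crop[1L])
  idx <- i0:(i0 + prep$n_samples - 1L)
  if (idx[length(idx)] > dim(epochs$data)[3L])
    stop("crop window extends past the epoch end")
  x <- epochs$data[, , idx, drop = FALSE]
  # per-trial, per-channel standardization
  mu <- apply(x, c(1L, 2L), mean)
  sdv <- apply(x, c(1L, 2L), sd)
  sdv[sdv == 0] <- 1
  (x - array(mu, dim(x))) / array(sdv, dim(x))
}

scale_target <- function(lat, prep)
  (lat - prep$search_window[1L]) / diff(prep$search_window)
unscale_target <- function(y, prep)
  y * diff(prep$search_window) + prep$search_window[1L]

#' Build the convolutional (EEGNet-style) latency regressor
#'
#' Two convolutional blocks — a temporal convolution (8 filters 1x64, same
#' padding, no bias) with batch-norm, a depthwise spatial convolution
#' (20x1, depth multiplier 2, max-norm 1) with batch-norm, ELU,
#' average-pool 1x4 and dropout 0.5; then a separable convolution (16
#' filters 1x16) with batch-norm, ELU, average-pool 1x8 and dropout 0.5 —
#' followed by a flatten (48 features) and a linear dense unit that
#' outputs the latency.
#'
#' @param n_channels input channel count.
#' @param n_samples input length in samples (101 at 250 Hz).
#' @param seed initialisation seed.
#' @param prep an `nn_prep` input-preparation contract.
#' @return An object of class `nn_model`.
#' @export
build_eegnet <- function(n_channels = 20L, n_samples = 101L, seed = 42L,
                         prep = nn_prep()) {
  w <- eegnet_init_cpp(n_channels, n_samples, seed)
  structure(list(kind = "eegnet", weights = w, prep = prep,
                 history = NULL), class = "nn_model")
}

#' Build the convolutional LSTM latency regressor
#'
#' The electrodes are mapped to a 5x5 scalp grid; the sequence of grid maps
#' passes through two convolutional-LSTM layers (6 filters 2x2, tanh cell
#' activation, dropout 0.2, recurrent dropout 0.1), each followed by batch
#' normalisation; per time index the maximum across filters and grid cells
#' is taken, the pooled sequence is flattened and a linear dense unit
#' outputs the latency.
#'
#' @param n_samples input sequence length (101 at 250 Hz).
#' @param seed initialisation seed.
#' @param prep an `nn_prep`.
#' @param montage a `grid_montage` for [map_to_grid()].
#' @return An object of class `nn_model`.
#' @export
build_convlstm <- function(n_samples = 101L, seed = 42L, prep = nn_prep(),
                           montage = oddball20_grid()) {
  w <- convlstm_init_cpp(n_samples, seed)
  structure(list(kind = "convlstm", weights = w, prep = prep,
                 montage = montage, history = NULL), class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  cat(sprintf("<nn_model:%s> %s\n", x$kind,
              if (is.null(x$history)) "untrained" else
                sprintf("trained (best epoch %d, val MSE %.3g)",
                        x$history$best_epoch, x$history$best_val_loss)))
  print(layer_summary(x))
  invisible(x)
}

#' Per-layer parameter counts of a network
#'
#' @param model an `nn_model`.
#' @return A data frame with layer names, parameter counts (batch-norm rows
#'   include the moving mean/variance) and output widths where meaningful
#'   (flatten/dense rows).
#' @export
layer_summary <- function(model) {
  if (model$kind == "eegnet") eegnet_param_counts_cpp(model$weights)
  else convlstm_param_counts_cpp(model$weights)
}

# model-specific input tensor
nn_input <- function(model, epochs) {
  x <- prepare_nn_array(epochs, model$prep)
  if (model$kind == "eegnet") return(x)
  ep <- epochs_set(x, model$prep$srate_target, 0,
                   epochs$channel_names)  # times irrelevant post-crop
  map_to_grid(ep, model$montage)
}

#' Train a neural-network latency regressor
#'
#' Inputs are downsampled to 250 Hz, cropped to the network's input window
#' and standardized per trial and channel; targets are the ground-truth
#' latencies, affinely scaled to `[0, 1]` over the search window (inverted
#' at prediction). Training minimises the MSE with Adam; the weights of
#' the best validation epoch are restored.
#'
#' @param model an `nn_model` from [build_eegnet()] or [build_convlstm()].
#' @param train an `epochs_set` whose component trials carry
#'   `true_latency`.
#' @param val optional validation `epochs_set`; when `NULL` a random
#'   fraction of the training trials is held out.
#' @param cfg a `train_config`.
#' @return The trained `nn_model` with a `history` element (per-epoch
#'   train/validation loss, best epoch).
#' @export
train_nn <- function(model, train, val = NULL, cfg = train_config()) {
  keep <- !is.na(train$true_latency)
  if (!any(keep)) stop("unlabeled training data: no trial carries true_latency")
  train <- subset_trials(train, keep)
  if (is.null(val)) {
    n <- n_trials(train)
    n_val <- max(1L, round(cfg$val_fraction * n))
    vi <- with_seed(cfg$seed, sample(n, n_val))
    val <- subset_trials(train, vi)
    train <- subset_trials(train, setdiff(seq_len(n), vi))
  } else {
    vkeep <- !is.na(val$true_latency)
    if (!any(vkeep)) stop("unlabeled validation data")
    val <- subset_trials(val, vkeep)
  }
  xt <- nn_input(model, train)
  xv <- nn_input(model, val)
  yt <- scale_target(train$true_latency, model$prep)
  yv <- scale_target(val$true_latency, model$prep)
  fit <- if (model$kind == "eegnet")
    eegnet_train_cpp(model$weights, xt, yt, xv, yv, cfg$max_epochs,
                     cfg$batch_size, cfg$lr, cfg$patience, cfg$seed,
                     cfg$lr_decay, cfg$lr_steps)
  else
    convlstm_train_cpp(model$weights, xt, yt, xv, yv, cfg$max_epochs,
                       cfg$batch_size, cfg$lr, cfg$patience, cfg$seed,
                       cfg$lr_decay, cfg$lr_steps)
  model$weights <- fit$weights
  model$history <- fit[c("train_loss", "val_loss", "best_epoch",
                         "best_val_loss")]
  model
}

#' Predict single-trial latencies with a trained network
#'
#' Inputs are preprocessed exactly as during training. Raw predictions are
#' reported as-is except for a clip (flagged in attribute `"clipped"`) to
#' the epoch span; predictions are deliberately NOT clipped to the search
#' window.
#'
#' @param model a trained `nn_model`.
#' @param epochs an `epochs_set`.
#' @return A latency table.
#' @export
predict_latencies <- function(model, epochs) {
  if (is.null(model$history)) warning("predicting with an untrained model")
  x <- nn_input(model, epochs)
  y <- if (model$kind == "eegnet") eegnet_predict_cpp(model$weights, x)
       else convlstm_predict_cpp(model$weights, x)
  lat <- unscale_target(as.numeric(y), model$prep)
  span <- c(epochs$t0, epochs$t0 + dim(epochs$data)[3L] / epochs$srate)
  clipped <- lat < span[1L] | lat > span[2L]
  lat <- pmin(pmax(lat, span[1L]), span[2L])
  structure(latency_table(epochs, lat, method = model$kind),
            clipped = which(clipped))
}
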