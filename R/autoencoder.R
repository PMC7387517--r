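#' Configuration of the convolutional autoencoder
#'
#' Architecture and training recipe of the 1D convolutional autoencoder used
#' for unsupervised representation learning on unlabelled typing inputs. The
#' encoder is a stack of same-padded conv layers (ReLU) with optional
#' max-pooling; the decoder mirrors it with nearest-neighbour upsampling and
#' a linear reconstruction layer. The default — three conv layers with
#' filters (32, 16, 8), kernels (5, 3, 3) and pooling after the first two —
#' compresses the 2 x 100 input to an 8 x 25 bottleneck (200 features).
#'
#' @param kernel_sizes Integer vector of kernel sizes, values in \{3, 5\}.
#' @param filters_per_layer Integer vector of filter counts, values in
#'   \[8, 32\].
#' @param pool_layers Logical mask: max-pool (factor 2) after each conv
#'   layer. The pooled length must stay even wherever pooling is applied.
#' @param epochs Training epochs (default 50).
#' @param batch_size Mini-batch size (default 64).
#' @param learning_rate RMSprop learning rate (default 1e-3).
#' @param train_fraction Fraction of inputs used for training; the rest is a
#'   held-out reconstruction set (default 0.8).
#' @param seed Integer seed controlling initialization, the train/test split
#'   and batch shuffling.
#' @return An object of class `autoencoder_config`.
#' @export
autoencoder_config <- function(kernel_sizes = c(5, 3, 3),
                               filters_per_layer = c(32, 16, 8),
                               pool_layers = c(TRUE, TRUE, FALSE),
                               epochs = 50, batch_size = 64,
                               learning_rate = 1e-3,
                               train_fraction = 0.8,
                               seed = 1L) {
  if (length(kernel_sizes) != length(filters_per_layer) ||
      length(kernel_sizes) != length(pool_layers)) {
    abort_bad_arg("kernel_sizes, filters_per_layer and pool_layers must have equal length.",
                  "fmikeys_config_error")
  }
  if (!all(kernel_sizes %in% c(3, 5))) {
    abort_bad_arg("kernel_sizes must be 3 or 5.", "fmikeys_config_error")
  }
  if (any(filters_per_layer < 8 | filters_per_layer > 32)) {
    abort_bad_arg("filters_per_layer must lie in [8, 32].", "fmikeys_config_error")
  }
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort_bad_arg("train_fraction must be in (0, 1).", "fmikeys_config_error")
  }
  len <- 100
  for (p in pool_layers) {
    if (p) {
      if (len %% 2 != 0) {
        abort_bad_arg("pooling mask would pool an odd sequence length.",
                      "fmikeys_config_error")
      }
      len <- len / 2
    }
  }
  structure(
    list(kernel_sizes = as.integer(kernel_sizes),
         filters_per_layer = as.integer(filters_per_layer),
         n_conv_layers = length(kernel_sizes),
         pool_layers = as.logical(pool_layers),
         bottleneck_length = as.integer(len),
         bottleneck_dim = as.integer(len * filters_per_layer[length(filters_per_layer)]),
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, optimizer = "rmsprop",
         train_fraction = train_fraction, seed = as.integer(seed)),
    class = "autoencoder_config"
  )
}

# Encoder/decoder layer lists for a given config (uninitialized).
build_autoencoder_layers <- function(config) {
  enc <- list()
  in_ch <- 2L
  for (i in seq_len(config$n_conv_layers)) {
    enc <- c(enc, list(layer_conv1d(in_ch, config$filters_per_layer[i],
                                    config$kernel_sizes[i])),
             list(layer_relu()))
    if (config$pool_layers[i]) enc <- c(enc, list(layer_maxpool()))
    in_ch <- config$filters_per_layer[i]
  }
  dec <- list()
  for (i in rev(seq_len(config$n_conv_layers))) {
    if (config$pool_layers[i]) dec <- c(dec, list(layer_upsample()))
    out_ch <- if (i > 1) config$filters_per_layer[i - 1] else 2L
    dec <- c(dec, list(layer_conv1d(in_ch, out_ch, config$kernel_sizes[i])))
    if (i > 1) dec <- c(dec, list(layer_relu()))
    in_ch <- out_ch
  }
  list(encoder = enc, decoder = dec)
}

#' Pretrain the convolutional autoencoder on unlabelled typing inputs
#'
#' Unsupervised representation learning: the network is trained to reproduce
#' its own 2 x 100 HT/FT input (identity target) by minimizing mean squared
#' reconstruction error with RMSprop, on a seeded train/held-out split of the
#' input pool. The learned encoder is then transferred to the supervised
#' fine-tuning stage.
#'
#' @param inputs A model-input tibble ([pad_to_inputs()] / [prepare_inputs()])
#'   or a plain list of 2 x 100 matrices. At least 2 inputs.
#' @param config An [autoencoder_config()].
#' @return An object of class `keystroke_autoencoder`: the trained encoder
#'   and decoder layers, the config, and a per-epoch `history` tibble with
#'   `train_mse` and `val_mse`.
#' @seealso [encode_inputs()], [finetune_loso()], [fit_hybrid()]
#' @export
pretrain_autoencoder <- function(inputs, config = autoencoder_config()) {
  stopifnot(inherits(config, "autoencoder_config"))
  X <- inputs_to_array(inputs)
  nB <- dim(X)[3]
  if (nB < 2) {
    abort_bad_arg("Need at least 2 inputs to split into train and held-out sets.",
                  "fmikeys_validation_error")
  }
  with_seed(derive_seed(config$seed, "pretrain"), {
    arch <- build_autoencoder_layers(config)
    layers <- nn_init(c(arch$encoder, arch$decoder))
    n_train <- max(1L, min(nB - 1L, round(config$train_fraction * nB)))
    ord <- sample.int(nB)
    tr <- ord[seq_len(n_train)]
    va <- ord[(n_train + 1L):nB]
    fit <- nn_train(layers, X[, , tr, drop = FALSE], X[, , tr, drop = FALSE],
                    epochs = config$epochs, batch_size = config$batch_size,
                    lr = config$learning_rate,
                    X_val = X[, , va, drop = FALSE],
                    Y_val = X[, , va, drop = FALSE])
    structure(
      list(layers = fit$layers,
           n_encoder_layers = length(arch$encoder),
           config = config, history = fit$history,
           n_train = n_train, n_val = length(va)),
      class = "keystroke_autoencoder"
    )
  })
}

encoder_layers <- function(autoencoder) {
  autoencoder$layers[seq_len(autoencoder$n_encoder_layers)]
}

#' Encode model inputs to bottleneck features
#'
#' @param autoencoder A trained [pretrain_autoencoder()] object.
#' @param inputs Model-input tibble or list of 2 x 100 matrices.
#' @return A numeric matrix, one row per input, one column per bottleneck
#'   feature.
#' @export
encode_inputs <- function(autoencoder, inputs) {
  stopifnot(inherits(autoencoder, "keystroke_autoencoder"))
  encode_features(encoder_layers(autoencoder), inputs)
}

#' Reconstruct inputs through the full autoencoder
#'
#' @inheritParams encode_inputs
#' @return A list of reconstructed 2 x 100 matrices.
#' @export
reconstruct_inputs <- function(autoencoder, inputs) {
  stopifnot(inherits(autoencoder, "keystroke_autoencoder"))
  X <- inputs_to_array(inputs)
  Y <- nn_forward(autoencoder$layers, X, want_cache = FALSE)$out
  lapply(seq_len(dim(Y)[3]), function(i) {
    m <- Y[, , i]
    rownames(m) <- c("ht", "ft")
    m
  })
}

#' @export
print.keystroke_autoencoder <- function(x, ...) {
  cat("<keystroke_autoencoder>\n")
  cat(sprintf("  conv layers: %s (kernels %s)\n",
              paste(x$config$filters_per_layer, collapse = "-"),
              paste(x$config$kernel_sizes, collapse = "-")))
  cat(sprintf("  bottleneck: %d x %d (%d features)\n",
              x$config$filters_per_layer[x$config$n_conv_layers],
              x$config$bottleneck_length, x$config$bottleneck_dim))
  cat(sprintf("  trained %d epochs on %d inputs; held-out MSE %.5f\n",
              x$config$epochs, x$n_train,
              utils::tail(x$history$val_mse, 1)))
  invisible(x)
}

#' @export
tidy.keystroke_autoencoder <- function(x, ...) x$history

#' @export
glance.keystroke_autoencoder <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train, n_val = x$n_val,
    epochs = x$config$epochs,
    final_train_mse = utils::tail(x$history$train_mse, 1),
    final_val_mse = utils::tail(x$history$val_mse, 1),
    bottleneck_dim = x$config$bottleneck_dim
  )
}
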