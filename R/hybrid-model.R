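#' Configuration of the supervised fine-tuning stage
#'
#' After representation learning, a two-layer fully-connected head (one
#' rectified hidden layer, one linear scalar output) is attached to the
#' pretrained encoder and the assembly is trained to regress one UPDRS
#' Part III single-item score (22: rigidity, 23: alternate finger tapping,
#' 31: body brady/hypokinesia) by mean squared error under RMSprop.
#'
#' `n_frozen_conv_layers` selects how much of the pretrained encoder is kept
#' fixed: the package default freezes all conv layers (pure feature-extraction
#' transfer, which also lets leave-one-subject-out runs reuse encoder features
#' across folds); `0` fine-tunes end-to-end. Any intermediate depth is
#' allowed — it is a searched hyperparameter, not a fixed design.
#'
#' @param target_item Which clinical item the head regresses: 22, 23 or 31.
#' @param head_nodes Hidden-layer width, typically one of 10/20/50/100
#'   (default 50).
#' @param n_frozen_conv_layers Number of leading conv layers kept frozen
#'   during fine-tuning; `NULL` (default) freezes all of them.
#' @param epochs Fine-tuning epochs (default 50).
#' @param batch_size Mini-batch size (default 32).
#' @param learning_rate RMSprop learning rate (default 1e-3).
#' @param seed Integer seed (weight init and batch shuffling; sub-streams per
#'   cross-validation fold).
#' @return An object of class `finetune_config`.
#' @export
finetune_config <- function(target_item, head_nodes = 50,
                            n_frozen_conv_layers = NULL,
                            epochs = 50, batch_size = 32,
                            learning_rate = 1e-3, seed = 1L) {
  if (missing(target_item) || !target_item %in% c(22, 23, 31)) {
    abort_bad_arg("`target_item` must be one of 22, 23, 31.", "fmikeys_config_error")
  }
  stopifnot_scalar_number(head_nodes, "head_nodes")
  structure(
    list(target_item = as.integer(target_item),
         head_nodes = as.integer(head_nodes),
         n_frozen_conv_layers = n_frozen_conv_layers,
         epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         learning_rate = learning_rate, seed = as.integer(seed)),
    class = "finetune_config"
  )
}

index_name_for_item <- function(item) {
  c(`22` = "dRSi", `23` = "dAFSi", `31` = "dBSi")[[as.character(item)]]
}

# Resolve the encoder argument: a trained autoencoder is transferred as-is;
# an autoencoder_config builds a randomly initialized encoder (the
# no-pretraining baseline), which is then necessarily trained end-to-end.
resolve_encoder <- function(encoder, seed) {
  if (inherits(encoder, "keystroke_autoencoder")) {
    return(list(layers = encoder_layers(encoder), config = encoder$config,
                pretrained = TRUE))
  }
  if (inherits(encoder, "autoencoder_config")) {
    arch <- build_autoencoder_layers(encoder)
    layers <- with_seed(derive_seed(seed, "rand_encoder"), nn_init(arch$encoder))
    return(list(layers = layers, config = encoder, pretrained = FALSE))
  }
  abort_bad_arg("`encoder` must be a trained autoencoder or an autoencoder_config.",
                "fmikeys_config_error")
}

n_frozen_resolved <- function(config, enc) {
  n_conv <- enc$config$n_conv_layers
  nf <- config$n_frozen_conv_layers
  if (is.null(nf)) nf <- n_conv
  nf <- as.integer(nf)
  if (nf < 0 || nf > n_conv) {
    abort_bad_arg("`n_frozen_conv_layers` outside the encoder depth.",
                  "fmikeys_config_error")
  }
  if (!enc$pretrained && nf > 0) nf <- 0L  # nothing worth freezing
  nf
}

head_layers <- function(in_dim, nodes) {
  list(layer_dense(in_dim, nodes), layer_relu(), layer_dense(nodes, 1L))
}

# Train one severity regressor. Fast path: all conv layers frozen -> the head
# is trained on precomputed bottleneck features (`feat`, inputs x features).
# Otherwise joint training through the (partially frozen) encoder on the raw
# (2, 100, B) array.
train_severity_model <- function(enc, config, X = NULL, feat = NULL, y, seed) {
  nf <- n_frozen_resolved(config, enc)
  n_conv <- enc$config$n_conv_layers
  with_seed(seed, {
    head <- nn_init(head_layers(enc$config$bottleneck_dim, config$head_nodes))
    if (nf == n_conv) {
      fit <- nn_train(head, t(feat), matrix(y, 1L), epochs = config$epochs,
                      batch_size = config$batch_size, lr = config$learning_rate)
      trained_head <- fit$layers
      enc_layers <- lapply(enc$layers, function(l) {
        if (!is.null(l$W)) l$trainable <- FALSE
        l
      })
      full <- c(enc_layers, list(layer_flatten()), trained_head)
    } else {
      conv_seen <- 0L
      enc_layers <- lapply(enc$layers, function(l) {
        if (l$type == "conv1d") {
          conv_seen <<- conv_seen + 1L
          l$trainable <- conv_seen > nf  # leading nf conv layers stay frozen
        }
        l
      })
      full <- c(enc_layers, list(layer_flatten()), head)
      fit <- nn_train(full, X, matrix(y, 1L), epochs = config$epochs,
                      batch_size = config$batch_size, lr = config$learning_rate)
      full <- fit$layers
    }
    list(layers = full, history = fit$history)
  })
}

predict_layers <- function(layers, X) {
  as.numeric(nn_forward(layers, X, want_cache = FALSE)$out)
}

join_scores <- function(inputs, manifest, target_item) {
  col <- paste0("updrs_", target_item)
  if (!col %in% names(manifest)) {
    abort_bad_arg(sprintf("Manifest lacks the `%s` column required for item %d.",
                          col, target_item),
                  "fmikeys_validation_error")
  }
  scores <- manifest[, c("subject_id", col)]
  names(scores)[2] <- "score"
  out <- dplyr::left_join(inputs, scores, by = "subject_id")
  dropped <- unique(out$subject_id[is.na(out$score)])
  if (length(dropped)) {
    warning(sprintf("Excluding %d subject(s) without a score for item %d: %s",
                    length(dropped), target_item, paste(dropped, collapse = ", ")),
            call. = FALSE)
    out <- out[!is.na(out$score), , drop = FALSE]
  }
  if (nrow(out) == 0) {
    abort_bad_arg("No labelled inputs left after score join.", "fmikeys_validation_error")
  }
  out
}

#' Fit one hybrid severity model on a full labelled cohort
#'
#' Attaches the fully-connected head to the (pretrained) encoder and trains
#' it on every labelled input. Used for deployment-style prediction,
#' saliency maps and ON/OFF analysis; for unbiased evaluation use
#' [finetune_loso()].
#'
#' @param inputs A model-input tibble ([prepare_inputs()]).
#' @param manifest A manifest tibble with `subject_id` and the
#'   `updrs_<item>` column for the target item.
#' @param encoder A trained [pretrain_autoencoder()] object, or an
#'   [autoencoder_config()] for a no-pretraining (randomly initialized,
#'   end-to-end trained) model.
#' @param config A [finetune_config()].
#' @return An object of class `fmi_hybrid` holding the full differentiable
#'   layer stack, the configs and the training history.
#' @export
fit_hybrid <- function(inputs, manifest, encoder, config) {
  stopifnot(inherits(config, "finetune_config"))
  enc <- resolve_encoder(encoder, config$seed)
  labelled <- join_scores(inputs, manifest, config$target_item)
  nf <- n_frozen_resolved(config, enc)
  feat <- NULL
  X <- NULL
  if (nf == enc$config$n_conv_layers) {
    feat <- encode_features(enc$layers, labelled$input)
  } else {
    X <- inputs_to_array(labelled$input)
  }
  fit <- train_severity_model(enc, config, X = X, feat = feat,
                              y = labelled$score,
                              seed = derive_seed(config$seed, "fit", config$target_item))
  structure(
    list(layers = fit$layers, history = fit$history,
         target_item = config$target_item,
         index_name = index_name_for_item(config$target_item),
         config = config, encoder_config = enc$config,
         pretrained = enc$pretrained, n_frozen = nf,
         n_inputs = nrow(labelled)),
    class = "fmi_hybrid"
  )
}

# Chunked encoder forward pass (keeps the im2col buffers bounded on large
# input collections).
encode_features <- function(enc_layers, inputs, chunk = 512L) {
  X <- inputs_to_array(inputs)
  nB <- dim(X)[3]
  starts <- seq(1L, nB, by = chunk)
  blocks <- lapply(starts, function(s) {
    idx <- s:min(s + chunk - 1L, nB)
    Z <- nn_forward(enc_layers, X[, , idx, drop = FALSE], want_cache = FALSE)$out
    d <- dim(Z)
    t(matrix(Z, d[1] * d[2], d[3]))
  })
  do.call(rbind, blocks)
}

#' Predict per-input severity with a fitted hybrid model
#'
#' @param object An `fmi_hybrid` model.
#' @param inputs A model-input tibble or list of 2 x 100 matrices.
#' @param ... Unused.
#' @return If `inputs` is a tibble, the tibble with a `prediction` column;
#'   otherwise a numeric vector.
#' @export
predict.fmi_hybrid <- function(object, inputs, ...) {
  pred <- predict_layers(object$layers, inputs_to_array(inputs))
  if (is.data.frame(inputs)) {
    inputs$prediction <- pred
    inputs$input <- NULL
    return(tibble::as_tibble(inputs))
  }
  pred
}

#' @export
print.fmi_hybrid <- function(x, ...) {
  cat(sprintf("<fmi_hybrid> %s (UPDRS item %d)\n", x$index_name, x$target_item))
  cat(sprintf("  encoder: %s, %d/%d conv layers frozen; head %d nodes\n",
              if (x$pretrained) "pretrained" else "random init",
              x$n_frozen, x$encoder_config$n_conv_layers, x$config$head_nodes))
  cat(sprintf("  trained on %d inputs, final MSE %.4f\n",
              x$n_inputs, utils::tail(x$history$train_mse, 1)))
  invisible(x)
}

#' Leave-one-subject-out fine-tuning
#'
#' The core evaluation protocol of the fine-tuning stage: for each subject, a
#' severity regressor is trained on all other subjects' inputs and predicts
#' the held-out subject's sessions, so every prediction is out-of-fold and no
#' subject's data ever reaches the model that scores it.
#'
#' @inheritParams fit_hybrid
#' @return An object of class `fmi_loso` with
#'   * `predictions`: tibble `subject_id`, `session_id`, `segment`,
#'     `start_time`, `fold`, `prediction`, `score`;
#'   * `folds`: tibble `fold`, `held_out`, `n_train`, `n_test`;
#'   plus the configs. Subjects without valid inputs or scores are excluded
#'   with a warning.
#' @export
finetune_loso <- function(inputs, manifest, encoder, config) {
  stopifnot(inherits(config, "finetune_config"))
  enc <- resolve_encoder(encoder, config$seed)
  labelled <- join_scores(inputs, manifest, config$target_item)
  subjects <- unique(labelled$subject_id)
  if (length(subjects) < 2) {
    abort_bad_arg("LOSO needs at least 2 subjects.", "fmikeys_validation_error")
  }
  nf <- n_frozen_resolved(config, enc)
  frozen_all <- nf == enc$config$n_conv_layers
  feat <- if (frozen_all) encode_features(enc$layers, labelled$input) else NULL
  X <- if (!frozen_all) inputs_to_array(labelled$input) else NULL

  preds <- vector("list", length(subjects))
  folds <- vector("list", length(subjects))
  for (k in seq_along(subjects)) {
    ho <- labelled$subject_id == subjects[k]
    fit <- train_severity_model(
      enc, config,
      X = if (!frozen_all) X[, , !ho, drop = FALSE],
      feat = if (frozen_all) feat[!ho, , drop = FALSE],
      y = labelled$score[!ho],
      seed = derive_seed(config$seed, "fold", k)
    )
    p <- if (frozen_all) {
      # head applied to precomputed features: skip the frozen conv stack
      nh <- 3L  # dense, relu, dense
      head <- fit$layers[(length(fit$layers) - nh + 1L):length(fit$layers)]
      predict_layers(head, t(feat[ho, , drop = FALSE]))
    } else {
      predict_layers(fit$layers, X[, , ho, drop = FALSE])
    }
    preds[[k]] <- tibble::tibble(
      subject_id = subjects[k],
      session_id = labelled$session_id[ho],
      segment = labelled$segment[ho],
      start_time = labelled$start_time[ho],
      fold = k,
      prediction = p,
      score = labelled$score[ho]
    )
    folds[[k]] <- tibble::tibble(fold = k, held_out = subjects[k],
                                 n_train = sum(!ho), n_test = sum(ho))
  }
  structure(
    list(predictions = dplyr::bind_rows(preds),
         folds = dplyr::bind_rows(folds),
         target_item = config$target_item,
         index_name = index_name_for_item(config$target_item),
         config = config, encoder_config = enc$config,
         pretrained = enc$pretrained, n_frozen = nf),
    class = "fmi_loso"
  )
}

#' @export
print.fmi_loso <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<fmi_loso> %s (item %d): %d folds, %d predictions\n",
              x$index_name, x$target_item, g$n_folds, nrow(x$predictions)))
  cat(sprintf("  subject-level Pearson r vs item score: %.3f\n", g$pearson_r))
  invisible(x)
}

#' @export
tidy.fmi_loso <- function(x, ...) x$predictions

#' @export
glance.fmi_loso <- function(x, ...) {
  subj <- dplyr::summarise(dplyr::group_by(x$predictions, .data$subject_id),
                           estimate = mean(.data$prediction),
                           score = .data$score[1], .groups = "drop")
  r <- if (stats::sd(subj$estimate) > 0 && stats::sd(subj$score) > 0) {
    stats::cor(subj$estimate, subj$score)
  } else {
    NA_real_
  }
  tibble::tibble(n_folds = nrow(x$folds),
                 n_subjects = nrow(subj),
                 n_predictions = nrow(x$predictions),
                 pearson_r = r,
                 pretrained = x$pretrained,
                 target_item = x$target_item)
}
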