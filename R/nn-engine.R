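# Minimal 1D neural-network engine.
#
# Activations for a batch are stored as arrays of dim (channels, length,
# batch); dense layers operate on (features, batch) matrices. Convolutions
# are im2col + BLAS matrix products; gradients are exact backprop. The only
# optimizer is RMSprop (the one the training recipe calls for). Everything is
# driven by R's RNG so a seed fixes initialization and batch order.

layer_conv1d <- function(in_ch, out_ch, kernel) {
  if (kernel %% 2 == 0) stop("conv1d kernels must be odd (same-padding).")
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, k = kernel,
       trainable = TRUE)
}
layer_relu <- function() list(type = "relu")
layer_maxpool <- function() list(type = "maxpool")
layer_upsample <- function() list(type = "upsample")
layer_flatten <- function() list(type = "flatten")
layer_dense <- function(in_dim, out_dim) {
  list(type = "dense", in_dim = in_dim, out_dim = out_dim, trainable = TRUE)
}

# He-normal initialization of all parameterized layers, in layer order, under
# the current RNG state.
nn_init <- function(layers) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv1d") {
      fan_in <- l$in_ch * l$k
      layers[[i]]$W <- matrix(stats::rnorm(l$out_ch * fan_in, 0, sqrt(2 / fan_in)),
                              l$out_ch, fan_in)
      layers[[i]]$b <- rep(0, l$out_ch)
    } else if (l$type == "dense") {
      layers[[i]]$W <- matrix(stats::rnorm(l$out_dim * l$in_dim, 0, sqrt(2 / l$in_dim)),
                              l$out_dim, l$in_dim)
      layers[[i]]$b <- rep(0, l$out_dim)
    }
  }
  layers
}

conv1d_fwd <- function(l, X) {
  list(out = cpp_conv1d_fwd(X, l$W, l$b, l$k), cache = list(X = X))
}

conv1d_bwd <- function(l, cache, dY) {
  cpp_conv1d_bwd(cache$X, l$W, dY, l$k)
}

nn_forward <- function(layers, X, want_cache = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$type == "conv1d") {
      r <- conv1d_fwd(l, X)
      X <- r$out
      caches[[i]] <- r$cache
    } else if (l$type == "relu") {
      mask <- X > 0
      X <- X * mask
      caches[[i]] <- list(mask = mask)
    } else if (l$type == "maxpool") {
      d <- dim(X)
      if (d[2] %% 2L != 0L) stop("maxpool requires an even sequence length.")
      X1 <- X[, seq(1L, d[2], 2L), , drop = FALSE]
      X2 <- X[, seq(2L, d[2], 2L), , drop = FALSE]
      mask <- X1 >= X2
      X <- pmax(X1, X2)
      caches[[i]] <- list(mask = mask, d = d)
    } else if (l$type == "upsample") {
      d <- dim(X)
      Y <- array(0, c(d[1], 2L * d[2], d[3]))
      Y[, seq(1L, 2L * d[2], 2L), ] <- X
      Y[, seq(2L, 2L * d[2], 2L), ] <- X
      caches[[i]] <- list(d = d)
      X <- Y
    } else if (l$type == "flatten") {
      d <- dim(X)
      caches[[i]] <- list(d = d)
      X <- matrix(X, d[1] * d[2], d[3])
    } else if (l$type == "dense") {
      caches[[i]] <- list(Xin = X)
      X <- l$W %*% X + l$b
    }
    if (!want_cache) caches[[i]] <- NULL
  }
  list(out = X, caches = caches)
}

# Backward pass; returns parameter gradients (NULL for parameterless layers)
# and the gradient with respect to the network input.
nn_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  dX <- dOut
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    c_ <- caches[[i]]
    if (l$type == "conv1d") {
      r <- conv1d_bwd(l, c_, dX)
      grads[[i]] <- list(dW = r$dW, db = r$db)
      dX <- r$dX
    } else if (l$type == "relu") {
      dX <- dX * c_$mask
    } else if (l$type == "maxpool") {
      d <- c_$d
      dFull <- array(0, d)
      dFull[, seq(1L, d[2], 2L), ] <- dX * c_$mask
      dFull[, seq(2L, d[2], 2L), ] <- dX * !c_$mask
      dX <- dFull
    } else if (l$type == "upsample") {
      d2 <- dim(dX)
      dX <- dX[, seq(1L, d2[2], 2L), , drop = FALSE] +
        dX[, seq(2L, d2[2], 2L), , drop = FALSE]
    } else if (l$type == "flatten") {
      dX <- array(dX, c_$d)
    } else if (l$type == "dense") {
      grads[[i]] <- list(dW = dX %*% t(c_$Xin), db = rowSums(dX))
      dX <- crossprod(l$W, dX)
    }
  }
  list(grads = grads, dX = dX)
}

rmsprop_state <- function(layers) {
  lapply(layers, function(l) {
    if (!is.null(l$W)) list(W = l$W * 0, b = l$b * 0) else NULL
  })
}

rmsprop_step <- function(layers, grads, state, lr, rho = 0.9, eps = 1e-8) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (is.null(l$W) || !isTRUE(l$trainable) || is.null(grads[[i]])) next
    state[[i]]$W <- rho * state[[i]]$W + (1 - rho) * grads[[i]]$dW^2
    state[[i]]$b <- rho * state[[i]]$b + (1 - rho) * grads[[i]]$db^2
    layers[[i]]$W <- l$W - lr * grads[[i]]$dW / (sqrt(state[[i]]$W) + eps)
    layers[[i]]$b <- l$b - lr * grads[[i]]$db / (sqrt(state[[i]]$b) + eps)
  }
  list(layers = layers, state = state)
}

batch_mse <- function(pred, target) mean((pred - target)^2)

# Mini-batch RMSprop training against mean-squared-error. `X` is either a
# (C, L, B) array (conv front end) or a (features, B) matrix (dense-only
# nets); `Y` likewise. Batch order reshuffles each epoch under the current
# RNG stream.
nn_train <- function(layers, X, Y, epochs, batch_size, lr,
                     X_val = NULL, Y_val = NULL) {
  ndim <- length(dim(X))
  nB <- dim(X)[ndim]
  take <- function(A, idx) {
    if (length(dim(A)) == 3L) A[, , idx, drop = FALSE] else A[, idx, drop = FALSE]
  }
  state <- rmsprop_state(layers)
  history <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(nB)
    starts <- seq(1L, nB, by = batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, nB)]
      xb <- take(X, idx)
      yb <- take(Y, idx)
      fwd <- nn_forward(layers, xb)
      dOut <- 2 * (fwd$out - yb) / length(yb)
      bwd <- nn_backward(layers, fwd$caches, dOut)
      upd <- rmsprop_step(layers, bwd$grads, state, lr)
      layers <- upd$layers
      state <- upd$state
      ep_loss <- ep_loss + batch_mse(fwd$out, yb) * length(idx)
    }
    val <- NA_real_
    if (!is.null(X_val)) {
      val <- batch_mse(nn_forward(layers, X_val, want_cache = FALSE)$out, Y_val)
    }
    history[[ep]] <- tibble::tibble(epoch = ep, train_mse = ep_loss / nB,
                                    val_mse = val)
  }
  list(layers = layers, history = dplyr::bind_rows(history))
}

# Stack a list of 2 x 100 input matrices into a (2, 100, B) array.
inputs_to_array <- function(inputs) {
  if (is.data.frame(inputs)) inputs <- inputs$input
  if (!length(inputs)) stop("no model inputs supplied.")
  array(unlist(inputs, use.names = FALSE), c(dim(inputs[[1]]), length(inputs)))
}
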