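#' 1D-CNN regression configuration
#'
#' Configuration of the one-dimensional convolutional network that maps a
#' spectrum to one nutrient value. The architecture follows the study
#' design: a Gaussian input-noise layer (sd 0.01, training only), two 1-D
#' convolution layers with ReLU, a flatten step, dropout (rate 0.045,
#' training only), a ReLU dense layer and a single linear output neuron.
#' Training minimizes the Huber loss with the Adadelta optimizer over
#' full-batch updates for `epochs` epochs.
#'
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   input during training (0 disables it).
#' @param conv_layers List of `c(filters, kernel, stride)` per
#'   convolution layer.
#' @param dropout_rate Dropout rate after flattening (training only).
#' @param dense_units Width of the penultimate dense layer.
#' @param huber_delta Transition point of the Huber loss.
#' @param epochs Training epochs.
#' @param rho,epsilon,adadelta_lr Adadelta decay, stabilizer and step
#'   scale (canonical defaults).
#' @param seed Integer seed for initialization, noise and dropout.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(noise_sd = 0.01,
                       conv_layers = list(c(32, 7, 1), c(16, 5, 1)),
                       dropout_rate = 0.045, dense_units = 64,
                       huber_delta = 1.0, epochs = 800,
                       rho = 0.95, epsilon = 1e-6, adadelta_lr = 1.0,
                       seed = 1L) {
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (dropout_rate < 0 || dropout_rate >= 1) abort("`dropout_rate` must be in [0, 1).")
  epochs <- assert_count(epochs, "epochs", min = 1L)
  structure(list(noise_sd = noise_sd, conv_layers = conv_layers,
                 dropout_rate = dropout_rate,
                 dense_units = assert_count(dense_units, "dense_units", min = 1L),
                 huber_delta = huber_delta, epochs = epochs,
                 rho = rho, epsilon = epsilon, adadelta_lr = adadelta_lr,
                 seed = as.integer(seed)),
            class = "cnn_config")
}

# ---- 1-D convolution as k shifted matrix products ----------------------
# An activation with L positions and C channels is kept as an n x (L*C)
# matrix in position-fastest order (column (c-1)*L + l), i.e. a flattened
# (n, L, C) array. A kernel of width k is stored as k (C_in x C_out)
# matrices; a convolution is then k shifted dense products, and the column
# indices of each shift are precomputed once per layer at init time.

conv_cols <- function(L, Cin, k, stride) {
  Lout <- (L - k) %/% stride + 1L
  if (Lout < 1L) abort("Input too short for this kernel/stride.")
  lapply(seq_len(k), function(j) {
    as.vector(outer(seq.int(j, by = stride, length.out = Lout),
                    (seq_len(Cin) - 1L) * L, `+`))
  })
}

conv1d_forward <- function(Amat, cv) {
  n <- nrow(Amat)
  Cin <- nrow(cv$W[[1L]]); Cout <- ncol(cv$W[[1L]])
  Lout <- cv$Lout
  Zmat <- matrix(rep(cv$b, each = n * Lout), n * Lout, Cout)
  for (j in seq_along(cv$W)) {
    Xs <- Amat[, cv$cols[[j]], drop = FALSE]
    dim(Xs) <- c(n * Lout, Cin)
    Zmat <- Zmat + Xs %*% cv$W[[j]]
  }
  dim(Zmat) <- c(n, Lout * Cout)
  Zmat
}

conv1d_backward <- function(Amat, cv, dZ) {
  n <- nrow(Amat)
  Cin <- nrow(cv$W[[1L]]); Cout <- ncol(cv$W[[1L]])
  Lout <- cv$Lout
  dZmat <- dZ; dim(dZmat) <- c(n * Lout, Cout)
  dW <- vector("list", length(cv$W))
  dA <- matrix(0, n, ncol(Amat))
  for (j in seq_along(cv$W)) {
    Xs <- Amat[, cv$cols[[j]], drop = FALSE]
    dim(Xs) <- c(n * Lout, Cin)
    dW[[j]] <- crossprod(Xs, dZmat)
    dXs <- tcrossprod(dZmat, cv$W[[j]])
    dim(dXs) <- c(n, Lout * Cin)
    dA[, cv$cols[[j]]] <- dA[, cv$cols[[j]], drop = FALSE] + dXs
  }
  list(dW = dW, db = colSums(dZmat), dA = dA)
}

glorot <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  runif(n, -lim, lim)
}

cnn_init <- function(n_bands, cfg) {
  Cin <- 1L; L <- n_bands
  convs <- vector("list", length(cfg$conv_layers))
  for (i in seq_along(cfg$conv_layers)) {
    spec <- cfg$conv_layers[[i]]
    Cout <- as.integer(spec[1L]); k <- as.integer(spec[2L]); stride <- as.integer(spec[3L])
    W <- lapply(seq_len(k), function(j) {
      matrix(glorot(k * Cin, Cout, Cin * Cout), Cin, Cout)
    })
    cols <- conv_cols(L, Cin, k, stride)
    Lout <- (L - k) %/% stride + 1L
    convs[[i]] <- list(W = W, b = rep(0, Cout), stride = stride, k = k,
                       cols = cols, Lout = Lout)
    L <- Lout
    Cin <- Cout
  }
  flat <- L * Cin
  list(convs = convs,
       dense1 = list(W = matrix(glorot(flat, cfg$dense_units, flat * cfg$dense_units),
                                flat, cfg$dense_units),
                     b = rep(0, cfg$dense_units)),
       dense2 = list(W = matrix(glorot(cfg$dense_units, 1L, cfg$dense_units),
                                cfg$dense_units, 1L),
                     b = 0),
       flat = flat, n_bands = n_bands)
}

cnn_forward <- function(net, X, cfg, training = FALSE) {
  n <- nrow(X)
  A <- X
  if (training && cfg$noise_sd > 0) {
    A <- A + matrix(rnorm(length(A), sd = cfg$noise_sd), nrow(A), ncol(A))
  }
  cache <- list(A0 = A)
  for (i in seq_along(net$convs)) {
    cv <- net$convs[[i]]
    Z <- conv1d_forward(A, cv)
    A <- Z * (Z > 0)
    cache[[paste0("Z", i)]] <- Z
    cache[[paste0("A", i)]] <- A
  }
  flatA <- A
  drop_mask <- NULL
  if (training && cfg$dropout_rate > 0) {
    drop_mask <- matrix(runif(length(flatA)) >= cfg$dropout_rate,
                        n, net$flat) / (1 - cfg$dropout_rate)
    flatA <- flatA * drop_mask
  }
  H <- flatA %*% net$dense1$W
  H <- sweep(H, 2L, net$dense1$b, "+")
  Hr <- H * (H > 0)
  pred <- as.numeric(Hr %*% net$dense2$W + net$dense2$b)
  cache$flatA <- flatA; cache$drop_mask <- drop_mask
  cache$H <- H; cache$Hr <- Hr; cache$pred <- pred
  cache
}

huber_loss_grad <- function(pred, y, delta) {
  r <- pred - y
  a <- abs(r)
  quad <- a <= delta
  loss <- mean(ifelse(quad, 0.5 * r^2, delta * (a - 0.5 * delta)))
  grad <- ifelse(quad, r, delta * sign(r)) / length(y)
  list(loss = loss, grad = grad)
}

# Flat parameter bookkeeping: collect, update, restore. Parameters are
# addressed as a flat list of tensors to keep Adadelta generic.
cnn_params <- function(net) {
  out <- list()
  for (i in seq_along(net$convs)) {
    for (j in seq_along(net$convs[[i]]$W)) {
      out[[sprintf("c%d_W%d", i, j)]] <- net$convs[[i]]$W[[j]]
    }
    out[[sprintf("c%d_b", i)]] <- net$convs[[i]]$b
  }
  out$d1_W <- net$dense1$W; out$d1_b <- net$dense1$b
  out$d2_W <- net$dense2$W; out$d2_b <- net$dense2$b
  out
}

cnn_set_params <- function(net, params) {
  for (i in seq_along(net$convs)) {
    for (j in seq_along(net$convs[[i]]$W)) {
      net$convs[[i]]$W[[j]] <- params[[sprintf("c%d_W%d", i, j)]]
    }
    net$convs[[i]]$b <- params[[sprintf("c%d_b", i)]]
  }
  net$dense1$W <- params$d1_W; net$dense1$b <- params$d1_b
  net$dense2$W <- params$d2_W; net$dense2$b <- params$d2_b
  net
}

cnn_grads <- function(net, cache, dpred, cfg) {
  n <- length(dpred)
  g <- list()
  dHr <- matrix(dpred, n, 1L) %*% t(net$dense2$W)
  g$d2_W <- crossprod(cache$Hr, matrix(dpred, n, 1L))
  g$d2_b <- sum(dpred)
  dH <- dHr * (cache$H > 0)
  g$d1_W <- crossprod(cache$flatA, dH)
  g$d1_b <- colSums(dH)
  dflat <- tcrossprod(dH, net$dense1$W)
  if (!is.null(cache$drop_mask)) dflat <- dflat * cache$drop_mask
  dA <- dflat
  for (i in rev(seq_along(net$convs))) {
    cv <- net$convs[[i]]
    dZ <- dA * (cache[[paste0("Z", i)]] > 0)
    Aprev <- if (i == 1L) cache$A0 else cache[[paste0("A", i - 1L)]]
    bk <- conv1d_backward(Aprev, cv, dZ)
    for (j in seq_along(cv$W)) g[[sprintf("c%d_W%d", i, j)]] <- bk$dW[[j]]
    g[[sprintf("c%d_b", i)]] <- bk$db
    dA <- bk$dA
  }
  g
}

#' Train the 1D-CNN regressor
#'
#' Full-batch training with Adadelta on the Huber loss. The Gaussian
#' input noise and dropout are active only during training; prediction is
#' deterministic. With `divisor` given, labels are trained on their
#' scaled `(0, 1)` representation and predictions are returned in g/kg.
#'
#' By default (`standardize = TRUE`) inputs are z-scored per channel and
#' the (possibly divisor-scaled) target is z-scored at fit time, with the
#' scalers stored in the model and inverted at prediction. Between-sample
#' reflectance differences are tiny compared to the mean spectrum level,
#' so this fit-time standardization puts the informative variation on
#' unit scale and is what makes full-batch Adadelta training converge in
#' a practical number of epochs; it changes the optimization, not the
#' model family.
#'
#' @param spectra A spectra tibble, `joint_tbl` (its label column is
#'   ignored), or numeric matrix of training inputs.
#' @param labels Numeric training targets, one per row.
#' @param config A [cnn_config()].
#' @param divisor Optional label divisor: train on `labels / divisor`,
#'   predict on the original scale.
#' @param standardize Z-score inputs per channel and the target at fit
#'   time (default `TRUE`).
#' @return A `cnn_model` with the fitted weights, config and loss trace.
#' @export
train_regressor <- function(spectra, labels, config = cnn_config(), divisor = NULL,
                            standardize = TRUE) {
  X <- regressor_matrix(spectra)
  if (nrow(X) != length(labels)) abort("Row count of `spectra` must equal `length(labels)`.")
  if (nrow(X) < 2L) abort("Need at least 2 training samples.")
  y <- as.numeric(labels)
  if (!is.null(divisor)) y <- y / divisor
  scaler <- NULL
  if (standardize) {
    x_mu <- colMeans(X)
    x_sd <- apply(X, 2L, sd)
    x_sd[!is.finite(x_sd) | x_sd < 1e-12] <- 1
    y_mu <- mean(y)
    y_sd <- sd(y)
    if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
    scaler <- list(x_mu = x_mu, x_sd = x_sd, y_mu = y_mu, y_sd = y_sd)
    X <- sweep(sweep(X, 2L, x_mu), 2L, x_sd, "/")
    y <- (y - y_mu) / y_sd
  }
  cfg <- config
  with_seed(cfg$seed, {
    net <- cnn_init(ncol(X), cfg)
    state <- NULL
    loss_trace <- numeric(cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      cache <- cnn_forward(net, X, cfg, training = TRUE)
      hl <- huber_loss_grad(cache$pred, y, cfg$huber_delta)
      loss_trace[ep] <- hl$loss
      if (!is.finite(hl$loss)) abort(sprintf("Non-finite training loss at epoch %d.", ep))
      g <- cnn_grads(net, cache, hl$grad, cfg)
      params <- cnn_params(net)
      if (is.null(state)) {
        state <- lapply(params, function(p) list(Eg = p * 0, Ed = p * 0))
      }
      for (nm in names(params)) {
        s <- state[[nm]]
        s$Eg <- cfg$rho * s$Eg + (1 - cfg$rho) * g[[nm]]^2
        step <- -sqrt(s$Ed + cfg$epsilon) / sqrt(s$Eg + cfg$epsilon) * g[[nm]]
        s$Ed <- cfg$rho * s$Ed + (1 - cfg$rho) * step^2
        params[[nm]] <- params[[nm]] + cfg$adadelta_lr * step
        state[[nm]] <- s
      }
      net <- cnn_set_params(net, params)
    }
    structure(list(net = net, config = cfg, divisor = divisor,
                   scaler = scaler,
                   n_train = nrow(X), n_bands = ncol(X),
                   loss = tibble(epoch = seq_len(cfg$epochs), loss = loss_trace)),
              class = "cnn_model")
  })
}

regressor_matrix <- function(spectra) {
  if (is.matrix(spectra)) {
    storage.mode(spectra) <- "double"
    spectra
  } else if (inherits(spectra, "joint_tbl")) {
    spectra_matrix(split_joint(spectra)$spectra)
  } else {
    spectra_matrix(spectra)
  }
}

#' @describeIn train_regressor Predict nutrient values for new spectra;
#'   one prediction per row, stochastic layers disabled.
#' @param object A `cnn_model`.
#' @param newdata Spectra tibble or matrix with the training width.
#' @param ... Unused.
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  X <- regressor_matrix(newdata)
  if (ncol(X) != object$n_bands) {
    abort(sprintf("`newdata` has %d channels; model expects %d.", ncol(X), object$n_bands))
  }
  if (nrow(X) == 0L) return(numeric(0))
  if (!is.null(object$scaler)) {
    X <- sweep(sweep(X, 2L, object$scaler$x_mu), 2L, object$scaler$x_sd, "/")
  }
  pred <- cnn_forward(object$net, X, object$config, training = FALSE)$pred
  if (!is.null(object$scaler)) pred <- pred * object$scaler$y_sd + object$scaler$y_mu
  if (!is.null(object$divisor)) pred <- pred * object$divisor
  pred
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %d channels, %d conv layers, trained %d epochs (final loss %.4g)\n",
              x$n_bands, length(x$net$convs), x$config$epochs, tail(x$loss$loss, 1L)))
  invisible(x)
}

#' @describeIn train_regressor One-row fit summary.
#' @exportS3Method
glance.cnn_model <- function(x, ...) {
  tibble(n_train = x$n_train, n_bands = x$n_bands,
         epochs = x$config$epochs, final_loss = tail(x$loss$loss, 1L))
}

#' Regression accuracy metrics
#'
#' `rmse = sqrt(mean((Y - y)^2))` with predictions `Y` and observations
#' `y`. Two coefficients of determination are offered: the `standard`
#' definition `1 - SSE/SST` (default), and `paper_eq8`, the
#' regression-sum-of-squares ratio `sum((Y - ybar)^2) / sum((y - ybar)^2)`
#' sometimes printed in chemometrics work; the two agree for unbiased
#' least-squares predictions but differ for biased predictors.
#'
#' @param y_true Observed values.
#' @param y_pred Predicted values (same length).
#' @param variant `"standard"` or `"paper_eq8"`.
#' @return A one-row tibble: `r2`, `rmse`, `n`, `variant`.
#' @export
compute_metrics <- function(y_true, y_pred, variant = c("standard", "paper_eq8")) {
  variant <- match.arg(variant)
  if (length(y_true) != length(y_pred) || length(y_true) == 0L) {
    abort("`y_true` and `y_pred` must have equal, non-zero length.")
  }
  sst <- sum((y_true - mean(y_true))^2)
  if (sst <= 0) abort("`y_true` is constant; R^2 is undefined.")
  rmse <- sqrt(mean((y_pred - y_true)^2))
  r2 <- if (variant == "standard") {
    1 - sum((y_pred - y_true)^2) / sst
  } else {
    sum((y_pred - mean(y_true))^2) / sst
  }
  tibble(r2 = r2, rmse = rmse, n = length(y_true), variant = variant)
}
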