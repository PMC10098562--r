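#' GAN training configuration
#'
#' Hyperparameters for the least-squares GAN trained on joint
#' spectrum-plus-label vectors. Defaults follow the study conditions:
#' 2000 epochs, learning rate 2e-4, Adam for both networks, sigmoid
#' activations, mean-squared-error (least-squares) adversarial objectives,
#' and a set of 300 generated samples saved at every 100th epoch.
#'
#' The generator maps `noise_dim` standard-normal inputs through
#' `hidden_g` fully connected layers to the joint-vector width; the
#' discriminator mirrors it down to one unit. Sigmoid output layers keep
#' every generated entry inside (0, 1), matching the normalized joint
#' representation.
#'
#' @param epochs Total training epochs.
#' @param learning_rate Adam step size for both networks.
#' @param checkpoint_interval Save generated samples every this many epochs.
#' @param samples_per_checkpoint Rows generated at each checkpoint.
#' @param noise_dim Generator input dimension.
#' @param hidden_g,hidden_d Hidden layer widths.
#' @param hidden_activation `"sigmoid"` (default, as in the study design)
#'   or `"relu"` for the hidden layers; output layers are always sigmoid.
#' @param beta1,beta2 Adam momentum parameters (GAN-standard 0.5 / 0.999).
#' @param include_epoch0 Also store the untrained (pure-noise) checkpoint;
#'   excluded from default listings.
#' @param seed Integer seed controlling initialization, noise draws and
#'   checkpoint sampling.
#' @return A `gan_config` list.
#' @export
gan_config <- function(epochs = 2000, learning_rate = 2e-4,
                       checkpoint_interval = 100, samples_per_checkpoint = 300,
                       noise_dim = 100, hidden_g = c(256, 512),
                       hidden_d = c(512, 256),
                       hidden_activation = c("sigmoid", "relu"),
                       beta1 = 0.5, beta2 = 0.999,
                       include_epoch0 = FALSE, seed = 1L) {
  epochs <- assert_count(epochs, "epochs", min = 1L)
  checkpoint_interval <- assert_count(checkpoint_interval, "checkpoint_interval", min = 1L)
  samples_per_checkpoint <- assert_count(samples_per_checkpoint, "samples_per_checkpoint", min = 1L)
  if (epochs < checkpoint_interval) abort("`epochs` must be >= `checkpoint_interval`.")
  if (learning_rate <= 0) abort("`learning_rate` must be positive.")
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 checkpoint_interval = checkpoint_interval,
                 samples_per_checkpoint = samples_per_checkpoint,
                 noise_dim = assert_count(noise_dim, "noise_dim", min = 1L),
                 hidden_g = as.integer(hidden_g), hidden_d = as.integer(hidden_d),
                 hidden_activation = match.arg(hidden_activation),
                 beta1 = beta1, beta2 = beta2,
                 include_epoch0 = isTRUE(include_epoch0),
                 seed = as.integer(seed)),
            class = "gan_config")
}

# ---- minimal fully-connected network machinery -------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_init <- function(sizes, rng_scale = "glorot") {
  layers <- vector("list", length(sizes) - 1L)
  for (i in seq_along(layers)) {
    fan_in <- sizes[i]; fan_out <- sizes[i + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    layers[[i]] <- list(
      W = matrix(runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
      b = rep(0, fan_out))
  }
  layers
}

# Forward pass; hidden activation per `act`, output always sigmoid.
mlp_forward <- function(layers, X, act) {
  n_lay <- length(layers)
  as_list <- vector("list", n_lay + 1L)
  as_list[[1L]] <- X
  for (i in seq_len(n_lay)) {
    Z <- as_list[[i]] %*% layers[[i]]$W
    Z <- sweep(Z, 2L, layers[[i]]$b, "+")
    A <- if (i == n_lay || act == "sigmoid") sigmoid(Z) else pmax(Z, 0)
    as_list[[i + 1L]] <- A
  }
  as_list
}

# Backward pass given dL/d(output activation); returns per-layer grads and
# dL/d(input) so the generator can be chained through the discriminator.
mlp_backward <- function(layers, acts, dA_out, act) {
  n_lay <- length(layers)
  grads <- vector("list", n_lay)
  dA <- dA_out
  for (i in rev(seq_len(n_lay))) {
    A <- acts[[i + 1L]]
    dZ <- if (i == n_lay || act == "sigmoid") dA * A * (1 - A) else dA * (acts[[i + 1L]] > 0)
    grads[[i]] <- list(W = crossprod(acts[[i]], dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, layers[[i]]$W)
  }
  list(grads = grads, dX = dA)
}

adam_init <- function(layers) {
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(layers, grads, state, lr, beta1, beta2, t, eps = 1e-8) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mhatW <- s$mW / (1 - beta1^t); vhatW <- s$vW / (1 - beta2^t)
    mhatb <- s$mb / (1 - beta1^t); vhatb <- s$vb / (1 - beta2^t)
    layers[[i]]$W <- layers[[i]]$W - lr * mhatW / (sqrt(vhatW) + eps)
    layers[[i]]$b <- layers[[i]]$b - lr * mhatb / (sqrt(vhatb) + eps)
    state[[i]] <- s
  }
  list(layers = layers, state = state)
}

# ---- training ----------------------------------------------------------

#' Train a least-squares GAN on a joint table
#'
#' Trains generator and discriminator by alternating full-batch Adam
#' updates with least-squares objectives: the discriminator drives its
#' sigmoid output towards 1 on real rows and 0 on generated rows
#' (`mean((D(x)-1)^2) + mean(D(G(z))^2)`); the generator drives
#' `mean((D(G(z))-1)^2)` down. At every `checkpoint_interval` epochs a set
#' of `samples_per_checkpoint` joint vectors is generated and stored, so a
#' default run (2000 epochs, interval 100) yields 20 checkpoints of
#' 300 x (n_bands + 1) samples, each entry in (0, 1).
#'
#' @param joint A `joint_tbl` with at least 2 rows, entries in `[0, 1]`.
#' @param config A [gan_config()].
#' @return A `gan_archive`: list with `checkpoints` (named by epoch),
#'   `generator`, `config`, joint metadata, and per-epoch loss traces.
#' @export
train_gan <- function(joint, config = gan_config()) {
  mat <- joint_matrix(joint)
  if (nrow(mat) < 2L) abort("Training data must contain at least 2 samples.")
  if (any(mat < -1e-9 | mat > 1 + 1e-9)) abort("Joint entries must lie in [0, 1].")
  width <- ncol(mat)
  meta <- joint_meta(joint)
  cfg <- config
  act <- cfg$hidden_activation

  with_seed(cfg$seed, {
    G <- mlp_init(c(cfg$noise_dim, cfg$hidden_g, width))
    D <- mlp_init(c(width, cfg$hidden_d, 1L))
    sG <- adam_init(G); sD <- adam_init(D)
    n <- nrow(mat)
    checkpoints <- list()
    loss_d <- loss_g <- numeric(cfg$epochs)

    gen_batch <- function(m) {
      Z <- matrix(rnorm(m * cfg$noise_dim), m, cfg$noise_dim)
      mlp_forward(G, Z, act)
    }

    if (cfg$include_epoch0) {
      checkpoints[["0"]] <- gen_batch(cfg$samples_per_checkpoint)[[length(G) + 1L]]
    }

    for (ep in seq_len(cfg$epochs)) {
      ## discriminator step (generator held fixed)
      fake <- gen_batch(n)[[length(G) + 1L]]
      aR <- mlp_forward(D, mat, act)
      aF <- mlp_forward(D, fake, act)
      dR <- aR[[length(D) + 1L]]; dF <- aF[[length(D) + 1L]]
      loss_d[ep] <- mean((dR - 1)^2) + mean(dF^2)
      if (!is.finite(loss_d[ep])) abort(sprintf("Non-finite discriminator loss at epoch %d.", ep))
      gR <- mlp_backward(D, aR, 2 * (dR - 1) / n, act)$grads
      gF <- mlp_backward(D, aF, 2 * dF / n, act)$grads
      gD <- Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b), gR, gF)
      up <- adam_step(D, gD, sD, cfg$learning_rate, cfg$beta1, cfg$beta2, ep)
      D <- up$layers; sD <- up$state

      ## generator step (fresh noise, discriminator held fixed)
      aG <- gen_batch(n)
      fake <- aG[[length(G) + 1L]]
      aF <- mlp_forward(D, fake, act)
      dF <- aF[[length(D) + 1L]]
      loss_g[ep] <- mean((dF - 1)^2)
      if (!is.finite(loss_g[ep])) abort(sprintf("Non-finite generator loss at epoch %d.", ep))
      dFake <- mlp_backward(D, aF, 2 * (dF - 1) / n, act)$dX
      gG <- mlp_backward(G, aG, dFake, act)$grads
      up <- adam_step(G, gG, sG, cfg$learning_rate, cfg$beta1, cfg$beta2, ep)
      G <- up$layers; sG <- up$state

      if (ep %% cfg$checkpoint_interval == 0L) {
        checkpoints[[as.character(ep)]] <-
          gen_batch(cfg$samples_per_checkpoint)[[length(G) + 1L]]
      }
    }

    structure(list(checkpoints = checkpoints,
                   generator = list(layers = G, noise_dim = cfg$noise_dim,
                                    activation = act),
                   discriminator = D,
                   config = cfg,
                   nutrient = meta$nutrient, divisor = meta$divisor,
                   norm_params = meta$norm_params, wavelengths = meta$wavelengths,
                   width = width,
                   training_digest = digest_matrix(mat),
                   loss = tibble(epoch = seq_len(cfg$epochs),
                                 loss_d = loss_d, loss_g = loss_g)),
              class = "gan_archive")
  })
}

digest_matrix <- function(mat) {
  # cheap content fingerprint: dimensions plus a few stable moments
  sprintf("%dx%d:%.12e:%.12e", nrow(mat), ncol(mat), sum(mat), sum(mat^2))
}

#' List checkpoint epochs of a GAN archive
#'
#' Epoch 0 (the untrained generator), when stored, is excluded from the
#' default listing.
#'
#' @param archive A `gan_archive`.
#' @param include_epoch0 Include the epoch-0 checkpoint if present.
#' @return Integer vector of epochs, increasing.
#' @export
archive_epochs <- function(archive, include_epoch0 = FALSE) {
  ep <- sort(as.integer(names(archive$checkpoints)))
  if (!include_epoch0) ep <- ep[ep > 0L]
  ep
}

#' Extract one checkpoint as a joint table
#'
#' @param archive A `gan_archive`.
#' @param epoch Checkpoint epoch.
#' @return A `joint_tbl` of generated rows, carrying the training data's
#'   nutrient tag, divisor and normalization parameters.
#' @export
archive_checkpoint <- function(archive, epoch) {
  key <- as.character(epoch)
  if (!key %in% names(archive$checkpoints)) {
    abort(sprintf("No checkpoint at epoch %s.", key))
  }
  mat <- archive$checkpoints[[key]]
  checkpoint_to_joint(mat, archive, prefix = sprintf("gen_e%s_", key))
}

checkpoint_to_joint <- function(mat, archive, prefix = "gen_") {
  nb <- archive$width - 1L
  data <- as_tibble(as.data.frame(mat), .name_repair = "minimal")
  names(data) <- c(as.character(archive$wavelengths %||% seq_len(nb)), "label_scaled")
  data <- dplyr::bind_cols(tibble(sample_id = paste0(prefix, seq_len(nrow(mat)))), data)
  new_joint_tbl(data, nutrient = archive$nutrient, divisor = archive$divisor,
                norm_params = archive$norm_params, wavelengths = archive$wavelengths)
}

#' Sample joint vectors from a trained (or fresh) generator
#'
#' @param archive A `gan_archive` (its final generator state is used).
#' @param n Number of rows to generate (>= 0).
#' @param seed Integer seed; identical `(archive, seed)` give identical draws.
#' @return A `joint_tbl` with `n` rows, entries in (0, 1).
#' @export
generate_samples <- function(archive, n, seed = 1L) {
  if (length(n) != 1L || !is.finite(n) || n < 0 || n != trunc(n)) {
    abort("`n` must be a single non-negative integer.")
  }
  gen <- archive$generator
  mat <- with_seed(seed, {
    Z <- matrix(rnorm(n * gen$noise_dim), nrow = n, ncol = gen$noise_dim)
    mlp_forward(gen$layers, Z, gen$activation)[[length(gen$layers) + 1L]]
  })
  checkpoint_to_joint(mat, archive, prefix = "gen_")
}

#' Map generated joint rows back to physical units
#'
#' Inverts the preprocessing applied before GAN training: the last column
#' is multiplied by the label divisor to recover g/kg, and the spectral
#' block is inverse min-max normalized back to reflectance.
#'
#' @param joint A `joint_tbl` (e.g. from [archive_checkpoint()]).
#' @param norm_params,divisor Override the metadata carried by `joint`.
#' @return `list(spectra = , labels_g_per_kg = )`.
#' @export
unpack_generated <- function(joint, norm_params = NULL, divisor = NULL) {
  norm_params <- norm_params %||% attr(joint, "norm_params")
  divisor <- divisor %||% attr(joint, "divisor")
  if (is.null(norm_params) || is.null(divisor)) {
    abort("Normalization parameters and divisor are required to unpack.")
  }
  parts <- split_joint(joint)
  if (norm_params$scope == "per_spectrum" &&
      length(norm_params$min_value) != nrow(parts$spectra)) {
    abort("Per-spectrum normalization cannot be inverted for generated rows; use global scope.")
  }
  list(spectra = minmax_denormalize(parts$spectra, norm_params),
       labels_g_per_kg = unscale_labels(parts$labels, divisor = divisor))
}

#' Write / read a GAN archive directory
#'
#' One directory per run: `config.json`, `manifest.json` (nutrient,
#' divisor, normalization parameters, wavelengths, training digest) and
#' one `epoch_XXXX.csv` joint matrix per checkpoint. The generator weights
#' are stored in `generator.json` so sampling stays reproducible.
#'
#' @param archive A `gan_archive`.
#' @param dir Directory path.
#' @return `dir`, invisibly (writer); a `gan_archive` (reader).
#' @export
write_archive <- function(archive, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- archive$config
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(nutrient = archive$nutrient, divisor = archive$divisor,
                   norm_params = archive$norm_params,
                   wavelengths = archive$wavelengths,
                   width = archive$width,
                   training_digest = archive$training_digest,
                   epochs = as.integer(names(archive$checkpoints)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  gen <- archive$generator
  jsonlite::write_json(list(noise_dim = gen$noise_dim, activation = gen$activation,
                            layers = lapply(gen$layers, function(l) {
                              list(W = l$W, b = l$b)
                            })),
                       file.path(dir, "generator.json"), digits = NA, auto_unbox = TRUE)
  for (key in names(archive$checkpoints)) {
    mat <- archive$checkpoints[[key]]
    readr::write_csv(as_tibble(as.data.frame(mat), .name_repair = "minimal"),
                     file.path(dir, sprintf("epoch_%04d.csv", as.integer(key))))
  }
  readr::write_csv(archive$loss, file.path(dir, "loss.csv"))
  invisible(dir)
}

#' @rdname write_archive
#' @export
read_archive <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  genj <- jsonlite::read_json(file.path(dir, "generator.json"), simplifyVector = TRUE)
  layers <- lapply(seq_len(if (is.data.frame(genj$layers)) nrow(genj$layers) else length(genj$layers)),
                   function(i) {
                     l <- if (is.data.frame(genj$layers)) genj$layers[i, ] else genj$layers[[i]]
                     list(W = as.matrix(if (is.list(l$W)) do.call(rbind, lapply(l$W, unlist)) else l$W),
                          b = as.numeric(unlist(l$b)))
                   })
  checkpoints <- list()
  for (ep in manifest$epochs) {
    f <- file.path(dir, sprintf("epoch_%04d.csv", as.integer(ep)))
    checkpoints[[as.character(ep)]] <- as.matrix(
      readr::read_csv(f, show_col_types = FALSE))
  }
  loss_f <- file.path(dir, "loss.csv")
  structure(list(checkpoints = checkpoints,
                 generator = list(layers = layers, noise_dim = genj$noise_dim,
                                  activation = genj$activation),
                 config = cfg,
                 nutrient = manifest$nutrient, divisor = manifest$divisor,
                 norm_params = manifest$norm_params,
                 wavelengths = manifest$wavelengths,
                 width = manifest$width,
                 training_digest = manifest$training_digest,
                 loss = if (file.exists(loss_f)) readr::read_csv(loss_f, show_col_types = FALSE) else NULL),
            class = "gan_archive")
}

#' @export
print.gan_archive <- function(x, ...) {
  ep <- archive_epochs(x)
  cat(sprintf("<gan_archive> %s, width %d, %d checkpoints (epochs %s..%s)\n",
              x$nutrient %||% "untagged", x$width, length(ep),
              if (length(ep)) min(ep) else NA, if (length(ep)) max(ep) else NA))
  invisible(x)
}

#' @describeIn train_gan Per-checkpoint summary: epoch, rows, column-mean
#'   gap to the training data (`NA` when the training matrix digest no
#'   longer matches), and adversarial losses at that epoch.
#' @param x A `gan_archive`.
#' @param ... Unused.
#' @exportS3Method
tidy.gan_archive <- function(x, ...) {
  eps <- archive_epochs(x, include_epoch0 = TRUE)
  purrr::map_dfr(eps, function(ep) {
    mat <- x$checkpoints[[as.character(ep)]]
    tibble(epoch = ep, n = nrow(mat), width = ncol(mat),
           min = min(mat), max = max(mat),
           label_mean = mean(mat[, ncol(mat)]))
  })
}

#' @describeIn train_gan One-row overview of the run.
#' @exportS3Method
glance.gan_archive <- function(x, ...) {
  tibble(nutrient = x$nutrient %||% NA_character_, width = x$width,
         epochs = x$config$epochs, n_checkpoints = length(archive_epochs(x)),
         samples_per_checkpoint = x$config$samples_per_checkpoint,
         final_loss_d = tail(x$loss$loss_d, 1L),
         final_loss_g = tail(x$loss$loss_g, 1L))
}
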