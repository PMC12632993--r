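#' Encoder/training specification for the compression networks
#'
#' Collects the architecture and training configuration for
#' [train_autoencoder()] and [train_beta_vae()]. The networks are fully
#' connected: a hidden layer with GELU activations on the way in, a linear
#' (autoencoder) or Gaussian (VAE) bottleneck, and a mirrored decoder. The
#' defaults are sized for small parametric images; scale (input size,
#' latent width, epochs) is a configuration concern, not a code path.
#'
#' @param input_size image side in pixels (inputs are `input_size^2 * 3`
#'   values).
#' @param latent_dim bottleneck width (>= 1).
#' @param hidden hidden-layer width.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param loss `"mse"` (autoencoder) or `"bce"` (VAE distortion).
#' @param l1_latent optional L1 penalty weight on latent magnitudes (the
#'   sparse-VAE variant); 0 disables it.
#' @param holdout fraction of images held out to evaluate rate/distortion.
#' @return list of class `encoder_spec`.
#' @export
encoder_spec <- function(input_size = 16L, latent_dim = 16L, hidden = 64L,
                         epochs = 50L, batch_size = 16L, lr = 1e-3,
                         loss = c("mse", "bce"), l1_latent = 0,
                         holdout = 0.2) {
  structure(list(
    input_size = check_count(input_size, "input_size", min = 8L),
    latent_dim = check_count(latent_dim, "latent_dim"),
    hidden = check_count(hidden, "hidden"),
    epochs = check_count(epochs, "epochs"),
    batch_size = check_count(batch_size, "batch_size"),
    lr = lr, loss = match.arg(loss), l1_latent = l1_latent,
    holdout = holdout
  ), class = "encoder_spec")
}

spec_input_dim <- function(spec) spec$input_size^2 * 3L

check_images_for_spec <- function(images, spec) {
  x <- flatten_images(images)
  if (ncol(x) != spec_input_dim(spec)) {
    stop_rdmem(sprintf(
      "images provide %d values per item but the spec expects %d (%dx%dx3)",
      ncol(x), spec_input_dim(spec), spec$input_size, spec$input_size),
      class = "rdmem_configuration")
  }
  x
}

#' Train a dense autoencoder on an image set
#'
#' Minimizes mean squared reconstruction error with Adam. Inputs are
#' normalized by subtracting the per-channel mean over the dataset (stored
#' on the model and re-applied at encode time). After training, `encode`
#' is a pure deterministic function from images to latent vectors.
#'
#' @param images an `image_set` (or `n x H x W x 3` array).
#' @param spec an [encoder_spec()] with `loss = "mse"`.
#' @param seed integer seed covering initialization and batch order.
#' @return object of class `autoencoder`: list with `params`, `spec`,
#'   `loss_history` (per-epoch training MSE), `channel_means`, and
#'   `encode(images)`.
#' @export
train_autoencoder <- function(images, spec = encoder_spec(), seed = 1L) {
  if (spec$loss != "mse") {
    stop_rdmem("autoencoder training uses the mean squared error loss",
               class = "rdmem_configuration")
  }
  x_raw <- check_images_for_spec(images, spec)
  n_px <- spec$input_size^2
  ch_means <- vapply(1:3, function(ch) {
    mean(x_raw[, (ch - 1L) * n_px + seq_len(n_px)])
  }, numeric(1))
  x <- center_channels(x_raw, ch_means, n_px)
  p <- ncol(x)
  model <- with_seed(seed, {
    layers <- list(
      enc1 = init_layer(p, spec$hidden),
      enc2 = init_layer(spec$hidden, spec$latent_dim),
      dec1 = init_layer(spec$latent_dim, spec$hidden),
      dec2 = init_layer(spec$hidden, p)
    )
    params <- flatten_params(layers)
    state <- adam_state(params)
    t_step <- 0L
    losses <- numeric(spec$epochs)
    n <- nrow(x)
    for (ep in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1L, n)]
        xb <- x[idx, , drop = FALSE]
        ly <- unflatten_params(params)
        a1 <- affine(xb, ly$enc1); h1 <- gelu(a1)
        z <- affine(h1, ly$enc2)
        a2 <- affine(z, ly$dec1); h2 <- gelu(a2)
        xhat <- affine(h2, ly$dec2)
        err <- xhat - xb
        loss <- mean(err^2)
        if (!is.finite(loss)) {
          stop_rdmem("training diverged (non-finite loss)",
                     class = "rdmem_divergence")
        }
        ep_loss <- ep_loss + loss * length(idx)
        g_out <- 2 * err / length(err)
        g <- backprop_dense(xb, list(a1 = a1, h1 = h1, z = z, a2 = a2,
                                     h2 = h2), ly, g_out, g_z_extra = NULL)
        t_step <- t_step + 1L
        upd <- adam_update(params, g, state, spec$lr, t_step)
        params <- upd$params
        state <- upd$state
      }
      losses[ep] <- ep_loss / n
    }
    list(params = params, losses = losses)
  })
  obj <- list(params = model$params, spec = spec,
              loss_history = model$losses, channel_means = ch_means,
              seed = check_seed(seed))
  obj$encode <- make_encoder(obj, vae = FALSE)
  class(obj) <- "autoencoder"
  obj
}

center_channels <- function(x, ch_means, n_px) {
  for (ch in 1:3) {
    cols <- (ch - 1L) * n_px + seq_len(n_px)
    x[, cols] <- x[, cols] - ch_means[ch]
  }
  x
}

# Shared decoder/encoder backprop for the deterministic autoencoder.
backprop_dense <- function(xb, act, ly, g_out, g_z_extra) {
  g <- list()
  g[["dec2.w"]] <- crossprod(act$h2, g_out)
  g[["dec2.b"]] <- colSums(g_out)
  g_h2 <- g_out %*% t(ly$dec2$w)
  g_a2 <- g_h2 * gelu_grad(act$a2)
  g[["dec1.w"]] <- crossprod(act$z, g_a2)
  g[["dec1.b"]] <- colSums(g_a2)
  g_z <- g_a2 %*% t(ly$dec1$w)
  if (!is.null(g_z_extra)) g_z <- g_z + g_z_extra
  g[["enc2.w"]] <- crossprod(act$h1, g_z)
  g[["enc2.b"]] <- colSums(g_z)
  g_h1 <- g_z %*% t(ly$enc2$w)
  g_a1 <- g_h1 * gelu_grad(act$a1)
  g[["enc1.w"]] <- crossprod(xb, g_a1)
  g[["enc1.b"]] <- colSums(g_a1)
  g
}

make_encoder <- function(obj, vae) {
  force(obj); force(vae)
  function(images) {
    x <- if (is.matrix(images)) images else flatten_images(images)
    if (!vae) {
      n_px <- obj$spec$input_size^2
      x <- center_channels(x, obj$channel_means, n_px)
    }
    ly <- unflatten_params(obj$params)
    h1 <- gelu(affine(x, ly$enc1))
    if (vae) affine(h1, ly$mu) else affine(h1, ly$enc2)
  }
}

#' @export
print.autoencoder <- function(x, ...) {
  cat(sprintf(
    "<autoencoder> %dx%dx3 -> %d latents | final MSE %.5f after %d epochs\n",
    x$spec$input_size, x$spec$input_size, x$spec$latent_dim,
    tail(x$loss_history, 1), x$spec$epochs))
  invisible(x)
}
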