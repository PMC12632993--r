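#' Train a beta-VAE and record its rate and distortion
#'
#' Trains a variational autoencoder whose loss weights the KL term by
#' `beta`: `L = BCE(x, xhat) + beta * KL(q(z|x) || N(0, I))` (plus an
#' optional L1 penalty on latent magnitudes, the sparse variant). The
#' reconstruction error (binary cross-entropy, summed over pixels per
#' image) is read as the distortion `D` and the KL divergence (nats per
#' image) as the rate `R`, so a sweep over `beta` traces a per-image
#' rate-distortion curve: large `beta` collapses the posterior toward the
#' prior (rate toward 0, distortion up), small `beta` approaches plain
#' reconstruction.
#'
#' Images are split into train and held-out evaluation sets
#' (`spec$holdout`); reported rate and distortion are per-image means on
#' the held-out split.
#'
#' @param images an `image_set` with values in `[0, 1]`.
#' @param beta KL weight, `>= 0`.
#' @param spec an [encoder_spec()] (its `loss` is read as `"bce"`).
#' @param seed integer seed (initialization, batch order, reparameterized
#'   noise, split).
#' @return object of class `beta_vae`: list with `params`, `record` (a
#'   list: `beta`, `rate`, `distortion`, `train_loss`, `test_loss`,
#'   `seed`), `per_image` (data frame of per-image rate/distortion over
#'   *all* images, with a `held_out` flag), `spec`, `encode(images)`
#'   returning posterior means.
#' @export
train_beta_vae <- function(images, beta, spec = encoder_spec(loss = "bce"),
                           seed = 1L) {
  if (beta < 0) {
    stop_rdmem("beta must be >= 0", class = "rdmem_invalid_parameter")
  }
  x <- check_images_for_spec(images, spec)
  if (min(x) < 0 || max(x) > 1) {
    stop_rdmem("images must lie in [0, 1] for the binary cross-entropy loss",
               class = "rdmem_validation")
  }
  p <- ncol(x)
  n <- nrow(x)
  l1 <- spec$l1_latent
  res <- with_seed(seed, {
    n_test <- max(1L, round(spec$holdout * n))
    test_idx <- sample.int(n, n_test)
    train_idx <- setdiff(seq_len(n), test_idx)
    layers <- list(
      enc1 = init_layer(p, spec$hidden),
      mu = init_layer(spec$hidden, spec$latent_dim),
      lv = init_layer(spec$hidden, spec$latent_dim),
      dec1 = init_layer(spec$latent_dim, spec$hidden),
      dec2 = init_layer(spec$hidden, p)
    )
    params <- flatten_params(layers)
    state <- adam_state(params)
    t_step <- 0L
    for (ep in seq_len(spec$epochs)) {
      ord <- sample(train_idx)
      for (start in seq(1L, length(ord), by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1L, length(ord))]
        xb <- x[idx, , drop = FALSE]
        b <- length(idx)
        ly <- unflatten_params(params)
        a1 <- affine(xb, ly$enc1); h1 <- gelu(a1)
        mu <- affine(h1, ly$mu)
        lv <- pmin(pmax(affine(h1, ly$lv), -10), 10)
        eps <- matrix(rnorm(b * spec$latent_dim), b)
        sdv <- exp(lv / 2)
        z <- mu + eps * sdv
        a2 <- affine(z, ly$dec1); h2 <- gelu(a2)
        logits <- affine(h2, ly$dec2)
        xhat <- sigmoid(logits)
        bce <- -sum(xb * plogis_log(logits) +
                      (1 - xb) * plogis_log(-logits)) / b
        kl <- 0.5 * sum(mu^2 + exp(lv) - 1 - lv) / b
        loss <- bce + beta * kl + l1 * sum(abs(z)) / b
        if (!is.finite(loss)) {
          stop_rdmem("training diverged (non-finite loss)",
                     class = "rdmem_divergence")
        }
        # gradients (per-image sums averaged over the batch)
        g_logits <- (xhat - xb) / b
        g <- list()
        g[["dec2.w"]] <- crossprod(h2, g_logits)
        g[["dec2.b"]] <- colSums(g_logits)
        g_h2 <- g_logits %*% t(ly$dec2$w)
        g_a2 <- g_h2 * gelu_grad(a2)
        g[["dec1.w"]] <- crossprod(z, g_a2)
        g[["dec1.b"]] <- colSums(g_a2)
        g_z <- g_a2 %*% t(ly$dec1$w)
        if (l1 > 0) g_z <- g_z + l1 * sign(z) / b
        g_mu <- g_z + beta * mu / b
        g_lv <- g_z * eps * sdv / 2 + beta * (exp(lv) - 1) / (2 * b)
        g[["mu.w"]] <- crossprod(h1, g_mu)
        g[["mu.b"]] <- colSums(g_mu)
        g[["lv.w"]] <- crossprod(h1, g_lv)
        g[["lv.b"]] <- colSums(g_lv)
        g_h1 <- g_mu %*% t(ly$mu$w) + g_lv %*% t(ly$lv$w)
        g_a1 <- g_h1 * gelu_grad(a1)
        g[["enc1.w"]] <- crossprod(xb, g_a1)
        g[["enc1.b"]] <- colSums(g_a1)
        t_step <- t_step + 1L
        upd <- adam_update(params, g, state, spec$lr, t_step)
        params <- upd$params
        state <- upd$state
      }
    }
    ev <- vae_evaluate(params, x, beta, l1)
    list(params = params, per_image = ev, train_idx = train_idx,
         test_idx = test_idx)
  })
  per_image <- res$per_image
  per_image$held_out <- seq_len(n) %in% res$test_idx
  rate <- mean(per_image$rate[per_image$held_out])
  distortion <- mean(per_image$distortion[per_image$held_out])
  record <- list(
    beta = beta, rate = rate, distortion = distortion,
    train_loss = mean(per_image$loss[!per_image$held_out]),
    test_loss = mean(per_image$loss[per_image$held_out]),
    seed = check_seed(seed)
  )
  obj <- list(params = res$params, record = record, per_image = per_image,
              spec = spec, seed = check_seed(seed))
  obj$encode <- make_encoder(obj, vae = TRUE)
  class(obj) <- "beta_vae"
  obj
}

# log(sigmoid(x)) computed stably.
plogis_log <- function(x) ifelse(x > 0, -log1p(exp(-x)), x - log1p(exp(x)))

# Deterministic per-image evaluation at the posterior mean.
vae_evaluate <- function(params, x, beta, l1) {
  ly <- unflatten_params(params)
  h1 <- gelu(affine(x, ly$enc1))
  mu <- affine(h1, ly$mu)
  lv <- pmin(pmax(affine(h1, ly$lv), -10), 10)
  h2 <- gelu(affine(mu, ly$dec1))
  logits <- affine(h2, ly$dec2)
  bce <- -rowSums(x * plogis_log(logits) + (1 - x) * plogis_log(-logits))
  kl <- 0.5 * rowSums(mu^2 + exp(lv) - 1 - lv)
  data.frame(image = seq_len(nrow(x)), rate = pmax(kl, 0),
             distortion = bce, loss = bce + beta * kl + l1 * rowSums(abs(mu)))
}

#' @export
print.beta_vae <- function(x, ...) {
  r <- x$record
  cat(sprintf(
    "<beta_vae> beta %.3g | rate %.4f nats | distortion %.2f | test loss %.2f\n",
    r$beta, r$rate, r$distortion, r$test_loss))
  invisible(x)
}

#' Estimate per-image rate-distortion curves from a beta sweep
#'
#' Trains one beta-VAE per (`beta`, training seed) pair and assembles, per
#' image, the ordered list of `(beta, rate, distortion)` points from the
#' seed with the lowest held-out loss (summed over the sweep). Also
#' reports the variational lossiness of each image: its mean
#' reconstruction error across the beta sweep.
#'
#' @param images an `image_set`.
#' @param betas numeric vector of at least 3 KL weights (a logarithmic
#'   grid is conventional since rates span orders of magnitude).
#' @param seeds integer vector of training seeds (>= 1 seed).
#' @param spec an [encoder_spec()].
#' @return object of class `rd_curves`: list with `curves` (per image, a
#'   data frame of `beta`, `rate`, `distortion`), `selected_seed`,
#'   `seed_losses`, `lossiness` (per-image mean distortion across betas),
#'   `ids`.
#' @export
estimate_rd_curve <- function(images, betas, seeds = 1L,
                              spec = encoder_spec(loss = "bce")) {
  if (length(betas) < 3L) {
    stop_rdmem("need at least 3 beta values", class = "rdmem_invalid_parameter")
  }
  if (length(seeds) < 1L) {
    stop_rdmem("need at least one seed", class = "rdmem_invalid_parameter")
  }
  per_seed <- lapply(seeds, function(sd) {
    tryCatch({
      fits <- lapply(betas, function(b) {
        train_beta_vae(images, beta = b, spec = spec, seed = sd)
      })
      list(
        test_loss = sum(vapply(fits, function(f) f$record$test_loss,
                               numeric(1))),
        per_image = lapply(fits, function(f) f$per_image)
      )
    }, rdmem_divergence = function(e) NULL)
  })
  losses <- vapply(per_seed, function(s) {
    if (is.null(s)) Inf else s$test_loss
  }, numeric(1))
  if (all(!is.finite(losses))) {
    stop_rdmem("all seeds diverged", class = "rdmem_estimation_failure")
  }
  best <- which.min(losses)
  chosen <- per_seed[[best]]$per_image
  ids <- if (inherits(images, "image_set")) images$ids else {
    sprintf("img%04d", seq_len(nrow(chosen[[1]])))
  }
  curves <- lapply(seq_along(ids), function(i) {
    data.frame(
      beta = betas,
      rate = vapply(chosen, function(pi) pi$rate[i], numeric(1)),
      distortion = vapply(chosen, function(pi) pi$distortion[i], numeric(1))
    )
  })
  names(curves) <- ids
  structure(
    list(curves = curves, selected_seed = seeds[best],
         seed_losses = stats::setNames(losses, seeds),
         lossiness = stats::setNames(
           vapply(curves, function(cv) mean(cv$distortion), numeric(1)),
           ids),
         ids = ids),
    class = "rd_curves"
  )
}

#' Assemble a rate-distortion curve from precomputed points
#'
#' Pass-through constructor for curves obtained outside the training loop
#' (e.g. simulated sweeps); preserves point order and count.
#'
#' @param beta,rate,distortion numeric vectors of equal length (>= 3
#'   points; rates and distortions finite and non-negative).
#' @param id image identifier.
#' @return data frame of class `rd_curve`.
#' @export
rd_curve <- function(beta, rate, distortion, id = "image") {
  if (length(beta) < 3L) {
    stop_rdmem("a curve needs at least 3 points",
               class = "rdmem_validation")
  }
  if (any(!is.finite(rate)) || any(!is.finite(distortion)) ||
      any(rate < 0) || any(distortion < 0)) {
    stop_rdmem("rates and distortions must be finite and >= 0",
               class = "rdmem_validation")
  }
  structure(data.frame(beta = beta, rate = rate, distortion = distortion),
            id = id, class = c("rd_curve", "data.frame"))
}

#' Normalized rate: slope of the semi-log rate-distortion curve
#'
#' The amount of information discarded per unit of distortion: the
#' ordinary least-squares slope of `log10(rate)` regressed on distortion
#' along a per-image rate-distortion curve. More negative (steeper) slopes
#' characterize forgetting that discards more information per unit of
#' distortion -- more aggressive compression; shallower slopes are more
#' conservative. Invariant to the ordering of the curve's points.
#'
#' @param curve a data frame with `rate` and `distortion` columns (an
#'   `rd_curve`, or one element of an `rd_curves` object). Points with
#'   `rate <= 0` are dropped with a warning; at least 2 usable points are
#'   required.
#' @return the slope (a real number).
#' @export
normalized_rate <- function(curve) {
  if (inherits(curve, "rd_curves")) {
    return(vapply(curve$curves, normalized_rate, numeric(1)))
  }
  stopifnot(all(c("rate", "distortion") %in% names(curve)))
  bad <- curve$rate <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d points with non-positive rate", sum(bad)))
    curve <- curve[!bad, , drop = FALSE]
  }
  if (nrow(curve) < 2L) {
    stop_rdmem("fewer than 2 usable points: slope not estimable",
               class = "rdmem_estimation_failure")
  }
  unname(coef(lm(log10(rate) ~ distortion, data = curve))[2L])
}
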