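# Dense feed-forward building blocks: weight init, GELU, Adam. The
# networks in this package are deliberately small (hundreds of inputs,
# tens of latents) so plain matrix algebra is fast enough and keeps the
# training loop fully deterministic under a seed.

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

sigmoid <- function(x) 1 / (1 + exp(-x))

init_layer <- function(n_in, n_out) {
  s <- sqrt(2 / (n_in + n_out))
  list(w = matrix(rnorm(n_in * n_out, 0, s), n_in, n_out),
       b = rep(0, n_out))
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in names(params)) {
    st <- state[[k]]
    st$m <- beta1 * st$m + (1 - beta1) * grads[[k]]
    st$v <- beta2 * st$v + (1 - beta2) * grads[[k]]^2
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
    state[[k]] <- st
  }
  list(params = params, state = state)
}

# Flatten nested layer lists into one named list of arrays.
flatten_params <- function(layers) {
  out <- list()
  for (nm in names(layers)) {
    out[[paste0(nm, ".w")]] <- layers[[nm]]$w
    out[[paste0(nm, ".b")]] <- layers[[nm]]$b
  }
  out
}

unflatten_params <- function(flat) {
  nms <- unique(sub("\\.[wb]$", "", names(flat)))
  stats::setNames(lapply(nms, function(nm) {
    list(w = flat[[paste0(nm, ".w")]], b = flat[[paste0(nm, ".b")]])
  }), nms)
}

affine <- function(x, layer) {
  sweep(x %*% layer$w, 2L, layer$b, `+`)
}
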