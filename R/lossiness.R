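#' Linearly interpolate between target and lure representations
#'
#' Builds the retrieval path in latent space: row 0 is the target, row
#' `k+1` the lure, and the `k` intermediate rows are evenly spaced convex
#' combinations, `row_i = target + (i / (k+1)) * (lure - target)`. The path
#' models memory retrieval traversing the latent manifold between the two
#' images.
#'
#' @param target,lure numeric vectors of equal length.
#' @param k number of interior interpolants (>= 0).
#' @return a `(k+2) x d` matrix (class `path_matrix`) whose first and last
#'   rows equal the inputs exactly.
#' @export
interpolate_path <- function(target, lure, k = 10L) {
  if (length(target) != length(lure)) {
    stop_rdmem("target and lure must have equal dimension",
               class = "rdmem_validation")
  }
  k <- check_count(k, "k", min = 0L)
  w <- seq(0, 1, length.out = k + 2L)
  path <- outer(1 - w, target) + outer(w, lure)
  path[1L, ] <- target
  path[k + 2L, ] <- lure
  class(path) <- c("path_matrix", class(path))
  path
}

#' Simulate a perceptual confusion matrix from a representation path
#'
#' Treats the path points as the symbols of a perceptual identification
#' channel. Pairwise cosine distances are converted to similarities
#' (`1 - distance`, negative values floored at zero), normalized by the
#' global maximum, row-normalized into an identification probability
#' matrix, and sampled: each input row draws `n_samples` identifications
#' from its row of probabilities (multinomial), simulating how often each
#' representation along the target--lure path is mistaken for every other.
#'
#' @param path a `path_matrix` (or any numeric matrix of representations).
#' @param n_samples identifications drawn per input row (default 250).
#' @param seed integer seed.
#' @return An object of class `confusion_model`: list with `distance`,
#'   `similarity`, `probability` (row-stochastic), `counts` (integer,
#'   row sums equal `n_samples`).
#' @export
confusion_from_path <- function(path, n_samples = 250L, seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples")
  path <- unclass(path)
  if (any(row_norms(path) == 0)) {
    stop_rdmem("zero-norm representation: cosine undefined",
               class = "rdmem_zero_norm")
  }
  dist <- cosine_distance(path)
  sim <- 1 - dist
  sim[sim < 0] <- 0
  sim <- sim / max(sim)
  prob <- sim / rowSums(sim)
  counts <- with_seed(seed, {
    t(apply(prob, 1L, function(p) rmultinom(1L, n_samples, p)[, 1L]))
  })
  structure(
    list(distance = dist, similarity = sim, probability = prob,
         counts = counts, n_samples = n_samples),
    class = "confusion_model"
  )
}

#' Lossiness of compressing a target into a lure
#'
#' The pipeline's core scalar: interpolates a latent path between the
#' target and lure embeddings ([interpolate_path()]), simulates the
#' identification channel along the path ([confusion_from_path()]), fits a
#' rate-distortion cost matrix to the confusion counts
#' ([fit_cost_matrix()]) and returns the fitted mean off-diagonal cost.
#' More separated (more orthogonal) pairs yield more diagonal confusion
#' matrices and hence larger inferred costs: compressing one into the
#' other is lossier.
#'
#' @param target,lure numeric embedding vectors of equal length.
#' @param config list of options forwarded to the stages: `k` (10 interior
#'   interpolants), `n_samples` (250), plus any [fit_cost_matrix()] config
#'   entries.
#' @param seed integer seed controlling both the confusion sampling and the
#'   fit restarts.
#' @return the lossiness scalar, with the `cost_fit` and the
#'   `confusion_model` attached as attributes `fit` and `confusion`.
#' @export
pair_lossiness <- function(target, lure, config = list(), seed = 1L) {
  cfg <- utils::modifyList(list(k = 10L, n_samples = 250L), config)
  path <- interpolate_path(target, lure, k = cfg$k)
  conf <- confusion_from_path(path, n_samples = cfg$n_samples, seed = seed)
  fit_cfg <- cfg[setdiff(names(cfg), c("k", "n_samples"))]
  fit <- fit_cost_matrix(conf$counts, config = fit_cfg, seed = seed)
  structure(fit$lossiness, fit = fit, confusion = conf)
}

#' Lossiness for every pair of an embedding set
#'
#' Applies [pair_lossiness()] to each target--lure pair of an
#' `embedding_set`, returning a tidy per-pair table.
#'
#' @param embeddings an `embedding_set` with a `pairs` component.
#' @param config,seed forwarded to [pair_lossiness()]; every pair shares
#'   the same seed (common random numbers), which removes simulation noise
#'   from cross-pair comparisons.
#' @return data frame with `target`, `lure`, `lossiness`, `logLik`,
#'   `converged`.
#' @export
set_lossiness <- function(embeddings, config = list(), seed = 1L) {
  stopifnot(inherits(embeddings, "embedding_set"),
            !is.null(embeddings$pairs))
  pairs <- embeddings$pairs
  seed <- check_seed(seed)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    tg <- embeddings$items[pairs$target[i], ]
    lu <- embeddings$items[pairs$lure[i], ]
    l <- pair_lossiness(tg, lu, config = config, seed = seed)
    fit <- attr(l, "fit")
    data.frame(target = pairs$target[i], lure = pairs$lure[i],
               lossiness = as.numeric(l), logLik = fit$logLik,
               converged = fit$converged, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' @export
print.confusion_model <- function(x, ...) {
  cat(sprintf("<confusion_model> %d symbols, %d samples per row\n",
              nrow(x$counts), x$n_samples))
  invisible(x)
}
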