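#' Optimal capacity-limited channel for a cost matrix (Blahut fixed point)
#'
#' Computes the rate-distortion optimal channel for a discrete source and
#' cost (distortion) matrix at trade-off `s`: the fixed point of
#' `q(j|i) = m(j) exp(-s d_ij) / Z_i` with output marginal
#' `m(j) = sum_i p(i) q(j|i)`, iterated from a uniform marginal. Sweeping
#' `s` from 0 upward traces the rate-distortion frontier `R(D)` from the
#' zero-rate point to the lossless limit.
#'
#' @param cost non-negative finite cost matrix `d_ij` (inputs by outputs).
#' @param source source probability vector over inputs (sums to 1).
#' @param s trade-off parameter `>= 0`; `s = 0` yields the zero-rate
#'   channel `q(j|i) = m(j)`.
#' @param tol convergence tolerance on the output marginal.
#' @param max_iter iteration cap.
#' @return list with `channel` (row-stochastic matrix), `marginal`, `rate`
#'   (mutual information, nats), `distortion` (expected cost),
#'   `iterations`, `converged`.
#' @examples
#' # binary uniform source, Hamming cost
#' ch <- optimal_channel(1 - diag(2), c(.5, .5), s = 2)
#' c(ch$rate, ch$distortion)
#' @export
optimal_channel <- function(cost, source, s, tol = 1e-12,
                            max_iter = 10000L) {
  cost <- as.matrix(cost)
  if (any(!is.finite(cost))) {
    stop_rdmem("cost matrix must be finite", class = "rdmem_validation")
  }
  if (s < 0) {
    stop_rdmem("s must be >= 0", class = "rdmem_invalid_parameter")
  }
  if (abs(sum(source) - 1) > 1e-8 || any(source < 0)) {
    stop_rdmem("source must be a probability vector",
               class = "rdmem_validation")
  }
  res <- blahut_core(cost, source, s, tol, max_iter)
  if (!res$converged) {
    stop_rdmem(sprintf(
      "Blahut iteration did not converge in %d iterations (last delta %.3g)",
      max_iter, res$delta), class = "rdmem_convergence")
  }
  res
}

blahut_core <- function(cost, source, s, tol, max_iter, m0 = NULL) {
  n_out <- ncol(cost)
  k <- exp(-s * cost)
  m <- m0 %||% rep(1 / n_out, n_out)
  converged <- FALSE
  iter <- 0L
  delta <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    a <- k * rep(m, each = nrow(k))
    q <- a / rowSums(a)
    m_new <- as.vector(source %*% q)
    delta <- max(abs(m_new - m))
    m <- m_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  a <- k * rep(m, each = nrow(k))
  q <- a / rowSums(a)
  lr <- log(q / rep(m, each = nrow(q)))
  lr[q == 0] <- 0
  rate <- sum(source * rowSums(q * lr))
  distortion <- sum(source * rowSums(q * cost))
  list(channel = q, marginal = m, rate = max(rate, 0),
       distortion = distortion, iterations = iter, converged = converged,
       delta = delta)
}

#' Infer a rate-distortion cost matrix from a confusion count matrix
#'
#' The central estimator: given an observed confusion matrix of counts
#' (rows = presented representations, columns = identified
#' representations), finds the cost matrix `d` whose rate-distortion
#' optimal channel (see [optimal_channel()]) maximizes the multinomial
#' log-likelihood of the counts, with a prior penalizing asymmetry
#' (`lambda_sym * sum_ij (d_ij - d_ji)^2`) and the diagonal constrained to
#' zero. Because the channel depends on the trade-off and cost only through
#' their product, the trade-off is held at `s = 1` and the scale of the
#' inferred costs carries the trade-off; the scalar *lossiness* summary is
#' the mean off-diagonal cost.
#'
#' Optimization alternates, for a configured number of outer iterations
#' (with early exit once the objective stalls), between (a) Blahut-style
#' updates of the channel's output marginal toward self-consistency
#' `m(j) = sum_i p(i) q(j|i)`, damped and accepted only while the
#' penalized likelihood does not fall -- which reaches the genuine
#' self-consistent channel when the confusion structure supports it while
#' avoiding the degenerate zero-rate fixed point when it does not -- and
#' (b) partial maximization over the off-diagonal costs by projected
#' gradient ascent with the marginal held fixed. The penalized
#' log-likelihood is non-decreasing across outer iterations by
#' construction.
#' Multiple restarts from jittered initializations (costs initialized from
#' one minus the empirical similarity implied by the counts) are run and
#' the best penalized log-likelihood kept.
#'
#' @param counts non-negative count matrix with positive row sums.
#' @param config list of options: `n_restarts` (10), `n_iter` (100 outer
#'   iterations), `lambda_sym` (1), `inner_steps` (8), `include_diagonal`
#'   (FALSE; whether the structurally zero diagonal enters the lossiness
#'   mean), `init_scale` (1).
#' @param seed integer seed for the restart jitter.
#' @return An object of class `cost_fit`: list with `cost` (matrix, zero
#'   diagonal), `s`, `logLik` (unpenalized, at the fitted channel),
#'   `penalized_logLik`, `lossiness`, `iterations`, `restart` (index of the
#'   winning restart), `trace` (penalized log-likelihood per outer
#'   iteration of the winning restart), `converged`, `channel`.
#' @export
fit_cost_matrix <- function(counts, config = list(), seed = 1L) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop_rdmem("counts must be non-negative and finite",
               class = "rdmem_validation")
  }
  if (any(rowSums(counts) <= 0)) {
    stop_rdmem("every row of counts needs a positive sum",
               class = "rdmem_validation")
  }
  cfg <- utils::modifyList(list(
    n_restarts = 10L, n_iter = 100L, lambda_sym = 1, inner_steps = 8L,
    include_diagonal = FALSE, init_scale = 1
  ), config)
  n <- nrow(counts)
  source <- rowSums(counts) / sum(counts)
  # empirical similarity proxy: symmetrized row-normalized counts
  phat <- counts / rowSums(counts)
  sim <- (phat + t(phat)) / 2
  sim <- sim / max(sim)
  d_base <- cfg$init_scale * (1 - sim)
  diag(d_base) <- 0
  # choose the starting cost scale on a doubling grid by penalized
  # likelihood (uniform output marginal), then refine
  m_unif <- rep(1 / ncol(counts), ncol(counts))
  grid <- 2^(-3:8)
  scale_ll <- vapply(grid, function(sc) {
    channel_pll(sc * d_base, m_unif, counts, cfg$lambda_sym)$value
  }, numeric(1))
  d_base <- d_base * grid[which.max(scale_ll)]

  best <- NULL
  with_seed(seed, {
    for (r in seq_len(cfg$n_restarts)) {
      d0 <- if (r == 1L) d_base else {
        sc <- mean(offdiag(d_base))
        jit <- d_base * exp(rnorm(1, 0, 0.4)) +
          matrix(abs(rnorm(n * n, 0, 0.1 * sc)), n)
        diag(jit) <- 0
        jit
      }
      fit <- fit_cost_once(counts, source, d0, cfg)
      if (is.null(best) || fit$penalized_logLik > best$penalized_logLik) {
        best <- fit
        best$restart <- r
      }
    }
  })
  offd <- offdiag(best$cost)
  lossiness <- if (cfg$include_diagonal) mean(best$cost) else mean(offd)
  structure(
    list(cost = best$cost, s = 1, logLik = best$logLik,
         penalized_logLik = best$penalized_logLik, lossiness = lossiness,
         iterations = best$iterations, restart = best$restart,
         trace = best$trace, converged = best$converged,
         channel = best$channel, marginal = best$marginal, config = cfg),
    class = "cost_fit"
  )
}

# Penalized log-likelihood of counts under the exponential channel
# q(j|i) = m_j exp(-d_ij) / Z_i at a given output marginal m.
channel_pll <- function(d, m, counts, lambda) {
  a <- rep(m, each = nrow(d)) * exp(-d)
  q <- a / rowSums(a)
  lq <- log(pmax(q, 1e-300))
  lq[counts == 0] <- 0  # 0 * log -> 0
  ll <- sum(counts * lq)
  list(value = ll - lambda * sum((d - t(d))^2), ll = ll, q = q)
}

# One restart: alternate (a) Blahut-style self-consistency updates of the
# output marginal, accepted only while the penalized likelihood does not
# fall (damped when it would), with (b) projected gradient ascent over the
# off-diagonal costs at fixed marginal. Keeping the marginal update
# conditional avoids the degenerate zero-rate fixed point (marginal
# collapsed on one output symbol) that the raw iteration reaches when the
# observed confusion structure is weak, while converging to the genuine
# self-consistent channel when the data support it.
fit_cost_once <- function(counts, source, d, cfg) {
  lambda <- cfg$lambda_sym
  n <- nrow(counts)
  rowtot <- rowSums(counts)
  m <- rep(1 / ncol(counts), ncol(counts))
  cur <- channel_pll(d, m, counts, lambda)
  trace <- numeric(cfg$n_iter)
  step <- 1 / max(sum(counts), 1)
  stall <- 0L
  it_used <- 0L
  for (it in seq_len(cfg$n_iter)) {
    it_used <- it
    prev <- cur$value
    # (a) marginal toward self-consistency m = sum_i p(i) q(j|i)
    m_prop <- as.vector(source %*% cur$q)
    for (damp in 1:6) {
      cand <- channel_pll(d, m_prop, counts, lambda)
      if (cand$value >= cur$value) {
        m <- m_prop
        cur <- cand
        break
      }
      m_prop <- (m_prop + m) / 2
    }
    # (b) cost ascent at fixed marginal
    d_new <- inner_ascent(d, counts, source, rowtot, m, lambda,
                          cfg$inner_steps, step)
    cand <- channel_pll(d_new, m, counts, lambda)
    if (cand$value >= cur$value) {
      d <- d_new
      cur <- cand
    }
    trace[it] <- cur$value
    stall <- if (cur$value - prev < 1e-8 * (abs(cur$value) + 1)) {
      stall + 1L
    } else {
      0L
    }
    if (stall >= 8L) break
  }
  list(cost = d, logLik = cur$ll, penalized_logLik = cur$value,
       channel = cur$q, marginal = m, trace = trace[seq_len(it_used)],
       iterations = it_used, converged = stall >= 8L)
}

# Gradient steps on the penalized likelihood with the output marginal held
# fixed; q(j|i) = m_j exp(-d_ij)/Z_i so the gradient is analytic.
inner_ascent <- function(d, counts, source, rowtot, m, lambda, steps,
                         step0) {
  n <- nrow(d)
  obj <- function(d) {
    a <- rep(m, each = n) * exp(-d)
    q <- a / rowSums(a)
    lq <- log(pmax(q, 1e-300))
    lq[counts == 0] <- 0
    sum(counts * lq) - lambda * sum((d - t(d))^2)
  }
  cur <- obj(d)
  step <- step0
  for (k in seq_len(steps)) {
    a <- rep(m, each = n) * exp(-d)
    q <- a / rowSums(a)
    grad <- rowtot * q - counts - 4 * lambda * (d - t(d))
    repeat {
      d_new <- d + step * grad
      d_new[d_new < 0] <- 0
      diag(d_new) <- 0
      val <- obj(d_new)
      if (val >= cur || step < 1e-12) break
      step <- step / 2
    }
    if (val < cur) break
    if (val > cur) step <- step * 1.5
    d <- d_new
    cur <- val
  }
  d
}

#' @export
print.cost_fit <- function(x, ...) {
  cat(sprintf(
    "<cost_fit> %d symbols | lossiness %.4f | logLik %.2f | restart %d/%d\n",
    nrow(x$cost), x$lossiness, x$logLik, x$restart, x$config$n_restarts))
  invisible(x)
}

#' @export
coef.cost_fit <- function(object, ...) object$cost

#' @export
logLik.cost_fit <- function(object, ...) {
  structure(object$logLik, df = sum(upper.tri(object$cost)) * 2 + 1,
            class = "logLik")
}
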