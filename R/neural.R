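#' Participation ratio: effective dimensionality of a neural code
#'
#' `PR = (sum lambda_i)^2 / sum lambda_i^2` over the eigenvalues of the
#' voxel covariance matrix -- a continuous count of how many principal
#' components effectively carry the variance. A flat spectrum over `N`
#' voxels gives `PR = N`; a rank-one code gives `PR = 1`. The statistic is
#' invariant to global scaling of the data and to orthogonal rotations of
#' the voxel basis.
#'
#' @param x either a voxel-by-time data matrix (covariance is taken across
#'   time with voxel-mean centering and a `1/(T-1)` divisor) or a numeric
#'   vector of eigenvalues.
#' @return the participation ratio, in `[1, N]`.
#' @examples
#' participation_ratio(c(1, 1, 1, 1))  # 4
#' participation_ratio(c(2, 1, 1))     # 16/6
#' @export
participation_ratio <- function(x) {
  lam <- if (is.matrix(x)) {
    if (nrow(x) < 2L || ncol(x) < 2L) {
      stop_rdmem("need >= 2 voxels and >= 2 time points",
                 class = "rdmem_validation")
    }
    eigen(stats::cov(t(x)), symmetric = TRUE, only.values = TRUE)$values
  } else {
    as.numeric(x)
  }
  if (any(lam < -1e-10 * max(abs(lam), 1))) {
    stop_rdmem("eigenvalues must be non-negative",
               class = "rdmem_validation")
  }
  lam[lam < 0] <- 0
  tot <- sum(lam)
  if (tot <= 0) {
    stop_rdmem("zero covariance: participation ratio undefined",
               class = "rdmem_undefined")
  }
  tot^2 / sum(lam^2)
}

#' Plug-in mutual information between two series from fixed binning
#'
#' Discretizes each series into `n_bins` equal-width bins spanning its
#' observed range and evaluates the plug-in mutual information of the
#' joint histogram, `I = sum_ij (n_ij / n) log(n_ij n / (n_i. n_.j))`,
#' in nats. Symmetric in its arguments and non-negative; a constant series
#' occupies a single bin and yields 0 with a warning.
#'
#' @param x,y numeric vectors of equal length (>= `n_bins`).
#' @param n_bins number of bins per variable (default 16).
#' @return mutual information in nats, with the joint histogram attached
#'   as attribute `histogram`.
#' @export
binned_mutual_information <- function(x, y, n_bins = 16L) {
  n_bins <- check_count(n_bins, "n_bins", min = 2L)
  if (length(x) != length(y)) {
    stop_rdmem("x and y must have equal length", class = "rdmem_validation")
  }
  if (length(x) < n_bins) {
    stop_rdmem("need at least n_bins observations",
               class = "rdmem_validation")
  }
  bx <- discretize_fixed(x, n_bins)
  by <- discretize_fixed(y, n_bins)
  if (is.null(bx) || is.null(by)) {
    warning("constant series: mutual information set to 0")
    return(structure(0, histogram = NULL))
  }
  counts <- table(factor(bx, levels = seq_len(n_bins)),
                  factor(by, levels = seq_len(n_bins)))
  structure(mi_from_counts(unclass(counts)),
            histogram = joint_histogram(unclass(counts)))
}

discretize_fixed <- function(x, n_bins) {
  r <- range(x)
  if (r[1] == r[2]) return(NULL)
  b <- findInterval(x, seq(r[1], r[2], length.out = n_bins + 1L),
                    rightmost.closed = TRUE, all.inside = TRUE)
  b
}

# MI in nats from a joint count table.
mi_from_counts <- function(n_ij) {
  n <- sum(n_ij)
  if (n == 0) return(0)
  p <- n_ij / n
  px <- rowSums(p)
  py <- colSums(p)
  e <- outer(px, py)
  pos <- p > 0
  max(sum(p[pos] * log(p[pos] / e[pos])), 0)
}

joint_histogram <- function(counts) {
  list(counts = counts, row_marginal = rowSums(counts),
       col_marginal = colSums(counts), n = sum(counts))
}

#' Regional signatures of lossy compression under voxel subsampling
#'
#' Computes, per region, the two neural signatures: (1) the
#' participation-ratio dimensionality of lure-trial activity, split by
#' behavioral outcome, and their difference (correct minus incorrect --
#' negative values mean dimensionality reduction with correct lure
#' discrimination); (2) the binned mutual information between the
#' concatenated, flattened target and lure time courses within each
#' outcome. Because both metrics scale with region size, a fixed budget of
#' voxels is resampled over many iterations and per-iteration values are
#' averaged, making regions of different sizes comparable.
#'
#' @param region a `region_data`.
#' @param n_voxels voxel budget per iteration (default 100; sampled
#'   without replacement when the region has at least that many voxels,
#'   with replacement otherwise).
#' @param n_iter number of subsampling iterations (default 100).
#' @param seed integer seed.
#' @param n_bins bins for the mutual information estimator.
#' @return An object of class `neural_signature`: list with `region`,
#'   per-iteration data frame `iterations` (`dim_correct`, `dim_incorrect`,
#'   `delta_dim`, `mi_correct`, `mi_incorrect`), their means, `n_voxels`,
#'   `n_iter`, `seed`.
#' @export
region_signatures <- function(region, n_voxels = 100L, n_iter = 100L,
                              seed = 1L, n_bins = 16L) {
  stopifnot(inherits(region, "region_data"))
  n_voxels <- check_count(n_voxels, "n_voxels", min = 2L)
  n_iter <- check_count(n_iter, "n_iter")
  lab <- region$labels
  sel <- function(role, outcome) {
    which(lab$role == role & lab$outcome == outcome)
  }
  groups <- list(
    lure_correct = sel("lure", "correct"),
    lure_incorrect = sel("lure", "incorrect"),
    target_correct = sel("target", "correct"),
    target_incorrect = sel("target", "incorrect")
  )
  if (length(groups$lure_correct) == 0L ||
      length(groups$lure_incorrect) == 0L) {
    stop_rdmem("region lacks correct or incorrect lure trials: signature undefined",
               class = "rdmem_undefined")
  }
  # concatenate trials in onset order once; subsampling picks voxel rows
  cat_mat <- lapply(groups, function(idx) {
    idx <- idx[order(lab$onset[idx])]
    do.call(cbind, region$trials[idx])
  })
  v_total <- nrow(region$trials[[1L]])
  replace <- v_total < n_voxels
  res <- with_seed(seed, {
    out <- matrix(NA_real_, nrow = n_iter, ncol = 5L)
    colnames(out) <- c("dim_correct", "dim_incorrect", "delta_dim",
                       "mi_correct", "mi_incorrect")
    for (it in seq_len(n_iter)) {
      v <- sample.int(v_total, n_voxels, replace = replace)
      dc <- participation_ratio(cat_mat$lure_correct[v, , drop = FALSE])
      di <- participation_ratio(cat_mat$lure_incorrect[v, , drop = FALSE])
      mi_c <- mi_between(cat_mat$target_correct[v, , drop = FALSE],
                         cat_mat$lure_correct[v, , drop = FALSE], n_bins)
      mi_i <- mi_between(cat_mat$target_incorrect[v, , drop = FALSE],
                         cat_mat$lure_incorrect[v, , drop = FALSE], n_bins)
      out[it, ] <- c(dc, di, dc - di, mi_c, mi_i)
    }
    as.data.frame(out)
  })
  structure(
    list(region = region$region, iterations = res,
         means = colMeans(res), sds = apply(res, 2L, stats::sd),
         n_voxels = n_voxels, n_iter = n_iter, seed = check_seed(seed),
         n_bins = n_bins),
    class = "neural_signature"
  )
}

# MI between two voxel-by-time blocks: flatten both (voxel-major) and
# truncate to the common length so samples pair one-to-one.
mi_between <- function(a, b, n_bins) {
  x <- as.vector(t(a))
  y <- as.vector(t(b))
  n <- min(length(x), length(y))
  if (length(a) == 0L || length(b) == 0L) return(NA_real_)
  suppressWarnings(
    as.numeric(binned_mutual_information(x[seq_len(n)], y[seq_len(n)],
                                         n_bins = n_bins)))
}

#' @export
print.neural_signature <- function(x, ...) {
  m <- x$means
  cat(sprintf(
    "<neural_signature> %s | delta-dim %.3f (dim_c %.2f, dim_i %.2f) | MI_c %.4f, MI_i %.4f | %d x %d voxels\n",
    x$region, m["delta_dim"], m["dim_correct"], m["dim_incorrect"],
    m["mi_correct"], m["mi_incorrect"], x$n_iter, x$n_voxels))
  invisible(x)
}

#' Gradient of dimensionality reduction along a processing hierarchy
#'
#' Tests whether the correct-minus-incorrect dimensionality difference
#' strengthens (grows more negative) along an ordered processing hierarchy
#' (e.g. early visual cortex through the hippocampal circuit): Spearman
#' rank correlation between hierarchy position and each region's mean
#' delta-dimensionality.
#'
#' @param signatures list of `neural_signature` objects.
#' @param order character vector of region names, earliest stage first;
#'   defaults to the order of `signatures`.
#' @return list with `rho`, `p`, `n_regions` and the per-region table.
#' @export
region_gradient <- function(signatures, order = NULL) {
  stopifnot(length(signatures) >= 3L)
  regions <- vapply(signatures, function(s) s$region, character(1))
  delta <- vapply(signatures, function(s) s$means[["delta_dim"]],
                  numeric(1))
  if (is.null(order)) order <- regions
  if (!setequal(order, regions)) {
    stop_rdmem("`order` must name exactly the signature regions",
               class = "rdmem_validation")
  }
  rank_pos <- match(regions, order)
  if (length(unique(delta)) == 1L) {
    warning("all delta-dimensionality values tied: gradient undefined")
    return(list(rho = NA_real_, p = NA_real_, n_regions = length(regions),
                table = data.frame(region = regions, position = rank_pos,
                                   delta_dim = delta)))
  }
  ct <- spearman_corr(rank_pos, delta)
  list(rho = ct$rho, p = ct$p, n_regions = length(regions),
       table = data.frame(region = regions, position = rank_pos,
                          delta_dim = delta))
}
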