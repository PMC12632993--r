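#' Generate trial-wise voxel time series with planted effective rank
#'
#' Simulates a region's evoked data: one voxel-by-time matrix per trial,
#' labelled by stimulus role (`target`/`lure`) and behavioral outcome
#' (`correct`/`incorrect`). The voxel covariance within each outcome class
#' is built from an eigen-spectrum whose participation ratio equals the
#' planted `effective_rank` to within 2 percent (a block of unit
#' eigenvalues plus one fractional eigenvalue solved by root finding), so
#' dimensionality estimators can be checked against ground truth. Under
#' `dependence = "coupled"`, the target trial and lure trial with the same
#' index share a latent Gaussian component with weight `coupling`, planting
#' target--lure mutual information; under `"independent"` the streams are
#' disjoint.
#'
#' @param n_voxels number of voxels (>= 2).
#' @param n_trials_per_class trials per role-by-outcome cell.
#' @param effective_rank planted participation ratio, either a single value
#'   or a named vector `c(correct = , incorrect = )`; each must lie in
#'   `[1, n_voxels]`.
#' @param dependence `"independent"` or `"coupled"`.
#' @param coupling shared-latent weight in `[0, 1)` used when coupled.
#' @param n_timepoints time points per trial.
#' @param seed integer seed.
#' @param region region label.
#' @return An object of class `region_data`: list with `region`, `trials`
#'   (list of voxel x time matrices), `labels` (data frame: `trial`, `role`,
#'   `outcome`, `onset`), and `planted` parameters.
#' @export
gen_voxel_timeseries <- function(n_voxels, n_trials_per_class = 20L,
                                 effective_rank = 5,
                                 dependence = c("independent", "coupled"),
                                 coupling = 0.9, n_timepoints = 12L,
                                 seed = 1L, region = "synthetic") {
  n_voxels <- check_count(n_voxels, "n_voxels", min = 2L)
  n_trials_per_class <- check_count(n_trials_per_class, "n_trials_per_class")
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 2L)
  dependence <- match.arg(dependence)
  er <- effective_rank
  if (is.null(names(er))) er <- c(correct = er[[1]], incorrect = er[[1]])
  if (any(er < 1) || any(er > n_voxels)) {
    stop_rdmem("effective_rank must lie in [1, n_voxels]",
               class = "rdmem_invalid_parameter")
  }
  if (dependence == "coupled" && (coupling < 0 || coupling >= 1)) {
    stop_rdmem("coupling must lie in [0, 1)",
               class = "rdmem_invalid_parameter")
  }
  with_seed(seed, {
    mixers <- lapply(er, function(e) {
      lam <- pr_spectrum(e, n_voxels)
      q <- qr.Q(qr(matrix(rnorm(n_voxels^2), n_voxels)))
      q %*% diag(sqrt(lam))
    })
    labels <- expand.grid(
      idx = seq_len(n_trials_per_class),
      role = c("target", "lure"), outcome = c("correct", "incorrect"),
      stringsAsFactors = FALSE
    )
    trials <- vector("list", nrow(labels))
    for (out in c("correct", "incorrect")) {
      a <- mixers[[out]]
      for (j in seq_len(n_trials_per_class)) {
        shared <- matrix(rnorm(n_voxels * n_timepoints), n_voxels)
        for (role in c("target", "lure")) {
          k <- which(labels$outcome == out & labels$role == role &
                       labels$idx == j)
          z <- matrix(rnorm(n_voxels * n_timepoints), n_voxels)
          if (dependence == "coupled") {
            z <- sqrt(1 - coupling) * z + sqrt(coupling) * shared
          }
          trials[[k]] <- a %*% z
        }
      }
    }
    labels$trial <- seq_len(nrow(labels))
    labels$onset <- labels$trial  # generation order doubles as onset order
    structure(
      list(
        region = region, trials = trials,
        labels = labels[, c("trial", "role", "outcome", "onset")],
        planted = list(effective_rank = er, dependence = dependence,
                       coupling = if (dependence == "coupled") coupling
                                  else 0,
                       n_voxels = n_voxels, seed = check_seed(seed))
      ),
      class = "region_data"
    )
  })
}

# Eigen-spectrum (descending) with participation ratio equal to `target`:
# floor(target) unit eigenvalues plus one fractional eigenvalue found by
# root finding, zeros elsewhere.
pr_spectrum <- function(target, n) {
  m <- floor(target)
  lam <- numeric(n)
  if (m >= n || abs(target - m) < 1e-12) {
    lam[seq_len(min(m, n))] <- 1
    return(lam)
  }
  f <- function(a) (m + a)^2 / (m + a^2) - target
  a <- stats::uniroot(f, c(1e-12, 1), tol = 1e-14)$root
  lam[seq_len(m)] <- 1
  lam[m + 1L] <- a
  lam
}

#' @export
print.region_data <- function(x, ...) {
  cat(sprintf("<region_data> %s: %d trials, %d voxels x %d time points each\n",
              x$region, length(x$trials), nrow(x$trials[[1]]),
              ncol(x$trials[[1]])))
  invisible(x)
}

#' Reconstruct evoked time series from amplitudes and an HRF kernel
#'
#' Given per-trial, per-voxel evoked amplitude estimates (as produced by a
#' trial-wise GLM) and a hemodynamic response kernel, rebuilds each trial's
#' voxel-by-time activity as `amplitude x kernel` placed at the trial onset
#' on the scan time grid.
#'
#' @param betas `n_voxels x n_trials` matrix of evoked amplitudes.
#' @param hrf numeric kernel sampled on the scan grid.
#' @param onsets trial onsets as scan-grid indices (1-based).
#' @param n_scan total scan length in grid points; each trial must satisfy
#'   `onset + length(hrf) - 1 <= n_scan`.
#' @param labels optional data frame of trial labels (`role`, `outcome`).
#' @param region region label.
#' @return A `region_data` whose per-trial matrices are the evoked segments
#'   (`n_voxels x length(hrf)`), with onsets recorded in the labels.
#' @export
reconstruct_timeseries <- function(betas, hrf, onsets,
                                   n_scan = max(onsets) + length(hrf),
                                   labels = NULL, region = "region") {
  betas <- as.matrix(betas)
  if (any(!is.finite(hrf))) {
    stop_rdmem("HRF kernel must be finite", class = "rdmem_validation")
  }
  n_trials <- ncol(betas)
  if (length(onsets) != n_trials) {
    stop_rdmem("one onset per trial required", class = "rdmem_validation")
  }
  if (any(onsets < 1) || any(onsets + length(hrf) - 1 > n_scan)) {
    stop_rdmem("trial onset outside the scan window", class = "rdmem_bounds")
  }
  trials <- lapply(seq_len(n_trials), function(j) outer(betas[, j], hrf))
  if (is.null(labels)) {
    labels <- data.frame(trial = seq_len(n_trials),
                         role = NA_character_, outcome = NA_character_)
  } else {
    labels <- as.data.frame(labels)
    labels$trial <- seq_len(n_trials)
  }
  labels$onset <- onsets
  structure(
    list(region = region, trials = trials,
         labels = labels[, c("trial", "role", "outcome", "onset")],
         planted = NULL),
    class = "region_data"
  )
}
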