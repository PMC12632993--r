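#' Spearman rank correlation with a large-sample p-value
#'
#' Rank correlation with average ranks for ties; the p-value uses the
#' standard large-sample t approximation,
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop_rdmem("need equal-length vectors of length >= 3",
               class = "rdmem_validation")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L || length(unique(x)) == 1L ||
      length(unique(y)) == 1L) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  rho <- cor(rank(x), rank(y))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Multiplicity correction
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini--Hochberg false discovery
#' rate step-up adjustment.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param method `"bonferroni"` or `"fdr"`.
#' @return adjusted p-values, same order as the input.
#' @export
adjust_pvalues <- function(pvals, method = c("bonferroni", "fdr")) {
  method <- match.arg(method)
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop_rdmem("p-values must lie in [0, 1]", class = "rdmem_validation")
  }
  p.adjust(pvals, method = if (method == "fdr") "BH" else "bonferroni")
}

#' Mixed-effects model of lure discrimination on lossiness
#'
#' Fits the bin-level random-intercept model
#' `LDI ~ lossiness (+ age) + (1 | participant)` by REML (lme4, with
#' Satterthwaite p-values via lmerTest). Age enters only for samples that
#' span a meaningful age range. A singular random-effects fit is flagged
#' and accompanied by a fixed-effects-only least-squares fit, reported
#' separately.
#'
#' @param bin_table output of [bin_and_aggregate()] (columns `ldi`,
#'   `lossiness`, `participant`, optionally `age`).
#' @param include_age add the age covariate.
#' @param reml fit by REML (default) or ML.
#' @return object of class `mixed_ldi_fit`: list with `coefficients`
#'   (estimate, SE, df, t, p per fixed effect), `ranef_var`,
#'   `residual_var`, `n_obs`, `n_participants`, `singular`, `fallback`
#'   (lm fit when singular), `model`.
#' @export
fit_mixed_ldi <- function(bin_table, include_age = FALSE, reml = TRUE) {
  need <- c("ldi", "lossiness", "participant")
  if (include_age) need <- c(need, "age")
  if (!all(need %in% names(bin_table))) {
    stop_rdmem("bin table lacks columns: ",
               paste(setdiff(need, names(bin_table)), collapse = ", "),
               class = "rdmem_schema")
  }
  bin_table <- bin_table[stats::complete.cases(bin_table[, need]), ,
                         drop = FALSE]
  if (length(unique(bin_table$participant)) < 2L) {
    stop_rdmem("need >= 2 participants", class = "rdmem_validation")
  }
  fml <- if (include_age) {
    ldi ~ lossiness + age + (1 | participant)
  } else {
    ldi ~ lossiness + (1 | participant)
  }
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(fml, data = bin_table, REML = reml)
  ))
  singular <- lme4::isSingular(fit)
  ct <- as.data.frame(summary(fit)$coefficients)
  names(ct) <- c("estimate", "se", "df", "t", "p")
  vc <- as.data.frame(lme4::VarCorr(fit))
  fallback <- NULL
  if (singular) {
    fml_lm <- if (include_age) ldi ~ lossiness + age else ldi ~ lossiness
    fallback <- lm(fml_lm, data = bin_table)
  }
  structure(
    list(coefficients = ct,
         ranef_var = vc$vcov[vc$grp == "participant"],
         residual_var = vc$vcov[vc$grp == "Residual"],
         n_obs = nrow(bin_table),
         n_participants = length(unique(bin_table$participant)),
         singular = singular, fallback = fallback, reml = reml,
         model = fit),
    class = "mixed_ldi_fit"
  )
}

#' @export
print.mixed_ldi_fit <- function(x, ...) {
  cat(sprintf(
    "<mixed_ldi_fit> %d obs, %d participants | REML %s | singular %s\n",
    x$n_obs, x$n_participants, x$reml, x$singular))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.mixed_ldi_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  rownames(object$coefficients))
}

#' Penalized-spline GAM of lure discrimination with age modulation
#'
#' Fits `LDI ~ s(lossiness, k = 4) + s(lossiness, by = age, k = 4)` with
#' mgcv, REML smoothing selection: a main smooth of lossiness plus a
#' varying-coefficient smooth whose effect scales with (continuous) age,
#' capturing linear and nonlinear lossiness effects and their age
#' modulation while penalizing over-fit. With a purely linear planted
#' relation the main smooth's effective degrees of freedom shrink toward
#' 1 and the age term toward 0.
#'
#' @param table data frame with `ldi`, `lossiness`, `age` columns.
#' @param k basis dimension per smooth (default 4).
#' @return object of class `gam_ldi_fit`: list with `smooths` (per-smooth
#'   edf, F, p), `intercept`, `method` (`"REML"`), `r_sq`, `model`.
#' @export
fit_gam_ldi <- function(table, k = 4L) {
  need <- c("ldi", "lossiness", "age")
  if (!all(need %in% names(table))) {
    stop_rdmem("table lacks columns: ",
               paste(setdiff(need, names(table)), collapse = ", "),
               class = "rdmem_schema")
  }
  table <- table[stats::complete.cases(table[, need]), , drop = FALSE]
  if (length(unique(table$lossiness)) < k) {
    stop_rdmem("fewer unique lossiness values than basis functions",
               class = "rdmem_basis")
  }
  fit <- mgcv::gam(ldi ~ s(lossiness, k = k) + s(lossiness, by = age, k = k),
                   data = table, method = "REML")
  st <- summary(fit)$s.table
  smooths <- data.frame(
    term = rownames(st), edf = st[, "edf"], F = st[, "F"],
    p = st[, "p-value"], row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(smooths = smooths, intercept = unname(coef(fit)[1]),
         method = "REML", k = k, r_sq = summary(fit)$r.sq, model = fit),
    class = "gam_ldi_fit"
  )
}

#' @export
print.gam_ldi_fit <- function(x, ...) {
  cat(sprintf("<gam_ldi_fit> REML, k = %d per smooth, adj. R^2 %.3f\n",
              x$k, x$r_sq))
  print(transform(x$smooths, edf = round(edf, 2), F = round(F, 2),
                  p = signif(p, 3)))
  invisible(x)
}

#' @export
predict.gam_ldi_fit <- function(object, newdata, ...) {
  predict(object$model, newdata = newdata, ...)
}

#' Bootstrap contrast of a reference region against the rest
#'
#' Tests whether a reference region's per-participant values (e.g.
#' region--behavior correlation contributions) differ from the mean of the
#' other regions: the statistic is the participant-mean of
#' `reference - mean(others)`, participants are resampled with
#' replacement, and a percentile 95 percent confidence interval and
#' two-sided bootstrap p-value are reported.
#'
#' @param values_by_region named list of equal-length numeric vectors,
#'   participant-aligned across regions.
#' @param reference name of the reference region.
#' @param n_iter bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @return object of class `bootstrap_contrast`: list with `observed`,
#'   `boot_mean`, `ci` (percentile 95 percent), `p`, `n_iter`, `seed`,
#'   `degenerate` flag (TRUE when `n_iter` is too small for a meaningful
#'   interval).
#' @export
bootstrap_contrast <- function(values_by_region, reference,
                               n_iter = 10000L, seed = 1L) {
  n_iter <- check_count(n_iter, "n_iter")
  if (!reference %in% names(values_by_region)) {
    stop_rdmem("unknown reference region", class = "rdmem_validation")
  }
  others <- values_by_region[setdiff(names(values_by_region), reference)]
  if (length(others) < 2L) {
    stop_rdmem("need >= 2 non-reference regions",
               class = "rdmem_validation")
  }
  lens <- vapply(values_by_region, length, integer(1))
  if (length(unique(lens)) != 1L) {
    stop_rdmem("regions are not participant-aligned",
               class = "rdmem_alignment")
  }
  ref <- values_by_region[[reference]]
  other_mean <- rowMeans(do.call(cbind, others))
  diff_i <- ref - other_mean
  n <- length(diff_i)
  observed <- mean(diff_i)
  boot <- with_seed(seed, {
    vapply(seq_len(n_iter), function(b) {
      mean(diff_i[sample.int(n, n, replace = TRUE)])
    }, numeric(1))
  })
  ci <- unname(quantile(boot, c(0.025, 0.975)))
  p <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))
  degenerate <- n_iter < 100L
  if (degenerate) {
    warning("n_iter too small for a stable interval; flagged degenerate")
  }
  structure(
    list(observed = observed, boot_mean = mean(boot), ci = ci, p = p,
         n_iter = n_iter, seed = check_seed(seed),
         degenerate = degenerate),
    class = "bootstrap_contrast"
  )
}

#' @export
print.bootstrap_contrast <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_contrast> diff %.4f [95%% CI %.4f, %.4f], p = %.4g (%d iterations)\n",
    x$observed, x$ci[1], x$ci[2], x$p, x$n_iter))
  invisible(x)
}
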