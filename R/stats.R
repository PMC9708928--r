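# Cohort-level statistics: gestational-age trends, group comparisons,
# lesion-burden analysis and brain-placenta correlations.

#' Ordinary least-squares regression with confidence band
#'
#' Simple linear regression y ~ x with the slope's two-sided t-test,
#' coefficient of determination, and the pointwise confidence band of the
#' mean response.
#'
#' @param x,y Numeric vectors (n >= 3, x not constant).
#' @param conf Confidence level for the band and the slope CI, default 0.95.
#' @param band_x Abscissae for the band; defaults to a 50-point grid over
#'   the range of `x`.
#' @return Object of class `placseg_linreg`: `slope`, `slope_se`,
#'   `slope_ci`, `intercept`, `r_squared`, `p_value`, `n`, `ci_band`
#'   (data.frame x, fit, lwr, upr).
#' @export
linreg <- function(x, y, conf = 0.95, band_x = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_placseg("linreg needs n >= 3 complete observations")
  if (stats::sd(x) == 0) stop_placseg("predictor is constant")
  fit <- stats::lm(y ~ x)
  # exact fits are legitimate inputs here; the degenerate cases are handled
  # explicitly below, so summary()'s perfect-fit warning is noise
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  se <- sm$coefficients[2, 2]
  p <- sm$coefficients[2, 4]
  r2 <- sm$r.squared
  if (stats::sd(y) == 0) { r2 <- 0; p <- 1 }       # flat response
  else if (sm$sigma == 0) p <- 0                   # exact non-trivial fit
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 2)
  if (is.null(band_x)) band_x <- seq(min(x), max(x), length.out = 50)
  pr <- stats::predict(fit, newdata = data.frame(x = band_x),
                       interval = "confidence", level = conf)
  structure(list(slope = slope, slope_se = se,
                 slope_ci = c(slope - tcrit * se, slope + tcrit * se),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2,
                 p_value = p, n = n,
                 ci_band = data.frame(x = band_x, fit = pr[, "fit"],
                                      lwr = pr[, "lwr"], upr = pr[, "upr"])),
            class = "placseg_linreg")
}

#' @export
print.placseg_linreg <- function(x, ...) {
  cat(sprintf("slope %.4g +/- %.3g, intercept %.4g, R^2 = %.3f, P = %.3g (n = %d)\n",
              x$slope, x$slope_se, x$intercept, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Mann-Whitney U-test
#'
#' U computed from midranks; the two-sided p-value is exact for small
#' samples (full enumeration of group assignments when ties are present and
#' the number of combinations is feasible, the exact untied U distribution
#' otherwise) and a tie-corrected normal approximation with continuity
#' correction for larger samples.
#'
#' @param a,b Numeric samples (non-empty).
#' @param exact_limit Use an exact method when `n1 * n2 <= exact_limit`
#'   (default 400).
#' @return Object of class `placseg_mwtest`: `u_statistic` (U of the first
#'   sample), `p_value`, `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney <- function(a, b, exact_limit = 400) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L) stop_placseg("empty sample")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  umin <- min(u, n1 * n2 - u)

  if (n1 * n2 <= exact_limit) {
    if (!ties) {
      p <- min(1, 2 * stats::pwilcox(umin, n1, n2))
      return(structure(list(u_statistic = u, p_value = p, method = "exact"),
                       class = "placseg_mwtest"))
    }
    ncomb <- choose(n, n1)
    if (ncomb <= 2e5) {
      idx <- utils::combn(n, n1)
      uvals <- apply(idx, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
      p <- mean(uvals <= umin | uvals >= n1 * n2 - umin)
      return(structure(list(u_statistic = u, p_value = p, method = "exact"),
                       class = "placseg_mwtest"))
    }
  }
  # tie-corrected normal approximation with continuity correction
  tt <- table(c(a, b))
  tiecor <- sum(tt^3 - tt) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tiecor)
  mu <- n1 * n2 / 2
  if (sigma2 <= 0) {
    p <- 1
  } else {
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  }
  structure(list(u_statistic = u, p_value = p, method = "normal_approx"),
            class = "placseg_mwtest")
}

#' @export
print.placseg_mwtest <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f, P = %.4g (%s)\n",
              x$u_statistic, x$p_value, x$method))
  invisible(x)
}

# Gestational-age bins: lower edges closed, so GA exactly 25 falls in the
# middle bin and 35 in the upper one.
ga_bins <- function(ga, breaks = c(25, 35)) {
  cut(ga, breaks = c(-Inf, breaks, Inf), right = FALSE,
      labels = c(sprintf("<%g", breaks[1]),
                 sprintf("%g-%g", breaks[1], breaks[2]),
                 sprintf(">%g", breaks[2])))
}

#' Gestational-age-binned group comparisons
#'
#' Splits subjects into GA bins (default < 25, 25-35, > 35 weeks; lower
#' edges closed) and runs a Mann-Whitney test on the chosen column for
#' every pair of non-empty bins.
#'
#' @param records Subject data.frame with a `ga_mri_weeks` column.
#' @param value_col Name of the column to compare (e.g. `"t2star_IVS"`).
#' @param breaks Inner bin edges (weeks), default `c(25, 35)`.
#' @return data.frame with one row per bin pair: bins, sample sizes, U, p,
#'   method; pairs with an empty bin are skipped with a warning.
#' @export
ga_binned_comparison <- function(records, value_col, breaks = c(25, 35)) {
  if (!value_col %in% names(records)) stop_placseg("no column '%s'", value_col)
  bins <- ga_bins(records$ga_mri_weeks, breaks)
  lv <- levels(bins)
  out <- list()
  for (i in seq_len(length(lv) - 1)) for (j in seq((i + 1), length(lv))) {
    va <- records[[value_col]][bins == lv[i]]
    vb <- records[[value_col]][bins == lv[j]]
    va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
    if (length(va) == 0L || length(vb) == 0L) {
      warn_placseg("skipping %s vs %s: empty bin", lv[i], lv[j])
      next
    }
    tst <- mann_whitney(va, vb)
    out[[length(out) + 1L]] <- data.frame(
      bin1 = lv[i], bin2 = lv[j], n1 = length(va), n2 = length(vb),
      u_statistic = tst$u_statistic, p_value = tst$p_value,
      method = tst$method, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Lesion-burden group analysis
#'
#' Mann-Whitney comparison of the lesion (PL) volume fraction between
#' healthy and complicated subjects, and pooled OLS regression of PL
#' fraction on gestational age at delivery.
#'
#' @param records Subject data.frame with `pl_fraction`, `group`
#'   (`"healthy"` / `"complicated"`) and `ga_delivery_weeks` columns.
#' @return List: `group_test` (`placseg_mwtest`), `delivery_regression`
#'   (`placseg_linreg`).
#' @export
pl_group_analysis <- function(records) {
  h <- records$pl_fraction[records$group == "healthy"]
  c_ <- records$pl_fraction[records$group == "complicated"]
  if (length(h) == 0L || length(c_) == 0L)
    stop_placseg("both groups must be non-empty")
  list(group_test = mann_whitney(c_, h),
       delivery_regression = linreg(records$ga_delivery_weeks,
                                    records$pl_fraction))
}

#' Brain-placenta T2* correlations
#'
#' OLS regression of fetal-brain T2* on each placental compartment's T2*
#' (total, IVS, PV, PT), with compartments ranked by R-squared. Records
#' missing brain values are dropped with a warning.
#'
#' @param records Subject data.frame with `brain_t2star_ms` and
#'   `t2star_total`, `t2star_IVS`, `t2star_PV`, `t2star_PT` columns.
#' @return List: `regressions` (named list of `placseg_linreg`), `summary`
#'   (data.frame compartment, slope, r_squared, p_value ordered by
#'   descending R^2), `best` (compartment name with highest R^2).
#' @export
brain_placenta_correlations <- function(records) {
  comps <- c("total", "IVS", "PV", "PT")
  miss <- !is.finite(records$brain_t2star_ms)
  if (any(miss)) {
    warn_placseg("dropping %d records without brain T2*", sum(miss))
    records <- records[!miss, , drop = FALSE]
  }
  if (nrow(records) < 3L) stop_placseg("need >= 3 records with brain T2*")
  regs <- list()
  for (cc in comps) {
    col <- paste0("t2star_", cc)
    if (!col %in% names(records)) stop_placseg("no column '%s'", col)
    regs[[cc]] <- linreg(records[[col]], records$brain_t2star_ms)
  }
  summ <- data.frame(
    compartment = comps,
    slope = vapply(regs, `[[`, numeric(1), "slope"),
    r_squared = vapply(regs, `[[`, numeric(1), "r_squared"),
    p_value = vapply(regs, `[[`, numeric(1), "p_value"),
    stringsAsFactors = FALSE)
  summ <- summ[order(-summ$r_squared), ]
  rownames(summ) <- NULL
  list(regressions = regs, summary = summ, best = summ$compartment[1])
}

#' Fetal-brain volume and mean T2*
#'
#' @param t2map A `placseg_t2map` (volumetric) or numeric array of T2*.
#' @param brain_mask 3-D logical array.
#' @param voxel_size Voxel dimensions in mm.
#' @return List: `volume_cm3`, `mean_t2star_ms`, `n_voxels` (valid-fit
#'   voxels contributing to the mean).
#' @export
summarize_brain <- function(t2map, brain_mask, voxel_size = c(1, 1, 1)) {
  if (!any(brain_mask)) stop_placseg("brain mask is empty")
  if (inherits(t2map, "placseg_t2map")) {
    vals <- t2map$t2star[brain_mask & t2map$fit_valid]
  } else {
    vals <- t2map[brain_mask]
  }
  vals <- vals[is.finite(vals)]
  list(volume_cm3 = sum(brain_mask) * prod(voxel_size) / 1000,
       mean_t2star_ms = if (length(vals)) mean(vals) else NA_real_,
       n_voxels = length(vals))
}

#' Per-layer gestational-age trends
#'
#' OLS of each depth layer's compartment mean (typically PV T2*) on
#' gestational age, one regression per layer.
#'
#' @param layer_records Long data.frame with columns `subject_id`,
#'   `ga_mri_weeks`, `layer`, `mean`.
#' @param min_n Minimum subjects per layer (default 3).
#' @return data.frame(layer, slope, slope_se, ci_lwr, ci_upr, r_squared,
#'   p_value, n); layers observed in fewer than half the subjects are
#'   omitted with a warning.
#' @export
layerwise_trend <- function(layer_records, min_n = 3L) {
  need <- c("subject_id", "ga_mri_weeks", "layer", "mean")
  if (!all(need %in% names(layer_records)))
    stop_placseg("layer_records must have columns %s", paste(need, collapse = ", "))
  n_subj <- length(unique(layer_records$subject_id))
  out <- list()
  for (ly in unique(as.character(layer_records$layer))) {
    d <- layer_records[as.character(layer_records$layer) == ly, ]
    d <- d[is.finite(d$mean), ]
    if (nrow(d) < max(min_n, ceiling(n_subj / 2))) {
      warn_placseg("layer %s observed in %d of %d subjects; omitted", ly,
                   nrow(d), n_subj)
      next
    }
    fit <- linreg(d$ga_mri_weeks, d$mean)
    out[[length(out) + 1L]] <- data.frame(
      layer = ly, slope = fit$slope, slope_se = fit$slope_se,
      ci_lwr = fit$slope_ci[1], ci_upr = fit$slope_ci[2],
      r_squared = fit$r_squared, p_value = fit$p_value, n = fit$n,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop_placseg("no layer had enough subjects")
  res <- do.call(rbind, out)
  res[order(res$layer), ]
}
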