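# Voxel-wise T2* estimation from multi-echo gradient-echo magnitude data.

#' Fit the mono-exponential T2* decay model
#'
#' Estimates per-voxel T2* and S0 from S(TE) = S0 exp(-TE/T2*) by weighted
#' log-linear least squares: ln S regressed on TE with weights proportional
#' to the squared signal (the variance-stabilizing choice for
#' log-transformed magnitude data), in two passes -- observed-signal
#' weights first, then weights from the predicted decay, which removes the
#' correlation between weights and noise. Voxels with fewer than 3 positive
#' echoes, a
#' non-positive estimated decay rate, or T2* above `cap` are flagged
#' invalid rather than raising an error; invalid voxels must be excluded
#' from downstream statistics.
#'
#' @param signals 4-D array (x, y, z, echo) or matrix (voxel x echo) of
#'   magnitude signals.
#' @param echo_times Echo times in ms, strictly increasing, length >= 3.
#' @param mask Optional 3-D logical array restricting the fit.
#' @param cap Upper bound (ms) on physically plausible T2*; default 300.
#' @param weighted Use S^2 weights (default) or unweighted log-linear fit.
#' @return Object of class `placseg_t2map`: `t2star`, `s0`, `fit_valid`
#'   (arrays matching the spatial grid, or vectors for matrix input).
#' @export
fit_t2star <- function(signals, echo_times, mask = NULL, cap = 300,
                       weighted = TRUE) {
  te <- as.numeric(echo_times)
  if (length(te) < 3L || any(diff(te) <= 0) || any(te <= 0))
    stop_placseg("echo_times must be >= 3 strictly increasing positive values")
  spatial <- NULL
  if (is.matrix(signals)) {
    S <- signals
  } else {
    dm <- dim(signals)
    if (length(dm) != 4L || dm[4] != length(te))
      stop_placseg("signals must be (x, y, z, echo) with %d echoes", length(te))
    spatial <- dm[1:3]
    S <- matrix(signals, prod(spatial), dm[4])
    if (!is.null(mask)) {
      if (!identical(dim(mask), spatial))
        stop_placseg("mask grid does not match signal grid")
      if (!any(mask)) stop_placseg("mask is empty")
      keep <- which(mask)
      S <- S[keep, , drop = FALSE]
    } else keep <- seq_len(nrow(S))
  }
  if (ncol(S) != length(te)) stop_placseg("echo count mismatch")

  pos <- is.finite(S) & S > 0
  y <- log(ifelse(pos, S, NA_real_))
  TE <- matrix(te, nrow(S), length(te), byrow = TRUE)
  wlls <- function(w) {
    sw <- rowSums(w)
    swx <- rowSums(w * TE)
    swxx <- rowSums(w * TE^2)
    swy <- rowSums(w * y, na.rm = TRUE)
    swxy <- rowSums(w * TE * y, na.rm = TRUE)
    det <- sw * swxx - swx^2
    list(slope = (sw * swxy - swx * swy) / det,
         intercept = (swxx * swy - swx * swxy) / det)
  }
  if (weighted) {
    # two-pass weighted fit: observed-signal weights first, then weights
    # from the predicted decay (removes the weight-noise correlation bias)
    f1 <- wlls(ifelse(pos, S^2, 0))
    pred <- exp(2 * (f1$intercept + f1$slope * TE))
    pred[!pos | !is.finite(pred)] <- 0
    refit <- is.finite(f1$slope) & f1$slope < 0
    f2 <- wlls(pred * refit)
    slope <- ifelse(refit & is.finite(f2$slope), f2$slope, f1$slope)
    intercept <- ifelse(refit & is.finite(f2$slope), f2$intercept, f1$intercept)
  } else {
    f1 <- wlls(ifelse(pos, 1, 0))
    slope <- f1$slope
    intercept <- f1$intercept
  }
  rate <- -slope                       # 1/T2* in 1/ms
  t2star <- 1 / rate
  s0 <- exp(intercept)
  valid <- rowSums(pos) >= 3L & is.finite(rate) & rate > 0 & t2star <= cap
  t2star[!valid] <- NA_real_
  s0[!valid] <- NA_real_

  if (!is.null(spatial)) {
    out_t2 <- array(NA_real_, spatial)
    out_s0 <- array(NA_real_, spatial)
    out_valid <- array(FALSE, spatial)
    out_t2[keep] <- t2star
    out_s0[keep] <- s0
    out_valid[keep] <- valid
    t2star <- out_t2; s0 <- out_s0; valid <- out_valid
  }
  structure(list(t2star = t2star, s0 = s0, fit_valid = valid, cap = cap),
            class = "placseg_t2map")
}
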