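# Voxel-wise diffusion-tensor fitting and derived metrics.

#' Diffusion acquisition scheme
#'
#' @param bvals Numeric b-values in s/mm2; at least one zero and at least
#'   six non-zero measurements.
#' @param bvecs Matrix (measurement x 3) of gradient directions; unit norm
#'   for non-zero b (within 1e-6), rows for b = 0 may be zero vectors.
#' @return Object of class `placseg_scheme`.
#' @export
diffusion_scheme <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- unname(as.matrix(bvecs))
  if (nrow(bvecs) != length(bvals) || ncol(bvecs) != 3L)
    stop_placseg("bvecs must be a (n x 3) matrix matching bvals")
  if (!any(bvals == 0)) stop_placseg("scheme needs at least one b = 0 measurement")
  nz <- bvals > 0
  if (sum(nz) < 6L) stop_placseg("scheme needs >= 6 diffusion-weighted measurements")
  nrm <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop_placseg("non-zero-b gradient directions must be unit vectors")
  # distinct directions up to sign
  dirs <- bvecs[nz, , drop = FALSE]
  canon <- t(apply(dirs, 1, function(v) if (v[which.max(abs(v))] < 0) -v else v))
  if (nrow(unique(round(canon, 6))) < 6L)
    stop_placseg("scheme needs >= 6 distinct (non-collinear) directions")
  if (qr(dirs)$rank < 3L) stop_placseg("gradient directions do not span 3-D space")
  structure(list(bvals = bvals, bvecs = bvecs), class = "placseg_scheme")
}

# Analytic eigenvalues of symmetric 3x3 tensors (trigonometric method),
# vectorized over voxels; columns of `d6`: xx, yy, zz, xy, xz, yz.
# Returns matrix (n x 3) sorted descending.
eig3_sym <- function(d6) {
  dxx <- d6[, 1]; dyy <- d6[, 2]; dzz <- d6[, 3]
  dxy <- d6[, 4]; dxz <- d6[, 5]; dyz <- d6[, 6]
  q <- (dxx + dyy + dzz) / 3
  p1 <- dxy^2 + dxz^2 + dyz^2
  p2 <- (dxx - q)^2 + (dyy - q)^2 + (dzz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  l1 <- l2 <- l3 <- q
  nz <- p > .Machine$double.eps * pmax(abs(q), 1)
  if (any(nz)) {
    bxx <- (dxx - q) / p; byy <- (dyy - q) / p; bzz <- (dzz - q) / p
    bxy <- dxy / p; bxz <- dxz / p; byz <- dyz / p
    detB <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1[nz] <- (q + 2 * p * cos(phi))[nz]
    l3[nz] <- (q + 2 * p * cos(phi + 2 * pi / 3))[nz]
    l2[nz] <- (3 * q - l1 - l3)[nz]
  }
  cbind(l1, l2, l3)
}

# FA of an eigenvalue triple; 0 when the tensor is null.
fa_from_eigs <- function(eigs) {
  lbar <- rowMeans(eigs)
  num <- (eigs[, 1] - lbar)^2 + (eigs[, 2] - lbar)^2 + (eigs[, 3] - lbar)^2
  den <- rowSums(eigs^2)
  fa <- sqrt(1.5 * num / pmax(den, .Machine$double.eps))
  fa[den == 0] <- 0
  pmin(fa, 1)
}

#' Fit the diffusion-tensor model
#'
#' Log-linear least-squares fit of ln S = ln S0 - b g' D g per voxel, with
#' eigen-decomposition (sorted descending) and the standard derived
#' metrics: AD = lambda1, RD = (lambda2 + lambda3)/2, ADC = mean(lambda),
#' FA = sqrt(3/2) ||lambda - mean|| / ||lambda||. Negative eigenvalues are
#' clipped to zero for the metrics and the voxel is flagged. Voxels with a
#' non-positive signal in any measurement are flagged invalid.
#'
#' @param dwi 4-D array (x, y, z, measurement) or matrix (voxel x
#'   measurement) of magnitude signals.
#' @param scheme A [diffusion_scheme()].
#' @param mask Optional 3-D logical array restricting the fit.
#' @param weighted Single-pass weighted least squares with weights
#'   proportional to the squared signal (default), the variance-stabilizing
#'   choice for log-transformed magnitude data; `FALSE` gives the plain
#'   log-linear fit. Noiseless recovery is exact either way.
#' @return Object of class `placseg_tensormap` with per-voxel `tensor`
#'   (n x 6 matrix, columns xx, yy, zz, xy, xz, yz, units 1e-3 mm2/s),
#'   `eigenvalues`, `adc`, `fa`, `ad`, `rd`, `fit_valid`, `clipped`, and
#'   (for 4-D input) the spatial grid layout.
#' @export
fit_tensor <- function(dwi, scheme, mask = NULL, weighted = TRUE) {
  if (!inherits(scheme, "placseg_scheme")) stop_placseg("scheme must be a diffusion_scheme()")
  bv <- scheme$bvals; g <- scheme$bvecs
  spatial <- NULL
  if (is.matrix(dwi)) {
    S <- dwi
    keep <- seq_len(nrow(S))
  } else {
    dm <- dim(dwi)
    if (length(dm) != 4L || dm[4] != length(bv))
      stop_placseg("dwi must be (x, y, z, measurement) with %d measurements", length(bv))
    spatial <- dm[1:3]
    S <- matrix(dwi, prod(spatial), dm[4])
    if (!is.null(mask)) {
      if (!identical(dim(mask), spatial)) stop_placseg("mask grid does not match dwi grid")
      if (!any(mask)) stop_placseg("mask is empty")
      keep <- which(mask)
      S <- S[keep, , drop = FALSE]
    } else keep <- seq_len(nrow(S))
  }
  if (ncol(S) != length(bv)) stop_placseg("measurement count mismatch")

  # design: ln S = [1, -b gx^2, -b gy^2, -b gz^2, -2b gxgy, -2b gxgz, -2b gygz]
  #               . [ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz]  (D in 1e-3 mm2/s)
  X <- cbind(1,
             -bv * g[, 1]^2 * 1e-3,
             -bv * g[, 2]^2 * 1e-3,
             -bv * g[, 3]^2 * 1e-3,
             -2 * bv * g[, 1] * g[, 2] * 1e-3,
             -2 * bv * g[, 1] * g[, 3] * 1e-3,
             -2 * bv * g[, 2] * g[, 3] * 1e-3)
  qx <- qr(X)
  if (qx$rank < 7L) stop_placseg("rank-deficient diffusion design matrix")

  valid <- rowSums(!is.finite(S) | S <= 0) == 0L
  Y <- t(log(pmax(S, .Machine$double.xmin)))
  if (weighted) {
    d6 <- matrix(NA_real_, nrow(S), 6)
    vrows <- which(valid)
    for (i in vrows) {
      cf <- tryCatch({
        c1 <- stats::lm.wfit(X, Y[, i], S[i, ]^2)$coefficients
        w2 <- exp(2 * as.numeric(X %*% c1))   # predicted-signal weights
        stats::lm.wfit(X, Y[, i], w2)$coefficients
      }, error = function(e) rep(NA_real_, 7))
      d6[i, ] <- cf[2:7]
    }
    # invalid voxels: unweighted estimate so downstream shapes stay filled
    if (any(!valid)) {
      cf <- qr.coef(qx, Y[, !valid, drop = FALSE])
      d6[!valid, ] <- t(cf[2:7, , drop = FALSE])
    }
  } else {
    coef <- qr.coef(qx, Y)            # 7 x n
    d6 <- t(coef[2:7, , drop = FALSE])
  }
  colnames(d6) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  eigs <- eig3_sym(d6)
  clipped <- eigs[, 3] < 0 | eigs[, 2] < 0 | eigs[, 1] < 0
  ceigs <- pmax(eigs, 0)
  dim(ceigs) <- dim(eigs)
  adc <- rowMeans(ceigs)
  ad <- ceigs[, 1]
  rd <- (ceigs[, 2] + ceigs[, 3]) / 2
  fa <- fa_from_eigs(ceigs)
  fit_valid <- valid & !clipped & is.finite(adc)
  adc[!valid] <- NA_real_; ad[!valid] <- NA_real_
  rd[!valid] <- NA_real_; fa[!valid] <- NA_real_

  to_vol <- function(v) {
    if (is.null(spatial)) return(v)
    out <- array(NA_real_, spatial); out[keep] <- v; out
  }
  structure(list(tensor = d6, eigenvalues = eigs,
                 adc = to_vol(adc), fa = to_vol(fa),
                 ad = to_vol(ad), rd = to_vol(rd),
                 fit_valid = if (is.null(spatial)) fit_valid else {
                   out <- array(FALSE, spatial); out[keep] <- fit_valid; out
                 },
                 clipped = if (is.null(spatial)) clipped else {
                   out <- array(FALSE, spatial); out[keep] <- clipped; out
                 },
                 voxel_index = keep, spatial = spatial),
            class = "placseg_tensormap")
}
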