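# Fuzzy Gaussian-mixture segmentation of the 5-feature voxel space.
#
# The model is a K-component full-covariance Gaussian mixture fitted by
# expectation-maximization on z-scored features. Soft (fuzzy) membership is
# the posterior responsibility; voxels atypical for every component -- the
# upper-tail chi-square(5) probability of the squared Mahalanobis distance
# below `alpha` for all components -- form the lesion (PL) cluster.

#' Assemble the clustering feature table
#'
#' Collects per-voxel (ADC, FA, AD, RD, T2*) from fitted maps into a matrix
#' of finite rows with a voxel back-map (0-based linear indices are not
#' used; indices are 1-based into the spatial grid).
#'
#' @param t2map A `placseg_t2map` from [fit_t2star()].
#' @param tensormap A `placseg_tensormap` from [fit_tensor()].
#' @param mask 3-D logical array of placental voxels.
#' @return Object of class `placseg_features`: `x` (n x 5 matrix),
#'   `voxel_index` (linear indices into the grid), `dim`.
#' @export
extract_features <- function(t2map, tensormap, mask) {
  stopifnot(inherits(t2map, "placseg_t2map"), inherits(tensormap, "placseg_tensormap"))
  if (!is.array(t2map$t2star)) stop_placseg("extract_features needs volumetric maps")
  dm <- dim(t2map$t2star)
  if (!identical(dim(mask), dm)) stop_placseg("mask grid does not match maps")
  ok <- mask & t2map$fit_valid & tensormap$fit_valid
  idx <- which(ok)
  if (length(idx) == 0L) stop_placseg("no valid voxels in mask")
  x <- cbind(ADC = tensormap$adc[idx], FA = tensormap$fa[idx],
             AD = tensormap$ad[idx], RD = tensormap$rd[idx],
             T2star = t2map$t2star[idx])
  fin <- rowSums(!is.finite(x)) == 0L
  structure(list(x = x[fin, , drop = FALSE], voxel_index = idx[fin], dim = dm),
            class = "placseg_features")
}

as_feature_matrix <- function(features) {
  if (inherits(features, "placseg_features")) return(features$x)
  x <- as.matrix(features)
  if (any(!is.finite(x))) stop_placseg("feature matrix contains non-finite values")
  x
}

# log N(x; mu, Sigma) for all rows of x, via Cholesky.
log_dnorm_mv <- function(x, mu, chol_sigma) {
  p <- ncol(x)
  z <- backsolve(chol_sigma, t(x) - mu, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(chol_sigma))) - 0.5 * p * log(2 * pi)
}

# squared Mahalanobis distance of rows of x to (mu, Sigma)
mahal2 <- function(x, mu, chol_sigma) {
  z <- backsolve(chol_sigma, t(x) - mu, transpose = TRUE)
  colSums(z^2)
}

# k-means++ seeding: K distinct data rows, probability proportional to
# squared distance to the nearest chosen centre. Caller owns the RNG.
kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(NA_real_, K, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums((x - rep(centers[1L, ], each = n))^2)
  if (K > 1L) for (k in 2:K) {
    pr <- pmax(d2, 0)
    if (sum(pr) <= 0) pr <- rep(1, n)
    i <- sample.int(n, 1L, prob = pr)
    centers[k, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - rep(centers[k, ], each = n))^2))
  }
  centers
}

em_once <- function(x, K, max_iter, tol, ridge) {
  n <- nrow(x); p <- ncol(x)
  centers <- kmeanspp_centers(x, K)
  # one-hot responsibilities by nearest centre
  d2 <- sapply(seq_len(K), function(k) rowSums((x - rep(centers[k, ], each = n))^2))
  gamma <- matrix(0, n, K)
  gamma[cbind(seq_len(n), max.col(-d2))] <- 1

  weights <- numeric(K); means <- matrix(0, K, p)
  covs <- vector("list", K); chols <- vector("list", K)
  loglik_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    # M step
    nk <- colSums(gamma)
    if (any(nk < p + 1)) return(list(ok = FALSE, reason = "empty component"))
    weights <- nk / n
    for (k in seq_len(K)) {
      mu <- colSums(gamma[, k] * x) / nk[k]
      xc <- x - rep(mu, each = n)
      sg <- crossprod(xc * gamma[, k], xc) / nk[k]
      sg <- sg + diag(ridge * sum(diag(sg)) / p, p)
      ch <- tryCatch(chol(sg), error = function(e) NULL)
      if (is.null(ch)) return(list(ok = FALSE, reason = "singular covariance",
                                   kappa = kappa(sg)))
      means[k, ] <- mu
      covs[[k]] <- sg
      chols[[k]] <- ch
    }
    # E step
    logd <- sapply(seq_len(K), function(k)
      log(weights[k]) + log_dnorm_mv(x, means[k, ], chols[[k]]))
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    gamma <- exp(logd - lse)
    ll <- sum(lse)
    loglik_trace <- c(loglik_trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(ok = TRUE, weights = weights, means = means, covs = covs,
       loglik = ll_old, loglik_trace = loglik_trace,
       converged = length(loglik_trace) < max_iter)
}

#' Fit the fuzzy Gaussian-mixture model
#'
#' EM on z-scored features with full covariances, a small ridge
#' (`1e-6 tr(Sigma)/p` on the diagonal each M-step) guarding the near-linear
#' dependence of ADC on AD and RD, k-means++ initialization, and the best of
#' `n_restarts` runs by final log-likelihood. The per-feature
#' standardization is stored in the model so new subjects are projected
#' consistently.
#'
#' @param features A `placseg_features` object or numeric matrix (voxel x 5).
#' @param K Number of components (>= 2 unless `allow_k1 = TRUE`).
#' @param seed Integer seed (restarts derive child seeds from it).
#' @param n_restarts EM restarts, default 5.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param ridge Relative ridge added to each covariance diagonal.
#' @param allow_k1 Permit K = 1 (degenerate single-Gaussian fit).
#' @return Object of class `placseg_mixture`: `K`, `weights`, `means` and
#'   `covariances` (standardized space), `standardizer` (center, scale),
#'   `loglik`, `loglik_trace`, `seed`, `converged`.
#' @export
fit_mixture <- function(features, K = 3L, seed = 1L, n_restarts = 5L,
                        max_iter = 200L, tol = 1e-6, ridge = 1e-6,
                        allow_k1 = FALSE) {
  x <- as_feature_matrix(features)
  K <- as.integer(K)
  if (K < 2L && !allow_k1) stop_placseg("K must be >= 2")
  if (nrow(x) < 50L * K)
    stop_placseg("need at least 50 K = %d rows, got %d", 50L * K, nrow(x))
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  if (any(scale <= 0)) stop_placseg("constant feature column: cannot standardize")
  z <- sweep(sweep(x, 2, center), 2, scale, "/")

  best <- NULL
  fails <- list()
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(child_seed(seed, r), em_once(z, K, max_iter, tol, ridge))
    if (!isTRUE(fit$ok)) { fails[[length(fails) + 1L]] <- fit; next }
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) {
    kap <- vapply(fails, function(f) f$kappa %||% NA_real_, numeric(1))
    stop_placseg("all %d EM restarts failed (%s); covariance condition numbers: %s",
                 n_restarts, paste(unique(vapply(fails, `[[`, "", "reason")),
                                   collapse = ", "),
                 paste(signif(kap, 3), collapse = ", "))
  }
  structure(list(K = K, weights = best$weights, means = best$means,
                 covariances = best$covs,
                 standardizer = list(center = center, scale = scale),
                 loglik = best$loglik, loglik_trace = best$loglik_trace,
                 converged = best$converged,
                 feature_names = colnames(x) %||% PLACSEG_FEATURES,
                 seed = as.integer(seed)),
            class = "placseg_mixture")
}

#' @export
print.placseg_mixture <- function(x, ...) {
  cat(sprintf("<Gaussian mixture: K = %d, n features = %d, loglik = %.2f, %s>\n",
              x$K, length(x$standardizer$center), x$loglik,
              if (x$converged) "converged" else "max iterations reached"))
  m <- mixture_means(x)
  rownames(m) <- sprintf("component %d (w = %.3f)", seq_len(x$K), x$weights)
  print(round(m, 3))
  invisible(x)
}

#' Component means in original feature units
#'
#' @param model A `placseg_mixture`.
#' @return K x p matrix of destandardized component means.
#' @export
mixture_means <- function(model) {
  m <- sweep(sweep(model$means, 2, model$standardizer$scale, "*"),
             2, model$standardizer$center, "+")
  colnames(m) <- model$feature_names
  m
}

standardize_features <- function(model, features) {
  x <- as_feature_matrix(features)
  sweep(sweep(x, 2, model$standardizer$center), 2, model$standardizer$scale, "/")
}

#' Posterior (fuzzy) membership probabilities
#'
#' gamma_k proportional to pi_k N(x; mu_k, Sigma_k), normalized per voxel.
#'
#' @param model A `placseg_mixture`.
#' @param features Feature table or matrix in original units.
#' @return n x K matrix of posteriors summing to 1 per row; rows with
#'   non-finite density are `NA` and flagged in `attr(, "valid")`.
#' @export
posterior_probabilities <- function(model, features) {
  z <- standardize_features(model, features)
  K <- model$K
  chols <- lapply(model$covariances, chol)
  logd <- sapply(seq_len(K), function(k)
    log(model$weights[k]) + log_dnorm_mv(z, model$means[k, ], chols[[k]]))
  logd <- matrix(logd, ncol = K)
  m <- apply(logd, 1, max)
  gamma <- exp(logd - m) / rowSums(exp(logd - m))
  valid <- is.finite(m) & rowSums(!is.finite(gamma)) == 0L
  gamma[!valid, ] <- NA_real_
  attr(gamma, "valid") <- valid
  gamma
}

#' Per-component typicality
#'
#' Upper-tail probability of the squared Mahalanobis distance to each
#' component under a chi-square law with p (= 5) degrees of freedom: the
#' probability that a voxel truly drawn from the component lies farther out
#' than observed. A voxel at a component mean has typicality 1.
#'
#' @inheritParams posterior_probabilities
#' @return n x K matrix of typicalities in \[0, 1\].
#' @export
typicality <- function(model, features) {
  z <- standardize_features(model, features)
  p <- ncol(z)
  chols <- lapply(model$covariances, chol)
  d2 <- sapply(seq_len(model$K), function(k) mahal2(z, model$means[k, ], chols[[k]]))
  d2 <- matrix(d2, ncol = model$K)
  stats::pchisq(d2, df = p, lower.tail = FALSE)
}

#' Flag outlier (lesion) voxels
#'
#' A voxel is assigned to the lesion (PL) cluster when its typicality is
#' below `alpha` for every physiological component: it is in the far tail
#' of all fitted distributions. With the default `alpha = 0.05`, a voxel
#' truly generated by the mixture is flagged with probability close to 0.05.
#'
#' @inheritParams posterior_probabilities
#' @param alpha Typicality threshold in (0, 1), default 0.05.
#' @return List: `outlier` (logical), `typicality` (n x K matrix).
#' @export
flag_outliers <- function(model, features, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop_placseg("alpha must lie in (0, 1)")
  typ <- typicality(model, features)
  list(outlier = apply(typ < alpha, 1, all), typicality = typ)
}

#' Map mixture components to named compartments
#'
#' For the K = 3 physiological model: the component with the highest mean FA
#' is the vessel compartment (PV); of the remaining two, the higher mean T2*
#' is the intervillous space (IVS) and the other placental tissue (PT).
#'
#' @param model A fitted `placseg_mixture` with K = 3.
#' @return Character vector of length 3 naming each component.
#' @export
component_compartments <- function(model) {
  if (model$K != 3L) stop_placseg("compartment naming requires K = 3")
  m <- mixture_means(model)
  fa <- m[, "FA"]; t2 <- m[, "T2star"]
  if (min(diff(sort(fa))) < 1e-6)
    stop_placseg("component FA means tied; manual compartment mapping required")
  pv <- which.max(fa)
  rest <- setdiff(seq_len(3L), pv)
  if (abs(diff(t2[rest])) < 1e-6)
    stop_placseg("component T2* means tied; manual compartment mapping required")
  ivs <- rest[which.max(t2[rest])]
  pt <- setdiff(rest, ivs)
  out <- character(3)
  out[pv] <- "PV"; out[ivs] <- "IVS"; out[pt] <- "PT"
  out
}

#' Segment placental voxels
#'
#' Fits (or applies) the mixture, computes posteriors and typicalities,
#' flags lesion voxels, and hard-labels the rest by their highest-posterior
#' component's compartment name.
#'
#' @param features A `placseg_features` or matrix.
#' @param model Optional pre-fitted `placseg_mixture` (pooled training);
#'   fitted on `features` when `NULL`.
#' @param K,seed,... Passed to [fit_mixture()] when fitting here.
#' @param alpha Outlier typicality threshold.
#' @return Object of class `placseg_segmentation`: `posterior`,
#'   `typicality`, `hard_label` (factor IVS/PV/PT/PL), `pl_fraction`,
#'   `component_names`, `model`, and `voxel_index`/`dim` when available.
#' @export
segment_placenta <- function(features, model = NULL, K = 3L, alpha = 0.05,
                             seed = 1L, ...) {
  if (is.null(model)) model <- fit_mixture(features, K = K, seed = seed, ...)
  gamma <- posterior_probabilities(model, features)
  fl <- flag_outliers(model, features, alpha = alpha)
  comp_names <- component_compartments(model)
  lab <- comp_names[max.col(gamma, ties.method = "first")]
  lab[fl$outlier] <- "PL"
  lab <- factor(lab, levels = c("IVS", "PV", "PT", "PL"))
  structure(list(posterior = gamma, typicality = fl$typicality,
                 hard_label = lab,
                 pl_fraction = mean(fl$outlier),
                 component_names = comp_names, alpha = alpha, model = model,
                 voxel_index = if (inherits(features, "placseg_features"))
                   features$voxel_index,
                 dim = if (inherits(features, "placseg_features")) features$dim),
            class = "placseg_segmentation")
}

#' Lesion-cluster volume fraction
#'
#' Fraction of placental voxels assigned to the lesion (PL) cluster; with a
#' segmentation on a 3-D grid, per-slice fractions are also reported.
#'
#' @param seg A `placseg_segmentation`.
#' @param placental_mask Optional 3-D mask: the denominator defaults to the
#'   segmented voxels; supplying the mask counts unsegmented (invalid-fit)
#'   voxels in the denominator.
#' @return List: `fraction`, and `per_slice` (data.frame) when the
#'   segmentation carries grid information.
#' @export
pl_fraction <- function(seg, placental_mask = NULL) {
  stopifnot(inherits(seg, "placseg_segmentation"))
  is_pl <- seg$hard_label == "PL"
  if (is.null(placental_mask)) {
    denom <- length(is_pl)
  } else {
    if (!any(placental_mask)) stop_placseg("placental mask is empty")
    denom <- sum(placental_mask)
  }
  out <- list(fraction = sum(is_pl) / denom)
  if (!is.null(seg$voxel_index) && !is.null(seg$dim)) {
    slice <- arrayInd(seg$voxel_index, seg$dim)[, 3]
    per <- tapply(is_pl, slice, mean)
    out$per_slice <- data.frame(slice = as.integer(names(per)),
                                fraction = as.numeric(per))
  }
  out
}

#' Match mixture components between two fits
#'
#' Optimal one-to-one assignment (minimum total squared distance between
#' component mean vectors) by enumeration over permutations; exact for the
#' small K used here.
#'
#' @param ref_means,means K x p matrices of component means.
#' @return Integer permutation `perm` such that `means[perm[k], ]`
#'   corresponds to `ref_means[k, ]`.
#' @export
match_components <- function(ref_means, means) {
  K <- nrow(ref_means)
  stopifnot(nrow(means) == K, K <= 8L)
  perms <- permutations_of(K)
  cost <- apply(perms, 1, function(p)
    sum((ref_means - means[p, , drop = FALSE])^2))
  perms[which.min(cost), ]
}

permutations_of <- function(K) {
  if (K == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(K - 1L)
  out <- matrix(0L, 0, K)
  for (i in seq_len(K)) {
    rest <- setdiff(seq_len(K), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), K - 1L)))
  }
  out
}

#' Subsampling stability of the mixture fit
#'
#' Repeatedly refits the mixture on random voxel subsamples and reports the
#' per-component, per-feature means (in original units) with their
#' coefficient of variation across repeats, components matched to the
#' full-data fit.
#'
#' @param features Feature table or matrix.
#' @param n_voxels Subsample size per repeat, default 10000.
#' @param repeats Number of repeats, default 10.
#' @param seed Integer seed.
#' @param K Components.
#' @param full_model Optional reference fit; fitted on all rows when `NULL`.
#' @param ... Passed to [fit_mixture()].
#' @return List: `means` (repeats x K x p array), `cv` (K x p matrix; `NA`
#'   when `repeats == 1`), `full_model`.
#' @export
subsample_stability <- function(features, n_voxels = 10000L, repeats = 10L,
                                seed = 1L, K = 3L, full_model = NULL, ...) {
  x <- as_feature_matrix(features)
  if (n_voxels > nrow(x))
    stop_placseg("n_voxels (%d) exceeds available rows (%d)", n_voxels, nrow(x))
  if (is.null(full_model))
    full_model <- fit_mixture(x, K = K, seed = seed, ...)
  ref <- mixture_means(full_model)
  p <- ncol(x)
  means <- array(NA_real_, c(repeats, K, p),
                 dimnames = list(NULL, NULL, colnames(x) %||% PLACSEG_FEATURES))
  for (r in seq_len(repeats)) {
    rows <- with_seed(child_seed(seed, 1000L + r),
                      sample.int(nrow(x), n_voxels))
    fit <- fit_mixture(x[rows, , drop = FALSE], K = K,
                       seed = child_seed(seed, 2000L + r), ...)
    m <- mixture_means(fit)
    perm <- match_components(ref, m)
    means[r, , ] <- m[perm, , drop = FALSE]
  }
  cv <- if (repeats > 1L) {
    apply(means, c(2, 3), stats::sd) / apply(means, c(2, 3), mean)
  } else {
    matrix(NA_real_, K, p)
  }
  list(means = means, cv = cv, full_model = full_model)
}
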