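test_that("single-component EM reduces to sample moments", {
  set.seed(1)
  x <- MASS::mvrnorm(500, mu = c(1, 2, 3, 4, 5), Sigma = diag(5))
  colnames(x) <- c("ADC", "FA", "AD", "RD", "T2star")
  m <- fit_mixture(x, K = 1, allow_k1 = TRUE, seed = 2)
  expect_equal(unname(mixture_means(m)[1, ]), unname(colMeans(x)),
               tolerance = 1e-8)
  # ML covariance (1/n) in z-space, up to the small ridge
  z <- scale(x)
  expect_equal(m$covariances[[1]],
               crossprod(sweep(z, 2, colMeans(z))) / nrow(z),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("EM is deterministic under seed and log-likelihood is monotone", {
  pool <- draw_gauss_pool(3000, seed = 5)
  m1 <- fit_mixture(pool$x, K = 3, seed = 9)
  m2 <- fit_mixture(pool$x, K = 3, seed = 9)
  expect_identical(m1$means, m2$means)
  expect_identical(m1$covariances, m2$covariances)
  m3 <- fit_mixture(rbind(pool$x, pool$x), K = 3, seed = 9)
  expect_s3_class(m3, "placseg_mixture")
  expect_true(all(diff(m1$loglik_trace) >= -1e-8 * abs(m1$loglik)))
})

test_that("well-separated components are recovered and cross-validated", {
  pool <- draw_gauss_pool(6000, seed = 2)
  expect_gte(min_separation(pool$specs), 5)
  m <- fit_mixture(pool$x, K = 3, seed = 4)
  truem <- t(sapply(pool$specs, function(s) s$mean))
  fitm <- mixture_means(m)
  perm <- match_components(
    sweep(sweep(truem, 2, m$standardizer$center), 2, m$standardizer$scale, "/"),
    m$means)
  expect_lt(max(abs(fitm[perm, ] - truem) / abs(truem)), 0.02)
  # label agreement vs the generating labels
  g <- posterior_probabilities(m, pool$x)
  inv <- match(seq_len(3), perm)
  expect_gte(mean(inv[max.col(g)] == pool$labels), 0.99)
  # independent EM implementation agrees on the component means
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))   # Mclust needs its namespace attached
  mc <- mclust::Mclust(pool$x, G = 3, modelNames = "VVV", verbose = FALSE)
  mcm <- t(mc$parameters$mean)
  perm2 <- match_components(truem, mcm)
  expect_lt(max(abs(fitm[perm, ] - mcm[perm2, ]) / abs(truem)), 0.01)
})

test_that("mean recovery error shrinks as separation grows", {
  # error measured against the generating components' sample means, so the
  # sigma/sqrt(n) sampling floor cancels and only EM misassignment remains
  errs <- vapply(c(3, 5, 8), function(s) {
    mu <- rbind(c(0, 0, 0, 0, 0), c(s, 0, 0, 0, 0), c(0, s, 0, 0, 0))
    set.seed(30 + s)
    draws <- lapply(1:3, function(k) MASS::mvrnorm(1500, mu[k, ], diag(5)))
    x <- do.call(rbind, draws)
    colnames(x) <- c("ADC", "FA", "AD", "RD", "T2star")
    m <- fit_mixture(x, K = 3, seed = 6)
    sample_means <- t(sapply(draws, colMeans))
    zt <- sweep(sweep(sample_means, 2, m$standardizer$center), 2,
                m$standardizer$scale, "/")
    perm <- match_components(zt, m$means)
    mean(abs(mixture_means(m)[perm, ] - sample_means))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("posteriors are normalized and peak at dominant component means", {
  pool <- draw_gauss_pool(3000, seed = 12)
  m <- fit_mixture(pool$x, K = 3, seed = 3)
  g <- posterior_probabilities(m, pool$x)
  expect_equal(rowSums(g), rep(1, nrow(g)), tolerance = 1e-9)
  expect_true(all(g >= 0 & g <= 1))
  at_means <- posterior_probabilities(m, mixture_means(m))
  expect_true(all(diag(at_means) > 0.99))
  # symmetric duplicate components give uniform posteriors
  dup <- m
  dup$K <- 2L
  dup$weights <- c(0.5, 0.5)
  dup$means <- rbind(m$means[1, ], m$means[1, ])
  dup$covariances <- list(m$covariances[[1]], m$covariances[[1]])
  gu <- posterior_probabilities(dup, pool$x[1:50, ])
  expect_equal(as.numeric(gu), rep(0.5, 100), tolerance = 1e-12)
})

test_that("typicality is 1 at component means and flags far contaminants", {
  pool <- draw_gauss_pool(6000, seed = 22)
  m <- fit_mixture(pool$x, K = 3, seed = 8)
  typ <- typicality(m, mixture_means(m))
  expect_equal(diag(typ), rep(1, 3), tolerance = 1e-9)
  fl <- flag_outliers(m, mixture_means(m))
  expect_false(any(fl$outlier))
  # contaminants far from every component in the standardized metric
  set.seed(1)
  contam <- matrix(rnorm(1000 * 5), 1000, 5)
  contam <- sweep(contam, 1, sqrt(rowSums(contam^2)), "/") * 9
  far <- sweep(contam, 2, m$standardizer$scale, "*")
  far <- sweep(far, 2, m$standardizer$center + 8 * m$standardizer$scale, "+")
  colnames(far) <- colnames(pool$x)
  d2 <- sapply(1:3, function(k)
    placseg:::mahal2(placseg:::standardize_features(m, far),
                     m$means[k, ], chol(m$covariances[[k]])))
  keep <- apply(sqrt(d2), 1, min) >= 6
  flc <- flag_outliers(m, far)
  expect_gte(mean(flc$outlier[keep]), 0.99)
  expect_error(flag_outliers(m, pool$x, alpha = 1.2), "alpha")
})

test_that("components are named by their FA and T2* signatures", {
  pool <- draw_gauss_pool(6000, seed = 31)
  m <- fit_mixture(pool$x, K = 3, seed = 2)
  nm <- component_compartments(m)
  truem <- t(sapply(pool$specs, function(s) s$mean))
  zt <- sweep(sweep(truem, 2, m$standardizer$center), 2,
              m$standardizer$scale, "/")
  perm <- match_components(zt, m$means)
  expect_equal(nm[perm], c("IVS", "PV", "PT"))
  # permuting component order permutes names identically
  m2 <- m
  m2$means <- m$means[c(2, 3, 1), ]
  m2$covariances <- m$covariances[c(2, 3, 1)]
  m2$weights <- m$weights[c(2, 3, 1)]
  expect_equal(component_compartments(m2), nm[c(2, 3, 1)])
  # tied FA means demand manual mapping
  m3 <- m
  m3$means[2, ] <- m3$means[1, ]
  expect_error(component_compartments(m3), "tied")
})

test_that("lesioned phantoms are predominantly labelled PL", {
  ref <- healthy_reference()
  res <- segment_test_subject(ref$model, ref$geometry,
                              lesion_fraction = 0.2, seed = 61)
  tr <- res$phantom$truth
  les_rows <- tr$label_volume[res$maps$features$voxel_index] == 4L
  expect_gte(mean(res$seg$hard_label[les_rows] == "PL"), 0.9)
  healthy_rows <- !les_rows
  expect_lte(mean(res$seg$hard_label[healthy_rows] == "PL"), 0.06)
})

test_that("pl_fraction handles degenerate segmentations", {
  seg_all <- structure(list(hard_label = factor(rep("PL", 10),
                                                levels = c("IVS", "PV", "PT", "PL"))),
                       class = "placseg_segmentation")
  expect_equal(pl_fraction(seg_all)$fraction, 1)
  seg_none <- structure(list(hard_label = factor(rep("PT", 10),
                                                 levels = c("IVS", "PV", "PT", "PL"))),
                        class = "placseg_segmentation")
  expect_equal(pl_fraction(seg_none)$fraction, 0)
  expect_error(pl_fraction(seg_none, array(FALSE, c(2, 2, 2))), "empty")
})

test_that("subsample stability reports matched-component dispersion", {
  pool <- draw_gauss_pool(8000, seed = 44)
  st <- subsample_stability(pool$x, n_voxels = 3000, repeats = 4, seed = 5)
  expect_equal(dim(st$means), c(4, 3, 5))
  expect_true(all(st$cv < 0.05))
  st2 <- subsample_stability(pool$x, n_voxels = 3000, repeats = 4, seed = 5)
  expect_identical(st$means, st2$means)
  st1 <- subsample_stability(pool$x, n_voxels = 3000, repeats = 1, seed = 5,
                             full_model = st$full_model)
  expect_true(all(is.na(st1$cv)))
  expect_error(subsample_stability(pool$x, n_voxels = 1e6), "exceeds")
})
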