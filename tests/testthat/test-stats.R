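# independent enumeration oracle for the Mann-Whitney U two-sided p
enumerate_mw_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  umin <- min(u_obs, n1 * length(b) - u_obs)
  uvals <- apply(utils::combn(n, n1), 2,
                 function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mean(uvals <= umin | uvals >= n1 * length(b) - umin)
}

test_that("OLS matches the closed-form normal equations", {
  x <- c(1.2, 2.5, 3.1, 4.8, 5.0, 6.3, 7.7, 8.1)
  y <- c(2.3, 3.9, 4.1, 6.6, 7.2, 7.9, 10.4, 10.9)
  fit <- linreg(x, y)
  # oracle: normal equations + t CDF, written out independently
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope_o <- sum((x - mean(x)) * (y - mean(y))) / sxx
  int_o <- mean(y) - slope_o * mean(x)
  res <- y - int_o - slope_o * x
  s2 <- sum(res^2) / (n - 2)
  se_o <- sqrt(s2 / sxx)
  r2_o <- 1 - sum(res^2) / sum((y - mean(y))^2)
  p_o <- 2 * stats::pt(-abs(slope_o / se_o), df = n - 2)
  expect_equal(fit$slope, slope_o, tolerance = 1e-10)
  expect_equal(fit$intercept, int_o, tolerance = 1e-10)
  expect_equal(fit$slope_se, se_o, tolerance = 1e-10)
  expect_equal(fit$r_squared, r2_o, tolerance = 1e-10)
  expect_equal(fit$p_value, p_o, tolerance = 1e-10)
  # CI band matches the standard mean-response formula at the data points
  band <- linreg(x, y, band_x = x)$ci_band
  tq <- stats::qt(0.975, n - 2)
  half <- tq * sqrt(s2 * (1 / n + (x - mean(x))^2 / sxx))
  expect_equal(band$upr - band$fit, half, tolerance = 1e-10)
})

test_that("degenerate regressions behave as documented", {
  x <- 1:10
  fit <- linreg(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  flat <- linreg(x, rep(3, 10))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0)
  expect_equal(flat$p_value, 1)
  expect_error(linreg(rep(1, 5), 1:5), "constant")
  expect_error(linreg(1:2, 1:2), "n >= 3")
})

test_that("Mann-Whitney exact p equals full enumeration", {
  t1 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t1$u_statistic, 0)
  expect_equal(t1$p_value, 0.1)
  expect_equal(t1$method, "exact")
  t2 <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(t2$u_statistic, 8)   # n1 n2 / 2 under symmetry
  expect_equal(t2$p_value, 1)
  # randomized spot checks, with and without ties
  set.seed(10)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    vals <- if (i %% 2) sample(1:5, n1 + n2, replace = TRUE) else
      rnorm(n1 + n2)
    a <- vals[seq_len(n1)]; b <- vals[-seq_len(n1)]
    expect_equal(mann_whitney(a, b)$p_value, enumerate_mw_p(a, b),
                 tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("normal approximation tracks the exact distribution", {
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    ex <- mann_whitney(a, b)
    ap <- mann_whitney(a, b, exact_limit = 0)
    expect_equal(ap$method, "normal_approx")
    # measured worst-case gap at n = 8 vs 8 is ~0.011, for mid-range p
    expect_lt(abs(ap$p_value - ex$p_value), 0.015)
  }
})

test_that("gestational-age bins close the lower edge", {
  b <- placseg:::ga_bins(c(20, 24.9, 25, 34.9, 35, 40))
  expect_equal(as.character(b),
               c("<25", "<25", "25-35", "25-35", ">35", ">35"))
})

test_that("binned comparisons detect planted trends and skip empty bins", {
  set.seed(6)
  rec <- data.frame(ga_mri_weeks = c(runif(7, 20, 24), runif(10, 26, 34),
                                     runif(5, 36, 38)))
  rec$t2star_IVS <- 100 - 1.5 * (rec$ga_mri_weeks - 30) + rnorm(22, 0, 3)
  res <- ga_binned_comparison(rec, "t2star_IVS")
  low_high <- res[res$bin1 == "<25" & res$bin2 == ">35", ]
  expect_lt(low_high$p_value, 0.05)
  rec2 <- rec[rec$ga_mri_weeks < 35, ]
  w <- capture_warnings(res2 <- ga_binned_comparison(rec2, "t2star_IVS"))
  expect_match(w, "empty bin", all = TRUE)
  expect_length(w, 2)   # both pairs involving the empty >35 bin
  expect_equal(nrow(res2), 1)
})

test_that("lesion-burden analysis separates groups and finds the slope", {
  set.seed(2)
  rec <- data.frame(
    group = rep(c("healthy", "complicated"), c(22, 5)),
    pl_fraction = c(runif(22, 0, 0.05), runif(5, 0.14, 0.38)))
  rec$ga_delivery_weeks <- 40 - 12 * rec$pl_fraction + rnorm(27, 0, 0.8)
  res <- pl_group_analysis(rec)
  expect_lt(res$group_test$p_value, 0.05)
  expect_lt(res$delivery_regression$slope, 0)
  # identical all-zero fractions give p = 1
  rec0 <- data.frame(group = rep(c("healthy", "complicated"), each = 4),
                     pl_fraction = 0, ga_delivery_weeks = c(37:40, 37:40))
  expect_equal(pl_group_analysis(rec0)$group_test$p_value, 1)
  expect_error(pl_group_analysis(rec[rec$group == "healthy", ]), "non-empty")
})

test_that("brain correlations rank compartments by coupling", {
  set.seed(8)
  rec <- data.frame(
    t2star_total = rnorm(22, 70, 8),
    t2star_IVS = rnorm(22, 100, 10),
    t2star_PV = rnorm(22, 75, 8),
    t2star_PT = rnorm(22, 55, 6))
  rec$brain_t2star_ms <- rec$t2star_IVS       # identity coupling
  res <- brain_placenta_correlations(rec)
  expect_equal(res$best, "IVS")
  expect_equal(res$regressions$IVS$r_squared, 1, tolerance = 1e-12)
  # zero coupling: all R^2 small at n = 22
  rec$brain_t2star_ms <- rnorm(22, 80, 5)
  res0 <- brain_placenta_correlations(rec)
  expect_true(all(res0$summary$r_squared < 0.2))
  rec$brain_t2star_ms[3] <- NA
  expect_warning(brain_placenta_correlations(rec), "dropping")
})

test_that("brain summaries are voxel-count arithmetic", {
  mask <- array(FALSE, c(10, 10, 10)); mask[1:10, 1:10, 1:10] <- TRUE
  t2 <- array(80, c(10, 10, 10))
  res <- summarize_brain(t2, mask, voxel_size = c(1, 1, 1))
  expect_equal(res$volume_cm3, 1)
  expect_equal(res$mean_t2star_ms, 80)
  expect_error(summarize_brain(t2, array(FALSE, c(10, 10, 10))), "empty")
})

test_that("layerwise trends recover a planted slope ordering", {
  set.seed(4)
  ga <- runif(20, 20, 38)
  slopes <- c(B = -2, C = -1.2, D = -0.6, E = 0, F = 0.8)
  rows <- do.call(rbind, lapply(names(slopes), function(ly)
    data.frame(subject_id = sprintf("S%02d", 1:20), ga_mri_weeks = ga,
               layer = ly,
               mean = 80 + slopes[[ly]] * (ga - 30) + rnorm(20, 0, 2))))
  res <- layerwise_trend(rows)
  expect_equal(res$layer, c("B", "C", "D", "E", "F"))
  expect_equal(order(res$slope), seq_len(5))      # steepest at the chorion
  expect_lt(res$p_value[res$layer == "B"], 0.05)
  expect_true(res$ci_lwr[res$layer == "E"] < 0 &
              res$ci_upr[res$layer == "E"] > 0)
  # sparse layer omitted with warning
  rows2 <- rbind(rows, data.frame(subject_id = "S01", ga_mri_weeks = ga[1],
                                  layer = "G", mean = 50))
  expect_warning(res2 <- layerwise_trend(rows2), "omitted")
  expect_false("G" %in% res2$layer)
})
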