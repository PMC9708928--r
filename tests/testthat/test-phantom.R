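test_that("compartment specs validate their invariants", {
  expect_error(compartment_spec("IVS", mean = c(1, 2, 3, 4, 5),
                                cov = matrix(0, 5, 5)),
               "positive-definite")
  expect_error(compartment_spec("PT", mean = c(1, 1.5, 1, 1, 50),
                                sd = rep(0.1, 5)), "FA")
  expect_error(compartment_spec("PT", mean = c(-1, 0.2, 1, 1, 50),
                                sd = rep(0.1, 5)), "positive")
  expect_error(healthy_compartments(fractions = c(IVS = 0.5, PV = 0.3, PT = 0.3)),
               "sum to 1")
  sp <- lesion_preset("case1")
  expect_equal(unname(sp$mean),  c(1.43, 0.27, 1.67, 1.33, 44.2))
  expect_equal(sp$name, "PL")
})

test_that("eigenvalue construction matches the drawn FA, AD, RD exactly", {
  fa <- c(0.27, 0.49, 0.15, 0.45)
  ad <- c(1.67, 2.01, 3.10, 2.40)
  rd <- c(1.33, 1.01, 2.65, 1.35)
  te <- placseg:::tensor_eigs_from_features(fa, ad, rd)
  expect_true(all(te$feasible))
  eig <- cbind(te$l1, te$l2, te$l3)
  # sorted descending, FA matched exactly, trace (hence ADC) preserved
  expect_true(all(eig[, 1] >= eig[, 2] & eig[, 2] >= eig[, 3]))
  expect_equal(placseg:::fa_from_eigs(eig), fa, tolerance = 1e-12)
  expect_equal(rowMeans(eig), (ad + 2 * rd) / 3, tolerance = 1e-12)
  # realized axial/radial diffusivities stay close to the drawn values
  expect_equal(eig[, 1], ad, tolerance = 0.01)
  expect_equal((eig[, 2] + eig[, 3]) / 2, rd, tolerance = 0.01)
  # FA below the axially symmetric minimum is infeasible
  bad <- tensor_eigs_from_features(0.05, 1.67, 1.33)
  expect_false(bad$feasible)
})

test_that("phantom is deterministic under seed and labels honour fractions", {
  geom <- tiny_geometry()
  a <- suppressWarnings(generate_phantom(geometry = geom, seed = 11))
  b <- suppressWarnings(generate_phantom(geometry = geom, seed = 11))
  c <- suppressWarnings(generate_phantom(geometry = geom, seed = 12))
  expect_identical(a$echo$volumes, b$echo$volumes)
  expect_identical(a$dwi$volumes, b$dwi$volumes)
  expect_false(identical(a$echo$volumes, c$echo$volumes))

  n <- length(a$truth$mask_idx)
  counts <- table(a$truth$label_volume[a$truth$mask_idx])
  expect_equal(as.integer(counts[["1"]]), round(0.35 * n))
  expect_equal(as.integer(counts[["2"]]), round(0.20 * n))
  # masks are coherent
  tr <- a$truth
  expect_false(any(tr$chorion_mask & tr$basal_mask))
  expect_true(all(tr$lesion_mask[!tr$placental_mask] == FALSE))
  expect_true(all(tr$label_volume[tr$placental_mask] %in% 1:3))
  expect_true(all(tr$label_volume[!tr$placental_mask] == 0L))
})

test_that("planted lesions occupy the requested fraction and parameters", {
  les <- lesion_preset("case1", volume_fraction = 0.2)
  ph <- suppressWarnings(generate_phantom(lesion = les,
                                          geometry = tiny_geometry(),
                                          noise_snr = Inf, seed = 5))
  tr <- ph$truth
  n <- length(tr$mask_idx)
  expect_equal(sum(tr$lesion_mask), round(0.2 * n))
  expect_true(all(tr$lesion_mask <= tr$placental_mask))
  lf <- tr$features[tr$label_volume[tr$mask_idx] == 4L, ]
  m <- colMeans(lf)
  # generative means: T2* as drawn; ADC is the tensor-implied value; the
  # FA mean sits slightly above the nominal 0.27 because draws below the
  # tensor-feasible FA minimum are rejected and re-drawn
  expect_equal(unname(m["T2star"]), 44.2, tolerance = 0.03)
  expect_equal(unname(m["FA"]), 0.27, tolerance = 0.10)
  expect_equal(unname(m["RD"]), 1.33, tolerance = 0.05)
  expect_equal(unname(m["ADC"]), (m[["AD"]] + 2 * m[["RD"]]) / 3,
               tolerance = 1e-12)
})

test_that("noiseless signals follow the stated forward models", {
  ph <- suppressWarnings(generate_phantom(geometry = tiny_geometry(),
                                          noise_snr = Inf, seed = 7))
  tr <- ph$truth
  te <- ph$echo$echo_times
  i <- tr$mask_idx[100]
  sig <- ph$echo$volumes[arrayInd(i, dim(tr$placental_mask))[1],
                         arrayInd(i, dim(tr$placental_mask))[2],
                         arrayInd(i, dim(tr$placental_mask))[3], ]
  expect_equal(sig, tr$s0 * exp(-te / tr$features[100, "T2star"]),
               tolerance = 1e-12)
  # diffusion signal at one gradient
  sch <- ph$dwi$scheme
  g <- sch$bvecs[5, ]; b <- sch$bvals[5]
  D <- tr$tensors[100, ]
  quad <- g[1]^2 * D["xx"] + g[2]^2 * D["yy"] + g[3]^2 * D["zz"] +
    2 * g[1] * g[2] * D["xy"] + 2 * g[1] * g[3] * D["xz"] +
    2 * g[2] * g[3] * D["yz"]
  sdwi <- ph$dwi$volumes[arrayInd(i, dim(tr$placental_mask))[1],
                         arrayInd(i, dim(tr$placental_mask))[2],
                         arrayInd(i, dim(tr$placental_mask))[3], 5]
  expect_equal(unname(sdwi), unname(tr$s0 * exp(-b * quad * 1e-3)),
               tolerance = 1e-12)
})

test_that("cohort trends are present in the recorded generative truth", {
  des <- cohort_design(n_subjects = 22, lesion_prevalence = 0,
                       geometry = tiny_geometry(dim = c(16L, 16L, 8L)))
  co <- suppressWarnings(generate_cohort(des, seed = 3))
  tt <- co$truth_table
  expect_equal(nrow(tt), 22)
  expect_true(all(tt$group == "healthy"))
  expect_true(all(vapply(co$subjects,
                         function(s) !any(s$truth$lesion_mask), logical(1))))
  # OLS on the truth recovers the planted slope signs
  expect_lt(linreg(tt$ga_mri_weeks, tt$t2star_IVS)$slope, 0)
  expect_lt(linreg(tt$ga_mri_weeks, tt$t2star_PV)$slope, 0)
  pt <- linreg(tt$ga_mri_weeks, tt$t2star_PT)
  expect_gt(pt$p_value, 0.05)
  # brain T2* coupled to IVS
  expect_gt(linreg(tt$t2star_IVS, tt$brain_t2star_ms)$r_squared, 0.5)
})

test_that("degenerate cohort designs behave as documented", {
  expect_error(cohort_design(n_subjects = 1), "n_subjects")
  expect_error(cohort_design(ga_range = c(10, 38)), "ga_range")
  des <- cohort_design(n_subjects = 3, trend_slopes = c(IVS = 0, PV = 0, PT = 0),
                       between_sd = 0, lesion_prevalence = 0,
                       geometry = tiny_geometry(dim = c(16L, 16L, 8L)))
  co <- suppressWarnings(generate_cohort(des, seed = 9))
  tt <- co$truth_table
  expect_equal(diff(range(tt$t2star_IVS)), 0, tolerance = 1e-12)
  expect_equal(diff(range(tt$t2star_PT)), 0, tolerance = 1e-12)
})
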