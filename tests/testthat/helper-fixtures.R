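# Shared fixtures, built in code. Expensive pooled objects are cached per
# test session in this environment.

.fixture_cache <- new.env(parent = emptyenv())

tiny_geometry <- function(dim = c(24L, 24L, 10L), brain = FALSE) {
  phantom_geometry(dim = dim, brain = brain)
}

# direct Gaussian draws from compartment specs (the feature-space view of a
# phantom cohort, without image synthesis); returns features + labels
draw_gauss_pool <- function(n, specs = healthy_compartments(), seed = 1) {
  set.seed(seed)
  fr <- vapply(specs, function(s) s$volume_fraction, numeric(1))
  fr <- fr / sum(fr)
  ns <- round(n * fr)
  ns[length(ns)] <- n - sum(ns[-length(ns)])
  x <- do.call(rbind, lapply(seq_along(specs), function(i)
    MASS::mvrnorm(ns[i], specs[[i]]$mean, specs[[i]]$cov)))
  colnames(x) <- c("ADC", "FA", "AD", "RD", "T2star")
  list(x = x, labels = rep(seq_along(specs), ns), specs = specs)
}

# minimum pairwise Mahalanobis separation between compartment specs
min_separation <- function(specs) {
  K <- length(specs)
  d <- Inf
  for (i in seq_len(K - 1)) for (j in seq((i + 1), K)) {
    S <- (specs[[i]]$cov + specs[[j]]$cov) / 2
    d <- min(d, sqrt(stats::mahalanobis(specs[[i]]$mean, specs[[j]]$mean, S)))
  }
  d
}

# pooled healthy reference: features fitted from `n_subjects` phantom
# subjects with cohort-like between-subject T2* spread, plus the fitted
# mixture model. Cached: built once per test run.
healthy_reference <- function(n_subjects = 8L, dim = c(36L, 36L, 14L),
                              seed = 42L) {
  key <- sprintf("ref_%d_%s_%d", n_subjects, paste(dim, collapse = "x"), seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  slopes <- c(IVS = -1.5, PV = -1.8, PT = 0)
  geom <- phantom_geometry(dim = dim, brain = FALSE)
  set.seed(seed)
  pool <- NULL
  for (i in seq_len(n_subjects)) {
    ga <- runif(1, 20, 38)
    sh <- rnorm(3, 0, 4) + slopes * (ga - 30)
    ph <- suppressWarnings(generate_phantom(
      healthy_compartments(t2s_shift = c(IVS = sh[1], PV = sh[2], PT = sh[3])),
      geometry = geom, seed = seed * 100 + i))
    mp <- fit_subject_maps(ph)
    pool <- rbind(pool, mp$features$x)
  }
  model <- fit_mixture(pool, K = 3, seed = seed)
  out <- list(pool = pool, model = model, geometry = geom, slopes = slopes,
              seed = seed)
  .fixture_cache[[key]] <- out
  out
}

# generate one test subject with cohort-like T2* offsets and an optional
# planted lesion, fit its maps, and segment it against a given model
segment_test_subject <- function(model, geom, lesion_fraction = 0,
                                 lesion_case = "case4", seed = 1L) {
  set.seed(seed)
  slopes <- c(IVS = -1.5, PV = -1.8, PT = 0)
  ga <- runif(1, 22, 36)
  sh <- rnorm(3, 0, 4) + slopes * (ga - 30)
  les <- if (lesion_fraction > 0)
    lesion_preset(lesion_case, volume_fraction = lesion_fraction)
  ph <- suppressWarnings(generate_phantom(
    healthy_compartments(t2s_shift = c(IVS = sh[1], PV = sh[2], PT = sh[3])),
    lesion = les, geometry = geom, seed = seed))
  mp <- fit_subject_maps(ph)
  seg <- segment_placenta(mp$features, model = model)
  list(phantom = ph, maps = mp, seg = seg,
       recovered = pl_fraction(seg, ph$truth$placental_mask)$fraction)
}

# axis-aligned slab with chorion above and basal below, for depth tests:
# slab occupies z in 2..(nz-1); chorion plane z = nz, basal plane z = 1
slab_masks <- function(nx = 3L, ny = 3L, nz = 102L) {
  dm <- c(nx, ny, nz)
  slab <- array(FALSE, dm); slab[, , 2:(nz - 1L)] <- TRUE
  chorion <- array(FALSE, dm); chorion[, , nz] <- TRUE
  basal <- array(FALSE, dm); basal[, , 1L] <- TRUE
  list(slab = slab, chorion = chorion, basal = basal, dim = dm)
}
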