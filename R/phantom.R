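# Digital dual-contrast placental phantom.
#
# Geometry: an ellipsoidal placental slab partitioned into cotyledon-like
# Voronoi lobules; intervillous-space cores at the lobule centres, a vessel
# network biased toward the chorionic plate, villous tissue elsewhere, and
# optional planted ellipsoidal lesions. An optional small spherical "fetal
# brain" sits outside the placenta so brain volume/T2* summaries can be
# exercised. Signals follow the mono-exponential gradient-echo decay
# S(TE) = S0 exp(-TE/T2*) and the diffusion-tensor model
# S(b, g) = S0 exp(-b g' D g), with Rician noise at a configurable SNR.

#' Phantom geometry configuration
#'
#' @param dim Grid size (3 integers).
#' @param voxel_size Voxel dimensions in mm.
#' @param semiaxes Ellipsoid semi-axes in voxels; default scales with `dim`.
#' @param n_cotyledons Number of cotyledon lobules.
#' @param brain Logical: include a fetal-brain sphere outside the placenta.
#' @param brain_radius_mm Brain sphere radius (mm).
#' @return List of class `placseg_geometry`.
#' @export
phantom_geometry <- function(dim = c(48L, 48L, 16L), voxel_size = c(3, 3, 3),
                             semiaxes = NULL, n_cotyledons = 5L,
                             brain = TRUE, brain_radius_mm = 10) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 8L), length(voxel_size) == 3L,
            all(voxel_size > 0), n_cotyledons >= 1L)
  if (is.null(semiaxes)) semiaxes <- c(0.42 * dim[1], 0.42 * dim[2], 0.40 * dim[3])
  structure(list(dim = dim, voxel_size = voxel_size, semiaxes = semiaxes,
                 n_cotyledons = as.integer(n_cotyledons), brain = brain,
                 brain_radius_mm = brain_radius_mm),
            class = "placseg_geometry")
}

#' Acquisition scheme for the phantom
#'
#' Defaults: 10 gradient echoes from 5 to 90 ms; diffusion scheme with one
#' b=0 volume plus 12 evenly spread hemisphere directions at b = 700 s/mm2.
#'
#' @param echo_times Echo times in ms (strictly increasing, >= 3).
#' @param b Non-zero b-value in s/mm2.
#' @param n_directions Number of diffusion directions.
#' @return List with `echo_times`, `scheme` (a [diffusion_scheme()]).
#' @export
acquisition_scheme <- function(echo_times = seq(5, 90, length.out = 10),
                               b = 700, n_directions = 12L) {
  if (length(echo_times) < 3L || any(diff(echo_times) <= 0) || any(echo_times <= 0))
    stop_placseg("echo_times must be >= 3 strictly increasing positive values")
  dirs <- hemisphere_directions(n_directions)
  scheme <- diffusion_scheme(bvals = c(0, rep(b, n_directions)),
                             bvecs = rbind(c(0, 0, 0), dirs))
  list(echo_times = echo_times, scheme = scheme)
}

# Evenly spread unit directions on the upper hemisphere (generalized spiral).
hemisphere_directions <- function(n) {
  stopifnot(n >= 6L)
  i <- seq_len(n)
  z <- (i - 0.5) / n              # cos(theta) in (0, 1): upper hemisphere
  phi <- i * pi * (3 - sqrt(5))   # golden-angle azimuth
  st <- sqrt(1 - z^2)
  cbind(st * cos(phi), st * sin(phi), z)
}

# Random rotation matrices from uniform quaternions; returns list of the 9
# entry vectors (r11, r12, ..., r33), vectorized over n.
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  list(
    r11 = 1 - 2 * (y^2 + z^2), r12 = 2 * (x * y - w * z), r13 = 2 * (x * z + w * y),
    r21 = 2 * (x * y + w * z), r22 = 1 - 2 * (x^2 + z^2), r23 = 2 * (y * z - w * x),
    r31 = 2 * (x * z - w * y), r32 = 2 * (y * z + w * x), r33 = 1 - 2 * (x^2 + y^2))
}

# D = R diag(l1,l2,l3) R' per voxel; returns the 6 unique entries as a
# matrix with columns xx, yy, zz, xy, xz, yz.
tensors_from_eigs <- function(eigs, rot) {
  l1 <- eigs[, 1]; l2 <- eigs[, 2]; l3 <- eigs[, 3]
  dxx <- l1 * rot$r11^2 + l2 * rot$r12^2 + l3 * rot$r13^2
  dyy <- l1 * rot$r21^2 + l2 * rot$r22^2 + l3 * rot$r23^2
  dzz <- l1 * rot$r31^2 + l2 * rot$r32^2 + l3 * rot$r33^2
  dxy <- l1 * rot$r11 * rot$r21 + l2 * rot$r12 * rot$r22 + l3 * rot$r13 * rot$r23
  dxz <- l1 * rot$r11 * rot$r31 + l2 * rot$r12 * rot$r32 + l3 * rot$r13 * rot$r33
  dyz <- l1 * rot$r21 * rot$r31 + l2 * rot$r22 * rot$r32 + l3 * rot$r23 * rot$r33
  cbind(xx = dxx, yy = dyy, zz = dzz, xy = dxy, xz = dxz, yz = dyz)
}

# Rician-corrupt a non-negative magnitude array: sqrt((S + n1)^2 + n2^2)
# with n1, n2 ~ N(0, sigma). Caller owns the RNG.
add_rician_noise <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- length(x)
  re <- x + stats::rnorm(n, 0, sigma)
  im <- stats::rnorm(n, 0, sigma)
  y <- sqrt(re^2 + im^2)
  dim(y) <- dim(x)
  y
}

# Build the label geometry: masks, cotyledon ids, compartment labels with
# exact voxel counts per requested volume fraction. Caller owns the RNG.
build_geometry <- function(geom, fractions, lesion_fraction = 0) {
  dm <- geom$dim; vs <- geom$voxel_size
  ctr <- (dm + 1) / 2
  ax <- geom$semiaxes
  xs <- seq_len(dm[1]); ys <- seq_len(dm[2]); zs <- seq_len(dm[3])
  X <- array(rep(xs, times = dm[2] * dm[3]), dm)
  Y <- array(rep(rep(ys, each = dm[1]), times = dm[3]), dm)
  Z <- array(rep(zs, each = dm[1] * dm[2]), dm)
  r2 <- ((X - ctr[1]) / ax[1])^2 + ((Y - ctr[2]) / ax[2])^2 + ((Z - ctr[3]) / ax[3])^2
  mask <- r2 <= 1

  # boundary voxels (6-neighbourhood) split into chorionic (upper) and basal
  # (lower) plates by the z mid-plane; the equatorial rim joins neither.
  shift <- function(a, dimn, by) {
    out <- array(FALSE, dim(a))
    if (dimn == 1) { if (by > 0) out[-1, , ] <- a[-dm[1], , ] else out[-dm[1], , ] <- a[-1, , ] }
    if (dimn == 2) { if (by > 0) out[, -1, ] <- a[, -dm[2], ] else out[, -dm[2], ] <- a[, -1, ] }
    if (dimn == 3) { if (by > 0) out[, , -1] <- a[, , -dm[3]] else out[, , -dm[3]] <- a[, , -1] }
    out
  }
  interior <- mask &
    shift(mask, 1, 1) & shift(mask, 1, -1) &
    shift(mask, 2, 1) & shift(mask, 2, -1) &
    shift(mask, 3, 1) & shift(mask, 3, -1)
  boundary <- mask & !interior
  chorion <- boundary & (Z > ctr[3] + 0.5)
  basal <- boundary & (Z < ctr[3] - 0.5)

  # cotyledon lobules: in-plane Voronoi regions of seeds on a ring
  nc <- geom$n_cotyledons
  ang0 <- stats::runif(1, 0, 2 * pi)
  ang <- ang0 + 2 * pi * (seq_len(nc) - 1) / nc
  sx <- ctr[1] + 0.55 * ax[1] * cos(ang)
  sy <- ctr[2] + 0.55 * ax[2] * sin(ang)
  idx <- which(mask)
  px <- X[idx]; py <- Y[idx]; pz <- Z[idx]
  d2seed <- vapply(seq_len(nc),
                   function(k) ((px - sx[k]) * vs[1])^2 + ((py - sy[k]) * vs[2])^2,
                   numeric(length(idx)))
  d2seed <- matrix(d2seed, ncol = nc)
  coty <- max.col(-d2seed)
  d_own <- sqrt(d2seed[cbind(seq_along(idx), coty)])
  if (nc > 1L) {
    d2s <- apply(d2seed, 1, function(r) sqrt(sort(r)[2]))
    septal <- d2s - d_own   # small near lobule boundaries
  } else {
    septal <- rep(1, length(idx))
  }

  # normalized depth within the slab for placement scores
  dc <- distance_transform(chorion, vs)
  db <- distance_transform(basal, vs)
  depth <- dc[idx] / pmax(dc[idx] + db[idx], .Machine$double.eps)

  n <- length(idx)
  n_pv <- round(fractions[["PV"]] * n)
  n_ivs <- round(fractions[["IVS"]] * n)
  lab <- rep(3L, n)  # PT by default
  # vessels: near the chorionic plate and along septal lobule boundaries
  pv_score <- depth + 0.25 * septal / max(septal) + 0.02 * stats::runif(n)
  pv_idx <- order(pv_score)[seq_len(n_pv)]
  lab[pv_idx] <- 2L
  # IVS cores: near lobule centres at mid-depth, among remaining voxels
  rest <- which(lab == 3L)
  ivs_score <- (d_own[rest] / max(d_own)) + 0.7 * abs(depth[rest] - 0.55) +
    0.02 * stats::runif(length(rest))
  lab[rest[order(ivs_score)[seq_len(n_ivs)]]] <- 1L

  lesion <- rep(FALSE, n)
  if (lesion_fraction > 0) {
    n_les <- round(lesion_fraction * n)
    if (n_les > 0) {
      cidx <- sample.int(n, 1L)
      axr <- c(1, stats::runif(1, 0.6, 0.9), stats::runif(1, 0.4, 0.7))
      dd <- ((px - px[cidx]) * vs[1] / axr[1])^2 +
            ((py - py[cidx]) * vs[2] / axr[2])^2 +
            ((pz - pz[cidx]) * vs[3] / axr[3])^2
      lesion[order(dd)[seq_len(n_les)]] <- TRUE
      lab[lesion] <- 4L
    }
  }

  label_volume <- array(0L, dm)
  label_volume[idx] <- lab
  lesion_mask <- array(FALSE, dm)
  lesion_mask[idx[lesion]] <- TRUE

  brain_mask <- array(FALSE, dm)
  if (isTRUE(geom$brain)) {
    rb <- geom$brain_radius_mm
    bc <- c(1 + ceiling(rb / vs[1]) + 1, 1 + ceiling(rb / vs[2]) + 1, ctr[3])
    bd2 <- ((X - bc[1]) * vs[1])^2 + ((Y - bc[2]) * vs[2])^2 + ((Z - bc[3]) * vs[3])^2
    brain_mask <- bd2 <= rb^2 & !mask
  }

  list(placental_mask = mask, chorion_mask = chorion, basal_mask = basal,
       label_volume = label_volume, lesion_mask = lesion_mask,
       brain_mask = brain_mask, mask_idx = idx, labels = lab,
       cotyledon = coty, dim = dm, voxel_size = vs)
}

#' Generate a synthetic dual-contrast placental MRI dataset
#'
#' Builds a cotyledon-structured placental phantom, draws per-voxel
#' (ADC, FA, AD, RD, T2*) features from the compartment distributions,
#' synthesizes the multi-echo gradient-echo and diffusion-weighted signal
#' volumes, and corrupts them with Rician noise. All generative parameters
#' are recorded in the returned truth object, making the phantom a full
#' oracle for every downstream module. Identical seeds give bit-identical
#' output.
#'
#' @param compartments Named list of healthy [compartment_spec()]s
#'   (default [healthy_compartments()]); volume fractions must sum to 1.
#' @param lesion Optional `"PL"` [compartment_spec()] (e.g. [lesion_preset()]);
#'   its `volume_fraction` is the planted lesion fraction of the placenta.
#' @param geometry A [phantom_geometry()].
#' @param acquisition An [acquisition_scheme()].
#' @param noise_snr Signal-to-noise ratio at b = 0 / shortest echo;
#'   `Inf` disables noise.
#' @param s0 Baseline proton-density signal (arbitrary units).
#' @param brain_t2star,brain_adc Fetal-brain T2* (ms) and isotropic
#'   diffusivity (1e-3 mm2/s).
#' @param seed Integer seed controlling all randomness.
#' @param ga_weeks,ga_delivery_weeks Gestational age (weeks) at the
#'   simulated scan and at delivery, recorded in the truth metadata.
#' @return List of class `placseg_phantom` with elements `echo`
#'   (`volumes` 4-D array, `echo_times`), `dwi` (`volumes`, `scheme`), and
#'   `truth` (masks, label volume, per-voxel true features/tensors/T2*,
#'   compartment specs, seed).
#' @export
generate_phantom <- function(compartments = healthy_compartments(),
                             lesion = NULL,
                             geometry = phantom_geometry(),
                             acquisition = acquisition_scheme(),
                             noise_snr = 25,
                             s0 = 1000,
                             brain_t2star = 80, brain_adc = 1.0,
                             seed = 1L,
                             ga_weeks = 30, ga_delivery_weeks = 39.5) {
  fr <- vapply(compartments, function(s) s$volume_fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-9)
    stop_placseg("compartment volume fractions must sum to 1 (got %.6f)", sum(fr))
  if (!is.finite(noise_snr) && !is.infinite(noise_snr))
    stop_placseg("noise_snr must be positive or Inf")
  if (is.finite(noise_snr) && noise_snr <= 0) stop_placseg("noise_snr must be > 0")
  te <- acquisition$echo_times
  scheme <- acquisition$scheme
  lesion_fraction <- if (is.null(lesion)) 0 else lesion$volume_fraction

  with_seed(seed, {
    geo <- build_geometry(geometry, fractions = fr,
                          lesion_fraction = lesion_fraction)
    n <- length(geo$mask_idx)
    feat <- matrix(NA_real_, n, 5, dimnames = list(NULL, PLACSEG_FEATURES))
    eigs <- matrix(NA_real_, n, 3)
    comp_order <- c(names(compartments), if (!is.null(lesion)) "PL")
    specs <- compartments
    if (!is.null(lesion)) specs$PL <- lesion
    code <- c(IVS = 1L, PV = 2L, PT = 3L, PL = 4L)
    for (nm in comp_order) {
      sel <- geo$labels == code[[nm]]
      dr <- draw_compartment_features(specs[[nm]], sum(sel))
      feat[sel, ] <- dr$features
      eigs[sel, ] <- dr$eigs
    }
    rot <- random_rotations(n)
    tens <- tensors_from_eigs(eigs, rot)

    dm <- geo$dim
    nb <- sum(geo$brain_mask)
    brain_spec <- if (nb > 0)
      compartment_spec("brain",
                       mean = c(brain_adc, 0.10, brain_adc * 1.12,
                                brain_adc * 0.94, brain_t2star),
                       sd = c(0.08, 0.03, 0.10, 0.08, 4))
    bfeat <- NULL; btens <- NULL
    if (nb > 0) {
      db <- draw_compartment_features(brain_spec, nb)
      bfeat <- db$features
      btens <- tensors_from_eigs(db$eigs, random_rotations(nb))
    }

    # ---- signal synthesis -------------------------------------------------
    ne <- length(te)
    echo_vol <- array(0, c(dm, ne))
    t2s_all <- rep(NA_real_, prod(dm))
    t2s_all[geo$mask_idx] <- feat[, "T2star"]
    if (nb > 0) t2s_all[which(geo$brain_mask)] <- bfeat[, "T2star"]
    sig_idx <- which(!is.na(t2s_all))
    nvox_slice <- prod(dm)
    for (e in seq_len(ne)) {
      v <- numeric(nvox_slice)
      v[sig_idx] <- s0 * exp(-te[e] / t2s_all[sig_idx])
      echo_vol[(e - 1) * nvox_slice + seq_len(nvox_slice)] <- v
    }

    bv <- scheme$bvals; g <- scheme$bvecs
    nm_dwi <- length(bv)
    dwi_vol <- array(0, c(dm, nm_dwi))
    tens_all <- matrix(NA_real_, prod(dm), 6)
    tens_all[geo$mask_idx, ] <- tens
    if (nb > 0) tens_all[which(geo$brain_mask), ] <- btens
    for (m in seq_len(nm_dwi)) {
      quad <- bv[m] * (g[m, 1]^2 * tens_all[sig_idx, 1] +
                       g[m, 2]^2 * tens_all[sig_idx, 2] +
                       g[m, 3]^2 * tens_all[sig_idx, 3] +
                       2 * g[m, 1] * g[m, 2] * tens_all[sig_idx, 4] +
                       2 * g[m, 1] * g[m, 3] * tens_all[sig_idx, 5] +
                       2 * g[m, 2] * g[m, 3] * tens_all[sig_idx, 6])
      v <- numeric(nvox_slice)
      # b in s/mm2 and D in 1e-3 mm2/s: exponent is -b * D * 1e-3
      v[sig_idx] <- s0 * exp(-quad * 1e-3)
      dwi_vol[(m - 1) * nvox_slice + seq_len(nvox_slice)] <- v
    }

    if (is.finite(noise_snr)) {
      sigma <- mean(echo_vol[, , , 1][geo$placental_mask]) / noise_snr
      echo_vol <- add_rician_noise(echo_vol, sigma)
      dwi_vol <- add_rician_noise(dwi_vol, sigma)
    }

    truth <- structure(list(
      label_volume = geo$label_volume,
      lesion_mask = geo$lesion_mask,
      chorion_mask = geo$chorion_mask,
      basal_mask = geo$basal_mask,
      placental_mask = geo$placental_mask,
      brain_mask = geo$brain_mask,
      mask_idx = geo$mask_idx,
      features = feat,
      tensors = tens,
      eigenvalues = eigs,
      s0 = s0,
      brain_features = bfeat,
      true_params = specs,
      brain_spec = brain_spec,
      ga_weeks = ga_weeks,
      ga_delivery_weeks = ga_delivery_weeks,
      voxel_size = geo$voxel_size,
      seed = as.integer(seed)), class = "placseg_truth")

    structure(list(
      echo = list(volumes = echo_vol, echo_times = te),
      dwi = list(volumes = dwi_vol, scheme = scheme),
      truth = truth,
      geometry = geometry,
      noise_snr = noise_snr,
      seed = as.integer(seed)), class = "placseg_phantom")
  })
}

#' Cohort design for synthetic subjects
#'
#' Defines the population the cohort generator draws from: gestational-age
#' range, per-compartment linear T2*-vs-GA trends, between-subject spread,
#' the coupling of fetal-brain T2* to intervillous-space T2*, and the
#' prevalence of planted lesions.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param ga_range Gestational-age range (weeks) at MRI, within \[18, 42\].
#' @param trend_slopes Named T2*-vs-GA slopes (ms/week) for IVS, PV, PT.
#' @param t2s_ref T2* means (ms) at the reference GA `ga_ref`.
#' @param ga_ref Reference GA (weeks) at which `t2s_ref` applies.
#' @param between_sd Between-subject SD (ms) of compartment T2* means.
#' @param brain_coupling Linear coefficient linking fetal-brain T2* to the
#'   subject's IVS T2* mean.
#' @param brain_sd Residual SD (ms) of brain T2* around the coupling line.
#' @param lesion_prevalence Fraction of subjects with planted lesions.
#' @param lesion_case Which [lesion_preset()] to plant.
#' @param lesion_fraction_range Planted lesion fraction range (uniform draw).
#' @param noise_snr SNR at b = 0 / shortest echo.
#' @param geometry A [phantom_geometry()] used for every subject.
#' @return List of class `placseg_cohort_design`.
#' @export
cohort_design <- function(n_subjects = 27L,
                          ga_range = c(20, 38),
                          trend_slopes = c(IVS = -1.5, PV = -1.8, PT = 0),
                          t2s_ref = c(IVS = 100, PV = 75, PT = 55),
                          ga_ref = 30,
                          between_sd = 4,
                          brain_coupling = 0.8,
                          brain_sd = 2.5,
                          lesion_prevalence = 5 / 27,
                          lesion_case = "case4",
                          lesion_fraction_range = c(0.14, 0.38),
                          noise_snr = 25,
                          geometry = phantom_geometry()) {
  if (n_subjects < 2L) stop_placseg("n_subjects must be >= 2 (regression undefined)")
  if (ga_range[1] < 18 || ga_range[2] > 42 || ga_range[1] >= ga_range[2])
    stop_placseg("ga_range must be increasing and within [18, 42] weeks")
  if (is.finite(noise_snr) && noise_snr <= 0) stop_placseg("noise_snr must be > 0")
  structure(list(n_subjects = as.integer(n_subjects), ga_range = ga_range,
                 trend_slopes = trend_slopes, t2s_ref = t2s_ref, ga_ref = ga_ref,
                 between_sd = between_sd, brain_coupling = brain_coupling,
                 brain_sd = brain_sd, lesion_prevalence = lesion_prevalence,
                 lesion_case = lesion_case,
                 lesion_fraction_range = lesion_fraction_range,
                 noise_snr = noise_snr, geometry = geometry),
            class = "placseg_cohort_design")
}

#' Generate a synthetic cohort of placental phantoms
#'
#' Each subject receives a gestational age drawn uniformly over the design
#' range, compartment T2* means following the design's linear GA trends plus
#' between-subject noise, a fetal-brain T2* coupled linearly to the
#' subject's IVS T2*, and (for a design-determined subset) a planted lesion.
#' Gestational age at delivery decreases with the planted lesion burden.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed.
#' @return List of class `placseg_cohort`: `subjects` (list of
#'   `placseg_phantom`), `truth_table` (one row per subject: GA, group,
#'   generative compartment T2* means, lesion fraction, brain T2*), `design`,
#'   `seed`.
#' @export
generate_cohort <- function(design = cohort_design(), seed = 1L) {
  n <- design$n_subjects
  with_seed(seed, {
    ga <- stats::runif(n, design$ga_range[1], design$ga_range[2])
    n_les <- round(design$lesion_prevalence * n)
    lesioned <- rep(FALSE, n)
    if (n_les > 0) lesioned[sample.int(n, n_les)] <- TRUE
    comp <- c("IVS", "PV", "PT")
    mu <- sapply(comp, function(cc)
      design$t2s_ref[[cc]] + design$trend_slopes[[cc]] * (ga - design$ga_ref) +
        stats::rnorm(n, 0, design$between_sd))
    mu <- matrix(mu, ncol = 3, dimnames = list(NULL, comp))
    brain_t2s <- design$brain_coupling * mu[, "IVS"] +
      stats::rnorm(n, 0, design$brain_sd)
    les_frac <- ifelse(lesioned,
                       stats::runif(n, design$lesion_fraction_range[1],
                                    design$lesion_fraction_range[2]), 0)
    ga_del <- ifelse(lesioned,
                     40 - 12 * les_frac + stats::rnorm(n, 0, 1),
                     pmin(pmax(stats::rnorm(n, 39.5, 1.2), 37), 41.5))
    ga_del <- pmax(ga_del, ga + 0.5)
    # brain radius grows with GA (scaled-down growth curve)
    brain_r <- 7 + 0.13 * (ga - 18) * 10 / 3   # mm, ~7.9 at 20w to ~15.7 at 38w
    seeds <- vapply(seq_len(n), function(i) child_seed(seed, i), integer(1))

    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      shift <- mu[i, ] - design$t2s_ref[comp]
      comps <- healthy_compartments(t2s_shift = shift)
      les <- if (lesioned[i])
        lesion_preset(design$lesion_case, volume_fraction = les_frac[i])
      geom <- design$geometry
      geom$brain_radius_mm <- min(brain_r[i], 0.30 * min(geom$dim * geom$voxel_size))
      subjects[[i]] <- generate_phantom(
        compartments = comps, lesion = les, geometry = geom,
        noise_snr = design$noise_snr,
        brain_t2star = brain_t2s[i],
        seed = seeds[i], ga_weeks = ga[i], ga_delivery_weeks = ga_del[i])
    }
    truth_table <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      ga_mri_weeks = ga,
      ga_delivery_weeks = ga_del,
      group = ifelse(lesioned, "complicated", "healthy"),
      t2star_IVS = mu[, "IVS"], t2star_PV = mu[, "PV"], t2star_PT = mu[, "PT"],
      brain_t2star_ms = brain_t2s,
      lesion_fraction = les_frac,
      seed = seeds,
      stringsAsFactors = FALSE)
    structure(list(subjects = subjects, truth_table = truth_table,
                   design = design, seed = as.integer(seed)),
              class = "placseg_cohort")
  })
}
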