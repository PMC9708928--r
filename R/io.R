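# Readers and writers: NIfTI volumes, JSON sidecars, FSL bval/bvec text,
# mixture-model JSON.

#' Write a volume as NIfTI
#'
#' @param x 3-D or 4-D numeric/logical array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel dimensions in mm.
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, voxel_size = c(1, 1, 1)) {
  if (is.logical(x)) x <- array(as.integer(x), dim(x))
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(x)) - 3L))[seq_along(dim(x))]
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return List: `data` (array), `voxel_size` (mm).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)
  data <- as.array(img)
  attributes(data) <- list(dim = dim(img))   # plain array, no NIfTI attrs
  list(data = data, voxel_size = vs[seq_len(min(3L, length(vs)))])
}

# error naming both files when two volumes disagree on grid shape
check_same_grid <- function(a, b, name_a, name_b) {
  da <- dim(a)[1:3]; db <- dim(b)[1:3]
  if (!identical(da, db))
    stop_placseg("grid mismatch between %s (%s) and %s (%s)",
                 name_a, paste(da, collapse = "x"),
                 name_b, paste(db, collapse = "x"))
  invisible(TRUE)
}

#' Write the acquisition sidecar
#'
#' JSON with `echo_times_ms`, `bvals`, `bvecs` (n x 3) and `voxel_size_mm`.
#'
#' @param path Output JSON path.
#' @param echo_times Echo times in ms.
#' @param scheme A [diffusion_scheme()].
#' @param voxel_size Voxel dimensions in mm.
#' @export
write_sidecar <- function(path, echo_times, scheme, voxel_size) {
  jsonlite::write_json(
    list(echo_times_ms = echo_times,
         bvals = scheme$bvals,
         bvecs = unname(apply(scheme$bvecs, 1, as.numeric, simplify = FALSE)),
         voxel_size_mm = voxel_size),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read an acquisition sidecar
#' @param path Sidecar JSON path.
#' @return List with `echo_times`, `scheme`, `voxel_size`.
#' @export
read_sidecar <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  bvecs <- if (is.matrix(j$bvecs)) j$bvecs else
    do.call(rbind, lapply(j$bvecs, as.numeric))
  list(echo_times = as.numeric(j$echo_times_ms),
       scheme = diffusion_scheme(as.numeric(j$bvals), bvecs),
       voxel_size = as.numeric(j$voxel_size_mm))
}

#' Read FSL-style bval/bvec text files
#'
#' @param bval_path One whitespace-separated row of b-values.
#' @param bvec_path Three whitespace-separated rows (x, y, z components).
#' @return A [diffusion_scheme()].
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bv <- scan(bval_path, quiet = TRUE)
  gm <- matrix(scan(bvec_path, quiet = TRUE), nrow = 3, byrow = TRUE)
  if (ncol(gm) != length(bv))
    stop_placseg("bval (%d) and bvec (%d) measurement counts differ between %s and %s",
                 length(bv), ncol(gm), bval_path, bvec_path)
  diffusion_scheme(bv, t(gm))
}

#' Serialize a fitted mixture model to JSON
#' @param model A `placseg_mixture`.
#' @param path Output JSON path.
#' @export
write_mixture_json <- function(model, path) {
  jsonlite::write_json(
    list(K = model$K, weights = model$weights,
         means = unname(apply(model$means, 1, as.numeric, simplify = FALSE)),
         covariances = lapply(model$covariances, function(s)
           unname(apply(s, 1, as.numeric, simplify = FALSE))),
         standardizer = list(center = model$standardizer$center,
                             scale = model$standardizer$scale),
         feature_names = model$feature_names,
         loglik = model$loglik, seed = model$seed),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Read a mixture model serialized by [write_mixture_json()]
#' @param path JSON path.
#' @return A `placseg_mixture`.
#' @export
read_mixture_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- as.integer(j$K)
  p <- length(j$standardizer$center)
  as_mat <- function(m) if (is.matrix(m)) m else
    do.call(rbind, lapply(m, as.numeric))
  covs <- lapply(seq_len(K), function(k) {
    s <- if (is.array(j$covariances) && length(dim(j$covariances)) == 3L)
      j$covariances[k, , ] else as_mat(j$covariances[[k]])
    dimnames(s) <- NULL
    s
  })
  structure(list(K = K, weights = as.numeric(j$weights),
                 means = unname(as_mat(j$means)),
                 covariances = covs,
                 standardizer = list(center = as.numeric(j$standardizer$center),
                                     scale = as.numeric(j$standardizer$scale)),
                 loglik = as.numeric(j$loglik),
                 loglik_trace = numeric(0), converged = NA,
                 feature_names = as.character(j$feature_names),
                 seed = as.integer(j$seed)),
            class = "placseg_mixture")
}

#' Write a phantom dataset to a directory
#'
#' Emits `echo.nii.gz`, `dwi.nii.gz`, mask volumes, the generative truth
#' label volume and feature volume, `sidecar.json` and `truth.json`.
#'
#' @param phantom A `placseg_phantom`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- phantom$truth
  vs <- tr$voxel_size
  write_volume(phantom$echo$volumes, file.path(dir, "echo.nii.gz"), vs)
  write_volume(phantom$dwi$volumes, file.path(dir, "dwi.nii.gz"), vs)
  write_volume(tr$placental_mask, file.path(dir, "placental_mask.nii.gz"), vs)
  write_volume(tr$chorion_mask, file.path(dir, "chorion_mask.nii.gz"), vs)
  write_volume(tr$basal_mask, file.path(dir, "basal_mask.nii.gz"), vs)
  write_volume(tr$brain_mask, file.path(dir, "brain_mask.nii.gz"), vs)
  write_volume(tr$label_volume, file.path(dir, "truth_labels.nii.gz"), vs)
  feat_vol <- array(NA_real_, c(dim(tr$label_volume), 5L))
  nsl <- prod(dim(tr$label_volume))
  for (f in 1:5) feat_vol[(f - 1) * nsl + tr$mask_idx] <- tr$features[, f]
  write_volume(feat_vol, file.path(dir, "truth_features.nii.gz"), vs)
  write_sidecar(file.path(dir, "sidecar.json"),
                phantom$echo$echo_times, phantom$dwi$scheme, vs)
  jsonlite::write_json(
    list(ga_weeks = tr$ga_weeks, ga_delivery_weeks = tr$ga_delivery_weeks,
         seed = tr$seed, s0 = tr$s0, noise_snr = phantom$noise_snr,
         compartments = lapply(tr$true_params, function(s)
           list(name = s$name, mean = s$mean,
                cov = unname(apply(s$cov, 1, as.numeric, simplify = FALSE)),
                volume_fraction = s$volume_fraction))),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Read a phantom dataset written by [write_phantom()]
#'
#' @param dir Directory path.
#' @return A list mirroring the `placseg_phantom` structure (per-voxel
#'   generative tensors are not round-tripped; masks, labels, features,
#'   signals and metadata are).
#' @export
read_phantom <- function(dir) {
  side <- read_sidecar(file.path(dir, "sidecar.json"))
  echo <- read_volume(file.path(dir, "echo.nii.gz"))
  dwi <- read_volume(file.path(dir, "dwi.nii.gz"))
  check_same_grid(echo$data, dwi$data, "echo.nii.gz", "dwi.nii.gz")
  if (dim(echo$data)[4] != length(side$echo_times))
    stop_placseg("echo volume has %d echoes but sidecar lists %d",
                 dim(echo$data)[4], length(side$echo_times))
  if (dim(dwi$data)[4] != length(side$scheme$bvals))
    stop_placseg("dwi volume has %d measurements but sidecar lists %d",
                 dim(dwi$data)[4], length(side$scheme$bvals))
  masks <- lapply(c(placental = "placental_mask", chorion = "chorion_mask",
                    basal = "basal_mask", brain = "brain_mask"),
                  function(f) {
                    v <- read_volume(file.path(dir, paste0(f, ".nii.gz")))$data
                    array(v > 0, dim(v))
                  })
  labels <- read_volume(file.path(dir, "truth_labels.nii.gz"))$data
  tj <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  mask_idx <- which(masks$placental)
  feats <- NULL
  fpath <- file.path(dir, "truth_features.nii.gz")
  if (file.exists(fpath)) {
    fv <- read_volume(fpath)$data
    nsl <- prod(dim(labels))
    feats <- sapply(1:5, function(f) fv[(f - 1) * nsl + mask_idx])
    colnames(feats) <- PLACSEG_FEATURES
  }
  truth <- structure(list(
    label_volume = array(as.integer(labels), dim(labels)),
    lesion_mask = array(labels == 4, dim(labels)),
    chorion_mask = masks$chorion, basal_mask = masks$basal,
    placental_mask = masks$placental, brain_mask = masks$brain,
    mask_idx = mask_idx, features = feats,
    s0 = tj$s0, ga_weeks = tj$ga_weeks,
    ga_delivery_weeks = tj$ga_delivery_weeks,
    voxel_size = side$voxel_size, seed = tj$seed), class = "placseg_truth")
  structure(list(
    echo = list(volumes = echo$data, echo_times = side$echo_times),
    dwi = list(volumes = dwi$data, scheme = side$scheme),
    truth = truth, noise_snr = tj$noise_snr, seed = tj$seed),
    class = "placseg_phantom")
}
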