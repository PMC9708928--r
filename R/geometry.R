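# Chorionic-to-basal depth coordinate and layer parcellation.

# 1-D squared Euclidean distance transform (lower envelope of parabolas,
# Felzenszwalb & Huttenlocher) with grid spacing d. f holds squared
# distances (Inf off the source set).
dt1d <- function(f, d) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(f)
  v <- integer(n)        # parabola apex indices
  z <- numeric(n + 1L)   # envelope breakpoints
  k <- 1L
  v[1L] <- fin[1L]
  z[1L] <- -Inf
  z[2L] <- Inf
  d2 <- d * d
  if (length(fin) > 1L) for (q in fin[-1L]) {
    repeat {
      p <- v[k]
      s <- ((f[q] + d2 * q * q) - (f[p] + d2 * p * p)) / (2 * d2 * (q - p))
      if (s <= z[k]) {
        k <- k - 1L
        if (k == 0L) { k <- 1L; v[1L] <- q; z[1L] <- -Inf; z[2L] <- Inf; break }
      } else {
        k <- k + 1L
        v[k] <- q
        z[k] <- s
        z[k + 1L] <- Inf
        break
      }
    }
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    out[q] <- d2 * (q - p)^2 + f[p]
  }
  out
}

#' Euclidean distance transform to a voxel set
#'
#' Exact Euclidean distance (in mm, honouring anisotropic voxel size) from
#' every voxel of a 3-D grid to the nearest `TRUE` voxel of `mask`, computed
#' with the separable squared-distance-transform algorithm.
#'
#' @param mask 3-D logical array of source voxels.
#' @param voxel_size Numeric length-3 voxel dimensions in mm.
#' @return 3-D numeric array of distances (mm); `Inf` if `mask` is empty.
#' @export
distance_transform <- function(mask, voxel_size = c(1, 1, 1)) {
  stopifnot(length(dim(mask)) == 3L, length(voxel_size) == 3L,
            all(voxel_size > 0))
  dm <- dim(mask)
  g <- array(Inf, dm)
  g[mask] <- 0
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2]))
    g[, j, k] <- dt1d(g[, j, k], voxel_size[1])
  for (k in seq_len(dm[3])) for (i in seq_len(dm[1]))
    g[i, , k] <- dt1d(g[i, , k], voxel_size[2])
  for (j in seq_len(dm[2])) for (i in seq_len(dm[1]))
    g[i, j, ] <- dt1d(g[i, j, ], voxel_size[3])
  sqrt(g)
}

#' Normalized chorionic-to-basal depth
#'
#' Assigns every placental voxel a depth in \[0, 1\]: 0 at the chorionic
#' (fetal) surface, 1 at the basal (maternal) surface, computed as
#' d_c / (d_c + d_b) from the Euclidean distances (mm) to the two surface
#' masks.
#'
#' @param placental_mask,chorion_mask,basal_mask 3-D logical arrays on one grid.
#' @param voxel_size Voxel dimensions in mm.
#' @return Object of class `placseg_depth`: list with `depth` (3-D array,
#'   `NA` outside the placenta), `d_chorion`, `d_basal`.
#' @export
compute_depth <- function(placental_mask, chorion_mask, basal_mask,
                          voxel_size = c(1, 1, 1)) {
  if (!any(placental_mask)) stop_placseg("placental mask is empty")
  if (!any(chorion_mask)) stop_placseg("chorionic surface mask is empty")
  if (!any(basal_mask)) stop_placseg("basal surface mask is empty")
  if (!identical(dim(placental_mask), dim(chorion_mask)) ||
      !identical(dim(placental_mask), dim(basal_mask)))
    stop_placseg("masks are not on the same grid")
  if (any(chorion_mask & basal_mask))
    stop_placseg("chorionic and basal surface masks overlap")
  dc <- distance_transform(chorion_mask, voxel_size)
  db <- distance_transform(basal_mask, voxel_size)
  tot <- dc + db
  if (any(tot[placental_mask] == 0))
    stop_placseg("voxel at zero distance to both surfaces: masks overlap")
  depth <- array(NA_real_, dim(placental_mask))
  depth[placental_mask] <- dc[placental_mask] / tot[placental_mask]
  structure(list(depth = depth, d_chorion = dc, d_basal = db,
                 voxel_size = voxel_size),
            class = "placseg_depth")
}

#' Parcellate depth into layers
#'
#' Cuts the normalized depth into `n_layers` equal-width bins, labelled from
#' the chorionic side onward (`B`, `C`, `D`, `E`, `F` for the default five
#' layers); depth exactly 1 falls in the last (basal) layer.
#'
#' @param depth A `placseg_depth` object or numeric array/vector in \[0, 1\].
#' @param n_layers Number of layers (>= 2), default 5.
#' @return Factor (same shape as input) with layer labels; `NA` where depth
#'   is `NA`.
#' @export
assign_layers <- function(depth, n_layers = 5L) {
  if (inherits(depth, "placseg_depth")) depth <- depth$depth
  if (n_layers < 2L) stop_placseg("n_layers must be >= 2")
  rng <- range(depth, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop_placseg("depth values must lie in [0, 1]")
  labs <- LETTERS[seq(2L, 1L + n_layers)]
  idx <- pmin(floor(depth * n_layers) + 1L, n_layers)
  out <- factor(labs[idx], levels = labs)
  dim(out) <- dim(depth)
  out
}

#' Per-layer feature summary within a compartment
#'
#' Mean of one or more feature maps in each depth layer, restricted to
#' voxels of a chosen compartment (or `"all"` for the whole mask). Layers
#' with no voxels are omitted from the output rather than reported as zero.
#'
#' @param features Named list of 3-D numeric arrays (e.g. `list(T2star = ...)`),
#'   or a single array.
#' @param layers Factor array from [assign_layers()].
#' @param labels Optional compartment label array (factor or character);
#'   required unless `compartment = "all"`.
#' @param compartment Compartment name or `"all"`.
#' @param valid Optional logical array of voxels with valid fits.
#' @return `data.frame(compartment, layer, feature, mean, n_voxels)`.
#' @export
layer_summary <- function(features, layers, labels = NULL,
                          compartment = "all", valid = NULL) {
  if (!is.list(features)) features <- list(value = features)
  sel <- !is.na(layers)
  if (!identical(compartment, "all")) {
    if (is.null(labels)) stop_placseg("labels required to restrict to a compartment")
    inl <- !is.na(labels) & as.character(labels) == compartment
    if (!any(inl & sel))
      stop_placseg("compartment %s absent from all layers", compartment)
    sel <- sel & inl
  }
  if (!is.null(valid)) sel <- sel & valid
  out <- list()
  for (fn in names(features)) {
    v <- features[[fn]]
    for (ly in levels(layers)) {
      s <- sel & (as.character(layers) == ly) & !is.na(layers)
      vals <- v[s]
      vals <- vals[is.finite(vals)]
      if (length(vals) == 0L) next
      out[[length(out) + 1L]] <- data.frame(
        compartment = compartment, layer = ly, feature = fn,
        mean = mean(vals), n_voxels = length(vals),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) stop_placseg("no voxels to summarize")
  do.call(rbind, out)
}
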