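# End-to-end orchestration: maps -> pooled clustering -> segmentation ->
# depth layers -> cohort statistics.

#' Fit both parametric maps for one subject
#'
#' @param phantom A `placseg_phantom` (or any list with `echo`, `dwi`,
#'   `truth` carrying masks and voxel size).
#' @return List: `t2map`, `tensormap`, `features` (placental feature table).
#' @export
fit_subject_maps <- function(phantom) {
  tr <- phantom$truth
  fitmask <- tr$placental_mask | tr$brain_mask
  t2map <- fit_t2star(phantom$echo$volumes, phantom$echo$echo_times, mask = fitmask)
  tmap <- fit_tensor(phantom$dwi$volumes, phantom$dwi$scheme, mask = fitmask)
  feats <- extract_features(t2map, tmap, tr$placental_mask)
  list(t2map = t2map, tensormap = tmap, features = feats)
}

# label array (factor levels IVS/PV/PT/PL) from a segmentation on a grid
segmentation_label_volume <- function(seg) {
  stopifnot(!is.null(seg$voxel_index), !is.null(seg$dim))
  lab <- array(NA_character_, seg$dim)
  lab[seg$voxel_index] <- as.character(seg$hard_label)
  lab
}

# one flat record per subject from its maps + segmentation + truth metadata
subject_record <- function(id, phantom, maps, seg) {
  tr <- phantom$truth
  x <- maps$features$x
  lab <- as.character(seg$hard_label)
  mean_t2 <- function(sel) if (any(sel)) mean(x[sel, "T2star"]) else NA_real_
  brain <- if (any(tr$brain_mask))
    summarize_brain(maps$t2map, tr$brain_mask, tr$voxel_size)
  else list(volume_cm3 = NA_real_, mean_t2star_ms = NA_real_)
  data.frame(
    subject_id = id,
    ga_mri_weeks = tr$ga_weeks,
    ga_delivery_weeks = tr$ga_delivery_weeks,
    group = if (any(tr$lesion_mask)) "complicated" else "healthy",
    t2star_total = mean(x[, "T2star"]),
    t2star_IVS = mean_t2(lab == "IVS"),
    t2star_PV = mean_t2(lab == "PV"),
    t2star_PT = mean_t2(lab == "PT"),
    t2star_PL = mean_t2(lab == "PL"),
    pl_fraction = seg$pl_fraction,
    brain_volume_cm3 = brain$volume_cm3,
    brain_t2star_ms = brain$mean_t2star_ms,
    stringsAsFactors = FALSE)
}

#' Analyze a cohort of subjects
#'
#' Runs the full analysis chain on a list of subjects: fits T2* and tensor
#' maps, pools feature vectors across healthy subjects to train one mixture
#' model (so lesions stay outliers relative to healthy statistics), segments
#' every subject, computes the chorionic-basal depth layers, and produces
#' the cohort statistics: per-compartment T2*-vs-GA regressions and binned
#' comparisons (healthy subjects), lesion-burden group analysis, fetal-brain
#' correlations, and per-layer vessel-compartment trends.
#'
#' @param cohort A `placseg_cohort` from [generate_cohort()], or a list of
#'   `placseg_phantom` objects.
#' @param K,alpha,n_restarts Clustering options.
#' @param seed Seed for training-pool subsampling and the mixture fit.
#' @param train_max_voxels Cap on pooled training rows (seeded subsample).
#' @param n_layers Depth layers, default 5.
#' @param layer_compartment Compartment for the layer trend table, default PV.
#' @return List of class `placseg_analysis`: `records`, `model`,
#'   `segmentations`, `layer_table`, `stats` (list: `trends`,
#'   `binned`, `pl`, `brain`, `layer_trend`).
#' @export
analyze_cohort <- function(cohort, K = 3L, alpha = 0.05, seed = 1L,
                           n_restarts = 5L, train_max_voxels = 50000L,
                           n_layers = 5L, layer_compartment = "PV") {
  subjects <- if (inherits(cohort, "placseg_cohort")) cohort$subjects else cohort
  n <- length(subjects)
  ids <- sprintf("S%02d", seq_len(n))

  maps <- lapply(subjects, fit_subject_maps)
  healthy <- vapply(subjects, function(s) !any(s$truth$lesion_mask), logical(1))
  if (!any(healthy)) stop_placseg("no healthy subjects to train the mixture on")
  pool <- do.call(rbind, lapply(which(healthy), function(i) maps[[i]]$features$x))
  if (nrow(pool) > train_max_voxels)
    pool <- pool[with_seed(child_seed(seed, 77L),
                           sample.int(nrow(pool), train_max_voxels)), ]
  model <- fit_mixture(pool, K = K, seed = seed, n_restarts = n_restarts)

  segs <- vector("list", n)
  records <- vector("list", n)
  layer_rows <- list()
  for (i in seq_len(n)) {
    tr <- subjects[[i]]$truth
    segs[[i]] <- segment_placenta(maps[[i]]$features, model = model, alpha = alpha)
    records[[i]] <- subject_record(ids[i], subjects[[i]], maps[[i]], segs[[i]])
    depth <- compute_depth(tr$placental_mask, tr$chorion_mask, tr$basal_mask,
                           tr$voxel_size)
    layers <- assign_layers(depth, n_layers)
    labv <- segmentation_label_volume(segs[[i]])
    ls <- tryCatch(
      layer_summary(list(T2star = maps[[i]]$t2map$t2star), layers,
                    labels = labv, compartment = layer_compartment,
                    valid = maps[[i]]$t2map$fit_valid),
      error = function(e) NULL)
    if (!is.null(ls)) {
      ls$subject_id <- ids[i]
      ls$ga_mri_weeks <- tr$ga_weeks
      ls$group <- records[[i]]$group
      layer_rows[[length(layer_rows) + 1L]] <- ls
    }
  }
  records <- do.call(rbind, records)
  layer_table <- if (length(layer_rows)) do.call(rbind, layer_rows)

  hrec <- records[records$group == "healthy", , drop = FALSE]
  comps <- c("total", "IVS", "PV", "PT")
  # stages degrade to NULL (with a warning) on cohorts too small for them
  trends <- lapply(comps, function(cc)
    tryCatch(linreg(hrec$ga_mri_weeks, hrec[[paste0("t2star_", cc)]]),
             error = function(e) {
               warn_placseg("T2* trend for %s skipped: %s", cc,
                            conditionMessage(e))
               NULL
             }))
  names(trends) <- comps
  binned <- lapply(comps, function(cc)
    suppressWarnings(ga_binned_comparison(hrec, paste0("t2star_", cc))))
  names(binned) <- comps
  pl <- if (length(unique(records$group)) == 2L) pl_group_analysis(records)
  brain <- tryCatch(brain_placenta_correlations(records),
                    error = function(e) NULL)
  layer_trend <- if (!is.null(layer_table)) {
    hl <- layer_table[layer_table$group == "healthy", , drop = FALSE]
    tryCatch(layerwise_trend(hl), error = function(e) NULL)
  }
  structure(list(records = records, model = model, segmentations = segs,
                 layer_table = layer_table,
                 stats = list(trends = trends, binned = binned, pl = pl,
                              brain = brain, layer_trend = layer_trend)),
            class = "placseg_analysis")
}

#' Pipeline configuration
#'
#' @param input_dir Directory of subject subdirectories written by
#'   [write_phantom()]; alternatively supply `cohort`.
#' @param cohort An in-memory `placseg_cohort`.
#' @param out_dir Optional output directory for CSV/JSON artifacts.
#' @param K,alpha,seed,n_restarts,n_layers Analysis options.
#' @param write_volumes Also write per-subject label volumes as NIfTI.
#' @return Validated config list of class `placseg_config`.
#' @export
pipeline_config <- function(input_dir = NULL, cohort = NULL, out_dir = NULL,
                            K = 3L, alpha = 0.05, seed = 1L, n_restarts = 5L,
                            n_layers = 5L, write_volumes = FALSE) {
  if (is.null(input_dir) && is.null(cohort))
    stop_placseg("config needs input_dir or an in-memory cohort")
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop_placseg("input_dir does not exist: %s", input_dir)
  if (alpha <= 0 || alpha >= 1) stop_placseg("alpha must lie in (0, 1)")
  if (K < 2L) stop_placseg("K must be >= 2")
  structure(list(input_dir = input_dir, cohort = cohort, out_dir = out_dir,
                 K = as.integer(K), alpha = alpha, seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts),
                 n_layers = as.integer(n_layers),
                 write_volumes = write_volumes),
            class = "placseg_config")
}

#' Run the full pipeline
#'
#' Loads (or takes) the cohort, runs [analyze_cohort()], and writes the
#' result bundle: `records.csv`, `layer_table.csv`, `trends.csv`,
#' `model.json`, `stats.json` and a run `manifest.json` (package version,
#' seed, options). Identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The `placseg_analysis`, invisibly if writing outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "placseg_config"))
  cohort <- config$cohort
  if (is.null(cohort)) {
    dirs <- list.dirs(config$input_dir, recursive = FALSE)
    if (length(dirs) == 0L) stop_placseg("no subject directories in %s",
                                         config$input_dir)
    cohort <- lapply(sort(dirs), read_phantom)
  }
  subjects <- if (inherits(cohort, "placseg_cohort")) cohort$subjects else cohort
  res <- analyze_cohort(cohort, K = config$K, alpha = config$alpha,
                        seed = config$seed, n_restarts = config$n_restarts,
                        n_layers = config$n_layers)
  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res$records, file.path(od, "records.csv"), row.names = FALSE)
    if (!is.null(res$layer_table))
      utils::write.csv(res$layer_table, file.path(od, "layer_table.csv"),
                       row.names = FALSE)
    trends <- do.call(rbind, lapply(names(res$stats$trends), function(cc) {
      f <- res$stats$trends[[cc]]
      if (is.null(f)) return(NULL)
      data.frame(compartment = cc, slope = f$slope, slope_se = f$slope_se,
                 ci_lwr = f$slope_ci[1], ci_upr = f$slope_ci[2],
                 r_squared = f$r_squared, p_value = f$p_value, n = f$n)
    }))
    if (!is.null(trends))
      utils::write.csv(trends, file.path(od, "trends.csv"), row.names = FALSE)
    write_mixture_json(res$model, file.path(od, "model.json"))
    stats_out <- list(
      pl_group_p = if (!is.null(res$stats$pl)) res$stats$pl$group_test$p_value,
      pl_delivery_slope = if (!is.null(res$stats$pl))
        res$stats$pl$delivery_regression$slope,
      brain_best_compartment = if (!is.null(res$stats$brain)) res$stats$brain$best,
      brain_r_squared = if (!is.null(res$stats$brain))
        stats::setNames(res$stats$brain$summary$r_squared,
                        res$stats$brain$summary$compartment))
    jsonlite::write_json(stats_out, file.path(od, "stats.json"),
                         digits = NA, auto_unbox = TRUE, null = "null")
    manifest <- list(package = "placseg",
                     version = as.character(utils::packageVersion("placseg")),
                     seed = config$seed,
                     options = list(K = config$K, alpha = config$alpha,
                                    n_restarts = config$n_restarts,
                                    n_layers = config$n_layers))
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
    if (config$write_volumes) {
      sd <- file.path(od, "labels")
      dir.create(sd, showWarnings = FALSE)
      code <- c(IVS = 1L, PV = 2L, PT = 3L, PL = 4L)
      for (i in seq_along(res$segmentations)) {
        seg <- res$segmentations[[i]]
        lab <- array(0L, seg$dim)
        lab[seg$voxel_index] <- code[as.character(seg$hard_label)]
        write_volume(lab, file.path(sd, sprintf("S%02d_labels.nii.gz", i)),
                     subjects[[i]]$truth$voxel_size %||% c(1, 1, 1))
      }
    }
    return(invisible(res))
  }
  res
}
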