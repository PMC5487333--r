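# NIfTI input/output, preprocessing (intensity normalization, ROI cropping),
# run configuration and the end-to-end pipeline.

#' Linear min-max intensity normalization to 0--255
#'
#' Applies \eqn{(I - I_{min}) / (I_{max} - I_{min}) \times 255} so the output
#' range is exactly [0, 255].
#'
#' @param I An [image_volume()] or numeric array.
#' @return An [image_volume()] with the same spacing.
#' @export
normalize_intensity <- function(I) {
  iv <- as_image_volume(I)
  rng <- range(iv$data)
  if (rng[1] == rng[2])
    stop("cannot normalize a constant image (min == max)")
  image_volume((iv$data - rng[1]) / (rng[2] - rng[1]) * 255, iv$spacing)
}

#' Bounding region of the union of labels
#'
#' Tight per-axis bounding box of the voxelwise union of the given masks,
#' dilated by `margin` voxels and clipped to the grid. Any structure contained
#' in the union is guaranteed to lie inside the region.
#'
#' @param labels List of congruent binary masks, at least one nonzero.
#' @param margin Dilation in voxels (default 5).
#' @return List with integer vectors `lo` and `hi` (inclusive per-axis
#'   bounds).
#' @export
roi_union <- function(labels, margin = 5L) {
  if (length(labels) < 1L) stop("need at least one label")
  for (L in labels) check_mask(L, "label")
  d <- do.call(check_congruent, c(labels, list(what = "labels")))
  u <- Reduce(`+`, labels) > 0
  if (!any(u)) stop("all labels are empty; no region of interest exists")
  idx <- which(u, arr.ind = TRUE)
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 1L)
  lo <- pmax(apply(idx, 2L, min) - margin, 1L)
  hi <- pmin(apply(idx, 2L, max) + margin, d)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

crop_to_roi <- function(x, roi) {
  d <- grid_dim(x)
  pick <- lapply(seq_along(d), function(a) roi$lo[a]:roi$hi[a])
  do.call(`[`, c(list(x), pick, list(drop = FALSE)))
}

uncrop_mask <- function(mask, roi, full_dim) {
  out <- array(0, full_dim)
  pick <- lapply(seq_along(full_dim), function(a) roi$lo[a]:roi$hi[a])
  do.call(`[<-`, c(list(out), pick, list(mask)))
}

#' Read a grayscale volume from NIfTI
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return An [image_volume()]; spacing is taken from the NIfTI pixdim.
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  sp <- RNifti::pixdim(img)[seq_along(dim(arr))]
  image_volume(arr, sp)
}

#' Read a binary mask from NIfTI
#'
#' Accepts files with exactly two distinct values `{0, k}` (any positive label
#' value k is relabelled to 1) or the single value 0.
#'
#' @inheritParams load_volume
#' @return List with `mask` (binary array) and `spacing`.
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  vals <- sort(unique(as.vector(arr)))
  if (length(vals) > 2L || (length(vals) == 2L && !(0 %in% vals)))
    stop("mask file ", path, " is not binary; values found: ",
         paste(utils::head(vals, 8), collapse = ", "))
  arr <- array(as.numeric(arr != 0), dim(arr))  # relabel {0,k} -> {0,1}
  sp <- RNifti::pixdim(img)[seq_along(dim(arr))]
  list(mask = arr, spacing = sp)
}

#' Write a mask (or volume) as NIfTI
#'
#' Copies grid metadata (affine, pixdim) from a reference image when given.
#'
#' @param mask Numeric array to write.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param reference Optional path to a NIfTI file or an `RNifti` image whose
#'   header geometry is copied.
#' @param spacing Per-axis voxel size used when no reference is given.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path, reference = NULL, spacing = 1) {
  if (!is.null(reference)) {
    ref <- if (is.character(reference)) RNifti::readNifti(reference) else reference
    img <- RNifti::asNifti(mask, reference = ref)
  } else {
    img <- RNifti::asNifti(mask)
    sp <- expand_spacing(spacing, length(grid_dim(mask)))
    RNifti::pixdim(img) <- sp
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Run configuration
#'
#' Assembles everything one segmentation run needs; mirrors the YAML config
#' accepted by the command line (see [read_run_config()]).
#'
#' @param target_path NIfTI path of the target volume.
#' @param atlas_label_paths Character vector of propagated-label NIfTI paths.
#' @param similarity_map_paths Optional character vector, same length, of
#'   nonnegative local-similarity NIfTI paths (omitted: uniform weights).
#' @param truth_path Optional ground-truth NIfTI path; enables metrics output.
#' @param params A [fusion_params()].
#' @param roi_mode `"union"` (crop to the dilated bounding box of the label
#'   union) or `"none"`.
#' @param roi_margin ROI dilation in voxels.
#' @param output_dir Directory for outputs (created if missing).
#' @param normalize Whether to min-max normalize the target to 0--255.
#' @return Object of class `run_config`.
#' @export
run_config <- function(target_path, atlas_label_paths,
                       similarity_map_paths = NULL, truth_path = NULL,
                       params = fusion_params(),
                       roi_mode = c("union", "none"), roi_margin = 5L,
                       output_dir = ".", normalize = TRUE) {
  roi_mode <- match.arg(roi_mode)
  if (!is.null(similarity_map_paths) &&
      length(similarity_map_paths) != length(atlas_label_paths))
    stop("atlas_label_paths and similarity_map_paths must have equal length")
  structure(list(target_path = target_path,
                 atlas_label_paths = atlas_label_paths,
                 similarity_map_paths = similarity_map_paths,
                 truth_path = truth_path, params = params,
                 roi_mode = roi_mode, roi_margin = as.integer(roi_margin),
                 output_dir = output_dir, normalize = isTRUE(normalize)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' The YAML mirrors [run_config()] field for field; the optional `params`
#' block mirrors [fusion_params()] (absent fields keep their defaults).
#'
#' @param path YAML file path.
#' @param base_dir Directory against which relative paths in the file are
#'   resolved (default: the YAML's directory).
#' @return A `run_config`.
#' @export
read_run_config <- function(path, base_dir = dirname(path)) {
  y <- yaml::read_yaml(path)
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    vapply(p, function(pi)
      if (file.exists(pi)) pi else file.path(base_dir, pi), character(1),
      USE.NAMES = FALSE)
  }
  params <- do.call(fusion_params, if (is.null(y$params)) list() else y$params)
  run_config(target_path = resolve(y$target_path),
             atlas_label_paths = resolve(y$atlas_label_paths),
             similarity_map_paths = resolve(y$similarity_map_paths),
             truth_path = resolve(y$truth_path),
             params = params,
             roi_mode = if (is.null(y$roi_mode)) "union" else y$roi_mode,
             roi_margin = if (is.null(y$roi_margin)) 5L else y$roi_margin,
             output_dir = if (is.null(y$output_dir)) "." else y$output_dir,
             normalize = if (is.null(y$normalize)) TRUE else y$normalize)
}

#' End-to-end segmentation pipeline
#'
#' Loads the target and propagated labels, normalizes intensities, crops to
#' the label-union region of interest, builds the atlas ensemble (signed
#' distances plus normalized weights), runs [malsf_segment()], pads the mask
#' back to the full grid, and writes the mask (NIfTI), energy trace (CSV),
#' metrics (CSV, when ground truth is supplied) and a JSON run manifest into
#' `output_dir`. Fully deterministic: identical inputs produce identical
#' outputs.
#'
#' @param config A [run_config()] or path to a YAML file.
#' @return Invisibly, a list with `result` ([malsf_segment()] output on the
#'   ROI grid), `mask` (full-grid binary array), `metrics` (or `NULL`), `roi`,
#'   and output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  target <- load_volume(config$target_path)
  full_dim <- grid_dim(target$data)

  labels <- lapply(config$atlas_label_paths, function(p) {
    lm <- load_mask(p)
    if (!identical(grid_dim(lm$mask), full_dim))
      stop("atlas label grid mismatch with target: ", p)
    lm$mask
  })
  similarity <- NULL
  if (!is.null(config$similarity_map_paths)) {
    similarity <- lapply(config$similarity_map_paths, function(p) {
      s <- load_volume(p)
      if (!identical(grid_dim(s$data), full_dim))
        stop("similarity map grid mismatch with target: ", p)
      s$data
    })
  }
  if (config$normalize) target <- normalize_intensity(target)

  if (config$roi_mode == "union") {
    roi <- roi_union(labels, config$roi_margin)
  } else {
    roi <- list(lo = rep(1L, length(full_dim)), hi = as.integer(full_dim))
  }
  img_c <- image_volume(crop_to_roi(target$data, roi), target$spacing)
  labels_c <- lapply(labels, crop_to_roi, roi = roi)
  sim_c <- if (is.null(similarity)) NULL
           else lapply(similarity, crop_to_roi, roi = roi)
  ensemble <- atlas_ensemble(labels_c, sim_c, spacing = target$spacing)

  result <- malsf_segment(img_c, ensemble, config$params)
  mask_full <- uncrop_mask(result$mask, roi, full_dim)

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    mask = file.path(config$output_dir, "segmentation.nii.gz"),
    energy = file.path(config$output_dir, "energy_trace.csv"),
    manifest = file.path(config$output_dir, "run_manifest.json"))
  save_mask(mask_full, paths$mask, reference = config$target_path)
  utils::write.csv(result$energy_trace, paths$energy, row.names = FALSE)

  metrics <- NULL
  if (!is.null(config$truth_path)) {
    truth <- load_mask(config$truth_path)$mask
    om <- overlap_metrics(truth, mask_full)
    hd <- hausdorff_distance(truth, mask_full, target$spacing)
    metrics <- data.frame(target_id = basename(config$target_path),
                          method = "malsf", si = om$si, p = om$precision,
                          r = om$recall, ro = om$ro, hd = hd)
    paths$metrics <- file.path(config$output_dir, "metrics.csv")
    utils::write.csv(metrics, paths$metrics, row.names = FALSE)
  }

  manifest <- list(
    target = config$target_path,
    n_atlases = length(labels),
    weights = if (is.null(similarity)) "uniform" else "similarity",
    roi_mode = config$roi_mode, roi = roi,
    params = unclass(config$params),
    iterations_run = result$iterations_run,
    converged = result$converged,
    deterministic = "no randomness in the fusion core; reruns are bit-identical",
    package_version = as.character(utils::packageVersion("malsf")))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(result = result, mask = mask_full, metrics = metrics,
                 roi = roi, paths = paths))
}
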