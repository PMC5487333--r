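# Voting baselines and segmentation-quality metrics.

#' Volumetric overlap metrics
#'
#' Computes, from voxel counts, the similarity index (Dice)
#' \eqn{SI = 2V(A\cap B)/(V(A)+V(B))}, precision \eqn{P = V(A\cap B)/V(B)},
#' recall \eqn{R = V(A\cap B)/V(A)} and relative overlap (Jaccard)
#' \eqn{RO = V(A\cap B)/V(A\cup B)}, with A the ground truth and B the
#' automatic segmentation.
#'
#' @param truth Binary ground-truth mask A.
#' @param auto Binary automatic mask B, congruent with `truth`.
#' @return List with fields `si`, `precision`, `recall`, `ro`, all in [0, 1].
#' @export
overlap_metrics <- function(truth, auto) {
  check_mask(truth, "truth mask"); check_mask(auto, "auto mask")
  check_congruent(truth, auto)
  va <- sum(truth); vb <- sum(auto)
  if (va == 0 && vb == 0) stop("both masks are empty; metrics undefined")
  vi <- sum(truth * auto)
  vu <- va + vb - vi
  list(si = 2 * vi / (va + vb),
       precision = if (vb > 0) vi / vb else NA_real_,
       recall = if (va > 0) vi / va else NA_real_,
       ro = vi / vu)
}

# Boundary voxels: structure voxels with at least one opposite-valued face
# neighbour (grid border counts as outside for mask voxels on the edge).
boundary_voxels <- function(mask) {
  d <- grid_dim(mask)
  inside <- mask > 0.5
  on_bnd <- array(FALSE, d)
  for (axis in seq_along(d)) {
    for (k in c(-1L, 1L)) {
      nb <- shift_edge(inside, k, axis)
      on_bnd <- on_bnd | (inside & !nb)
    }
  }
  which(on_bnd, arr.ind = TRUE)
}

# Shift with "outside" (FALSE) padding at the grid edge.
shift_edge <- function(x, k, axis) {
  d <- grid_dim(x)
  n <- d[axis]
  idx <- seq_len(n) - k
  out_of <- idx < 1L | idx > n
  idx[out_of] <- 1L
  pick <- rep(list(quote(expr = )), length(d))
  pick[[axis]] <- idx
  res <- do.call(`[`, c(list(x), pick, list(drop = FALSE)))
  fill <- rep(list(quote(expr = )), length(d))
  fill[[axis]] <- which(out_of)
  if (any(out_of)) res <- do.call(`[<-`, c(list(res), fill, list(FALSE)))
  res
}

#' Hausdorff distance between two masks
#'
#' Symmetric Hausdorff distance \eqn{HD = \max(H_1, H_2)} where
#' \eqn{H_1 = \max_{a\in A}\min_{b\in B} d(a,b)} and \eqn{H_2} swaps the
#' roles; the point sets are the boundary voxels of each mask (voxels with an
#' opposite-valued face neighbour) and d is the Euclidean distance in physical
#' units. Directed distances are evaluated through an exact distance transform
#' of each boundary set.
#'
#' @param truth,auto Nonempty congruent binary masks.
#' @param spacing Per-axis voxel size (mm); scalar recycled.
#' @return Single nonnegative number (0 iff the boundary sets coincide).
#' @export
hausdorff_distance <- function(truth, auto, spacing = 1) {
  check_mask(truth, "truth mask"); check_mask(auto, "auto mask")
  d <- check_congruent(truth, auto)
  if (sum(truth) == 0 || sum(auto) == 0)
    stop("Hausdorff distance undefined for an empty mask")
  spacing <- expand_spacing(spacing, length(d))
  ba <- boundary_voxels(truth)
  bb <- boundary_voxels(auto)
  sites_a <- array(FALSE, d); sites_a[ba] <- TRUE
  sites_b <- array(FALSE, d); sites_b[bb] <- TRUE
  dist_to_b <- sqrt(edt_squared(sites_b, spacing))
  dist_to_a <- sqrt(edt_squared(sites_a, spacing))
  h1 <- max(dist_to_b[sites_a])
  h2 <- max(dist_to_a[sites_b])
  max(h1, h2)
}

#' Majority-vote label fusion
#'
#' Assigns a voxel to the structure iff strictly more than half of the atlases
#' label it so (ties go to background).
#'
#' @param labels List of N congruent binary masks.
#' @return Binary mask array.
#' @export
majority_vote <- function(labels) {
  if (length(labels) < 1L) stop("need at least one label")
  for (L in labels) check_mask(L, "label")
  do.call(check_congruent, c(labels, list(what = "labels")))
  total <- Reduce(`+`, labels)
  array(as.numeric(total > length(labels) / 2), grid_dim(labels[[1L]]))
}

#' Weighted-vote label fusion
#'
#' Assigns a voxel to the structure iff the weight-averaged label
#' \eqn{\sum_i \omega_i(x) L_i(x)} exceeds 0.5 (ties to background). With
#' uniform weights this reduces to [majority_vote()].
#'
#' @param labels List of N congruent binary masks.
#' @param weights List of N voxelwise weights summing to 1 (see
#'   [normalize_weights()]).
#' @return Binary mask array.
#' @export
weighted_vote <- function(labels, weights) {
  if (length(labels) < 1L) stop("need at least one label")
  if (length(weights) != length(labels))
    stop("got ", length(labels), " labels but ", length(weights), " weights")
  for (L in labels) check_mask(L, "label")
  do.call(check_congruent, c(labels, weights, list(what = "labels/weights")))
  acc <- array(0, grid_dim(labels[[1L]]))
  for (i in seq_along(labels)) acc <- acc + weights[[i]] * labels[[i]]
  array(as.numeric(acc > 0.5), grid_dim(labels[[1L]]))
}
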