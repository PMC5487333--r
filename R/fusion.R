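# MALSF core: the label-fusion energy, total energy E = alpha*F + beta*D +
# gamma*R, and the level-set evolution that minimizes it.

#' Fusion framework parameters
#'
#' Bundles every tunable of the variational fusion model. Defaults are the
#' values used throughout: term coefficients alpha = 0.1 (label fusion),
#' beta = 1 (image term), gamma = 0.1 (regularization, energy reporting),
#' mu = 0.1 (distance regularization), upsilon = 0.01 (curvature flow),
#' lambda1 = lambda2 = 1e-4 (inside/outside fitting weights); numerics
#' eps = 1 voxel (Heaviside width), rho = 3 voxels (fitting window scale),
#' dt = 0.1 (time step), max_iters = 200, tol = 1e-4 relative energy change
#' over a 5-iteration window (`tol = 0` disables early stopping).
#'
#' @param alpha,beta,gamma Coefficients of the fusion, image and regularization
#'   energies (nonnegative).
#' @param mu Distance-regularization coefficient.
#' @param upsilon Curvature (arc-length shrinking) flow coefficient.
#' @param lambda1,lambda2 Weights of the inside/outside fitting residuals.
#' @param eps Smoothed Heaviside/Dirac width (voxels).
#' @param rho Gaussian fitting-window scale (voxels).
#' @param dt Explicit Euler time step.
#' @param max_iters Maximum number of evolution steps (>= 0).
#' @param tol Relative energy-change stopping tolerance (5-iteration window).
#' @param fusion_in_flow If `TRUE` (default) the analytic gradient of the
#'   fusion term drives the evolution; if `FALSE` the atlas prior enters only
#'   through the initialization.
#' @param curvature_coeff_mode `"upsilon"` (default): the curvature flow is
#'   scaled by `upsilon` alone; `"gamma_upsilon"`: scaled by `gamma * upsilon`.
#' @param init Default initialization of [malsf_segment()]: `"weighted"`
#'   (pointwise weighted mean of atlas level sets) or `"majority"` (signed
#'   distance of the majority-vote mask).
#' @return Object of class `fusion_params`.
#' @export
fusion_params <- function(alpha = 0.1, beta = 1, gamma = 0.1, mu = 0.1,
                          upsilon = 0.01, lambda1 = 1e-4, lambda2 = 1e-4,
                          eps = 1, rho = 3, dt = 0.1, max_iters = 200L,
                          tol = 1e-4, fusion_in_flow = TRUE,
                          curvature_coeff_mode = c("upsilon", "gamma_upsilon"),
                          init = c("weighted", "majority")) {
  coef <- c(alpha = alpha, beta = beta, gamma = gamma, mu = mu,
            upsilon = upsilon, lambda1 = lambda1, lambda2 = lambda2)
  if (any(!is.finite(coef)) || any(coef < 0))
    stop("all term coefficients must be finite and >= 0")
  if (!is.finite(eps) || eps <= 0) stop("eps must be > 0")
  if (!is.finite(rho) || rho <= 0) stop("rho must be > 0")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (max_iters < 0) stop("max_iters must be >= 0")
  if (tol < 0) stop("tol must be >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, mu = mu,
                 upsilon = upsilon, lambda1 = lambda1, lambda2 = lambda2,
                 eps = eps, rho = rho, dt = dt,
                 max_iters = as.integer(max_iters), tol = tol,
                 fusion_in_flow = isTRUE(fusion_in_flow),
                 curvature_coeff_mode = match.arg(curvature_coeff_mode),
                 init = match.arg(init)),
            class = "fusion_params")
}

#' @export
print.fusion_params <- function(x, ...) {
  cat("<fusion_params>\n")
  cat(sprintf("  alpha=%g beta=%g gamma=%g mu=%g upsilon=%g lambda1=%g lambda2=%g\n",
              x$alpha, x$beta, x$gamma, x$mu, x$upsilon, x$lambda1, x$lambda2))
  cat(sprintf("  eps=%g rho=%g dt=%g max_iters=%d tol=%g\n",
              x$eps, x$rho, x$dt, x$max_iters, x$tol))
  cat(sprintf("  fusion_in_flow=%s curvature_coeff_mode=%s init=%s\n",
              x$fusion_in_flow, x$curvature_coeff_mode, x$init))
  invisible(x)
}

#' Pointwise-normalized fusion weights
#'
#' Turns N nonnegative local-similarity maps into voxelwise convex weights
#' \eqn{\omega_i(x) = s_i(x)/\sum_j s_j(x)}; voxels where every map is zero
#' fall back to the uniform weight 1/N.
#'
#' @param similarity_maps List of N congruent nonnegative arrays.
#' @return List of N weight arrays summing to 1 at every voxel.
#' @export
normalize_weights <- function(similarity_maps) {
  if (length(similarity_maps) < 1L) stop("need at least one similarity map")
  do.call(check_congruent, c(similarity_maps, list(what = "similarity maps")))
  for (s in similarity_maps)
    if (any(s < 0)) stop("similarity maps must be nonnegative")
  total <- Reduce(`+`, similarity_maps)
  n <- length(similarity_maps)
  zero <- total <= 0
  total[zero] <- 1
  lapply(similarity_maps, function(s) {
    w <- s / total
    w[zero] <- 1 / n
    w
  })
}

#' Atlas ensemble for label fusion
#'
#' Packs N propagated binary atlas labels with their signed-distance level
#' sets and voxelwise fusion weights. Weights come from the optional
#' local-similarity maps via [normalize_weights()]; with none given, uniform
#' 1/N weights are used.
#'
#' @param labels List of N congruent binary masks (propagated atlas labels).
#' @param similarity Optional list of N nonnegative similarity maps on the
#'   same grid.
#' @param spacing Per-axis voxel size (mm) used for the signed distances.
#' @return Object of class `atlas_ensemble` with fields `labels`, `lsfs`,
#'   `weights`, `spacing`, `n`.
#' @export
atlas_ensemble <- function(labels, similarity = NULL, spacing = 1) {
  if (length(labels) < 1L) stop("need at least one atlas label")
  for (L in labels) check_mask(L, "atlas label")
  do.call(check_congruent, c(labels, list(what = "atlas labels")))
  n <- length(labels)
  if (!is.null(similarity)) {
    if (length(similarity) != n)
      stop("similarity list length (", length(similarity),
           ") must match number of labels (", n, ")")
    check_congruent(labels[[1L]], similarity[[1L]])
    weights <- normalize_weights(similarity)
  } else {
    d <- grid_dim(labels[[1L]])
    weights <- replicate(n, array(1 / n, d), simplify = FALSE)
  }
  lsfs <- lapply(labels, signed_distance, spacing = spacing)
  structure(list(labels = labels, lsfs = lsfs, weights = weights,
                 spacing = expand_spacing(spacing, length(grid_dim(labels[[1L]]))),
                 n = n),
            class = "atlas_ensemble")
}

#' @export
print.atlas_ensemble <- function(x, ...) {
  cat("<atlas_ensemble> ", x$n, " atlases on ",
      paste(dim(x$labels[[1L]]), collapse = " x "), " grid\n", sep = "")
  invisible(x)
}

#' Label-fusion energy
#'
#' \eqn{F(\phi) = \sum_x \sum_i \omega_i(x)\,|\phi(x) - \phi_i(x)|^2}: the
#' weighted squared deviation of the evolving level set from each atlas level
#' set. Zero exactly when \eqn{\phi} coincides with every atlas field wherever
#' its weight is positive.
#'
#' @param phi Level set array.
#' @param ensemble An [atlas_ensemble()].
#' @return Single nonnegative number.
#' @export
fusion_energy <- function(phi, ensemble) {
  check_congruent(phi, ensemble$lsfs[[1L]])
  total <- 0
  for (i in seq_len(ensemble$n)) {
    d <- phi - ensemble$lsfs[[i]]
    total <- total + sum(ensemble$weights[[i]] * d * d)
  }
  total
}

#' Gradient-descent force of the fusion energy
#'
#' \eqn{-2\sum_i \omega_i(x)(\phi(x) - \phi_i(x))}; vanishes exactly at the
#' pointwise weighted mean \eqn{\sum_i \omega_i \phi_i}, the fusion term's
#' minimizer.
#'
#' @inheritParams fusion_energy
#' @return Force array, same dimensions as `phi`.
#' @export
fusion_force <- function(phi, ensemble) {
  check_congruent(phi, ensemble$lsfs[[1L]])
  acc <- array(0, grid_dim(phi))
  for (i in seq_len(ensemble$n))
    acc <- acc + ensemble$weights[[i]] * (phi - ensemble$lsfs[[i]])
  -2 * acc
}

weighted_mean_lsf <- function(ensemble) {
  acc <- array(0, grid_dim(ensemble$lsfs[[1L]]))
  for (i in seq_len(ensemble$n))
    acc <- acc + ensemble$weights[[i]] * ensemble$lsfs[[i]]
  acc
}

#' Contour-length regularization energy
#'
#' Smoothed co-area form of the arc length of the zero level contour:
#' \eqn{R(\phi) = \sum_x \delta_\varepsilon(\phi)\,|\nabla\phi|
#'  = \sum_x |\nabla H_\varepsilon(\phi)|}. For a signed distance to a circle
#' of radius r this approximates the perimeter \eqn{2\pi r}.
#'
#' @param phi Level set array.
#' @param eps Heaviside/Dirac width (voxels).
#' @param spacing Per-axis voxel size; scalar recycled.
#' @return Single nonnegative number.
#' @export
regularization_energy <- function(phi, eps = 1, spacing = 1) {
  g <- gradient_list(phi, spacing)
  mag <- sqrt(Reduce(`+`, lapply(g, function(gi) gi * gi)))
  sum(dirac_eps(phi, eps) * mag)
}

#' Total fusion energy and its components
#'
#' Evaluates \eqn{E = \alpha F + \beta D + \gamma R} for the current level
#' set, reporting each weighted component.
#'
#' @inheritParams fusion_energy
#' @param I Target [image_volume()] or array.
#' @param f Fitting functions from [compute_fitting_functions()].
#' @param params A [fusion_params()].
#' @return Named list: `fusion` (\eqn{\alpha F}), `data` (\eqn{\beta D}),
#'   `regularization` (\eqn{\gamma R}), `total`.
#' @export
total_energy <- function(phi, I, ensemble, f, params = fusion_params()) {
  I_arr <- as_image_volume(I)$data
  check_congruent(phi, I_arr)
  comp <- list(
    fusion = params$alpha * fusion_energy(phi, ensemble),
    data = params$beta * rsf_energy(I_arr, phi, f, params),
    regularization = params$gamma *
      regularization_energy(phi, params$eps, ensemble$spacing))
  comp$total <- comp$fusion + comp$data + comp$regularization
  comp
}

# One explicit-Euler update; f/e are the current-iterate fitting quantities.
evolve_update <- function(phi, I_arr, ensemble, params, f, e) {
  spacing <- ensemble$spacing
  dl <- dirac_eps(phi, params$eps)
  upd <- array(0, grid_dim(phi))
  if (params$fusion_in_flow && params$alpha > 0)
    upd <- upd + params$alpha * fusion_force(phi, ensemble)
  if (params$beta > 0)
    upd <- upd + params$beta * dl *
      (params$lambda1 * e$e1 - params$lambda2 * e$e2)
  curv_coef <- if (params$curvature_coeff_mode == "gamma_upsilon")
    params$gamma * params$upsilon else params$upsilon
  if (curv_coef > 0 || params$mu > 0) {
    kappa <- curvature(phi, spacing)
    if (curv_coef > 0) upd <- upd + curv_coef * dl * kappa
    if (params$mu > 0)
      upd <- upd + params$mu * (laplacian(phi, spacing) - kappa)
  }
  phi_new <- phi + params$dt * upd
  if (!all(is.finite(phi_new)))
    stop("level set evolution diverged (non-finite update); reduce dt = ",
         params$dt)
  phi_new
}

#' Single level-set evolution step
#'
#' Recomputes the fitting functions from the current level set, then applies
#' one explicit Euler step of the full evolution equation: fusion force
#' (coefficient alpha), data force (beta, lambda1/lambda2), curvature flow
#' (upsilon) and distance regularization (mu). With all coefficients zero the
#' step is the identity.
#'
#' @inheritParams total_energy
#' @return Updated level set array.
#' @export
evolve_step <- function(phi, I, ensemble, params = fusion_params()) {
  I_arr <- as_image_volume(I)$data
  check_congruent(phi, I_arr, ensemble$lsfs[[1L]])
  f <- compute_fitting_functions(I_arr, phi, params$rho, params$eps)
  e <- compute_e_fields(I_arr, f, params$rho)
  evolve_update(phi, I_arr, ensemble, params, f, e)
}

#' Multi-atlas level-set segmentation
#'
#' Top-level fusion routine: initializes the level set (by default at the
#' pointwise weighted mean of the atlas level sets, the fusion term's
#' minimizer), then evolves it under the fusion, image and regularity forces
#' until `max_iters` steps or until the relative change of the total energy
#' over a 5-iteration window falls below `tol`. The output mask is the strict
#' interior `phi < 0`.
#'
#' @param I Target [image_volume()] (or array; the ensemble spacing is used).
#' @param ensemble An [atlas_ensemble()] of propagated labels in the target
#'   frame.
#' @param params A [fusion_params()].
#' @param init Optional initial level set array; default per `params$init`.
#' @return Object of class `malsf_result`: `mask` (binary array, `phi < 0`),
#'   `phi` (final level set), `energy_trace` (data.frame with one row per
#'   iteration plus the initial state: `iter`, `fusion`, `data`,
#'   `regularization`, `total`), `iterations_run`, `converged`, `empty_mask`.
#' @examples
#' ph <- make_phantom(phantom_spec(grid_size = c(48, 48), seed = 1))
#' ens <- make_atlas_ensemble(ph$truth, atlas_perturb_spec(n_atlases = 5, seed = 1))
#' res <- malsf_segment(ph$image, ens, fusion_params(max_iters = 30))
#' overlap_metrics(ph$truth, res$mask)$si
#' @export
malsf_segment <- function(I, ensemble, params = fusion_params(), init = NULL) {
  iv <- as_image_volume(I, ensemble$spacing)
  I_arr <- iv$data
  check_congruent(I_arr, ensemble$lsfs[[1L]])
  phi <- if (!is.null(init)) {
    check_congruent(init, I_arr)
    init
  } else if (params$init == "majority") {
    signed_distance(majority_vote(ensemble$labels), ensemble$spacing)
  } else {
    weighted_mean_lsf(ensemble)
  }

  energy_row <- function(iter, phi, f) {
    comp <- total_energy(phi, I_arr, ensemble, f, params)
    data.frame(iter = iter, fusion = comp$fusion, data = comp$data,
               regularization = comp$regularization, total = comp$total)
  }

  f <- compute_fitting_functions(I_arr, phi, params$rho, params$eps)
  trace <- vector("list", params$max_iters + 1L)
  trace[[1L]] <- energy_row(0L, phi, f)
  iters <- 0L
  converged <- FALSE
  window <- 5L
  if (params$max_iters > 0) for (t in seq_len(params$max_iters)) {
    e <- compute_e_fields(I_arr, f, params$rho)
    phi <- evolve_update(phi, I_arr, ensemble, params, f, e)
    f <- compute_fitting_functions(I_arr, phi, params$rho, params$eps)
    iters <- t
    trace[[t + 1L]] <- energy_row(t, phi, f)
    if (params$tol > 0 && t > window) {
      e_now <- trace[[t + 1L]]$total
      e_ref <- trace[[t + 1L - window]]$total
      if (abs(e_now - e_ref) < params$tol * max(abs(e_ref), .Machine$double.eps)) {
        converged <- TRUE
        break
      }
    }
  }
  mask <- array(as.numeric(phi < 0), grid_dim(phi))
  empty <- sum(mask) == 0
  if (empty) warning("final segmentation mask is empty")
  structure(list(mask = mask, phi = phi,
                 energy_trace = do.call(rbind, trace[seq_len(iters + 1L)]),
                 iterations_run = iters, converged = converged,
                 empty_mask = empty, params = params),
            class = "malsf_result")
}

#' @export
print.malsf_result <- function(x, ...) {
  tr <- x$energy_trace
  cat("<malsf_result> ", sum(x$mask), " voxels segmented after ",
      x$iterations_run, " iterations",
      if (x$converged) " (converged)" else "", "\n", sep = "")
  cat(sprintf("  energy %.4g -> %.4g (fusion %.4g, data %.4g, regularization %.4g)\n",
              tr$total[1L], tr$total[nrow(tr)], tr$fusion[nrow(tr)],
              tr$data[nrow(tr)], tr$regularization[nrow(tr)]))
  invisible(x)
}

#' Grid search for fusion parameters
#'
#' Leave-one-out style tuner: every combination of the supplied per-parameter
#' value lists is run on every training target, the similarity index against
#' the target's ground truth is averaged, and the combination with the highest
#' mean SI wins. Ties are broken by first position in grid iteration order
#' (first parameter varying fastest), so the search is deterministic.
#'
#' @param training_targets List of lists, each with fields `image`
#'   ([image_volume()] or array), `truth` (binary mask) and `ensemble`
#'   ([atlas_ensemble()]).
#' @param grid Named list of candidate value vectors for [fusion_params()]
#'   arguments (e.g. `list(alpha = c(0.05, 0.1), upsilon = c(0.01))`).
#' @param base A [fusion_params()] supplying every parameter not in `grid`.
#' @return The winning `fusion_params`, with attributes `mean_si` (winner's
#'   score) and `search` (data.frame of all combinations and scores).
#' @export
tune_parameters <- function(training_targets, grid, base = fusion_params()) {
  if (length(training_targets) < 2L)
    stop("need at least two training targets")
  if (length(grid) == 0L || any(lengths(grid) == 0L))
    stop("parameter grid must be a nonempty named list of nonempty vectors")
  if (is.null(names(grid)) || any(names(grid) == ""))
    stop("parameter grid entries must be named")
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  scores <- numeric(nrow(combos))
  for (k in seq_len(nrow(combos))) {
    args <- as.list(base)[setdiff(names(base), names(combos))]
    args <- c(args, as.list(combos[k, , drop = FALSE]))
    pk <- do.call(fusion_params, args)
    si <- vapply(training_targets, function(tt) {
      res <- malsf_segment(tt$image, tt$ensemble, pk)
      overlap_metrics(tt$truth, res$mask)$si
    }, numeric(1))
    scores[k] <- mean(si)
  }
  best <- which.max(scores)  # first maximum: first-in-grid tie-break
  args <- as.list(base)[setdiff(names(base), names(combos))]
  args <- c(args, as.list(combos[best, , drop = FALSE]))
  out <- do.call(fusion_params, args)
  attr(out, "mean_si") <- scores[best]
  attr(out, "search") <- cbind(combos, mean_si = scores)
  out
}
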