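# Region-scalable fitting (RSF) image term.
#
# Around every point y the image is approximated inside/outside the contour by
# local constants f1(y), f2(y), fitted within a Gaussian window K_rho. The
# closed-form minimizers and the e-fields below are the standard alternating
# scheme: f is refit from the current phi, then phi moves along the data force.

#' Local fitting functions f1 and f2
#'
#' Closed-form minimizers of the region-scalable fitting energy for a fixed
#' level set: \eqn{f_i = K_\rho * (M_i(\phi) I) / K_\rho * M_i(\phi)} with
#' membership \eqn{M_1 = 1 - H_\varepsilon(\phi)} (inside, \eqn{\phi < 0}) and
#' \eqn{M_2 = H_\varepsilon(\phi)} (outside). Denominators are floored at
#' 1e-10 so a locally absent phase yields a finite (if meaningless) fit rather
#' than NaN.
#'
#' @param I An [image_volume()] or numeric array.
#' @param phi Level set array congruent with `I`.
#' @param rho Gaussian window scale (voxels).
#' @param eps Heaviside width (voxels).
#' @return List with fields `f1` (inside fit) and `f2` (outside fit).
#' @export
compute_fitting_functions <- function(I, phi, rho = 3, eps = 1) {
  I <- as_image_volume(I)$data
  check_congruent(I, phi)
  H <- heaviside_eps(phi, eps)
  m1 <- 1 - H
  m2 <- H
  k_m1 <- pmax(gaussian_kernel_apply(m1, rho), 1e-10)
  k_m2 <- pmax(gaussian_kernel_apply(m2, rho), 1e-10)
  list(f1 = gaussian_kernel_apply(m1 * I, rho) / k_m1,
       f2 = gaussian_kernel_apply(m2 * I, rho) / k_m2)
}

#' Pointwise local fitting residual fields e1, e2
#'
#' \eqn{e_i(x) = \int K_\rho(x-y)\,|I(x) - f_i(y)|^2\,dy}, evaluated through
#' the expansion \eqn{e_i = I^2 - 2 I (K_\rho * f_i) + K_\rho * f_i^2} (exact
#' for a unit-mass kernel, so \eqn{K_\rho * 1 = 1}). Clamped at 0 against
#' floating-point round-off.
#'
#' @inheritParams compute_fitting_functions
#' @param f List with `f1`, `f2` from [compute_fitting_functions()].
#' @return List with nonnegative arrays `e1`, `e2`.
#' @export
compute_e_fields <- function(I, f, rho = 3) {
  I <- as_image_volume(I)$data
  check_congruent(I, f$f1, f$f2)
  e_one <- function(fi) {
    e <- I * I - 2 * I * gaussian_kernel_apply(fi, rho) +
      gaussian_kernel_apply(fi * fi, rho)
    pmax(e, 0)
  }
  list(e1 = e_one(f$f1), e2 = e_one(f$f2))
}

#' Region-scalable fitting energy
#'
#' The image-based data energy
#' \eqn{D = \sum_x [\lambda_1 e_1(x) M_1(\phi(x)) + \lambda_2 e_2(x) M_2(\phi(x))]},
#' i.e. the kernel-weighted intensity misfit of each voxel to the local inside
#' and outside fits, gated by its smoothed region membership.
#'
#' @inheritParams compute_e_fields
#' @param phi Level set array.
#' @param params A [fusion_params()] object (uses `lambda1`, `lambda2`, `rho`,
#'   `eps`).
#' @return Single nonnegative number.
#' @export
rsf_energy <- function(I, phi, f, params = fusion_params()) {
  I <- as_image_volume(I)$data
  check_congruent(I, phi, f$f1, f$f2)
  e <- compute_e_fields(I, f, params$rho)
  H <- heaviside_eps(phi, params$eps)
  sum(params$lambda1 * e$e1 * (1 - H) + params$lambda2 * e$e2 * H)
}

#' Data-term force of the RSF energy
#'
#' Gradient-descent direction of [rsf_energy()] with respect to the level set
#' under the negative-inside convention (\eqn{M_1 = 1 - H_\varepsilon}):
#' \eqn{+\delta_\varepsilon(\phi)(\lambda_1 e_1 - \lambda_2 e_2)}. Where the
#' local inside fit is worse than the outside fit (\eqn{\lambda_1 e_1 >
#' \lambda_2 e_2}) the force is positive, pushing \eqn{\phi} up and the voxel
#' out of the structure, which decreases the energy. The force is concentrated
#' on the interface by the Dirac factor and vanishes far from the zero level.
#'
#' @inheritParams rsf_energy
#' @param e Optional precomputed e-fields (list `e1`, `e2`); computed from `f`
#'   when `NULL`.
#' @return Force array, same dimensions as `phi`.
#' @export
rsf_force <- function(I, phi, f, params = fusion_params(), e = NULL) {
  I <- as_image_volume(I)$data
  check_congruent(I, phi, f$f1, f$f2)
  if (is.null(e)) e <- compute_e_fields(I, f, params$rho)
  dirac_eps(phi, params$eps) * (params$lambda1 * e$e1 - params$lambda2 * e$e2)
}
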