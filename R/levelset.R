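#' @keywords internal
"_PACKAGE"

# ---- internal grid helpers ---------------------------------------------------

# Dimensions of a 2D/3D grid as an integer vector; plain vectors are rejected.
grid_dim <- function(x) {
  d <- dim(x)
  if (is.null(d) || length(d) < 2L || length(d) > 3L)
    stop("expected a 2D or 3D array, got ", paste(class(x), collapse = "/"))
  d
}

check_congruent <- function(..., what = "grids") {
  grids <- list(...)
  d0 <- grid_dim(grids[[1L]])
  for (g in grids[-1L]) {
    if (!identical(grid_dim(g), d0))
      stop(what, " are not congruent: ", paste(d0, collapse = "x"),
           " vs ", paste(grid_dim(g), collapse = "x"))
  }
  invisible(d0)
}

expand_spacing <- function(spacing, ndim) {
  if (length(spacing) == 1L) spacing <- rep(spacing, ndim)
  if (length(spacing) != ndim)
    stop("spacing must have length 1 or ", ndim)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be strictly positive and finite")
  spacing
}

# Shift an array by k along an axis with reflective padding (neighbour beyond
# the edge mirrors across it, i.e. x[0] := x[2]); central differences built on
# this have zero normal derivative at the border, avoiding spurious boundary
# curvature.
shift_reflect <- function(x, k, axis) {
  d <- grid_dim(x)
  n <- d[axis]
  idx <- seq_len(n) - k
  idx[idx < 1L] <- 2L - idx[idx < 1L]
  idx[idx > n] <- 2L * n - idx[idx > n]
  pick <- rep(list(quote(expr = )), length(d))
  pick[[axis]] <- idx
  do.call(`[`, c(list(x), pick, list(drop = FALSE)))
}

# Central first difference along an axis, physical spacing h.
central_diff <- function(x, axis, h = 1) {
  (shift_reflect(x, 1L, axis) - shift_reflect(x, -1L, axis)) / (2 * h)
}

# Central second difference along an axis.
second_diff <- function(x, axis, h = 1) {
  (shift_reflect(x, 1L, axis) - 2 * x + shift_reflect(x, -1L, axis)) / (h * h)
}

gradient_list <- function(phi, spacing) {
  d <- grid_dim(phi)
  spacing <- expand_spacing(spacing, length(d))
  lapply(seq_along(d), function(a) central_diff(phi, a, spacing[a]))
}

# ---- image volume container --------------------------------------------------

#' Grayscale image volume
#'
#' Lightweight container pairing a 2D or 3D intensity array with its per-axis
#' physical voxel spacing (mm). This is the target image of the fusion
#' framework; intensities are arbitrary units (0--255 after
#' [normalize_intensity()]).
#'
#' @param data Numeric 2D matrix or 3D array of finite intensities.
#' @param spacing Per-axis voxel size in mm (scalar recycled to all axes).
#' @return An object of class `image_volume` with fields `data` and `spacing`.
#' @examples
#' iv <- image_volume(matrix(runif(25), 5, 5), spacing = 1)
#' dim(iv$data)
#' @export
image_volume <- function(data, spacing = 1) {
  d <- grid_dim(data)
  if (!all(is.finite(data))) stop("image values must all be finite")
  spacing <- expand_spacing(spacing, length(d))
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm, range [", signif(min(x$data), 5), ", ", signif(max(x$data), 5),
      "]\n", sep = "")
  invisible(x)
}

as_image_volume <- function(x, spacing = 1) {
  if (inherits(x, "image_volume")) x else image_volume(x, spacing)
}

check_mask <- function(mask, what = "mask") {
  grid_dim(mask)
  u <- unique(as.vector(mask))
  if (!all(u %in% c(0, 1)))
    stop(what, " must be binary {0,1}; found values: ",
         paste(utils::head(sort(u), 8), collapse = ", "))
  invisible(mask)
}

# ---- signed distance ---------------------------------------------------------

# Felzenszwalb-Huttenlocher 1D squared distance transform on a sampled
# function f at positions h*(0:(n-1)); returns the lower envelope of the
# parabolas f(q) + (x - q)^2.
edt_sq_1d <- function(f, h) {
  n <- length(f)
  fin <- which(is.finite(f))
  if (length(fin) == 0L) return(f)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- fin[1L]
  z[1L] <- -Inf; z[2L] <- Inf
  h2 <- h * h
  if (length(fin) > 1L) for (q in fin[-1L]) {
    repeat {
      p <- v[k]
      s <- ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2 * h2 * (q - p))
      if (s <= z[k]) { k <- k - 1L } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  out <- numeric(n)
  k <- 1L
  for (q in seq_len(n)) {
    while (z[k + 1L] < q) k <- k + 1L
    p <- v[k]
    out[q] <- h2 * (q - p) * (q - p) + f[p]
  }
  out
}

# Squared Euclidean distance (physical units) from every voxel to the nearest
# TRUE voxel, by separable 1D transforms over each axis.
edt_squared <- function(sites, spacing) {
  d <- grid_dim(sites)
  spacing <- expand_spacing(spacing, length(d))
  f <- array(Inf, d)
  f[sites] <- 0
  for (axis in seq_along(d)) {
    perm <- c(axis, seq_along(d)[-axis])
    fp <- aperm(f, perm)
    m <- matrix(fp, nrow = d[axis])
    for (j in seq_len(ncol(m))) m[, j] <- edt_sq_1d(m[, j], spacing[axis])
    fp <- array(m, dim(fp))
    f <- aperm(fp, order(perm))
  }
  f
}

#' Signed Euclidean distance to a mask boundary
#'
#' Builds a level set function from a binary mask: negative distances inside
#' the structure, positive outside, zero level set on the boundary. Distances
#' are voxel-centre Euclidean distances in physical units, computed with two
#' exact (separable Felzenszwalb--Huttenlocher) distance transforms:
#' `phi = dist(to inside set) - dist(to outside set)`, so an inside voxel gets
#' minus its distance to the nearest outside voxel and vice versa. With this
#' convention `signed_distance(m) == -signed_distance(1 - m)` exactly.
#'
#' @param mask Binary 2D/3D array (1 = structure).
#' @param spacing Per-axis voxel size (mm); scalar recycled.
#' @return Numeric array `phi` of the same dimensions.
#' @examples
#' m <- matrix(0, 5, 5); m[3, 3] <- 1
#' phi <- signed_distance(m)
#' phi[3, 4]  # +1: one voxel outside the structure
#' @export
signed_distance <- function(mask, spacing = 1) {
  check_mask(mask)
  d <- grid_dim(mask)
  if (any(d < 3L)) stop("mask grid must have at least 3 voxels per axis")
  inside <- mask > 0.5
  if (all(inside) || !any(inside))
    stop("degenerate mask: all-zero or all-one, no boundary exists")
  sq_in <- edt_squared(inside, spacing)    # distance to the inside set
  sq_out <- edt_squared(!inside, spacing)  # distance to the outside set
  sqrt(sq_in) - sqrt(sq_out)
}

# ---- smoothed Heaviside / Dirac ----------------------------------------------

#' Smoothed Heaviside step function
#'
#' Arctangent-regularized Heaviside
#' \eqn{H_\varepsilon(z) = \frac{1}{2}[1 + \frac{2}{\pi}\arctan(z/\varepsilon)]},
#' used to express region membership of a level set function. Strictly
#' increasing, with limits 0 and 1 at \eqn{\mp\infty}.
#'
#' @param z Numeric vector/array.
#' @param eps Width parameter \eqn{\varepsilon > 0} (voxels).
#' @return Values in (0, 1), same shape as `z`.
#' @export
heaviside_eps <- function(z, eps = 1) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("eps must be a single positive number")
  0.5 * (1 + (2 / pi) * atan(z / eps))
}

#' Smoothed Dirac delta function
#'
#' Exact derivative of [heaviside_eps()]: the Cauchy kernel
#' \eqn{\delta_\varepsilon(z) = \frac{1}{\pi}\frac{\varepsilon}{\varepsilon^2 + z^2}}.
#' Nonnegative, symmetric, and integrates to 1 over the real line.
#'
#' @inheritParams heaviside_eps
#' @return Nonnegative values, same shape as `z`.
#' @export
dirac_eps <- function(z, eps = 1) {
  if (!is.numeric(eps) || length(eps) != 1L || !is.finite(eps) || eps <= 0)
    stop("eps must be a single positive number")
  (1 / pi) * eps / (eps * eps + z * z)
}

# ---- Gaussian kernel ---------------------------------------------------------

#' Continuous Gaussian kernel value
#'
#' Evaluates \eqn{K_\rho(u) = (2\pi)^{-n/2}\rho^{-n} e^{-|u|^2/2\rho^2}} for an
#' offset of magnitude `u` in `ndim` dimensions — the kernel that localizes the
#' region-scalable fitting energy before discretization.
#'
#' @param u Offset magnitude(s) (voxels).
#' @param rho Scale parameter \eqn{\rho > 0} (voxels).
#' @param ndim Dimensionality n of the grid (2 or 3).
#' @return Kernel value(s).
#' @export
gaussian_kernel_value <- function(u, rho, ndim) {
  if (rho <= 0) stop("rho must be positive")
  (2 * pi)^(-ndim / 2) * rho^(-ndim) * exp(-u^2 / (2 * rho^2))
}

# Discrete Gaussian taps truncated at 3*rho, capped at the axis extent (a
# zero-padded tap beyond the domain never touches data), unit sum.
gaussian_taps_1d <- function(rho, n_axis) {
  r <- min(ceiling(3 * rho), n_axis - 1L)
  k <- exp(-(seq(-r, r))^2 / (2 * rho^2))
  k / sum(k)
}

# Zero-padded separable 1D convolution along one axis.
conv1d_axis <- function(x, taps, axis) {
  d <- grid_dim(x)
  n <- d[axis]
  r <- (length(taps) - 1L) / 2L
  perm <- c(axis, seq_along(d)[-axis])
  xp <- matrix(aperm(x, perm), nrow = n)
  pad <- rbind(matrix(0, r, ncol(xp)), xp, matrix(0, r, ncol(xp)))
  out <- matrix(0, n, ncol(xp))
  for (j in seq_along(taps))
    out <- out + taps[j] * pad[seq_len(n) + j - 1L, , drop = FALSE]
  aperm(array(out, d[perm]), order(perm))
}

# Per-voxel kernel mass inside the domain along one axis (conv of ones).
axis_mass <- function(taps, n) {
  r <- (length(taps) - 1L) / 2L
  ones <- rep(1, n)
  pad <- c(rep(0, r), ones, rep(0, r))
  m <- numeric(n)
  for (j in seq_along(taps)) m <- m + taps[j] * pad[seq_len(n) + j - 1L]
  m
}

#' Smooth a field with a domain-normalized Gaussian kernel
#'
#' Weighted local average with the Gaussian kernel of scale `rho` (voxels),
#' truncated at \eqn{3\rho}: a normalized convolution
#' \eqn{(K_\rho * f)(x) = \sum_y \tilde K_x(y) f(y)} whose weights
#' \eqn{\tilde K_x} are renormalized to unit mass over the grid domain at
#' every voxel — the discrete counterpart of the domain-restricted integral
#' \eqn{\int_\Omega K_\rho(x-y) f(y)\,dy / \int_\Omega K_\rho(x-y)\,dy}.
#' Consequences relied on elsewhere: a constant field maps to itself exactly
#' (`K*1 = 1` everywhere, including at the grid border), and as `rho` grows
#' past the domain size the result approaches the global mean of `f`.
#'
#' @param field Numeric 2D/3D array.
#' @param rho Kernel scale \eqn{\rho > 0} (voxels).
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_kernel_apply <- function(field, rho) {
  if (!is.numeric(rho) || length(rho) != 1L || !is.finite(rho) || rho <= 0)
    stop("rho must be a single positive number")
  d <- grid_dim(field)
  mass <- NULL
  for (axis in seq_along(d)) {
    taps <- gaussian_taps_1d(rho, d[axis])
    field <- conv1d_axis(field, taps, axis)
    m_a <- axis_mass(taps, d[axis])
    m_arr <- array(rep(m_a, times = prod(d) / d[axis]), d[c(axis, seq_along(d)[-axis])])
    m_arr <- aperm(m_arr, order(c(axis, seq_along(d)[-axis])))
    mass <- if (is.null(mass)) m_arr else mass * m_arr
  }
  field / mass
}

# ---- curvature and distance regularization -----------------------------------

#' Mean curvature of level sets
#'
#' Computes \eqn{\mathrm{div}(\nabla\phi/|\nabla\phi|)} by central differences
#' with reflective padding; the gradient magnitude is floored at `eta` to avoid
#' division by zero on flat regions. For a signed distance to a circle of
#' radius r the interior values approximate 1/r.
#'
#' @param phi Level set array.
#' @param spacing Per-axis voxel size; scalar recycled.
#' @param eta Gradient-magnitude floor (default 1e-8).
#' @return Curvature array, same dimensions as `phi`.
#' @export
curvature <- function(phi, spacing = 1, eta = 1e-8) {
  d <- grid_dim(phi)
  spacing <- expand_spacing(spacing, length(d))
  g <- gradient_list(phi, spacing)
  mag <- sqrt(Reduce(`+`, lapply(g, function(gi) gi * gi)))
  mag <- pmax(mag, eta)
  out <- array(0, d)
  for (a in seq_along(d)) out <- out + central_diff(g[[a]] / mag, a, spacing[a])
  out
}

laplacian <- function(phi, spacing = 1) {
  d <- grid_dim(phi)
  spacing <- expand_spacing(spacing, length(d))
  out <- array(0, d)
  for (a in seq_along(d)) out <- out + second_diff(phi, a, spacing[a])
  out
}

#' Distance-regularization term
#'
#' The level-set penalty \eqn{\nabla^2\phi - \mathrm{div}(\nabla\phi/|\nabla\phi|)}
#' that drives \eqn{|\nabla\phi|} back toward 1, maintaining a signed-distance
#' profile without periodic reinitialization. Vanishes (away from the border)
#' on an exact signed distance function.
#'
#' @inheritParams curvature
#' @return Array of the same dimensions as `phi`.
#' @export
distance_regularization <- function(phi, spacing = 1, eta = 1e-8) {
  laplacian(phi, spacing) - curvature(phi, spacing, eta)
}
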