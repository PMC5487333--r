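# Synthetic low-contrast phantoms and deformed atlas ensembles. These stand in
# for a registered multi-atlas study: a blurred, noisy two-phase image with a
# small intensity gap plays the target, and independently deformed copies of
# the truth mask play the propagated labels.

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' Parameters of the synthetic target volume: a two-phase image whose
#' structure/background intensity gap, boundary blur and additive noise
#' emulate a low-contrast structure with diffuse boundaries. Defaults define
#' the standard desk-scale fixture: a 64 x 64 grid, bean-shaped structure,
#' intensity gap 20 (inside 120 / outside 100 on the 0--255 scale), boundary
#' blur 1.5 voxels, noise sigma 8.
#'
#' @param grid_size Integer vector of 2 or 3 axis lengths.
#' @param shape `"bean"` (ellipse plus a lobe, non-convex) or
#'   `"ellipse"` (ellipsoid in 3D).
#' @param inside_mean,outside_mean Mean intensities of the two phases
#'   (must differ).
#' @param boundary_blur_sigma Gaussian blur applied to the two-phase image
#'   (voxels, >= 0).
#' @param noise_sigma Additive Gaussian noise standard deviation (>= 0).
#' @param seed Integer RNG seed; the phantom is deterministic given the spec.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = c(64L, 64L),
                         shape = c("bean", "ellipse"),
                         inside_mean = 120, outside_mean = 100,
                         boundary_blur_sigma = 1.5, noise_sigma = 8,
                         seed = 0L) {
  shape <- match.arg(shape)
  if (length(grid_size) < 2L || length(grid_size) > 3L || any(grid_size < 8L))
    stop("grid_size must give 2 or 3 axes of at least 8 voxels")
  if (inside_mean == outside_mean)
    stop("inside_mean and outside_mean must differ")
  if (boundary_blur_sigma < 0 || noise_sigma < 0)
    stop("sigmas must be >= 0")
  structure(list(grid_size = as.integer(grid_size), shape = shape,
                 inside_mean = inside_mean, outside_mean = outside_mean,
                 boundary_blur_sigma = boundary_blur_sigma,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Analytic truth mask; sized relative to the grid so the structure occupies
# roughly 10-15% of the domain.
phantom_truth_mask <- function(spec) {
  d <- spec$grid_size
  ctr <- (d + 1) / 2
  ax <- pmax(d * 0.22, 3)          # main semi-axes (voxels)
  coords <- lapply(seq_along(d), function(a) {
    slc <- slice.index(array(0, d), a)
    (slc - ctr[a]) / ax[a]
  })
  r2 <- Reduce(`+`, lapply(coords, function(x) x * x))
  mask <- r2 <= 1
  if (spec$shape == "bean") {
    # lobe: smaller ball offset along the first axis
    off <- ctr
    off[1L] <- ctr[1L] + ax[1L] * 0.85
    lax <- ax * 0.55
    lcoords <- lapply(seq_along(d), function(a) {
      slc <- slice.index(array(0, d), a)
      (slc - off[a]) / lax[a]
    })
    lr2 <- Reduce(`+`, lapply(lcoords, function(x) x * x))
    mask <- mask | (lr2 <= 1)
  }
  frac <- mean(mask)
  if (frac < 0.05 || frac > 0.40)
    stop("phantom shape does not fit the grid sensibly (occupies ",
         round(100 * frac, 1), "% of it)")
  array(as.numeric(mask), d)
}

#' Generate a low-contrast phantom
#'
#' Builds the analytic truth mask for the spec's shape, paints the two-phase
#' image `inside_mean * mask + outside_mean * (1 - mask)`, blurs it with a
#' Gaussian of `boundary_blur_sigma` voxels and adds i.i.d. Gaussian noise.
#' Deterministic for a fixed spec (seeded; the caller's RNG state is left
#' untouched).
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (an [image_volume()], unit spacing) and `truth`
#'   (binary mask array).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- phantom_truth_mask(spec)
  img <- spec$inside_mean * truth + spec$outside_mean * (1 - truth)
  if (spec$boundary_blur_sigma > 0)
    img <- gaussian_kernel_apply(img, spec$boundary_blur_sigma)
  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed,
                       array(stats::rnorm(length(img), 0, spec$noise_sigma),
                             dim(img)))
    img <- img + noise
  }
  list(image = image_volume(img, spacing = 1), truth = truth)
}

#' Atlas perturbation specification
#'
#' Parameters of the simulated registration error applied to the truth mask
#' to produce "propagated" atlas labels: each atlas is the truth resampled
#' through an independent smooth random displacement field, optionally with
#' sparse voxelwise label flips. Defaults define the standard fixture:
#' 10 atlases, peak displacement 3 voxels, displacement smoothness 8 voxels,
#' flip rate 0.02.
#'
#' @param n_atlases Number of atlases N >= 1.
#' @param deform_amplitude Peak displacement magnitude (voxels, >= 0).
#' @param deform_smoothness Gaussian smoothing scale of the displacement
#'   field (voxels).
#' @param label_flip_rate Per-voxel flip probability in [0, 0.5).
#' @param seed Integer RNG seed.
#' @return Object of class `atlas_perturb_spec`.
#' @export
atlas_perturb_spec <- function(n_atlases = 10L, deform_amplitude = 3,
                               deform_smoothness = 8, label_flip_rate = 0.02,
                               seed = 0L) {
  if (n_atlases < 1L) stop("n_atlases must be >= 1")
  if (deform_amplitude < 0) stop("deform_amplitude must be >= 0")
  if (deform_smoothness <= 0) stop("deform_smoothness must be > 0")
  if (label_flip_rate < 0 || label_flip_rate >= 0.5)
    stop("label_flip_rate must be in [0, 0.5)")
  structure(list(n_atlases = as.integer(n_atlases),
                 deform_amplitude = deform_amplitude,
                 deform_smoothness = deform_smoothness,
                 label_flip_rate = label_flip_rate, seed = as.integer(seed)),
            class = "atlas_perturb_spec")
}

# Smooth random displacement field scaled to the requested peak magnitude;
# nearest-neighbour pull-back resampling keeps labels binary.
deform_mask <- function(mask, amplitude, smoothness) {
  d <- grid_dim(mask)
  nd <- length(d)
  if (amplitude == 0) return(mask)
  comp <- lapply(seq_len(nd), function(a)
    gaussian_kernel_apply(array(stats::rnorm(prod(d)), d), smoothness))
  mag <- sqrt(Reduce(`+`, lapply(comp, function(u) u * u)))
  scale <- amplitude / max(mag, 1e-12)
  grid_idx <- lapply(seq_len(nd), function(a) slice.index(array(0L, d), a))
  src <- lapply(seq_len(nd), function(a) {
    idx <- round(grid_idx[[a]] + scale * comp[[a]])
    pmin(pmax(idx, 1L), d[a])
  })
  flat <- src[[1L]]
  mult <- 1
  for (a in seq_len(nd - 1L)) {
    mult <- mult * d[a]
    flat <- flat + (src[[a + 1L]] - 1L) * mult
  }
  array(as.vector(mask)[as.vector(flat)], d)
}

#' Generate a deformed atlas ensemble with similarity maps
#'
#' Simulates N propagated atlas labels: each is the truth mask resampled
#' through an independent smooth random displacement field (white noise
#' smoothed at `deform_smoothness` voxels, scaled to peak `deform_amplitude`),
#' with optional sparse voxelwise flips. Local-similarity maps are built as
#' the Gaussian-smoothed agreement between each deformed label and the
#' ensemble consensus (mean label) — a stand-in for the registration-derived
#' similarity a real pipeline would supply — and turned into fusion weights by
#' [normalize_weights()]. Deterministic given `truth` and the spec.
#'
#' @param truth Binary ground-truth mask.
#' @param spec An [atlas_perturb_spec()].
#' @param spacing Per-axis voxel size passed to [atlas_ensemble()].
#' @return An [atlas_ensemble()].
#' @export
make_atlas_ensemble <- function(truth, spec = atlas_perturb_spec(),
                                spacing = 1) {
  stopifnot(inherits(spec, "atlas_perturb_spec"))
  check_mask(truth, "truth mask")
  d <- grid_dim(truth)
  labels <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_atlases), function(i) {
      L <- deform_mask(truth, spec$deform_amplitude, spec$deform_smoothness)
      if (spec$label_flip_rate > 0) {
        flip <- stats::runif(prod(d)) < spec$label_flip_rate
        L <- array(ifelse(flip, 1 - as.vector(L), as.vector(L)), d)
      }
      L
    })
  })
  consensus <- Reduce(`+`, labels) / spec$n_atlases
  similarity <- lapply(labels, function(L) {
    agree <- 1 - abs(L - consensus)
    pmax(gaussian_kernel_apply(agree, 3), 0)
  })
  atlas_ensemble(labels, similarity, spacing)
}

#' Standard synthetic fixture
#'
#' Convenience wrapper generating the standard desk-scale study: the default
#' [phantom_spec()] phantom and the default [atlas_perturb_spec()] ensemble,
#' both reseeded to `seed`.
#'
#' @param seed Integer seed applied to both the phantom and ensemble specs.
#' @param grid_size Passed to [phantom_spec()].
#' @param n_atlases Passed to [atlas_perturb_spec()].
#' @return List with `image`, `truth`, `ensemble`.
#' @export
standard_fixture <- function(seed = 0L, grid_size = c(64L, 64L),
                             n_atlases = 10L) {
  ph <- make_phantom(phantom_spec(grid_size = grid_size, seed = seed))
  ens <- make_atlas_ensemble(
    ph$truth, atlas_perturb_spec(n_atlases = n_atlases, seed = seed))
  list(image = ph$image, truth = ph$truth, ensemble = ens)
}
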