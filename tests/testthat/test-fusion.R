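test_that("weight normalization produces convex voxelwise weights", {
  s <- matrix(runif(25), 5, 5)
  w <- normalize_weights(list(s, s))
  expect_equal(w[[1]], matrix(0.5, 5, 5))
  # all-zero maps fall back to uniform
  z <- matrix(0, 4, 4)
  w3 <- normalize_weights(list(z, z, z))
  expect_equal(w3[[2]], matrix(1 / 3, 4, 4))
  # random maps: sums to one everywhere
  set.seed(8)
  maps <- replicate(4, matrix(runif(36), 6, 6), simplify = FALSE)
  maps[[1]][2, 3] <- 0; maps[[2]][2, 3] <- 0; maps[[3]][2, 3] <- 0; maps[[4]][2, 3] <- 0
  wr <- normalize_weights(maps)
  expect_lt(max(abs(Reduce(`+`, wr) - 1)), 1e-12)
  expect_true(all(vapply(wr, function(w) all(w >= 0), logical(1))))
  expect_error(normalize_weights(list(matrix(-1, 3, 3))), "nonnegative")
})

test_that("fusion energy follows the weighted squared-deviation definition", {
  set.seed(15)
  m <- random_mask(c(8, 8))
  ens1 <- atlas_ensemble(list(m))
  expect_equal(fusion_energy(ens1$lsfs[[1]], ens1), 0)
  # two constant-LSF atlases at -1/+1 with equal weights, phi = 0 -> F = V
  d <- c(6, 6)
  ens_c <- list(lsfs = list(array(-1, d), array(1, d)),
                weights = list(array(0.5, d), array(0.5, d)),
                spacing = c(1, 1), n = 2L)
  class(ens_c) <- "atlas_ensemble"
  expect_equal(fusion_energy(array(0, d), ens_c), prod(d))
  # random instance against the double-loop oracle
  set.seed(16)
  labs <- replicate(3, random_mask(c(7, 7)), simplify = FALSE)
  sims <- replicate(3, matrix(runif(49), 7, 7), simplify = FALSE)
  ens <- atlas_ensemble(labs, sims)
  phi <- matrix(rnorm(49, 0, 2), 7, 7)
  expect_equal(fusion_energy(phi, ens),
               bf_fusion_energy(phi, ens$lsfs, ens$weights), tolerance = 1e-12)
})

test_that("fusion force vanishes at the weighted mean and descends the energy", {
  set.seed(17)
  labs <- replicate(3, random_mask(c(8, 8)), simplify = FALSE)
  sims <- replicate(3, matrix(runif(64), 8, 8), simplify = FALSE)
  ens <- atlas_ensemble(labs, sims)
  wm <- Reduce(`+`, Map(`*`, ens$weights, ens$lsfs))
  expect_lt(max(abs(fusion_force(wm, ens))), 1e-12)
  phi <- matrix(rnorm(64, 0, 3), 8, 8)
  f0 <- fusion_energy(phi, ens)
  f1 <- fusion_energy(phi + 0.05 * fusion_force(phi, ens), ens)
  expect_lt(f1, f0)
})

test_that("pure-fusion flow converges to the weighted mean of atlas level sets", {
  fx <- standard_fixture(2, grid_size = c(32L, 32L), n_atlases = 4L)
  p <- fusion_params(alpha = 0.1, beta = 0, gamma = 0, mu = 0, upsilon = 0,
                     max_iters = 600, tol = 0)
  res <- malsf_segment(fx$image, fx$ensemble, p, init = array(0, c(32, 32)))
  wm <- Reduce(`+`, Map(`*`, fx$ensemble$weights, fx$ensemble$lsfs))
  expect_lt(max(abs(res$phi - wm)), 1e-3)
})

test_that("regularization energy measures contour length", {
  n <- 81
  xs <- matrix(rep(1:n, n), n); ys <- t(xs)
  r0 <- 15
  phi <- sqrt((xs - 41)^2 + (ys - 41)^2) - r0
  expect_lt(abs(regularization_energy(phi, eps = 1) - 2 * pi * r0),
            0.05 * 2 * pi * r0)
  # no interface
  expect_lt(regularization_energy(array(50, c(20, 20)), eps = 1), 1e-2)
  # a wiggly contour is longer than its smooth counterpart
  wig <- sqrt((xs - 41)^2 + (ys - 41)^2) - (r0 + 3 * sin(8 * atan2(ys - 41, xs - 41)))
  expect_gt(regularization_energy(wig, 1), regularization_energy(phi, 1))
})

test_that("total energy is the coefficient-weighted sum of its three terms", {
  set.seed(19)
  fx <- standard_fixture(1, grid_size = c(24L, 24L), n_atlases = 3L)
  I <- fx$image$data
  phi <- fx$ensemble$lsfs[[1]] + matrix(rnorm(576, 0, 0.5), 24, 24)
  p <- fusion_params(alpha = 0.3, beta = 2, gamma = 0.7)
  f <- compute_fitting_functions(I, phi, p$rho, p$eps)
  comp <- total_energy(phi, I, fx$ensemble, f, p)
  expect_equal(comp$fusion, 0.3 * fusion_energy(phi, fx$ensemble))
  expect_equal(comp$data, 2 * rsf_energy(I, phi, f, p))
  expect_equal(comp$regularization, 0.7 * regularization_energy(phi, p$eps))
  expect_equal(comp$total, comp$fusion + comp$data + comp$regularization)
  # independent recomputation from the raw definitions
  H <- 0.5 * (1 + (2 / pi) * atan(phi / p$eps))
  e1 <- bf_e_field(I, f$f1, p$rho); e2 <- bf_e_field(I, f$f2, p$rho)
  D <- sum(p$lambda1 * e1 * (1 - H) + p$lambda2 * e2 * H)
  Fe <- bf_fusion_energy(phi, fx$ensemble$lsfs, fx$ensemble$weights)
  gx <- central_diff_oracle(phi); gy <- t(central_diff_oracle(t(phi)))
  R <- sum((1 / pi) * p$eps / (p$eps^2 + phi^2) * sqrt(gx^2 + gy^2))
  expect_equal(comp$total, 0.3 * Fe + 2 * D + 0.7 * R, tolerance = 1e-8)
  # all coefficients zero
  p0 <- fusion_params(alpha = 0, beta = 0, gamma = 0)
  expect_equal(total_energy(phi, I, fx$ensemble, f, p0)$total, 0)
})

test_that("a zero-coefficient evolution step is the identity", {
  fx <- standard_fixture(3, grid_size = c(24L, 24L), n_atlases = 3L)
  phi <- fx$ensemble$lsfs[[1]]
  p0 <- fusion_params(alpha = 0, beta = 0, gamma = 0, mu = 0, upsilon = 0)
  expect_equal(evolve_step(phi, fx$image, fx$ensemble, p0), phi)
})

test_that("the distance-regularization flow restores a unit gradient profile", {
  fx <- standard_fixture(3, grid_size = c(24L, 24L), n_atlases = 3L)
  phi <- 2 * fx$ensemble$lsfs[[1]]  # |grad phi| = 2
  p <- fusion_params(alpha = 0, beta = 0, upsilon = 0, mu = 0.2, max_iters = 1)
  grad_dev <- function(x) {
    gx <- central_diff_oracle(x); gy <- t(central_diff_oracle(t(x)))
    mean(abs(sqrt(gx^2 + gy^2) - 1))
  }
  devs <- grad_dev(phi)
  for (s in 1:10) {
    phi <- evolve_step(phi, fx$image, fx$ensemble, p)
    devs <- c(devs, grad_dev(phi))
  }
  expect_true(all(diff(devs) < 0))
})

test_that("evolution reports divergence for an absurd time step", {
  fx <- standard_fixture(3, grid_size = c(24L, 24L), n_atlases = 3L)
  p <- fusion_params(dt = 1e308, max_iters = 3)
  expect_error(malsf_segment(fx$image, fx$ensemble, p), "diverged")
})

test_that("identical correct atlases on a clean phantom are a fixed point", {
  ph <- make_phantom(phantom_spec(grid_size = c(48L, 48L),
                                  boundary_blur_sigma = 0, noise_sigma = 0,
                                  seed = 4))
  ens <- atlas_ensemble(replicate(5, ph$truth, simplify = FALSE))
  res <- malsf_segment(ph$image, ens, fusion_params())
  expect_gte(overlap_metrics(ph$truth, res$mask)$si, 0.99)
})

test_that("segmentation bookkeeping: trace length, mask identity, zero-iteration run", {
  fx <- standard_fixture(4, grid_size = c(32L, 32L), n_atlases = 4L)
  p <- fusion_params(max_iters = 8, tol = 0)
  res <- malsf_segment(fx$image, fx$ensemble, p)
  expect_equal(nrow(res$energy_trace), res$iterations_run + 1L)
  expect_equal(res$iterations_run, 8L)
  expect_equal(res$mask, array(as.numeric(res$phi < 0), dim(res$phi)))
  # zero iterations returns the thresholded initialization
  p0 <- fusion_params(max_iters = 0)
  res0 <- malsf_segment(fx$image, fx$ensemble, p0)
  wm <- Reduce(`+`, Map(`*`, fx$ensemble$weights, fx$ensemble$lsfs))
  expect_equal(res0$mask, array(as.numeric(wm < 0), dim(wm)))
  expect_equal(res0$iterations_run, 0L)
  # an initialization that stays empty raises the empty-mask warning
  pz <- fusion_params(alpha = 0, beta = 0, gamma = 0, mu = 0, upsilon = 0,
                      max_iters = 0)
  expect_warning(malsf_segment(fx$image, fx$ensemble, pz,
                               init = array(5, c(32, 32))), "empty")
})

test_that("segmentation is deterministic: identical inputs give identical results", {
  fx <- standard_fixture(5, grid_size = c(32L, 32L), n_atlases = 4L)
  p <- fusion_params(max_iters = 25)
  r1 <- malsf_segment(fx$image, fx$ensemble, p)
  r2 <- malsf_segment(fx$image, fx$ensemble, p)
  expect_identical(r1$phi, r2$phi)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$energy_trace, r2$energy_trace)
})

test_that("parameter tuning picks the grid point with the best mean SI", {
  # two training targets whose image term is deliberately misleading: the
  # intensity boundary is shifted relative to the (perfect) atlas labels, so
  # a strong fusion term must win over a fusion-free configuration
  make_target <- function(seed) {
    ph <- make_phantom(phantom_spec(grid_size = c(24L, 24L),
                                    boundary_blur_sigma = 0, noise_sigma = 0,
                                    seed = seed))
    shifted <- ph$truth * 0
    shifted[1:20, ] <- ph$truth[5:24, ]  # image boundary 4 voxels off
    img <- image_volume(120 * shifted + 100 * (1 - shifted))
    ens <- atlas_ensemble(replicate(3, ph$truth, simplify = FALSE))
    list(image = img, truth = ph$truth, ensemble = ens)
  }
  targets <- list(make_target(1), make_target(2))
  base <- fusion_params(beta = 1, lambda1 = 0.05, lambda2 = 0.05,
                        max_iters = 40, tol = 0)
  best <- tune_parameters(targets, grid = list(alpha = c(0, 5)), base = base)
  expect_equal(best$alpha, 5)
  srch <- attr(best, "search")
  expect_equal(nrow(srch), 2L)
  expect_gt(srch$mean_si[srch$alpha == 5], srch$mean_si[srch$alpha == 0])
  # a single grid point is returned unchanged
  one <- tune_parameters(targets, grid = list(alpha = 0.1),
                         base = fusion_params(max_iters = 2))
  expect_equal(one$alpha, 0.1)
  # exact ties resolve to the first grid point in iteration order
  tie <- tune_parameters(targets, grid = list(alpha = c(0.3, 0.3)),
                         base = fusion_params(max_iters = 2))
  expect_equal(attr(tie, "search")$mean_si[1], attr(tie, "search")$mean_si[2])
  expect_equal(best$beta, 1)  # non-grid fields inherited from base
  expect_error(tune_parameters(targets, grid = list()), "nonempty")
  expect_error(tune_parameters(targets[1], grid = list(alpha = 1)), "two")
})
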