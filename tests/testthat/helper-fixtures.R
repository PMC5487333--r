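# Shared fixtures, generated once per test run and cached.

withr_local_tempdir <- function(env = parent.frame()) {
  withr::local_tempdir(.local_envir = env)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# The standard desk-scale study: 64^2 grid, 10 atlases, deformation amplitude
# 3 voxels, flip rate 0.02, contrast gap 20, noise sigma 8.
std_fixture <- function(seed = 0L) {
  cached(paste0("fixture_", seed), standard_fixture(seed))
}

# Default-parameter segmentation of the standard fixture.
std_segmentation <- function(seed = 0L) {
  cached(paste0("seg_", seed), {
    fx <- std_fixture(seed)
    malsf_segment(fx$image, fx$ensemble, fusion_params())
  })
}

# Full-length (200-step, no early stopping) default-parameter run.
std_segmentation_full <- function(seed = 0L) {
  cached(paste0("segfull_", seed), {
    fx <- std_fixture(seed)
    malsf_segment(fx$image, fx$ensemble, fusion_params(tol = 0))
  })
}
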