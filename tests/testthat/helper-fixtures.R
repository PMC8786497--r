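# Small fixture builders shared across test files.

# volume with a single nonzero voxel (1-based index)
point_mass_volume <- function(dims, at, voxel_size = c(1, 1, 1)) {
  a <- array(0, dims)
  a[at[1], at[2], at[3]] <- 1
  volume(a, voxel_size)
}

# seeded random volume with strictly positive intensities
random_volume <- function(dims, voxel_size = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  volume(array(stats::runif(prod(dims), 0, 100), dims), voxel_size)
}

# a small phantom pair for fast registration tests
small_phantom <- function(dims = c(16, 16, 16), seed = 1, noise_sd = 2) {
  make_phantom_pair(phantom_spec(dims = dims, seed = seed,
                                 noise_sd = noise_sd))
}

expect_rigid_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$t, b$t, tolerance = tol)
  expect_equal(a$R, b$R, tolerance = tol)
}
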