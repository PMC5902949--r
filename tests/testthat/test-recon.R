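test_that("phase wrap maps to (-pi, pi] with ties at +pi", {
  expect_equal(wrap_phase(3 * pi / 2), -pi / 2, tolerance = 1e-12)
  expect_equal(wrap_phase(-3 * pi / 2), pi / 2, tolerance = 1e-12)
  expect_equal(wrap_phase(pi), pi)
  expect_equal(wrap_phase(-pi), pi)
  expect_equal(wrap_phase(0.3), 0.3)
})

test_that("the centered inverse DFT matches the independent oracle", {
  set.seed(5)
  N <- 16; FOV <- 32
  kvec <- complex(real = rnorm(N), imaginary = rnorm(N))
  expect_equal(as.vector(pcasim:::.idft_matrix(N, FOV) %*% kvec),
               oracle_idft1(kvec, N, FOV), tolerance = 1e-12)
})

test_that("all-zero k-space reconstructs to zero magnitude", {
  K <- pcasim:::.idft_matrix(8, 16) %*% matrix(0i, 8, 8)
  expect_true(all(Mod(K) == 0))
})

test_that("conjugate-symmetric k-space gives near-zero phase", {
  # build k-space as the forward transform of a real positive image
  N <- 16; FOV <- 32
  W <- pcasim:::.idft_matrix(N, FOV)
  img <- matrix(0, N, N)
  img[6:10, 7:12] <- 1
  img <- img + 0.01
  K <- solve(W) %*% img %*% t(solve(W))
  I2 <- W %*% K %*% t(W)
  expect_lt(max(abs(Arg(I2))), 1e-6)
})

test_that("phase difference of identical images is zero", {
  p <- list(magnitude = matrix(1, 4, 4), phase = matrix(0.7, 4, 4),
            complex = matrix(exp(0.7i), 4, 4))
  class(p) <- "image_pair"
  expect_true(all(phase_difference(p, p) == 0))
})

test_that("phase difference wraps: 3pi/4 minus -3pi/4 is -pi/2", {
  a <- list(phase = array(3 * pi / 4, c(1, 1, 1)))
  b <- list(phase = array(-3 * pi / 4, c(1, 1, 1)))
  class(a) <- class(b) <- "image_pair"
  expect_equal(as.numeric(phase_difference(a, b)), -pi / 2, tolerance = 1e-12)
})

test_that("velocity from phase follows Eq. 5", {
  expect_equal(velocity_from_phase(pi, 100), 100)
  expect_equal(velocity_from_phase(0, 100), 0)
  expect_equal(velocity_from_phase(pi / 2, 150), 75)
})

test_that("velocity magnitude is the Euclidean norm per voxel", {
  u <- array(3, c(2, 2, 1)); v <- array(4, c(2, 2, 1)); w <- array(0, c(2, 2, 1))
  expect_true(all(velocity_magnitude(u, v, w) == 5))
  expect_equal(as.numeric(velocity_magnitude(array(0, c(1, 1, 1)),
                                             array(0, c(1, 1, 1)),
                                             array(0, c(1, 1, 1)))), 0)
  set.seed(8)
  a <- array(rnorm(8), c(2, 2, 2)); b <- array(rnorm(8), c(2, 2, 2))
  cc <- array(rnorm(8), c(2, 2, 2))
  expect_equal(as.numeric(velocity_magnitude(a, b, cc)),
               sqrt(as.numeric(a)^2 + as.numeric(b)^2 + as.numeric(cc)^2),
               tolerance = 1e-12)
})

test_that("magnitude masking thresholds and zeroes out-of-mask voxels", {
  mag <- array(c(1, 0.05, 0.5, 0.01), c(2, 2, 1))
  vel <- list(w = array(10, c(2, 2, 1)))
  mk <- mask_velocity(mag, vel, threshold_fraction = 0.1)
  expect_equal(as.numeric(mk$w), c(10, 0, 10, 0))
  expect_equal(as.numeric(mk$mask), c(1, 0, 1, 0))
  # threshold above the maximum: empty mask
  mk2 <- mask_velocity(mag, vel, threshold_fraction = 1.5)
  expect_false(any(mk2$mask))
  # threshold near zero: all nonzero-magnitude voxels pass
  mk3 <- mask_velocity(mag, vel, threshold_fraction = 1e-9)
  expect_equal(sum(mk3$mask), 4L)
})

test_that("tube phantom mask area approximates the lumen area", {
  p <- sequence_params(TE = 3, TR = 25, FA = 30, t_ACQ = 1.25, FOV = c(16, 16),
                       matrix_size = c(32, 32), slice_thickness = 3,
                       VENC = 100, n_dummy = 2L)
  ens <- plug_flow_ensemble(radius = 4, length = 40, speed = 30,
                            density = 2, rng_seed = 3)
  map <- velocity_maps(acquire(ens, p))
  a_vox <- sum(map$mask[, , 1])
  a_true <- pi * 16 / (0.5 * 0.5)
  expect_lt(abs(a_vox - a_true) / a_true, 0.2)
})

test_that("reconstruction is linear in k-space", {
  ens1 <- static_ensemble(rbind(c(2, 0, 0)))
  ens2 <- static_ensemble(rbind(c(-3, 1, 0)))
  p <- sequence_params(TE = 3, TR = 25, FA = 30, t_ACQ = 1.25, FOV = c(16, 16),
                       matrix_size = c(16, 16), VENC = 100, n_dummy = 1L)
  k1 <- acquire(ens1, p); k2 <- acquire(ens2, p)
  k12 <- acquire(combine_ensembles(ens1, ens2), p)
  r1 <- reconstruct(k1)$SS$plus$complex
  r2 <- reconstruct(k2)$SS$plus$complex
  r12 <- reconstruct(k12)$SS$plus$complex
  expect_equal(r12, r1 + r2, tolerance = 1e-8 * max(Mod(r12)))
})
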