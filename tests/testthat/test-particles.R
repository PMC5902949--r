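poiseuille_tube_ensemble <- function(radius = 2, length_mm = 100 / (pi * 4),
                                     v_mean = 10, density = 15,
                                     n_streamlines = 200L, seed = 1L) {
  tube <- straight_tube_tree(radius = radius, length = length_mm)
  sol <- solve_flow(tube, list(mean_velocity = v_mean))
  sls <- trace_streamlines(sol, n_streamlines, rng_seed = seed)
  list(sol = sol, ens = seed_particles(sls, density, rng_seed = seed))
}

test_that("particle count matches density times lumen volume", {
  # lumen volume 100 mm^3, density 15 -> 1500 expected, 1350-1650 allowed
  f <- poiseuille_tube_ensemble()
  expect_gte(n_particles(f$ens), 1350)
  expect_lte(n_particles(f$ens), 1650)
})

test_that("uniform-speed streamlines give uniform particle spacing", {
  ens <- plug_flow_ensemble(radius = 2, length = 30, speed = 10,
                            density = 4, rng_seed = 1, n_streamlines = 20L)
  P <- particle_positions(ens)
  one <- which(ens$sl == 1L)
  z <- sort(P[one, 3])
  expect_lt(diff(range(diff(z))), 1e-6)
})

test_that("spacing doubles where speed doubles along a streamline", {
  # narrowing tube: radius R -> R/sqrt(2) doubles the speed; repeated end
  # radii keep the interpolating radius spline flat in the measurement
  # windows so the area ratio there is 2 to within a percent
  zs <- seq(0, 30, by = 5)
  rs <- c(2, 2, 2, 2 / 2^0.25, sqrt(2), sqrt(2), sqrt(2))
  taper <- vessel_tree(list(centerline(cbind(0, 0, zs), rs)), NA_integer_)
  sol <- solve_flow(taper, list(mean_velocity = 8))
  sls <- trace_streamlines(sol, 30, rng_seed = 3)
  ens <- seed_particles(sls, density = 30, rng_seed = 3)
  P <- particle_positions(ens)
  j <- ens$sl[1]
  sel <- which(ens$sl == j)
  z <- sort(P[sel, 3])
  sp_in <- mean(diff(z[z < 8 & z > 1][1:5]))
  ztail <- z[z > 22 & z < 29]
  sp_out <- mean(diff(ztail[seq_len(min(5, length(ztail) - 1))]))
  expect_equal(sp_out / sp_in, 2, tolerance = 0.1)
})

test_that("advance with dt = 0 is the identity and count is invariant", {
  f <- poiseuille_tube_ensemble()
  e2 <- advance(f$ens, 0)
  expect_identical(e2$tau, f$ens$tau)
  e3 <- f$ens
  for (k in 1:25) e3 <- advance(e3, 7)
  expect_equal(n_particles(e3), n_particles(f$ens))
})

test_that("a particle passing the trajectory end recycles with fresh M", {
  L <- 30
  ens <- plug_flow_ensemble(radius = 1, length = L, speed = 10,
                            density = 3, rng_seed = 1, n_streamlines = 5L)
  # put particle 1 one mm short of its streamline end, mark its M
  Ttot <- ens$tables[[ens$sl[1]]]$Ttot
  ens$tau[1] <- Ttot - 1 / 100                 # 1 mm at 100 mm/s
  ens$M[1, ] <- c(0.5, 0.2, 0.3)
  z0 <- particle_positions(ens)[1, 3]
  ens2 <- advance(ens, 20)                     # 20 ms -> 2 mm > 1 mm left
  z1 <- particle_positions(ens2)[1, 3]
  expect_lt(z1, z0)                            # wrapped to the start
  expect_equal(ens2$M[1, ], c(0, 0, 1))        # fresh equilibrium
})

test_that("Monte-Carlo particle flux through a cross-section matches Q", {
  f <- poiseuille_tube_ensemble(radius = 2, length_mm = 40, v_mean = 10,
                                density = 15, n_streamlines = 200L)
  Q <- f$sol$Q_inlet_ml_s * 1000               # mm^3/s
  ens <- f$ens
  z <- particle_positions(ens)[, 3]
  crossings <- 0
  dt <- 1                                      # ms
  nstep <- 200L
  for (k in seq_len(nstep)) {
    ens <- advance(ens, dt)
    z1 <- particle_positions(ens)[, 3]
    dz <- z1 - z
    up <- (z < 0 & z1 >= 0 & abs(dz) < 20)     # exclude wrap jumps
    crossings <- crossings + sum(up)
    z <- z1
  }
  flux <- crossings / (nstep * dt * 1e-3) / ens$density
  expect_lt(abs(flux - Q) / Q, 0.01)
})

test_that("particle density is stationary under advection", {
  f <- poiseuille_tube_ensemble(radius = 2, length_mm = 40)
  ens <- f$ens
  slab <- function(e) {
    z <- particle_positions(e)[, 3]
    sum(z > -10 & z < 10)
  }
  n0 <- slab(ens)
  for (k in 1:1000) ens <- advance(ens, 2)
  expect_lt(abs(slab(ens) - n0) / n0, 0.10)
})

test_that("combining ensembles preserves particles and rejects T1/T2 clashes", {
  a <- plug_flow_ensemble(1, 10, 10, density = 2, n_streamlines = 5L)
  b <- static_ensemble(rbind(c(0, 0, 0), c(1, 1, 1)))
  ab <- combine_ensembles(a, b)
  expect_equal(n_particles(ab), n_particles(a) + 2L)
  expect_equal(tail(particle_positions(ab), 2), rbind(c(0, 0, 0), c(1, 1, 1)),
               ignore_attr = TRUE)
  b2 <- static_ensemble(rbind(c(0, 0, 0)), T1 = 800)
  expect_error(combine_ensembles(a, b2), "T1/T2")
})
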