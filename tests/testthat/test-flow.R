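test_that("single tube inlet flow equals v_mean * pi * r^2", {
  tube <- straight_tube_tree(radius = 4, length = 60)
  sol <- solve_flow(tube, list(mean_velocity = 10))
  expect_equal(sol$Q_inlet_ml_s, 10 * pi * 0.4^2, tolerance = 1e-12)
})

test_that("symmetric bifurcation splits flow exactly 50/50", {
  tr <- symmetric_y_tree()
  sol <- solve_flow(tr, list(mean_velocity = 20))
  q <- segment_flow(sol)
  expect_equal(q[2], q[3], tolerance = 1e-12)
  expect_equal(q[2] + q[3], q[1], tolerance = 1e-12)
})

test_that("asymmetric divider matches the hand-solved two-resistor system", {
  parent <- centerline(rbind(c(0, 0, 0), c(0, 0, 10)), 2)
  chA <- centerline(rbind(c(0, 0, 10), c(4, 0, 18)), 1.4)
  chB <- centerline(rbind(c(0, 0, 10), c(-3, 0, 14)), 1.1)
  tr <- vessel_tree(list(parent, chA, chB), c(NA, 1L, 1L))
  mu <- 3.5e-3
  sol <- solve_flow(tr, list(mean_velocity = 15), viscosity = mu)
  # hand-computed resistances of the two constant-radius children:
  # R = 8 mu L / (pi r^4); equal outlet pressures -> Q_A/Q_B = R_B/R_A
  RA <- 8 * mu * oracle_norm(c(4, 0, 8) * 1e-3) / (pi * (1.4e-3)^4)
  RB <- 8 * mu * oracle_norm(c(-3, 0, 4) * 1e-3) / (pi * (1.1e-3)^4)
  q <- segment_flow(sol)
  Q <- sol$Q_inlet_ml_s
  expect_equal(q[2], Q * (1 / RA) / (1 / RA + 1 / RB), tolerance = 1e-10)
  expect_equal(q[3], Q * (1 / RB) / (1 / RA + 1 / RB), tolerance = 1e-10)
})

test_that("flow is conserved at every junction of a grown tree", {
  tr <- cached_calix_tree()
  sol <- solve_flow(tr, list(pressure_drop = 100))
  q <- segment_flow(sol)
  for (i in seq_along(tr$centerlines)) {
    kids <- which(!is.na(tr$parent) & tr$parent == i)
    if (!length(kids)) next
    expect_equal(q[i], sum(q[kids]), tolerance = 1e-10 * q[i])
  }
})

test_that("Poiseuille profile points: axis, wall, half radius", {
  tube <- straight_tube_tree(radius = 4, length = 60)
  sol <- solve_flow(tube, list(mean_velocity = 10))
  v_axis <- velocity_at(sol, c(0, 0, 0))
  expect_equal(as.numeric(v_axis), c(0, 0, 20), tolerance = 1e-9)  # 2 v_mean
  v_wall <- velocity_at(sol, c(4 - 1e-9, 0, 0))
  expect_equal(as.numeric(v_wall[3]), 0, tolerance = 1e-6)          # no-slip
  v_half <- velocity_at(sol, c(2, 0, 0))
  expect_equal(as.numeric(v_half[3]), 15, tolerance = 1e-9)  # 2*10*(1-0.25)
  v_out <- velocity_at(sol, c(10, 0, 0))
  expect_false(attr(v_out, "inside"))
  expect_equal(as.numeric(v_out), c(0, 0, 0))
})

test_that("pressure-drop driven flow matches the analytic tube resistance", {
  tube <- straight_tube_tree(radius = 2, length = 50)
  mu <- 3.5e-3
  dP <- 100
  sol <- solve_flow(tube, list(pressure_drop = dP), viscosity = mu)
  R <- 8 * mu * 50e-3 / (pi * (2e-3)^4)
  expect_equal(sol$Q_inlet_ml_s, dP / R * 1e6, tolerance = 1e-6)
  expect_equal(sol$total_pressure_drop, dP, tolerance = 1e-9)
})

test_that("scale_flow scales velocities linearly", {
  tube <- straight_tube_tree(radius = 4, length = 60)
  sol <- solve_flow(tube, list(mean_velocity = 10))
  sol2 <- scale_flow(sol, 2.5)
  expect_equal(as.numeric(velocity_at(sol2, c(0, 0, 0))[3]), 50,
               tolerance = 1e-9)
  expect_equal(sol2$Q_inlet_ml_s, 2.5 * sol$Q_inlet_ml_s)
})
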