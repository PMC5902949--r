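#' Straight constant-radius tube tree
#'
#' @param radius Tube radius, mm.
#' @param length Tube length, mm.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param center Tube center, mm.
#' @return A single-segment [vessel_tree()].
#' @export
straight_tube_tree <- function(radius, length, axis = "z", center = c(0, 0, 0)) {
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  p0 <- p1 <- center
  p0[ax] <- p0[ax] - length / 2
  p1[ax] <- p1[ax] + length / 2
  mid <- (p0 + p1) / 2
  vessel_tree(list(centerline(rbind(p0, mid, p1), radius)), NA_integer_)
}

#' Translate a tree rigidly
#'
#' @param tree A [vessel_tree()].
#' @param delta 3-vector shift, mm.
#' @return The shifted [vessel_tree()].
#' @export
translate_tree <- function(tree, delta) {
  cls <- lapply(tree$centerlines, function(cl) {
    centerline(sweep(cl$nodes, 2, delta, "+"), cl$radii)
  })
  out <- vessel_tree(cls, tree$parent, tree$s_attach)
  attr(out, "growth") <- attr(tree, "growth")
  out
}

#' Rescale the flows of a solved laminar network
#'
#' In a rigid laminar network the flow field is linear in the driving
#' pressure: scaling the inlet pressure by `factor` scales every flow,
#' velocity and pressure drop by `factor` without changing the geometry.
#'
#' @param solution A [solve_flow()] result.
#' @param factor Positive scale.
#' @return The scaled `flow_solution`.
#' @export
scale_flow <- function(solution, factor) {
  stopifnot(inherits(solution, "flow_solution"), factor > 0)
  solution$flow_ml_s <- lapply(solution$flow_ml_s, `*`, factor)
  solution$pressure_drop <- lapply(solution$pressure_drop, `*`, factor)
  solution$Q_inlet_ml_s <- solution$Q_inlet_ml_s * factor
  solution$total_pressure_drop <- solution$total_pressure_drop * factor
  for (i in seq_along(solution$polylines)) {
    solution$polylines[[i]]$Q_mm3_s <- solution$polylines[[i]]$Q_mm3_s * factor
  }
  solution
}

#' Peak velocity of the analytic flow field
#'
#' Maximum on-axis Poiseuille velocity `2 Q / (pi R^2)` over all centerline
#' samples.
#'
#' @param solution A [solve_flow()] result.
#' @return Peak velocity, cm/s.
#' @export
peak_velocity <- function(solution) {
  mx <- 0
  for (p in solution$polylines) {
    mx <- max(mx, max(2 * p$Q_mm3_s / (pi * p$r^2)))
  }
  mx / 10
}

#' Ground-truth velocity maps on an acquisition grid
#'
#' Samples the analytic laminar field at the voxel centers of the sequence
#' geometry, giving the reference against which image-derived maps are
#' compared.
#'
#' @param solution A [solve_flow()] result.
#' @param params A [sequence_params()] defining the grid.
#' @return List of arrays `u`, `v`, `w`, `m` (cm/s) and the logical `lumen`
#'   occupancy of the voxel centers, plus the grid `geometry`.
#' @export
ground_truth_map <- function(solution, params) {
  g <- .grid_geometry(params)
  nx <- length(g$x); ny <- length(g$y); nz <- length(g$z)
  pts <- cbind(rep(g$x, times = ny * nz),
               rep(rep(g$y, each = nx), times = nz),
               rep(g$z, each = nx * ny))
  v <- velocity_field(solution, pts)
  dm <- c(nx, ny, nz)
  list(u = array(v[, 1], dm), v = array(v[, 2], dm), w = array(v[, 3], dm),
       m = array(attr(v, "speed"), dm),
       lumen = array(attr(v, "inside"), dm), geometry = g)
}

#' Phase-velocity linearity experiment
#'
#' Simulates 2D PCA of a straight plug-flow tube at a series of through-plane
#' velocities and extracts the mean phase difference over the core of the
#' vessel cross-section, the direct probe of the phase-velocity law
#' `delta_phi = pi v / VENC` (velocities beyond VENC alias by phase
#' wrapping).
#'
#' @param velocities Plug velocities to simulate, cm/s (may exceed VENC).
#' @param VENC Aliasing velocity, cm/s.
#' @param rng_seed Integer seed.
#' @param density Particle density per mm^3.
#' @param radius,tube_length Tube geometry, mm.
#' @return Data frame with `velocity`, mean `dphi` (rad) and the apparent
#'   velocity `v_meas` (cm/s).
#' @export
phase_velocity_experiment <- function(velocities, VENC = 100, rng_seed = 1L,
                                      density = 2, radius = 4,
                                      tube_length = 60) {
  params <- sequence_params(TE = 3, TR = 40, FA = 30, t_ACQ = 1.25,
                            FOV = c(16, 16), matrix_size = c(32, 32),
                            slice_thickness = 3, n_slices = 1, VENC = VENC,
                            dimension = "2D", slab_center = 0)
  g <- .grid_geometry(params)
  core <- outer(g$x^2, g$y^2, "+") <= (radius / 2)^2
  out <- lapply(velocities, function(v) {
    ens <- plug_flow_ensemble(radius, tube_length, v, density,
                              rng_seed = rng_seed)
    ks <- acquire(ens, params, rng_seed = rng_seed)
    rec <- reconstruct(ks)
    dphi <- phase_difference(rec$SS$plus, rec$SS$minus)[, , 1]
    mdp <- Arg(mean(exp(1i * dphi[core])))     # circular mean (wrap-safe)
    data.frame(velocity = v, dphi = mdp,
               v_meas = velocity_from_phase(mdp, VENC))
  })
  do.call(rbind, out)
}

#' Synthetic renal-type tree for the 3D error study
#'
#' Grows a compact tree (about 200 mm^3 of lumen) that fits a
#' 25.6 x 25.6 x 20 mm 3D acquisition slab, the scaled-down stand-in for a
#' patient renal arterial model.
#'
#' @param rng_seed Integer seed.
#' @return A [vessel_tree()].
#' @export
error_study_tree <- function(rng_seed = 1L) {
  cfg <- growth_config(
    perfusion_region = list(type = "box",
                            lower = c(-9, -9, 10), upper = c(9, 9, 18)),
    n_terminals = 6L,
    terminal_flows = 0.35,
    inlet_position = c(0, 0, 1),
    target_inlet_radius = 1.7,
    rng_seed = rng_seed)
  grow_tree(cfg)
}

#' 3D PCA velocity measurement error experiment
#'
#' End-to-end scaled-down error study: grow a synthetic tree, solve laminar
#' flow at a prescribed mean inlet velocity, seed spin isochromats, simulate
#' a three-axis velocity-encoded 3D PCA acquisition at both polarities,
#' reconstruct the velocity-magnitude map, and quantify the K-nearest-node
#' measurement error against the analytic field, as a percentage of VENC.
#'
#' @param rng_seed Integer seed for all randomness.
#' @param inlet_velocity Mean inlet velocity, cm/s (default 18).
#' @param VENC Aliasing velocity, cm/s (default 250).
#' @param FA Flip angle, degrees (default 15).
#' @param density Particle density per mm^3 (default 15).
#' @param n_streamlines Streamlines traced (default 400).
#' @param n_ref_nodes Reference-lattice nodes (default 2e4).
#' @param K Nearest nodes per voxel (default 5).
#' @return List with the `tree`, flow `solution`, velocity `map`, error
#'   `report` and `pct_venc` (mean of the mean-of-K error, % of VENC).
#' @export
pca_error_experiment_3d <- function(rng_seed = 1L, inlet_velocity = 18,
                                    VENC = 250, FA = 15, density = 15,
                                    n_streamlines = 400L, n_ref_nodes = 2e4,
                                    K = 5L) {
  tree <- error_study_tree(rng_seed)
  sol <- solve_flow(tree, list(mean_velocity = inlet_velocity))
  sls <- trace_streamlines(sol, n_streamlines, rng_seed = rng_seed + 1L)
  ens <- seed_particles(sls, density, rng_seed = rng_seed + 2L)
  params <- sequence_params(TE = 2.5, TR = 40, FA = FA, t_ACQ = 1,
                            FOV = c(25.6, 25.6), matrix_size = c(32, 32),
                            slice_spacing = 2.5, n_partitions = 8L,
                            VENC = VENC, dimension = "3D", slab_center = 10)
  ks <- acquire(ens, params, rng_seed = rng_seed + 3L)
  map <- velocity_maps(ks)
  ref <- sample_reference_field(sol, n_ref_nodes, rng_seed = rng_seed + 4L)
  rep <- voxel_errors(map, ref, K = K)
  list(tree = tree, solution = sol, map = map, report = rep,
       pct_venc = rep$pct_venc_mean)
}

#' 14-outlet synthetic tree aligned for 2D through-plane imaging
#'
#' Grows the 14-outlet renal-type tree, remodels the distal segments into
#' curved vessels, and recenters it so the feeding artery crosses the
#' origin at the requested cutplane height with the dominant flow along the
#' slice-selection (z) axis.
#'
#' @param rng_seed Integer seed.
#' @param cut_z Cutplane height on the feeding artery, mm (default 8).
#' @param curve_amplitude Remodelling amplitude for non-root segments, mm.
#' @param fov Planned in-plane field of view of the 2D acquisitions, mm
#'   (used only for cutplane planning).
#' @param slab Planned excited slice thickness, mm.
#' @return A [vessel_tree()]; the selected imaging planes are attached as
#'   attributes: `"cut_z"` (feeding-artery entry plane), `"cut_z2"` (plane
#'   distal to the first bifurcation) and `"cut_center2"` (in-plane FOV
#'   center for cutplane 2).
#' @export
calix_tree <- function(rng_seed = 1L, cut_z = 8, curve_amplitude = 0.8,
                       fov = 16, slab = 3) {
  tree <- grow_tree(calix_config(rng_seed))
  tree <- remodel_curved(tree, curve_amplitude, rng_seed = rng_seed + 1L,
                         exclude = tree$inlet)
  # recenter: feeding artery point at height cut_z moved onto the z axis
  root <- tree$centerlines[[tree$inlet]]
  s <- seq(0, 1, length.out = 200)
  P <- eval_position(root, s)
  k <- which.min(abs(P[, 3] - cut_z))
  tree <- translate_tree(tree, c(-P[k, 1], -P[k, 2], 0))
  attr(tree, "cut_z") <- cut_z
  # cutplane 2 planning: among planes distal to the first bifurcation,
  # select the most proximal one whose excited-slab lumen fits the planned
  # FOV (with a 2 mm fold-over margin), and center the FOV on that content —
  # the scaled-down analogue of a radiographer positioning the second slice
  # over the artery branches
  z_end <- max(tree$centerlines[[tree$inlet]]$nodes[, 3])
  kids <- which(tree$parent == tree$inlet)
  artery <- vessel_tree(tree$centerlines[c(tree$inlet, kids)],
                        c(NA_integer_, rep(1L, length(kids))))
  g1 <- seq(-24, 24, by = 0.5)
  pts0 <- cbind(rep(g1, times = length(g1)), rep(g1, each = length(g1)))
  best <- NULL
  for (zc in z_end + seq(1.5, 8, by = 0.5)) {
    # the plane must actually show the artery's first branches
    n_art <- sum(points_in_lumen(artery, cbind(pts0, zc)))
    if (n_art < 20) next
    inslab <- rep(FALSE, nrow(pts0))
    for (dz in seq(-slab / 2, slab / 2, length.out = 5)) {
      inslab <- inslab | points_in_lumen(tree, cbind(pts0, zc + dz))
    }
    xr <- range(pts0[inslab, 1]); yr <- range(pts0[inslab, 2])
    ext <- max(diff(xr), diff(yr))
    cand <- list(z = zc, ext = ext,
                 center = round(c(mean(xr), mean(yr)) * 2) / 2)
    if (ext <= fov - 2) { best <- cand; break }
    if (is.null(best) || ext < best$ext) best <- cand
  }
  attr(tree, "cut_z2") <- best$z
  attr(tree, "cut_center2") <- best$center
  tree
}

#' Conventional versus EPI 2D PCA comparison experiment
#'
#' Simulates through-plane 2D PCA of the renal-artery cross-section of a
#' 14-outlet synthetic tree at ten pressure-driven inlet levels, with
#' conventional and echo-planar readouts, and compares cross-section
#' averages and peak velocities against the analytic ground truth.
#'
#' @param rng_seed Integer seed.
#' @param netls Echo train lengths to simulate (1 = conventional readout).
#' @param VENC Aliasing velocity, cm/s (default 100).
#' @param peak_range Range of ground-truth peak velocities spanned by the
#'   pressure levels, cm/s (default `c(45, 93)`).
#' @param n_levels Number of levels (default 10).
#' @param density Particle density per mm^3 (default 20).
#' @param n_streamlines Streamlines traced (default 600).
#' @param TE,TR,FA Sequence timing/flip (defaults 4 ms / 70 ms / 30 deg).
#' @return Data frame with one row per (level, readout, cutplane): `level`,
#'   `peak_target`, `netl`, `readout`, `cutplane` (1 = artery entry, 2 =
#'   after the split), measured cross-section average `meas_avg` and peak
#'   `meas_peak`, ground-truth `truth_avg` and `truth_peak` (all cm/s).
#' @export
epi_comparison_experiment <- function(rng_seed = 1L,
                                      netls = c(1L, 4L, 8L, 16L),
                                      VENC = 100, peak_range = c(45, 93),
                                      n_levels = 10L, density = 20,
                                      n_streamlines = 600L,
                                      TE = 4, TR = 70, FA = 30) {
  tree <- calix_tree(rng_seed)
  cut_z <- c(attr(tree, "cut_z"), attr(tree, "cut_z2"))
  sol0 <- solve_flow(tree, list(pressure_drop = 100))
  peak0 <- peak_velocity(sol0)
  targets <- seq(peak_range[1], peak_range[2], length.out = n_levels)
  sls0 <- trace_streamlines(sol0, n_streamlines, rng_seed = rng_seed + 1L)

  # one single-slice acquisition per cutplane, one protocol for both
  # (16 mm FOV at 32x32 = 0.5 mm pixels); cutplane 2 uses the planned
  # off-center FOV position over the artery branches
  mk_params <- function(netl, cp) {
    sequence_params(TE = TE, TR = TR, FA = FA, t_ACQ = 1.25,
                    FOV = c(16, 16), matrix_size = c(32, 32),
                    slice_thickness = 3, n_slices = 1L, VENC = VENC,
                    readout = if (netl > 1) "EPI" else "conventional",
                    NETL = netl, dimension = "2D", slab_center = cut_z[cp],
                    fov_center = if (cp == 2) attr(tree, "cut_center2")
                                 else c(0, 0))
  }
  params_list <- lapply(1:2, function(cp) lapply(netls, mk_params, cp = cp))
  # measurement region: the renal artery itself -- the feeding segment and
  # its first-generation branches.  Distal vessels of the subtree also cross
  # cutplane 2 but are not part of the artery cross-section being measured.
  kids <- which(tree$parent == tree$inlet)
  artery <- vessel_tree(tree$centerlines[c(tree$inlet, kids)],
                        c(NA_integer_, rep(1L, length(kids))))
  region <- lapply(1:2, function(cp) {
    g <- .grid_geometry(params_list[[cp]][[1]])
    pts <- cbind(rep(g$x, times = length(g$y)),
                 rep(g$y, each = length(g$x)), g$z[1])
    matrix(points_in_lumen(artery, pts), length(g$x), length(g$y))
  })

  rows <- list()
  for (li in seq_len(n_levels)) {
    f <- targets[li] / peak0
    sol <- scale_flow(sol0, f)
    sls <- scale_streamlines(sls0, f)
    ens <- seed_particles(sls, density, rng_seed = rng_seed + 10L + li)
    for (cp in 1:2) {
      gt <- ground_truth_map(sol, params_list[[cp]][[1]])
      for (ni in seq_along(netls)) {
        ks <- acquire(ens, params_list[[cp]][[ni]],
                      rng_seed = rng_seed + 100L + li)
        map <- velocity_maps(ks)
        wsl <- map$w[, , 1]
        rows[[length(rows) + 1L]] <- data.frame(
          level = li, peak_target = targets[li], netl = netls[ni],
          readout = if (netls[ni] > 1) sprintf("EPI%d", netls[ni]) else "conventional",
          cutplane = cp,
          meas_avg = mean(wsl[region[[cp]]]),
          meas_peak = max(wsl[region[[cp]]]),
          truth_avg = mean(gt$w[, , 1][region[[cp]]]),
          truth_peak = max(gt$w[, , 1][region[[cp]]]))
      }
    }
  }
  do.call(rbind, rows)
}
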