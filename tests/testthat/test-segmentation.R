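# analytic cylinder volume/mask builders (no synth_ct; exact occupancy)
analytic_cylinder_vol <- function(radius, half_len, voxel = 0.5, pad = 3,
                                  axis = 3L, hi = 200, lo = 50) {
  ext <- rep(radius + pad, 3)
  ext[axis] <- half_len + pad
  d <- ceiling(2 * ext / voxel)
  origin <- -ext + voxel / 2
  co <- lapply(1:3, function(a) origin[a] + (seq_len(d[a]) - 1) * voxel)
  perp <- setdiff(1:3, axis)
  r2 <- outer(co[[perp[1]]]^2, co[[perp[2]]]^2, "+")
  inside <- array(FALSE, d)
  for (k in seq_len(d[axis])) {
    sl <- r2 <= radius^2 & abs(co[[axis]][k]) <= half_len
    idx <- rep(list(quote(expr =)), 3)
    idx[[axis]] <- k
    inside <- do.call(`[<-`, c(list(inside), idx, list(sl)))
  }
  vol <- volume_image(array(lo + (hi - lo) * inside, d), voxel, origin)
  list(vol = vol, mask = binary_mask(inside, vol))
}

test_that("vesselness enhances a tube and vanishes on a uniform image", {
  cyl <- analytic_cylinder_vol(radius = 2, half_len = 8, voxel = 1, pad = 6)
  v <- vesselness(cyl$vol, scales = c(1.5, 2.5))
  d <- dim(v$data)
  ctr <- ceiling(d / 2)
  on_axis <- v$data[ctr[1], ctr[2], ctr[3]]
  off_axis <- v$data[2, 2, ctr[3]]          # far corner, pure background
  expect_gt(on_axis, 2 * max(off_axis, 1e-12))
  flat <- volume_image(array(100, c(10, 10, 10)), 1)
  vf <- vesselness(flat, scales = 2)
  expect_equal(max(vf$data), 0)
})

test_that("vesselness suppresses plates relative to tubes", {
  d <- c(21, 21, 21)
  plate <- array(50, d)
  plate[, , 10:12] <- 200                    # bright slab
  vp <- vesselness(volume_image(plate, 1), scales = 2)
  cyl <- analytic_cylinder_vol(radius = 1.5, half_len = 9, voxel = 1, pad = 9)
  vt <- vesselness(cyl$vol, scales = 2)
  dc <- dim(vt$data); ctr <- ceiling(dc / 2)
  expect_gt(vt$data[ctr[1], ctr[2], ctr[3]], 2 * vp$data[11, 11, 11])
})

test_that("vesselness is equivariant under axis permutation", {
  cz <- analytic_cylinder_vol(radius = 2, half_len = 7, voxel = 1, pad = 7,
                              axis = 3L)
  cx <- analytic_cylinder_vol(radius = 2, half_len = 7, voxel = 1, pad = 7,
                              axis = 1L)
  vz <- vesselness(cz$vol, scales = 2)
  vx <- vesselness(cx$vol, scales = 2)
  dz <- ceiling(dim(vz$data) / 2); dx <- ceiling(dim(vx$data) / 2)
  expect_equal(vx$data[dx[1], dx[2], dx[3]],
               vz$data[dz[1], dz[2], dz[3]], tolerance = 1e-8)
})

test_that("flood fill recovers the full in-window set from one seed", {
  cyl <- analytic_cylinder_vol(radius = 2, half_len = 8, voxel = 0.5)
  ctr <- ceiling(dim(cyl$vol$data) / 2)
  m <- flood_fill(cyl$vol, rbind(ctr), lower = 125)
  expect_identical(m$data, cyl$mask$data)
})

test_that("flood fill respects connectivity between disjoint blobs", {
  img <- array(0, c(20, 10, 10))
  img[2:5, 4:6, 4:6] <- 100
  img[15:18, 4:6, 4:6] <- 100
  vol <- volume_image(img, 1)
  m <- flood_fill(vol, rbind(c(3, 5, 5)), lower = 50)
  expect_true(all(which(m$data, arr.ind = TRUE)[, 1] <= 5))
  expect_equal(sum(m$data), 4L * 3L * 3L)
})

test_that("widening the flood-fill window never shrinks the result", {
  tube <- straight_tube_tree(radius = 2, length = 20)
  img <- synth_ct(tube, voxel_size = 0.7, noise_sd = 10, rng_seed = 5)
  ctr <- ceiling(dim(img$data) / 2)
  m_narrow <- flood_fill(img, rbind(ctr), lower = 160)
  m_wide <- flood_fill(img, rbind(ctr), lower = 125)
  expect_true(all(m_wide$data[m_narrow$data]))
  expect_gte(sum(m_wide$data), sum(m_narrow$data))
})

test_that("flood fill on a tube phantom reaches Dice > 0.9 vs the lumen", {
  tube <- straight_tube_tree(radius = 2.5, length = 25)
  img <- synth_ct(tube, voxel_size = 0.7)
  lum <- attr(img, "lumen")
  ctr <- ceiling(dim(img$data) / 2)
  m <- flood_fill(img, rbind(ctr), lower = 125)
  dice <- 2 * sum(m$data & lum) / (sum(m$data) + sum(lum))
  expect_gt(dice, 0.9)
})

test_that("flood fill rejects seeds outside the intensity window", {
  vol <- volume_image(array(10, c(5, 5, 5)), 1)
  expect_error(flood_fill(vol, rbind(c(1, 1, 1)), lower = 50), "outside")
})

test_that("threshold from wall samples separates vessel from background", {
  tube <- straight_tube_tree(radius = 2.5, length = 25)
  img <- synth_ct(tube, voxel_size = 0.5, vessel_intensity = 200,
                  background_intensity = 50)
  ws <- sample_wall_positions(tube, n = 200, rng_seed = 2)
  thr <- estimate_threshold(img, ws)
  # wall voxels are partial-volume: strictly between the two intensities
  expect_gt(thr, 75)
  expect_lt(thr, 185)
  # and the threshold segments the tube well
  ctr <- ceiling(dim(img$data) / 2)
  m <- flood_fill(img, rbind(ctr), lower = thr)
  lum <- attr(img, "lumen")
  dice <- 2 * sum(m$data & lum) / (sum(m$data) + sum(lum))
  expect_gt(dice, 0.9)
  expect_error(estimate_threshold(img, ws[0, , drop = FALSE]), "wall sample")
})

test_that("estimate_threshold is the exact mean at nearest voxels", {
  vol <- volume_image(array(seq_len(27), c(3, 3, 3)), 1, origin = c(0, 0, 0))
  # sample positions exactly at voxel centers [1,1,1] and [3,2,1] (0-based
  # mm coords (0,0,0) and (2,1,0)) -> values 1 and 6
  thr <- estimate_threshold(vol, rbind(c(0, 0, 0), c(2, 1, 0)))
  expect_identical(thr, mean(c(vol$data[1, 1, 1], vol$data[3, 2, 1])))
})

test_that("skeleton of a straight tube stays on the axis", {
  cyl <- analytic_cylinder_vol(radius = 2, half_len = 12, voxel = 0.5)
  sk <- skeletonize(cyl$mask)
  vox <- which(sk$skeleton, arr.ind = TRUE)
  mm <- sweep(sweep(vox - 1, 2, cyl$mask$voxel_size, "*"),
              2, cyl$mask$origin, "+")
  interior <- abs(mm[, 3]) <= 9              # keep clear of the end caps
  expect_gt(sum(interior), 10)
  expect_lt(max(sqrt(mm[interior, 1]^2 + mm[interior, 2]^2)), 1.0)
  # axial coverage: skeleton spans most of the interior length
  expect_gt(diff(range(mm[interior, 3])), 0.8 * 18)
})

test_that("skeletonization preserves topology at a Y junction", {
  ytree <- symmetric_y_tree()
  img <- synth_ct(ytree, voxel_size = 0.7)
  mask <- binary_mask(attr(img, "lumen"), img)
  sk <- skeletonize(mask)
  expect_gte(length(sk$chains), 3L)
  expect_gte(nrow(sk$junctions), 1L)
  # chain endpoints in mm reach near the three tree extremities
  ends <- do.call(rbind, lapply(sk$chains_mm, function(ch) {
    rbind(ch[1, ], ch[nrow(ch), ])
  }))
  # tips erode by up to prune_iters + 1 voxels (spur pruning plus endpoint
  # erosion) plus sub-voxel offsets: ~4 * 0.7 mm + half a diagonal
  tips <- rbind(c(0, 0, 0), c(6, 0, 20), c(-6, 0, 20))
  for (k in 1:3) {
    dmin <- min(sqrt(rowSums(sweep(ends, 2, tips[k, ])^2)))
    expect_lt(dmin, 4 * 0.7 + 0.7 * sqrt(3))
  }
})

test_that("skeletonizing an empty mask errors", {
  vol <- volume_image(array(0, c(5, 5, 5)), 1)
  expect_error(skeletonize(binary_mask(array(FALSE, c(5, 5, 5)), vol)),
               "empty")
})

test_that("centerline smoothing: lambda 0 identity, large lambda straight", {
  set.seed(11)
  chain <- cbind(seq(0, 10, length.out = 9), rnorm(9, 0, 0.5), rnorm(9, 0, 0.5))
  cl0 <- smooth_centerline(chain, lambda = 0)
  expect_equal(cl0$nodes, chain, tolerance = 1e-12, ignore_attr = TRUE)
  clinf <- smooth_centerline(chain, lambda = 1e8)
  # interior nodes collapse onto the endpoint chord
  a <- chain[1, ]; b <- chain[9, ]
  u <- (b - a) / sqrt(sum((b - a)^2))
  dev <- apply(clinf$nodes, 1, function(p) {
    w <- p - a
    sqrt(sum((w - sum(w * u) * u)^2))
  })
  expect_lt(max(dev), 0.02)
  expect_error(smooth_centerline(chain[1:2, ]), "3 nodes")
  expect_error(smooth_centerline(chain, lambda = -1), "non-negative")
})

test_that("centerline smoothing matches a direct numerical minimizer", {
  set.seed(13)
  n <- 7; lambda <- 0.7
  chain <- cbind(seq_len(n), rnorm(n), rnorm(n))
  cl <- smooth_centerline(chain, lambda = lambda)
  for (c3 in 1:3) {
    p <- chain[, c3]
    obj <- function(xf) {
      x <- c(p[1], xf, p[n])
      sum((x - p)^2) + lambda * sum(diff(x, differences = 2)^2)
    }
    op <- stats::optim(p[2:(n - 1)], obj, method = "BFGS",
                       control = list(reltol = 1e-14, maxit = 500))
    expect_equal(cl$nodes[2:(n - 1), c3], op$par, tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("covariance radius is exact for in-plane rays on a cylinder", {
  cyl <- analytic_cylinder_vol(radius = 3, half_len = 10, voxel = 0.25)
  ang <- seq(0, 2 * pi, length.out = 33)[-33]
  dirs <- cbind(cos(ang), sin(ang), 0)
  est <- estimate_radius(cyl$mask, c(0, 0, 0), directions = dirs)
  expect_lt(abs(est$radius - 3) / 3, 0.02)
  # crossing points themselves sit on the radius-3 circle
  rr <- sqrt(est$points[, 1]^2 + est$points[, 2]^2)
  expect_lt(max(abs(rr - 3)), 0.2)
})

test_that("default-ray radius and direction recover a digital cylinder", {
  cyl <- analytic_cylinder_vol(radius = 2.5, half_len = 12, voxel = 0.5)
  est <- estimate_radius(cyl$mask, c(0, 0, 0))
  expect_lt(abs(est$radius - 2.5) / 2.5, 0.15)
  expect_gt(abs(est$direction[3]), cos(10 * pi / 180))
  expect_false(est$degenerate)
})

test_that("a sphere is flagged degenerate", {
  d <- c(31, 31, 31)
  vol <- volume_image(array(0, d), 0.5, origin = -c(7.5, 7.5, 7.5))
  co <- pcasim:::.vol_coords(vol)
  ball <- array(outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+") <= 25, d)
  mask <- binary_mask(ball, vol)
  est <- estimate_radius(mask, c(0, 0, 0))
  expect_true(est$degenerate)
  # crossings on a sphere of radius R have covariance eigenvalues R^2/3,
  # so the circle rule reports R * sqrt(2/3)
  expect_lt(abs(est$radius - 5 * sqrt(2 / 3)) / 5, 0.05)
})

test_that("estimate_radius rejects a node outside the mask", {
  cyl <- analytic_cylinder_vol(radius = 2, half_len = 5, voxel = 0.5)
  expect_error(estimate_radius(cyl$mask, c(4, 4, 0)), "inside the mask")
})

test_that("tube round trip recovers the radius within 20%", {
  tube <- straight_tube_tree(radius = 2.5, length = 25)
  img <- synth_ct(tube, voxel_size = 0.7)
  ctr <- ceiling(dim(img$data) / 2)
  thr <- estimate_threshold(img, sample_wall_positions(tube, n = 100))
  rec <- recover_tree(img, rbind(ctr), lower = thr)
  radii <- unlist(lapply(rec$centerlines, `[[`, "radii"))
  radii <- radii[!is.na(radii)]
  expect_gt(length(radii), 3)
  rel_err <- abs(radii - 2.5) / 2.5
  expect_lt(median(rel_err), 0.20)
})
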