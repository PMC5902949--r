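fake_map <- function(vals, x = NULL, VENC = 100) {
  # minimal single-slice velocity_map with unit voxels centered on integers
  d <- dim(vals)
  if (length(d) == 2) {
    vals <- array(vals, c(d, 1))
    d <- dim(vals)
  }
  g <- list(voxel = c(1, 1, 1),
            x = if (is.null(x)) seq_len(d[1]) else x,
            y = seq_len(d[2]), z = seq_len(d[3]))
  structure(list(u = array(0, d), v = array(0, d), w = vals, m = abs(vals),
                 magnitude = array(1, d), mask = array(TRUE, d),
                 geometry = g, VENC = VENC),
            class = "velocity_map")
}

test_that("voxel errors vanish when references equal the map", {
  m <- fake_map(matrix(7, 3, 3))
  g <- m$geometry
  nodes <- as.matrix(expand.grid(g$x, g$y, g$z))
  ref <- reference_field(nodes, rep(7, nrow(nodes)))
  rep5 <- voxel_errors(m, ref, K = 5)
  expect_equal(rep5$mean_e_mean, 0)
  expect_equal(rep5$mean_e_min, 0)
})

test_that("single-voxel K = 3 case matches the brute-force differences", {
  m <- fake_map(matrix(10, 1, 1))
  ref <- reference_field(rbind(c(1, 1, 1), c(1.2, 1, 1), c(1, 1.3, 1),
                               c(9, 9, 9)),
                         c(8, 9, 14, 0))
  r <- voxel_errors(m, ref, K = 3)
  expect_equal(r$e_mean, (2 + 1 + 4) / 3)
  expect_equal(r$e_min, 1)
})

test_that("K = 1 makes the mean and min errors identical", {
  set.seed(4)
  m <- fake_map(matrix(runif(9, 0, 20), 3, 3))
  nodes <- as.matrix(expand.grid(1:3, 1:3, 1)) + matrix(runif(27, -0.2, 0.2), 9, 3)
  ref <- reference_field(nodes, runif(9, 0, 20))
  r <- voxel_errors(m, ref, K = 1)
  expect_equal(r$e_mean, r$e_min)
})

test_that("K = 10 neighbour sets contain the K = 5 sets (nesting)", {
  set.seed(6)
  nodes <- matrix(runif(90, 0, 10), 30, 3)
  q <- matrix(runif(15, 0, 10), 5, 3)
  nn5 <- pcasim:::.knn_indices(nodes, q, 5L)
  nn10 <- pcasim:::.knn_indices(nodes, q, 10L)
  for (i in 1:5) expect_true(all(nn5[i, ] %in% nn10[i, ]))
})

test_that("signed errors average to zero on symmetric deviations", {
  m <- fake_map(matrix(10, 1, 1))
  ref <- reference_field(rbind(c(1, 1, 1.1), c(1, 1, 0.9)), c(8, 12))
  r <- voxel_errors(m, ref, K = 2, signed = TRUE)
  expect_equal(r$e_mean, 0)
  r2 <- voxel_errors(m, ref, K = 2)
  expect_equal(r2$e_mean, 2)
})

test_that("cross-section average reduces to the plain in-mask mean", {
  vals <- matrix(c(2, 4, 6, 8), 2, 2)
  m <- fake_map(vals)
  expect_equal(cross_section_average(m, 1), 5)
  m$mask[1, 1, 1] <- FALSE
  expect_equal(cross_section_average(m, 1), mean(c(4, 6, 8)))
  # uniform map: the average is the constant; single-voxel mask: that voxel
  mu <- fake_map(matrix(3.3, 4, 4))
  expect_equal(cross_section_average(mu, 1), 3.3)
  mu$mask[] <- FALSE; mu$mask[2, 3, 1] <- TRUE
  expect_equal(cross_section_average(mu, 1), mu$w[2, 3, 1])
})

test_that("disk-sampled Poiseuille average is half the peak", {
  n <- 64
  xy <- seq(-1, 1, length.out = n)
  r2 <- outer(xy^2, xy^2, "+")
  vbar <- 10
  vals <- ifelse(r2 <= 1, 2 * vbar * (1 - r2), 0)
  m <- fake_map(vals)
  m$mask <- array(r2 <= 1, c(n, n, 1))
  expect_gte(sum(m$mask), 200)
  expect_lt(abs(cross_section_average(m, 1) - vbar) / vbar, 0.05)
})

test_that("Bland-Altman statistics match hand computation", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$loa, c(0, 0))
  ba1 <- bland_altman(c(1, 0), c(0, 1))        # diffs {1, -1}
  expect_equal(ba1$mean_diff, 0)
  expect_equal(ba1$sd_diff, sqrt(2))           # sample SD, n - 1
  expect_equal(ba1$loa, c(-1.96, 1.96) * sqrt(2))
  ba2 <- bland_altman(c(4, 5, 6), c(1, 2, 3))
  expect_equal(ba2$mean_diff, 3)
})

test_that("linear agreement matches the normal-equation oracle", {
  expect_equal(linear_agreement(1:5, 1:5),
               list(slope = 1, intercept = 0, correlation = 1))
  la <- linear_agreement(2 * (1:5) + 3, 1:5)
  expect_equal(la$slope, 2, tolerance = 1e-12)
  expect_equal(la$intercept, 3, tolerance = 1e-12)
  expect_equal(la$correlation, 1, tolerance = 1e-12)
  set.seed(9)
  x <- runif(10); y <- 1.4 * x + 0.2 + rnorm(10, 0, 0.05)
  la2 <- linear_agreement(y, x)
  ab <- oracle_lm(x, y)
  expect_equal(la2$intercept, ab[1], tolerance = 1e-10)
  expect_equal(la2$slope, ab[2], tolerance = 1e-10)
})

test_that("cutline profiles sample the map geometrically", {
  m <- fake_map(matrix(5, 8, 8))
  pr <- cutline_profile(m, c(1, 4, 1), c(8, 4, 1), n_samples = 16)
  expect_true(all(pr$value == 5))
  pr1 <- cutline_profile(m, c(1, 4, 1), c(8, 4, 1), n_samples = 1)
  expect_equal(nrow(pr1), 1L)
  expect_equal(pr1$distance, 3.5)
  # parabolic profile across a Poiseuille disk
  n <- 33
  xy <- seq(-1, 1, length.out = n)
  r2 <- outer(xy^2, xy^2, "+")
  vals <- ifelse(r2 <= 1, 20 * (1 - r2), 0)
  mp <- fake_map(vals, x = NULL)
  mp$geometry$x <- xy; mp$geometry$y <- xy; mp$geometry$z <- 0
  mp$geometry$voxel <- c(diff(xy)[1], diff(xy)[1], 1)
  pd <- cutline_profile(mp, c(-1, 0, 0), c(1, 0, 0), n_samples = n)
  expect_equal(which.max(pd$value), (n + 1) / 2)
  expect_equal(max(pd$value), 20, tolerance = 1e-9)
  # symmetry of the parabola
  expect_equal(pd$value, rev(pd$value), tolerance = 1e-9)
  expect_error(cutline_profile(m, c(-50, 0, 1), c(50, 0, 1)), "outside")
})

test_that("compare_errors runs a paired t test", {
  set.seed(2)
  a <- rnorm(10); b <- a + rnorm(10, 0.01, 0.002)
  ht <- compare_errors(a, b)
  expect_s3_class(ht, "htest")
  expect_equal(unname(ht$estimate), mean(a - b), tolerance = 1e-12)
})
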