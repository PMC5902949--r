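# Independent oracles used by the unit tests.  Each one re-derives the
# quantity under test by a different route than the package implementation.

# Natural cubic spline: solve the tridiagonal second-derivative system
# directly and evaluate piecewise.  Independent of stats::splinefun.
oracle_natural_spline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 1; A[n, n] <- 1            # natural: M_1 = M_n = 0
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  M <- solve(A, b)                      # second derivatives at the knots
  vapply(xout, function(xx) {
    i <- findInterval(xx, x, rightmost.closed = TRUE)
    i <- min(max(i, 1L), n - 1L)
    t1 <- x[i + 1] - xx; t0 <- xx - x[i]
    (M[i] * t1^3 + M[i + 1] * t0^3) / (6 * h[i]) +
      (y[i] / h[i] - M[i] * h[i] / 6) * t1 +
      (y[i + 1] / h[i] - M[i + 1] * h[i] / 6) * t0
  }, 0)
}

# Eq. 1 as an explicit matrix product: Rot_z(tg) Rot_z(ti) R12 M + R1.
oracle_eq1 <- function(M, M0, T1, T2, dt, theta_g, theta_i) {
  rotz <- function(a) matrix(c(cos(a), sin(a), 0,
                               -sin(a), cos(a), 0,
                               0, 0, 1), 3, 3)
  R12 <- diag(c(exp(-dt / T2), exp(-dt / T2), exp(-dt / T1)))
  as.numeric(rotz(theta_g) %*% rotz(theta_i) %*% R12 %*% M +
               c(0, 0, M0 * (1 - exp(-dt / T1))))
}

# Total segment volume of a one-inlet/two-terminal tree with the bifurcation
# at xb: radii from Poiseuille with the bifurcation law r ~ Q^(1/3).
oracle_bif_volume <- function(xb, inlet, t1, t2, q1, q2, r_root) {
  qr <- q1 + q2
  rr <- function(q) r_root * (q / qr)^(1 / 3)
  seg <- function(a, b, r) pi * r^2 * sqrt(sum((a - b)^2))
  seg(inlet, xb, r_root) + seg(xb, t1, rr(q1)) + seg(xb, t2, rr(q2))
}

# Unit-norm helper for vector checks.
oracle_norm <- function(v) sqrt(sum(v^2))

# 2D centered inverse DFT consistent with the documented convention:
# k_n = (n - N/2)/FOV, voxel centers x_i = -FOV/2 + (i + 0.5) FOV/N.
oracle_idft1 <- function(kvec, N, FOV) {
  k <- (seq_len(N) - 1 - N / 2) / FOV
  x <- -FOV / 2 + (seq_len(N) - 0.5) * FOV / N
  as.vector(exp(-2i * pi * outer(x, k)) %*% kvec) / N
}

# Normal-equation least squares for y ~ x.
oracle_lm <- function(x, y) {
  X <- cbind(1, x)
  solve(t(X) %*% X, t(X) %*% y)
}

# Shared small fixtures -------------------------------------------------

# a gently curved centerline used by several geometry tests
curved_cl <- function() {
  s <- seq(0, 1, length.out = 9)
  centerline(cbind(10 * s, 2 * sin(pi * s), 0.5 * s^2), 1.5 - 0.4 * s)
}

# symmetric Y tree: one parent up the z axis, two mirror children
symmetric_y_tree <- function() {
  parent <- centerline(rbind(c(0, 0, 0), c(0, 0, 5), c(0, 0, 10)), 2)
  ch1 <- centerline(rbind(c(0, 0, 10), c(3, 0, 15), c(6, 0, 20)), 1.58)
  ch2 <- centerline(rbind(c(0, 0, 10), c(-3, 0, 15), c(-6, 0, 20)), 1.58)
  vessel_tree(list(parent, ch1, ch2), c(NA, 1L, 1L))
}

# Cross-file cache for expensive fixtures (helpers are sourced once per run,
# so acceptance blocks and unit tests can share one grown tree / experiment).
.fixture_cache <- new.env(parent = emptyenv())
cached_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

cached_calix_tree <- function() cached_fixture("calix", calix_tree(rng_seed = 1))
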