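#' Ground-truth reference field for error quantification
#'
#' A set of reference nodes (3-D positions with ground-truth velocity
#' magnitudes), playing the role of the flow-simulation lattice against
#' which image-derived velocities are validated.
#'
#' @param nodes Numeric matrix `n x 3` (mm).
#' @param values Velocity magnitudes at the nodes, cm/s.
#' @return An object of class `reference_field`.
#' @export
reference_field <- function(nodes, values) {
  nodes <- as.matrix(nodes)
  stopifnot(ncol(nodes) == 3, nrow(nodes) == length(values))
  structure(list(nodes = nodes, values = as.numeric(values)),
            class = "reference_field")
}

#' Sample a reference field from an analytic flow solution
#'
#' Draws uniform random points inside the lumen (rejection sampling over the
#' tree bounding box) and evaluates the analytic velocity magnitude there,
#' emulating the dense lattice a flow solver would export.
#'
#' @param solution A [solve_flow()] result.
#' @param n_nodes Number of reference nodes.
#' @param rng_seed Integer seed.
#' @return A [reference_field()].
#' @export
sample_reference_field <- function(solution, n_nodes = 2e4, rng_seed = 1L) {
  set.seed(rng_seed)
  tr <- solution$tree
  # the box must enclose the lumen, not just the centerline nodes
  bb <- .tree_bbox(tr)
  pts <- matrix(0, 0, 3)
  while (nrow(pts) < n_nodes) {
    m <- 4L * n_nodes
    cand <- cbind(runif(m, bb$lo[1], bb$hi[1]),
                  runif(m, bb$lo[2], bb$hi[2]),
                  runif(m, bb$lo[3], bb$hi[3]))
    keep <- points_in_lumen(tr, cand)
    pts <- rbind(pts, cand[keep, , drop = FALSE])
  }
  pts <- pts[seq_len(n_nodes), , drop = FALSE]
  v <- velocity_field(solution, pts)
  reference_field(pts, attr(v, "speed"))
}

# K nearest reference nodes per query point: brute force, chunked.
# Returns n x K matrix of node indices (ties broken by node index).
.knn_indices <- function(nodes, query, K) {
  n <- nrow(query)
  out <- matrix(0L, n, K)
  nd2 <- rowSums(nodes^2)
  chunk <- 500L
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    Q <- query[idx, , drop = FALSE]
    d2 <- outer(rowSums(Q^2), nd2, "+") - 2 * Q %*% t(nodes)
    for (r in seq_along(idx)) {
      out[idx[r], ] <- order(d2[r, ])[seq_len(K)]
    }
  }
  out
}

#' K-nearest-node velocity measurement errors
#'
#' For every in-mask voxel, finds the `K` reference nodes closest to the
#' voxel center and forms two error estimates between the measured velocity
#' magnitude `m_i` and the reference magnitudes `m_j`: the mean difference
#' over the K neighbours and the minimum difference (the latter guards
#' against sparse reference sampling in small branches fictitiously
#' inflating the error).  By default both use absolute differences
#' `|m_i - m_j|`; `signed = TRUE` uses raw differences for audit.
#'
#' @param map A masked `velocity_map` ([velocity_maps()]).
#' @param ref A [reference_field()] with at least `K` nodes.
#' @param K Number of nearest nodes (default 5).
#' @param signed Use signed differences instead of absolute ones.
#' @return An object of class `error_report`: per-voxel vectors `e_mean`
#'   and `e_min` (cm/s), their means and standard deviations, the same as a
#'   percentage of VENC, `K`, and the voxel coordinates used.
#' @export
voxel_errors <- function(map, ref, K = 5L, signed = FALSE) {
  stopifnot(inherits(map, "velocity_map"), inherits(ref, "reference_field"))
  K <- as.integer(K)
  if (K < 1) stop("K must be >= 1")
  if (nrow(ref$nodes) < K) stop("reference field has fewer than K nodes")
  g <- map$geometry
  idx <- which(map$mask, arr.ind = TRUE)
  if (!nrow(idx)) stop("velocity map has an empty mask")
  centers <- cbind(g$x[idx[, 1]], g$y[idx[, 2]], g$z[idx[, 3]])
  mi <- map$m[map$mask]
  nn <- .knn_indices(ref$nodes, centers, K)
  diffs <- matrix(ref$values[nn], nrow(nn), K)
  diffs <- mi - diffs
  if (!signed) diffs <- abs(diffs)
  e_mean <- rowMeans(diffs)
  e_min <- if (signed) apply(diffs, 1, min) else apply(diffs, 1, min)
  venc <- map$VENC
  structure(list(e_mean = e_mean, e_min = e_min,
                 mean_e_mean = mean(e_mean), sd_e_mean = sd(e_mean),
                 mean_e_min = mean(e_min), sd_e_min = sd(e_min),
                 pct_venc_mean = 100 * mean(e_mean) / venc,
                 pct_venc_min = 100 * mean(e_min) / venc,
                 K = K, signed = signed, VENC = venc,
                 voxels = centers),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("<error_report> K = %d over %d voxels\n", x$K, length(x$e_mean)))
  cat(sprintf("  mean-of-K error: %.2f +/- %.2f cm/s (%.2f%% of VENC)\n",
              x$mean_e_mean, x$sd_e_mean, x$pct_venc_mean))
  cat(sprintf("  min-of-K  error: %.2f +/- %.2f cm/s (%.2f%% of VENC)\n",
              x$mean_e_min, x$sd_e_min, x$pct_venc_min))
  invisible(x)
}

#' Cross-sectional average of a velocity component
#'
#' Mean of the chosen component over the in-mask voxels of one image plane.
#'
#' @param map A `velocity_map`.
#' @param plane Slice/partition index along z (third array dimension).
#' @param component `"w"` (default), `"u"`, `"v"` or `"m"`.
#' @return Mean velocity, cm/s.
#' @export
cross_section_average <- function(map, plane, component = "w") {
  stopifnot(inherits(map, "velocity_map"))
  comp <- map[[component]]
  msk <- map$mask[, , plane]
  if (!any(msk)) stop("plane does not intersect the mask")
  mean(comp[, , plane][msk])
}

#' Bland-Altman agreement statistics
#'
#' @param a,b Paired measurement series of equal length (`>= 2`).
#' @return List with `mean_diff`, `sd_diff`, and the 95% limits of agreement
#'   `loa` (`mean_diff +/- 1.96 sd_diff`).
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("series length mismatch")
  if (length(a) < 2) stop("need at least 2 paired values")
  d <- a - b
  md <- mean(d)
  s <- sd(d)
  list(mean_diff = md, sd_diff = s, loa = md + c(-1.96, 1.96) * s,
       mean_level = (a + b) / 2, diff = d)
}

#' Linear agreement of measured against true values
#'
#' Ordinary least-squares fit `measured ~ truth` plus the Pearson
#' correlation coefficient.
#'
#' @param measured,truth Numeric series of equal length (`>= 3`).
#' @return List with `slope`, `intercept`, `correlation`.
#' @export
linear_agreement <- function(measured, truth) {
  if (length(measured) != length(truth)) stop("series length mismatch")
  if (length(measured) < 3) stop("need at least 3 paired values")
  if (sd(truth) == 0) stop("zero variance in truth series")
  fit <- lm(measured ~ truth)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       correlation = cor(measured, truth))
}

#' Velocity profile along a cutline
#'
#' Samples a component of the velocity map along a straight line using
#' nearest-voxel lookup.
#'
#' @param map A `velocity_map`.
#' @param start,end Line endpoints, mm (3-vectors).
#' @param n_samples Number of samples (`>= 1`).
#' @param component `"w"` (default), `"u"`, `"v"` or `"m"`.
#' @return Data frame with `distance` (mm from `start`) and `value` (cm/s).
#' @export
cutline_profile <- function(map, start, end, n_samples = 64L, component = "w") {
  stopifnot(inherits(map, "velocity_map"), n_samples >= 1)
  g <- map$geometry
  tseq <- if (n_samples == 1) 0.5 else seq(0, 1, length.out = n_samples)
  pts <- outer(1 - tseq, start) + outer(tseq, end)
  near <- function(coords, centers) {
    i <- findInterval(coords, c(-Inf, centers[-1] - diff(centers) / 2, Inf))
    pmin(pmax(i, 1L), length(centers))
  }
  ix <- near(pts[, 1], g$x); iy <- near(pts[, 2], g$y); iz <- near(pts[, 3], g$z)
  if (any(pts[, 1] < g$x[1] - g$voxel[1] | pts[, 1] > g$x[length(g$x)] + g$voxel[1]) ||
      any(pts[, 2] < g$y[1] - g$voxel[2] | pts[, 2] > g$y[length(g$y)] + g$voxel[2])) {
    stop("cutline extends outside the field of view")
  }
  comp <- map[[component]]
  data.frame(distance = sqrt(rowSums((pts - matrix(start, nrow(pts), 3,
                                                   byrow = TRUE))^2)),
             value = comp[cbind(ix, iy, iz)])
}

#' Paired comparison of two error series
#'
#' Two-sided paired t test, as used to compare measurement-error series
#' between sequence settings.
#'
#' @param a,b Paired error series.
#' @return The `htest` object from [stats::t.test()].
#' @export
compare_errors <- function(a, b) {
  t.test(a, b, paired = TRUE)
}
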