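#' Vessel centerline with continuous position and radius splines
#'
#' A centerline is an ordered series of nodes (3-D positions in mm with an
#' associated lumen radius in mm).  The node sequence is parameterized by
#' normalized arc length `s` in `[0, 1]` and interpolated by natural cubic
#' splines, one per coordinate and one for the radius, so that positions and
#' radii are continuous functions of `s` that reproduce the nodes exactly at
#' the knots.
#'
#' @param positions Numeric matrix `n x 3` of node positions (mm), `n >= 2`.
#' @param radii Numeric vector of node radii (mm), length `n` or 1 (recycled).
#'   All radii must be positive.
#' @return An object of class `centerline` with elements `nodes`, `radii`,
#'   `arc` (normalized arc-length knots), and `length` (total arc length, mm).
#' @examples
#' cl <- centerline(cbind(0:3, 0, 0), c(2, 1.8, 1.6, 1.5))
#' eval_radius(cl, 0.5)
#' @export
centerline <- function(positions, radii) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3L) stop("positions must be an n x 3 matrix")
  n <- nrow(positions)
  if (n < 2L) stop("a centerline needs at least 2 nodes")
  if (!all(is.finite(positions))) stop("node positions must be finite")
  radii <- rep_len(as.numeric(radii), n)
  if (!all(is.finite(radii)) || any(radii <= 0)) {
    stop("node radii must be finite and positive")
  }
  seg <- sqrt(rowSums((positions[-1, , drop = FALSE] -
                         positions[-n, , drop = FALSE])^2))
  if (any(seg < 1e-12)) stop("consecutive centerline nodes coincide")
  arc <- c(0, cumsum(seg))
  total <- arc[n]
  s <- arc / total
  obj <- list(nodes = positions, radii = radii, arc = s, length = total)
  obj$fx <- stats::splinefun(s, positions[, 1], method = "natural")
  obj$fy <- stats::splinefun(s, positions[, 2], method = "natural")
  obj$fz <- stats::splinefun(s, positions[, 3], method = "natural")
  obj$fr <- stats::splinefun(s, radii, method = "natural")
  class(obj) <- "centerline"
  obj
}

.check_s <- function(s) {
  if (any(!is.finite(s)) || any(s < -1e-12) || any(s > 1 + 1e-12)) {
    stop("normalized arc position s must lie in [0, 1]")
  }
  pmin(pmax(s, 0), 1)
}

#' Evaluate the interpolated radius of a centerline
#'
#' Natural cubic-spline interpolation of the node radii against normalized
#' arc length; exact at the knots.
#'
#' @param cl A [centerline()].
#' @param s Normalized arc position(s) in `[0, 1]`.
#' @return Radius (mm), vectorized over `s`.
#' @export
eval_radius <- function(cl, s) {
  stopifnot(inherits(cl, "centerline"))
  cl$fr(.check_s(s))
}

#' Evaluate the interpolated position of a centerline
#'
#' @param cl A [centerline()].
#' @param s Normalized arc position(s) in `[0, 1]`.
#' @return Numeric matrix `length(s) x 3` of positions (mm).
#' @export
eval_position <- function(cl, s) {
  stopifnot(inherits(cl, "centerline"))
  s <- .check_s(s)
  cbind(cl$fx(s), cl$fy(s), cl$fz(s))
}

#' Evaluate the unit tangent of a centerline
#'
#' Derivative of the position spline with respect to normalized arc length,
#' normalized to unit length.
#'
#' @param cl A [centerline()].
#' @param s Normalized arc position(s) in `[0, 1]`.
#' @return Numeric matrix `length(s) x 3` of unit tangent vectors.
#' @export
eval_tangent <- function(cl, s) {
  stopifnot(inherits(cl, "centerline"))
  s <- .check_s(s)
  d <- cbind(cl$fx(s, deriv = 1), cl$fy(s, deriv = 1), cl$fz(s, deriv = 1))
  d / sqrt(rowSums(d^2))
}

# Parallel-transport frames (t, e1, e2) along a centerline at positions s.
# The initial normal is propagated by projecting out the new tangent, which
# avoids the torsion flips a Frenet frame exhibits at inflections.  An
# optional e1_init seeds the first normal (used to keep frames continuous
# across a junction).
.pt_frames <- function(cl, s, e1_init = NULL) {
  s <- .check_s(s)
  tg <- eval_tangent(cl, s)
  m <- length(s)
  e1 <- matrix(0, m, 3)
  e2 <- matrix(0, m, 3)
  t0 <- tg[1, ]
  if (is.null(e1_init)) {
    ref <- if (abs(t0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1_cur <- .normalize(.cross3(t0, ref))
  } else {
    e1_cur <- e1_init - sum(e1_init * t0) * t0
    if (sqrt(sum(e1_cur^2)) < 1e-8) {
      ref <- if (abs(t0[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      e1_cur <- .cross3(t0, ref)
    }
    e1_cur <- .normalize(e1_cur)
  }
  for (i in seq_len(m)) {
    ti <- tg[i, ]
    v <- e1_cur - sum(e1_cur * ti) * ti
    if (sqrt(sum(v^2)) < 1e-8) {
      ref <- if (abs(ti[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
      v <- .cross3(ti, ref)
    }
    e1_cur <- .normalize(v)
    e1[i, ] <- e1_cur
    e2[i, ] <- .cross3(ti, e1_cur)
  }
  list(t = tg, e1 = e1, e2 = e2)
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d nodes, length %.2f mm, radius %.3f-%.3f mm\n",
              nrow(x$nodes), x$length, min(x$radii), max(x$radii)))
  invisible(x)
}
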