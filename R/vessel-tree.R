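#' Vascular tree of connected centerlines
#'
#' A tree is a list of [centerline()]s with parent/child connectivity: each
#' non-root centerline attaches to its parent at a normalized arc position
#' `s_attach`.  Connectivity must be acyclic with exactly one root (the
#' inlet), and a child's inlet radius may not exceed the parent radius at the
#' attachment point beyond a small tolerance.
#'
#' @param centerlines List of [centerline()] objects.
#' @param parent Integer vector, one entry per centerline: index of the parent
#'   centerline, or `NA` for the root.  Exactly one entry must be `NA`.
#' @param s_attach Numeric vector of attachment arc positions on the parent
#'   (ignored for the root); defaults to 1 (attachment at the parent outlet).
#' @param radius_tol Allowed fractional excess of a child inlet radius over
#'   the parent radius at the attachment (default 0.05).
#' @return An object of class `vessel_tree` with elements `centerlines`,
#'   `parent`, `s_attach`, `inlet` (root index).
#' @export
vessel_tree <- function(centerlines, parent, s_attach = rep(1, length(centerlines)),
                        radius_tol = 0.05) {
  if (!length(centerlines)) stop("centerlines: empty centerline list")
  if (!all(vapply(centerlines, inherits, TRUE, "centerline"))) {
    stop("all elements of centerlines must be centerline objects")
  }
  n <- length(centerlines)
  parent <- as.integer(parent)
  if (length(parent) != n) stop("parent must have one entry per centerline")
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("connectivity must have exactly one root")
  if (any(parent[!is.na(parent)] < 1 | parent[!is.na(parent)] > n)) {
    stop("parent index out of range")
  }
  s_attach <- rep_len(as.numeric(s_attach), n)
  # acyclicity: walking up from every node must reach the root
  for (i in seq_len(n)) {
    seen <- logical(n)
    j <- i
    while (!is.na(parent[j])) {
      if (seen[j]) stop("connectivity contains a cycle")
      seen[j] <- TRUE
      j <- parent[j]
    }
  }
  for (i in seq_len(n)) {
    if (is.na(parent[i])) next
    rp <- eval_radius(centerlines[[parent[i]]], s_attach[i])
    rc <- centerlines[[i]]$radii[1]
    if (rc > rp * (1 + radius_tol)) {
      stop(sprintf("child %d inlet radius %.3f exceeds parent radius %.3f at s=%.3f",
                   i, rc, rp, s_attach[i]))
    }
  }
  structure(list(centerlines = centerlines, parent = parent,
                 s_attach = s_attach, inlet = root),
            class = "vessel_tree")
}

#' Indices of the leaf (outlet) centerlines of a tree
#'
#' @param tree A [vessel_tree()].
#' @return Integer vector of centerline indices with no children.
#' @export
tree_leaves <- function(tree) {
  stopifnot(inherits(tree, "vessel_tree"))
  setdiff(seq_along(tree$centerlines), tree$parent[!is.na(tree$parent)])
}

.tree_children <- function(tree, i) which(!is.na(tree$parent) & tree$parent == i)

#' Total lumen volume of a tree
#'
#' Either the analytic sum of per-segment volumes `pi * integral r(s)^2 dl`
#' (fast; counts junction overlap regions twice) or a Monte-Carlo estimate
#' from uniform samples in the bounding box classified by [points_in_lumen()]
#' (counts the union).
#'
#' @param tree A [vessel_tree()].
#' @param method `"analytic"` or `"mc"`.
#' @param n_samples Monte-Carlo sample count.
#' @param rng_seed Seed for the Monte-Carlo estimate.
#' @return Volume in mm^3.
#' @export
tree_volume <- function(tree, method = c("analytic", "mc"),
                        n_samples = 2e5, rng_seed = 1) {
  method <- match.arg(method)
  if (method == "analytic") {
    sum(vapply(tree$centerlines, function(cl) {
      s <- seq(0, 1, length.out = 200)
      r <- eval_radius(cl, s)
      # arc-length element from the position spline derivative
      d <- cbind(cl$fx(s, deriv = 1), cl$fy(s, deriv = 1), cl$fz(s, deriv = 1))
      dl <- sqrt(rowSums(d^2))
      pi * sum((r[-1]^2 * dl[-1] + r[-200]^2 * dl[-200]) / 2 * diff(s))
    }, 0))
  } else {
    set.seed(rng_seed)
    # the box must enclose the lumen, not just the centerline nodes
    bb <- .tree_bbox(tree)
    pts <- cbind(runif(n_samples, bb$lo[1], bb$hi[1]),
                 runif(n_samples, bb$lo[2], bb$hi[2]),
                 runif(n_samples, bb$lo[3], bb$hi[3]))
    frac <- mean(points_in_lumen(tree, pts))
    frac * prod(bb$hi - bb$lo)
  }
}

# Dense polyline sampling of every centerline; cached on the tree object by
# callers that reuse it.  step is the target arc spacing in mm.
.tree_polylines <- function(tree, step = 0.2) {
  lapply(tree$centerlines, function(cl) {
    m <- max(8L, ceiling(cl$length / step) + 1L)
    s <- seq(0, 1, length.out = m)
    P <- eval_position(cl, s)
    r <- eval_radius(cl, s)
    A <- P[-m, , drop = FALSE]
    B <- P[-1, , drop = FALSE]
    D <- B - A
    L2 <- rowSums(D^2)
    list(s = s, P = P, r = r, A = A, D = D, L2 = pmax(L2, 1e-300), m = m)
  })
}

.tree_bbox <- function(tree, margin = NULL) {
  allp <- do.call(rbind, lapply(tree$centerlines, function(cl) cl$nodes))
  rmax <- max(vapply(tree$centerlines, function(cl) max(cl$radii), 0))
  if (is.null(margin)) margin <- rmax * 1.5
  list(lo = apply(allp, 2, min) - margin, hi = apply(allp, 2, max) + margin)
}

#' Test whether points lie inside the vessel lumen
#'
#' A point is inside the lumen when its distance to some centerline is
#' smaller than the spline radius at the closest centerline position.  Tube
#' ends are flat: points axially beyond a centerline's first or last node
#' are outside, consistent with the analytic [tree_volume()] and the
#' flat-capped [sweep_surface()] mesh.
#'
#' @param tree A [vessel_tree()].
#' @param points Numeric matrix `n x 3` (mm).
#' @param step Polyline sampling step (mm) used for the distance query.
#' @return Logical vector of length `n`.
#' @export
points_in_lumen <- function(tree, points, step = 0.2) {
  stopifnot(inherits(tree, "vessel_tree"))
  points <- as.matrix(points)
  pl <- .tree_polylines(tree, step)
  inside <- logical(nrow(points))
  chunk <- 2000L
  for (start in seq(1L, nrow(points), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(points))
    X <- points[idx, , drop = FALSE]
    inc <- logical(length(idx))
    for (p in pl) {
      # prune by bounding box of this centerline
      lo <- apply(p$P, 2, min) - max(p$r)
      hi <- apply(p$P, 2, max) + max(p$r)
      cand <- which(!inc &
                      X[, 1] >= lo[1] & X[, 1] <= hi[1] &
                      X[, 2] >= lo[2] & X[, 2] <= hi[2] &
                      X[, 3] >= lo[3] & X[, 3] <= hi[3])
      if (!length(cand)) next
      Y <- X[cand, , drop = FALSE]
      res <- .nearest_on_polyline(p, Y)
      inc[cand] <- inc[cand] | (res$d2 <= res$r^2 & !res$beyond)
    }
    inside[idx] <- inc
  }
  inside
}

# Nearest point on one polyline for a block of query points.
# Returns squared distance, interpolated radius and arc position s.
.nearest_on_polyline <- function(p, Y) {
  np <- nrow(Y)
  m1 <- nrow(p$A)
  # t parameter of the projection of each point on each segment
  YD <- Y %*% t(p$D)                           # np x m1
  AD <- matrix(rowSums(p$A * p$D), np, m1, byrow = TRUE)
  tt <- (YD - AD) / matrix(p$L2, np, m1, byrow = TRUE)
  tt[tt < 0] <- 0
  tt[tt > 1] <- 1
  # squared distances
  Y2 <- matrix(rowSums(Y^2), np, m1)
  A2 <- matrix(rowSums(p$A^2), np, m1, byrow = TRUE)
  YA <- Y %*% t(p$A)
  AD2 <- matrix(rowSums(p$A * p$D), np, m1, byrow = TRUE)
  D2 <- matrix(p$L2, np, m1, byrow = TRUE)
  d2 <- Y2 + A2 + 2 * tt * AD2 + tt^2 * D2 - 2 * YA - 2 * tt * YD
  j <- max.col(-d2, ties.method = "first")
  pick <- cbind(seq_len(np), j)
  tbest <- tt[pick]
  sseg <- p$s[j] + tbest * (p$s[j + 1L] - p$s[j])
  rloc <- p$r[j] + tbest * (p$r[j + 1L] - p$r[j])
  # flat end caps: a point whose nearest polyline point is an extreme end
  # and that lies axially beyond that end is past the tube, not inside a
  # rounded cap (keeps the lumen consistent with the analytic volume and
  # the flat-capped surface mesh)
  beyond <- rep(FALSE, np)
  at0 <- j == 1L & tbest <= 0
  if (any(at0)) {
    beyond[at0] <- (Y[at0, , drop = FALSE] -
                      matrix(p$A[1, ], sum(at0), 3, byrow = TRUE)) %*%
      p$D[1, ] < 0
  }
  atn <- j == m1 & tbest >= 1
  if (any(atn)) {
    endpt <- p$A[m1, ] + p$D[m1, ]
    beyond[atn] <- (Y[atn, , drop = FALSE] -
                      matrix(endpt, sum(atn), 3, byrow = TRUE)) %*%
      p$D[m1, ] > 0
  }
  list(d2 = pmax(d2[pick], 0), r = rloc, s = sseg, seg = j, beyond = beyond)
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("<vessel_tree> %d centerlines, %d outlets, inlet radius %.2f mm\n",
              length(x$centerlines), length(tree_leaves(x)),
              x$centerlines[[x$inlet]]$radii[1]))
  invisible(x)
}
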