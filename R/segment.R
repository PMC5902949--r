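#' Flood fill segmentation within an intensity window
#'
#' 26-connected region growing from seed voxels, constrained to voxels whose
#' intensity lies in `[lower, upper]`.  Implemented as iterated 26-neighbour
#' dilation restricted to the in-range set, so widening the window can never
#' shrink the result.
#'
#' @param img A [volume_image()].
#' @param seeds Integer matrix `n x 3` of 1-based voxel indices.
#' @param lower,upper Intensity window bounds.
#' @return A `binary_mask`.
#' @export
flood_fill <- function(img, seeds, lower, upper = Inf) {
  stopifnot(inherits(img, "volume_image"))
  seeds <- matrix(as.integer(seeds), ncol = 3)
  d <- dim(img$data)
  inr <- img$data >= lower & img$data <= upper
  for (r in seq_len(nrow(seeds))) {
    v <- img$data[seeds[r, 1], seeds[r, 2], seeds[r, 3]]
    if (v < lower || v > upper) {
      stop(sprintf("seed (%d, %d, %d) intensity %.4g outside [%.4g, %.4g]",
                   seeds[r, 1], seeds[r, 2], seeds[r, 3], v, lower, upper))
    }
  }
  cur <- array(FALSE, d)
  cur[seeds] <- TRUE
  repeat {
    grown <- .dilate26(cur) & inr
    if (sum(grown) == sum(cur)) break
    cur <- grown
  }
  binary_mask(cur, img)
}

# one 26-neighbourhood dilation by axis shifting
.dilate26 <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift1 <- function(m, axis, by) {
    idx <- lapply(d, seq_len)
    src <- seq_len(d[axis]) - by
    keep <- src >= 1 & src <= d[axis]
    res <- array(FALSE, d)
    idx_to <- idx; idx_to[[axis]] <- which(keep)
    idx_from <- idx; idx_from[[axis]] <- src[keep]
    res[idx_to[[1]], idx_to[[2]], idx_to[[3]]] <-
      m[idx_from[[1]], idx_from[[2]], idx_from[[3]]]
    res
  }
  for (dx in -1:1) {
    mx <- if (dx == 0) mask else shift1(mask, 1, dx)
    for (dy in -1:1) {
      my <- if (dy == 0) mx else shift1(mx, 2, dy)
      for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        out <- out | (if (dz == 0) my else shift1(my, 3, dz))
      }
    }
  }
  out
}

#' Flood-fill threshold from sampled wall intensities
#'
#' The lower flood-fill threshold is taken as the arithmetic mean of the
#' image intensity at sampled vessel-wall locations (on a sharp noiseless
#' phantom this is the midpoint of the vessel and background levels).
#'
#' @param img A [volume_image()].
#' @param wall_samples Matrix `n x 3` of sample positions in mm.
#' @return Mean intensity at the nearest voxels.
#' @export
estimate_threshold <- function(img, wall_samples) {
  stopifnot(inherits(img, "volume_image"))
  wall_samples <- as.matrix(wall_samples)
  if (!nrow(wall_samples)) stop("need at least one wall sample")
  fi <- .mm_to_index(img, wall_samples)
  d <- dim(img$data)
  iv <- pmin(pmax(round(fi) + 1, 1), matrix(d, nrow(fi), 3, byrow = TRUE))
  mean(img$data[cbind(iv[, 1], iv[, 2], iv[, 3])])
}

#' Random vessel-wall sample positions of a tree
#'
#' Samples points on the lumen surface (centerline position plus local
#' radius along a random normal direction), emulating manual wall sampling
#' on an angiogram.
#'
#' @param tree A [vessel_tree()].
#' @param n Number of samples (default 100).
#' @param rng_seed Integer seed.
#' @return Matrix `n x 3` of positions, mm.
#' @export
sample_wall_positions <- function(tree, n = 100L, rng_seed = 1L) {
  set.seed(rng_seed)
  ncl <- length(tree$centerlines)
  ci <- sample.int(ncl, n, replace = TRUE)
  out <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    cl <- tree$centerlines[[ci[k]]]
    s <- runif(1, 0.05, 0.95)
    fr <- .pt_frames(cl, c(0, s))
    phi <- runif(1, 0, 2 * pi)
    out[k, ] <- eval_position(cl, s) +
      eval_radius(cl, s) * (cos(phi) * fr$e1[2, ] + sin(phi) * fr$e2[2, ])
  }
  out
}

#' Skeletonize a binary mask to voxel-chain centerlines
#'
#' Topological 3D thinning to a unit-wide curve skeleton (topology
#' preserving: only simple points are removed, so connected components are
#' conserved), followed by splitting the skeleton at junction voxels
#' (voxels with three or more 26-neighbours on the skeleton).
#'
#' @param mask A `binary_mask`.
#' @return List with `skeleton` (logical array), `chains` (list of `n x 3`
#'   1-based voxel index matrices, each a simple path), `chains_mm` (the
#'   same in mm coordinates) and `junctions` (voxel indices).
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) stop("cannot skeletonize an empty mask")
  sk <- thin_skeleton_cpp(as.logical(mask$data), dim(mask$data))
  sk <- array(sk, dim(mask$data))
  vox <- which(sk, arr.ind = TRUE)
  n <- nrow(vox)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  lut <- new.env(hash = TRUE)
  for (i in seq_len(n)) assign(key(vox[i, , drop = FALSE]), i, envir = lut)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- sweep(offs, 2, vox[i, ], "+")
    kk <- key(cand)
    hit <- vapply(kk, function(s) {
      v <- mget(s, envir = lut, ifnotfound = list(NULL))[[1]]
      if (is.null(v)) 0L else v
    }, 0L)
    nbrs[[i]] <- hit[hit > 0L]
  }
  deg <- lengths(nbrs)
  junction <- deg >= 3L
  # walk chains between endpoints/junctions over non-junction voxels
  visited <- logical(n)
  chains <- list()
  walk <- function(start, from) {
    path <- integer(0)
    cur <- start; prev <- from
    repeat {
      path <- c(path, cur)
      if (junction[cur]) break
      visited[cur] <<- TRUE
      nx <- setdiff(nbrs[[cur]], prev)
      nx <- nx[!visited[nx] | junction[nx]]
      if (!length(nx)) break
      prev <- cur
      cur <- nx[1]
    }
    path
  }
  starts <- which(deg == 1L & !junction)
  for (s0 in starts) {
    if (visited[s0]) next
    chains[[length(chains) + 1L]] <- walk(s0, integer(0))
  }
  # chains emanating from junctions
  for (j in which(junction)) {
    for (nb in nbrs[[j]]) {
      if (visited[nb] || junction[nb]) next
      chains[[length(chains) + 1L]] <- c(j, walk(nb, j))
    }
  }
  # isolated loops or leftovers
  for (i in which(!visited & !junction & deg > 0)) {
    if (visited[i]) next
    chains[[length(chains) + 1L]] <- walk(i, integer(0))
  }
  chains <- chains[lengths(chains) >= 2L]
  chain_idx <- lapply(chains, function(ch) vox[ch, , drop = FALSE])
  chain_mm <- lapply(chain_idx, function(m) {
    sweep(sweep(m - 1, 2, mask$voxel_size, "*"), 2, mask$origin, "+")
  })
  list(skeleton = sk, chains = chain_idx, chains_mm = chain_mm,
       junctions = vox[junction, , drop = FALSE])
}

#' Smooth a discrete centerline chain
#'
#' Minimizes data fidelity plus a second-difference penalty,
#' `sum ||x_k - p_k||^2 + lambda sum ||x_{k-1} - 2 x_k + x_{k+1}||^2`, with
#' both endpoints fixed, then wraps the result as a [centerline()] with
#' normalized arc length.
#'
#' @param chain_mm Matrix `n x 3` of chain node positions, mm (`n >= 3`).
#' @param lambda Smoothing weight (`>= 0`).
#' @param radii Node radii for the resulting centerline (default 1, a
#'   placeholder until radii are estimated).
#' @return A [centerline()].
#' @export
smooth_centerline <- function(chain_mm, lambda = 1, radii = 1) {
  chain_mm <- as.matrix(chain_mm)
  n <- nrow(chain_mm)
  if (n < 3) stop("chain must have at least 3 nodes")
  if (lambda < 0) stop("lambda must be non-negative")
  X <- chain_mm
  if (lambda > 0 && n > 2) {
    # second-difference operator on all nodes; endpoints clamped
    D <- matrix(0, n - 2, n)
    for (k in seq_len(n - 2)) D[k, k:(k + 2)] <- c(1, -2, 1)
    free <- 2:(n - 1)
    A <- diag(n)[free, free] + lambda * (t(D[, free]) %*% D[, free])
    for (c3 in 1:3) {
      b <- chain_mm[free, c3] -
        lambda * as.numeric(t(D[, free]) %*%
                              (D[, -free, drop = FALSE] %*% chain_mm[-free, c3]))
      X[free, c3] <- solve(A, b)
    }
  }
  centerline(X, radii)
}

#' Estimate local vessel direction and radius from a mask
#'
#' Casts `n_rays` half-lines from a node, records the first wall crossing of
#' each (quarter-voxel marching with trilinear interpolation of the mask
#' occupancy, crossing at the 0.5 level), and forms the covariance matrix of
#' the crossing points about their mean.  The eigenvector of the largest
#' eigenvalue is the local vessel direction; the radius estimate is
#' `sqrt(smallest eigenvalue) * sqrt(2)` — exact for points on an ideal
#' circular cross-section, whose covariance eigenvalues are `R^2/2`.
#' Near-zero eigenvalues from rank-deficient ray patterns (e.g. rays
#' confined to a plane) are excluded before taking the smallest.
#'
#' @param mask A `binary_mask`.
#' @param node Position, mm (must be inside the mask).
#' @param n_rays Number of rays (`>= 12`); directions from a Fibonacci
#'   sphere unless `directions` is given.
#' @param directions Optional `n x 3` matrix of ray directions.
#' @param max_dist Maximum marching distance, mm.
#' @return List with `direction` (unit 3-vector), `radius` (mm),
#'   `degenerate` (eigenvalue spread below 10%, e.g. inside a sphere),
#'   `truncated` (some ray left the volume before exiting the mask), and
#'   the crossing `points`.
#' @export
estimate_radius <- function(mask, node, n_rays = 64L, directions = NULL,
                            max_dist = 30) {
  stopifnot(inherits(mask, "binary_mask"))
  if (is.null(directions)) {
    if (n_rays < 12) stop("need at least 12 rays")
    i <- seq_len(n_rays) - 0.5
    phi <- acos(1 - 2 * i / n_rays)
    theta <- pi * (1 + sqrt(5)) * i
    directions <- cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  }
  directions <- as.matrix(directions)
  step <- min(mask$voxel_size) / 4
  occ <- function(pts) {
    # trilinear interpolation of the binary occupancy
    fi <- .mm_to_index(mask, pts)
    d <- dim(mask$data)
    i0 <- pmax(pmin(floor(fi), matrix(d - 2, nrow(fi), 3, byrow = TRUE)), 0)
    w <- fi - i0
    v <- numeric(nrow(pts))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ii <- cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)
      ii[, 1] <- pmin(pmax(ii[, 1], 1), d[1])
      ii[, 2] <- pmin(pmax(ii[, 2], 1), d[2])
      ii[, 3] <- pmin(pmax(ii[, 3], 1), d[3])
      wt <- (dx * w[, 1] + (1 - dx) * (1 - w[, 1])) *
        (dy * w[, 2] + (1 - dy) * (1 - w[, 2])) *
        (dz * w[, 3] + (1 - dz) * (1 - w[, 3]))
      v <- v + wt * mask$data[ii]
    }
    v
  }
  if (occ(matrix(node, 1, 3))[1] < 0.5) stop("node is not inside the mask")
  nr <- nrow(directions)
  pts <- matrix(NA_real_, nr, 3)
  truncated <- FALSE
  tsteps <- seq(step, max_dist, by = step)
  for (r in seq_len(nr)) {
    ray <- outer(tsteps, directions[r, ]) +
      matrix(node, length(tsteps), 3, byrow = TRUE)
    v <- occ(ray)
    k <- which(v < 0.5)[1]
    if (is.na(k)) {
      truncated <- TRUE
      next
    }
    if (k == 1) {
      frac <- 0.5
      pts[r, ] <- node + directions[r, ] * step * frac
    } else {
      # linear interpolation of the 0.5 crossing between steps k-1 and k
      f <- (v[k - 1] - 0.5) / max(v[k - 1] - v[k], 1e-12)
      tcross <- tsteps[k - 1] + f * step
      pts[r, ] <- node + directions[r, ] * tcross
    }
  }
  if (truncated) warning("truncated ray: some rays left the volume inside the mask")
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) < 3) stop("too few wall crossings for a covariance estimate")
  C <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
  e <- eigen(C, symmetric = TRUE)
  vals <- e$values
  spread <- (max(vals) - min(vals)) / max(vals, 1e-300)
  keep <- vals > 1e-6 * max(vals)
  lam_min <- min(vals[keep])
  list(direction = e$vectors[, 1], radius = sqrt(lam_min) * sqrt(2),
       degenerate = spread < 0.1, truncated = truncated, points = pts,
       eigenvalues = vals)
}

#' Recover tree geometry from a synthetic angiographic volume
#'
#' Convenience chain for the geometry round trip: threshold segmentation
#' (optionally gated by [vesselness()]), skeletonization, centerline
#' smoothing and per-node radius estimation.
#'
#' @param img A [volume_image()].
#' @param seeds Seed voxel indices for [flood_fill()] (`n x 3`).
#' @param lower Flood-fill lower threshold (e.g. from
#'   [estimate_threshold()]).
#' @param lambda Centerline smoothing weight.
#' @param n_rays Rays per radius estimate.
#' @return List with `mask`, `skeleton` (from [skeletonize()]), and
#'   `centerlines`: per chain, the smoothed [centerline()] plus per-node
#'   radius estimates.
#' @export
recover_tree <- function(img, seeds, lower, lambda = 1, n_rays = 64L) {
  mask <- flood_fill(img, seeds, lower)
  sk <- skeletonize(mask)
  cls <- lapply(sk$chains_mm, function(ch) {
    if (nrow(ch) < 3) return(NULL)
    cl <- smooth_centerline(ch, lambda = lambda)
    ns <- nrow(cl$nodes)
    pick <- unique(round(seq(2, ns - 1, length.out = min(8, ns - 2))))
    radii <- rep(NA_real_, ns)
    for (k in pick) {
      est <- tryCatch(
        suppressWarnings(estimate_radius(mask, cl$nodes[k, ], n_rays = n_rays)),
        error = function(e) NULL)
      if (!is.null(est)) radii[k] <- est$radius
    }
    list(centerline = cl, radii = radii)
  })
  list(mask = mask, skeleton = sk, centerlines = Filter(Negate(is.null), cls))
}
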