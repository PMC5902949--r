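#' Triangle mesh of a swept vessel surface
#'
#' Sweeps a circular disk along every centerline of a tree: cross-section
#' rings are placed orthogonal to the local centerline tangent (the disk
#' normal equals the normalized position-spline derivative), with radius from
#' [eval_radius()], and consecutive rings are stitched with triangles.  Ring
#' orientation uses parallel-transport frames, so the tube exhibits no
#' torsion flips.  Both tube ends are capped, making the swept surface of a
#' single vessel watertight (every edge shared by exactly two faces).
#'
#' @param tree A [vessel_tree()] (or a single [centerline()]).
#' @param angular_segments Vertices per ring (`>= 8`).
#' @param axial_step Target ring spacing along the centerline (mm).
#' @return An object of class `triangle_mesh`: list with `vertices`
#'   (`n x 3`, mm) and `faces` (`m x 3`, 1-based vertex indices).
#' @export
sweep_surface <- function(tree, angular_segments = 32L, axial_step = 0.5) {
  if (inherits(tree, "centerline")) {
    tree <- vessel_tree(list(tree), NA_integer_)
  }
  stopifnot(inherits(tree, "vessel_tree"), angular_segments >= 8)
  na <- as.integer(angular_segments)
  verts <- list()
  faces <- list()
  nv <- 0L
  for (cl in tree$centerlines) {
    if (min(cl$radii) < axial_step / 10) {
      warning(sprintf("degenerate geometry: radius %.3g mm below axial_step/10",
                      min(cl$radii)))
    }
    nr <- max(2L, ceiling(cl$length / axial_step) + 1L)
    s <- seq(0, 1, length.out = nr)
    P <- eval_position(cl, s)
    r <- eval_radius(cl, s)
    fr <- .pt_frames(cl, s)
    th <- 2 * pi * (seq_len(na) - 1) / na
    ring <- function(i) {
      P[rep(i, na), ] + r[i] * (outer(cos(th), fr$e1[i, ]) +
                                  outer(sin(th), fr$e2[i, ]))
    }
    V <- do.call(rbind, lapply(seq_len(nr), ring))
    V <- rbind(V, P[1, ], P[nr, ])          # cap centers
    i_c0 <- nr * na + 1L
    i_c1 <- nr * na + 2L
    F <- vector("list", nr - 1L)
    for (i in seq_len(nr - 1L)) {
      a <- (i - 1L) * na + seq_len(na)
      b <- i * na + seq_len(na)
      a2 <- a[c(2:na, 1L)]
      b2 <- b[c(2:na, 1L)]
      F[[i]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
    }
    j <- seq_len(na)
    j2 <- j[c(2:na, 1L)]
    cap0 <- cbind(j2, j, i_c0)              # inlet cap, outward orientation
    last <- (nr - 1L) * na + seq_len(na)
    cap1 <- cbind(last, last[c(2:na, 1L)], i_c1)
    F <- do.call(rbind, c(F, list(cap0, cap1)))
    verts[[length(verts) + 1L]] <- V
    faces[[length(faces) + 1L]] <- F + nv
    nv <- nv + nrow(V)
  }
  structure(list(vertices = do.call(rbind, verts),
                 faces = do.call(rbind, faces)),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# edge multiplicity table; a closed manifold has every edge in exactly 2 faces
.mesh_edge_counts <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Export a triangle mesh as binary STL
#'
#' @param mesh A `triangle_mesh`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(formatC("pcasim swept vessel surface", width = -80))
  writeBin(header[1:80], con)
  nf <- nrow(mesh$faces)
  writeBin(as.integer(nf), con, size = 4, endian = "little")
  V <- mesh$vertices
  for (i in seq_len(nf)) {
    tri <- V[mesh$faces[i, ], , drop = FALSE]
    n <- .cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
    ln <- sqrt(sum(n^2))
    if (ln > 0) n <- n / ln
    writeBin(as.numeric(c(n, t(tri))), con, size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Export a triangle mesh or streamlines as legacy VTK polydata (ASCII)
#'
#' @param x A `triangle_mesh` or a `streamline_set`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_vtk_polydata <- function(x, path) {
  if (inherits(x, "triangle_mesh")) {
    V <- x$vertices
    F <- x$faces
    lines <- c("# vtk DataFile Version 3.0", "pcasim polydata", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(V)),
               apply(V, 1, function(p) paste(format(p, digits = 12), collapse = " ")),
               sprintf("POLYGONS %d %d", nrow(F), 4L * nrow(F)),
               apply(F - 1L, 1, function(f) paste(c(3L, f), collapse = " ")))
    writeLines(lines, path)
  } else if (inherits(x, "streamline_set")) {
    pts <- do.call(rbind, lapply(x$streamlines, `[[`, "points"))
    ns <- vapply(x$streamlines, function(s) nrow(s$points), 0L)
    off <- cumsum(c(0L, ns[-length(ns)]))
    conn <- mapply(function(n, o) paste(c(n, seq_len(n) - 1L + o), collapse = " "),
                   ns, off)
    spd <- unlist(lapply(x$streamlines, `[[`, "speed"))
    lines <- c("# vtk DataFile Version 3.0", "pcasim streamlines", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(pts)),
               apply(pts, 1, function(p) paste(format(p, digits = 12), collapse = " ")),
               sprintf("LINES %d %d", length(ns), sum(ns + 1L)),
               conn,
               sprintf("POINT_DATA %d", nrow(pts)),
               "SCALARS speed_cm_s double 1", "LOOKUP_TABLE default",
               format(spd, digits = 9))
    writeLines(lines, path)
  } else {
    stop("unsupported object for VTK export")
  }
  invisible(path)
}
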