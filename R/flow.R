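#' Solve laminar flow on a vascular tree
#'
#' Computes the steady laminar flow distribution of an incompressible
#' Newtonian fluid through the tree, modelled as a network of Poiseuille
#' resistors: every segment has hydraulic resistance
#' `R = integral 8 mu / (pi r(l)^4) dl` along its radius spline, flows are
#' conserved at junctions, and all outlets share a common pressure.  The flow
#' is driven either by a prescribed mean inlet velocity (`Q = v_mean * pi *
#' r_inlet^2`) or by the pressure difference between inlet and outlets.
#'
#' @param tree A [vessel_tree()].
#' @param inlet_condition Exactly one of `list(mean_velocity = v)` (cm/s) or
#'   `list(pressure_drop = dp)` (Pa).
#' @param viscosity Dynamic viscosity in Pa s (default 3.5e-3).
#' @param n_quad Quadrature samples per sub-segment resistance integral.
#' @return An object of class `flow_solution`; see Details.
#' @details The returned object carries, per centerline, the breakpoints
#'   introduced by child attachments, the flow (ml/s) and Poiseuille pressure
#'   drop (Pa) on each sub-interval, and cached dense polylines used by
#'   [velocity_at()] and [trace_streamlines()].  `segment_flow(sol)` returns
#'   the inlet flow of every centerline.
#' @export
solve_flow <- function(tree, inlet_condition, viscosity = 3.5e-3, n_quad = 64L) {
  stopifnot(inherits(tree, "vessel_tree"))
  has_v <- !is.null(inlet_condition$mean_velocity)
  has_p <- !is.null(inlet_condition$pressure_drop)
  if (has_v == has_p) {
    stop("inlet_condition must contain exactly one of mean_velocity, pressure_drop")
  }
  ncl <- length(tree$centerlines)

  # breakpoints: child attachment positions split each centerline into
  # series sub-resistors
  breaks <- vector("list", ncl)
  child_at <- vector("list", ncl)    # per break index, child centerline ids
  for (i in seq_len(ncl)) {
    kids <- .tree_children(tree, i)
    sb <- sort(unique(c(0, tree$s_attach[kids], 1)))
    breaks[[i]] <- sb
    child_at[[i]] <- lapply(sb, function(s0) {
      kids[abs(tree$s_attach[kids] - s0) < 1e-12]
    })
  }

  sub_res <- function(i, sa, sb) {
    cl <- tree$centerlines[[i]]
    s <- seq(sa, sb, length.out = n_quad)
    r_m <- eval_radius(cl, s) * 1e-3
    if (any(r_m <= 0)) stop("singular resistance: zero-radius segment")
    d <- cbind(cl$fx(s, deriv = 1), cl$fy(s, deriv = 1), cl$fz(s, deriv = 1))
    dl_m <- sqrt(rowSums(d^2)) * 1e-3
    f <- 8 * viscosity / (pi * r_m^4) * dl_m
    sum((f[-1] + f[-n_quad]) / 2 * diff(s))
  }
  Rsub <- lapply(seq_len(ncl), function(i) {
    sb <- breaks[[i]]
    if (length(sb) < 2) return(numeric(0))
    vapply(seq_len(length(sb) - 1L),
           function(k) sub_res(i, sb[k], sb[k + 1]), 0)
  })

  # equivalent downstream resistance from node (i, k) (k indexes breaks[[i]])
  memo <- new.env()
  req <- function(i, k) {
    key <- paste(i, k)
    if (!is.null(memo[[key]])) return(memo[[key]])
    branches <- list()
    if (k < length(breaks[[i]])) {
      branches[[length(branches) + 1L]] <-
        list(type = "sub", i = i, k = k, R = Rsub[[i]][k] + req(i, k + 1L))
    }
    for (j in child_at[[i]][[k]]) {
      branches[[length(branches) + 1L]] <-
        list(type = "child", j = j, R = Rsub[[j]][1] + req(j, 2L))
    }
    val <- if (!length(branches)) 0 else {
      1 / sum(vapply(branches, function(b) 1 / b$R, 0))
    }
    memo[[key]] <- val
    attr(memo[[key]], "branches") <- branches
    val
  }

  root <- tree$inlet
  R_total <- Rsub[[root]][1] + req(root, 2L)
  r_in_m <- tree$centerlines[[root]]$radii[1] * 1e-3
  if (has_v) {
    v_ms <- inlet_condition$mean_velocity * 1e-2
    Q_root_si <- v_ms * pi * r_in_m^2          # m^3/s
  } else {
    Q_root_si <- inlet_condition$pressure_drop / R_total
  }

  # distribute flows top-down
  Qint <- lapply(breaks, function(sb) numeric(max(length(sb) - 1L, 0)))
  assign_flow <- function(i, k, Q) {
    branches <- attr(memo[[paste(i, k)]], "branches")
    if (!length(branches)) return(invisible())
    Rb <- vapply(branches, `[[`, 0, "R")
    Qb <- Q * (1 / Rb) / sum(1 / Rb)
    for (b in seq_along(branches)) {
      br <- branches[[b]]
      if (br$type == "sub") {
        Qint[[i]][br$k] <<- Qb[b]
        assign_flow(i, br$k + 1L, Qb[b])
      } else {
        Qint[[br$j]][1] <<- Qb[b]
        assign_flow(br$j, 2L, Qb[b])
      }
    }
    invisible()
  }
  req(root, 2L)
  Qint[[root]][1] <- Q_root_si
  assign_flow(root, 2L, Q_root_si)

  dp <- lapply(seq_len(ncl), function(i) Qint[[i]] * Rsub[[i]])

  # dense polylines with per-sample flow, for field evaluation and tracing
  pl <- .tree_polylines(tree, step = 0.2)
  for (i in seq_len(ncl)) {
    iv <- findInterval(pl[[i]]$s, breaks[[i]], rightmost.closed = TRUE,
                       all.inside = TRUE)
    pl[[i]]$Q_mm3_s <- Qint[[i]][iv] * 1e9     # m^3/s -> mm^3/s
  }

  structure(list(tree = tree,
                 breaks = breaks,
                 flow_ml_s = lapply(Qint, function(q) q * 1e6),
                 pressure_drop = dp,
                 Q_inlet_ml_s = Q_root_si * 1e6,
                 R_total = R_total,
                 total_pressure_drop = Q_root_si * R_total,
                 inlet_condition = inlet_condition,
                 viscosity = viscosity,
                 polylines = pl),
            class = "flow_solution")
}

#' Per-centerline inlet flows of a flow solution
#'
#' @param solution A [solve_flow()] result.
#' @return Numeric vector, ml/s, one entry per centerline.
#' @export
segment_flow <- function(solution) {
  stopifnot(inherits(solution, "flow_solution"))
  vapply(solution$flow_ml_s, function(q) q[1], 0)
}

#' Evaluate the laminar velocity field at arbitrary points
#'
#' Velocity direction is the local centerline tangent; magnitude follows the
#' fully developed Poiseuille parabola `2 v_mean (1 - (rho/R)^2)` where `rho`
#' is the distance to the centerline and `v_mean = Q / (pi R^2)` the local
#' mean velocity.  Points outside every lumen get a zero vector and an
#' `inside = FALSE` flag.
#'
#' @param solution A [solve_flow()] result.
#' @param points Numeric matrix `n x 3` (mm).
#' @return Matrix `n x 3` of velocities (cm/s) with attributes `inside`
#'   (logical) and `speed` (cm/s magnitudes).
#' @export
velocity_field <- function(solution, points) {
  stopifnot(inherits(solution, "flow_solution"))
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be n x 3")
  n <- nrow(points)
  vel <- matrix(0, n, 3)
  inside <- logical(n)
  best <- rep(Inf, n)                 # best rho/R ratio so far
  chunk <- 2000L
  tr <- solution$tree
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    X <- points[idx, , drop = FALSE]
    for (i in seq_along(solution$polylines)) {
      p <- solution$polylines[[i]]
      lo <- apply(p$P, 2, min) - max(p$r)
      hi <- apply(p$P, 2, max) + max(p$r)
      cand <- which(X[, 1] >= lo[1] & X[, 1] <= hi[1] &
                      X[, 2] >= lo[2] & X[, 2] <= hi[2] &
                      X[, 3] >= lo[3] & X[, 3] <= hi[3])
      if (!length(cand)) next
      res <- .nearest_on_polyline(p, X[cand, , drop = FALSE])
      ratio2 <- res$d2 / res$r^2
      gidx <- idx[cand]
      upd <- which(ratio2 <= 1 + 1e-9 & !res$beyond & ratio2 < best[gidx])
      if (!length(upd)) next
      g <- gidx[upd]
      su <- res$s[upd]
      tg <- eval_tangent(tr$centerlines[[i]], su)
      Rloc <- res$r[upd]
      Qloc <- p$Q_mm3_s[res$seg[upd]]
      vbar <- Qloc / (pi * Rloc^2)            # mm/s
      speed <- 2 * vbar * (1 - ratio2[upd])
      vel[g, ] <- tg * speed / 10             # cm/s
      inside[g] <- TRUE
      best[g] <- ratio2[upd]
    }
  }
  attr(vel, "inside") <- inside
  attr(vel, "speed") <- sqrt(rowSums(vel^2))
  vel
}

#' @rdname velocity_field
#' @param point A single 3-vector (mm).
#' @return `velocity_at` returns a 3-vector (cm/s) with attribute `inside`.
#' @export
velocity_at <- function(solution, point) {
  v <- velocity_field(solution, matrix(point, 1, 3))
  out <- as.numeric(v[1, ])
  attr(out, "inside") <- attr(v, "inside")[1]
  out
}

#' @export
print.flow_solution <- function(x, ...) {
  cat(sprintf("<flow_solution> Q_inlet = %.3f ml/s, total dP = %.2f Pa, %d segments\n",
              x$Q_inlet_ml_s, x$total_pressure_drop, length(x$flow_ml_s)))
  invisible(x)
}

#' Tabular flow report
#'
#' @param solution A [solve_flow()] result.
#' @return A data frame with one row per centerline: flow `Q` (ml/s),
#'   pressure drop `dP` (Pa), mean and peak velocities (cm/s) at the segment
#'   inlet.
#' @export
flow_report <- function(solution) {
  stopifnot(inherits(solution, "flow_solution"))
  tr <- solution$tree
  q <- segment_flow(solution)
  r0 <- vapply(tr$centerlines, function(cl) cl$radii[1], 0)
  vbar <- .ml_s_to_mm3_s(q) / (pi * r0^2) / 10
  data.frame(segment = seq_along(q), Q_ml_s = q,
             dP_Pa = vapply(solution$pressure_drop, sum, 0),
             v_mean_cm_s = vbar, v_peak_cm_s = 2 * vbar)
}
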