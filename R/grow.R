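#' Configuration for synthetic vascular tree growth
#'
#' Describes the perfusion territory and the physiological demand used by
#' [grow_tree()].  Growth is constrained by matter preservation (flows add at
#' bifurcations), Poiseuille's law (pressure drop `8 mu L Q / (pi r^4)` per
#' segment) and the bifurcation law `r_p^gamma = r_1^gamma + r_2^gamma`;
#' bifurcation points minimize the total volume of their three adjoining
#' segments.
#'
#' @param perfusion_region Either `list(type = "box", lower, upper)` or
#'   `list(type = "ellipsoid", center, semiaxes)`, all in mm.
#' @param n_terminals Number of tree outlets (`>= 1`).
#' @param terminal_flows Flow demand per outlet in ml/s (recycled to
#'   `n_terminals`); all positive.
#' @param viscosity Blood dynamic viscosity in Pa s (default 3.5e-3).
#' @param bifurcation_exponent Exponent `gamma` of the bifurcation law
#'   (default 3, Murray's law).
#' @param inlet_position 3-vector, mm.
#' @param target_inlet_radius Optional inlet radius (mm).  When `NULL`, the
#'   root radius is set from Poiseuille's law so the root segment dissipates
#'   `pressure_drop` at its flow.
#' @param pressure_drop Pressure budget (Pa) used only when
#'   `target_inlet_radius` is `NULL` (default 80 Pa).
#' @param rng_seed Integer seed controlling terminal sampling.
#' @param min_separation Minimum allowed distance between terminals (mm);
#'   default 2% of the region diagonal.
#' @return An object of class `growth_config`.
#' @export
growth_config <- function(perfusion_region, n_terminals, terminal_flows,
                          viscosity = 3.5e-3, bifurcation_exponent = 3,
                          inlet_position = c(0, 0, 0),
                          target_inlet_radius = NULL, pressure_drop = 80,
                          rng_seed = 1L, min_separation = NULL) {
  stopifnot(n_terminals >= 1, all(terminal_flows > 0), bifurcation_exponent > 0,
            viscosity > 0, length(inlet_position) == 3)
  type <- perfusion_region$type
  if (is.null(type) || !type %in% c("box", "ellipsoid")) {
    stop("perfusion_region$type must be 'box' or 'ellipsoid'")
  }
  structure(list(perfusion_region = perfusion_region,
                 n_terminals = as.integer(n_terminals),
                 terminal_flows = rep_len(terminal_flows, n_terminals),
                 viscosity = viscosity,
                 bifurcation_exponent = bifurcation_exponent,
                 inlet_position = as.numeric(inlet_position),
                 target_inlet_radius = target_inlet_radius,
                 pressure_drop = pressure_drop,
                 rng_seed = as.integer(rng_seed),
                 min_separation = min_separation),
            class = "growth_config")
}

.region_diag <- function(region) {
  if (region$type == "box") sqrt(sum((region$upper - region$lower)^2))
  else 2 * sqrt(sum(region$semiaxes^2))
}

.sample_region <- function(region, n) {
  if (region$type == "box") {
    lo <- region$lower; hi <- region$upper
    cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]), runif(n, lo[3], hi[3]))
  } else {
    out <- matrix(0, 0, 3)
    while (nrow(out) < n) {
      u <- matrix(runif(3 * n, -1, 1), ncol = 3)
      u <- u[rowSums(u^2) <= 1, , drop = FALSE]
      if (nrow(u)) {
        p <- sweep(sweep(u, 2, region$semiaxes, "*"), 2, region$center, "+")
        out <- rbind(out, p)
      }
    }
    out[seq_len(n), , drop = FALSE]
  }
}

#' Grow a synthetic vascular tree
#'
#' Staged constrained-constructive growth: terminal sites are sampled inside
#' the perfusion region (seeded RNG) and added sequentially; each new
#' terminal connects to the nearest existing segment, creating a bifurcation
#' whose position is then optimized to minimize the total volume
#' `pi * sum r_k^2 L_k` of the three adjoining segments.  Segment radii obey
#' `r_seg = r_root * (Q / Q_root)^(1/gamma)`, which satisfies the bifurcation law
#' exactly because flows add at junctions.  After every insertion, all
#' bifurcation positions are relaxed by coordinate-descent sweeps until each
#' is a local minimizer of its own bifurcation volume.
#'
#' @param config A [growth_config()].
#' @return A [vessel_tree()] with exactly `n_terminals` outlet segments.
#'   Per-segment flows (ml/s) and pressure drops (Pa) implied by the growth
#'   demand are stored in `attr(tree, "growth")`.
#' @export
grow_tree <- function(config) {
  stopifnot(inherits(config, "growth_config"))
  set.seed(config$rng_seed)
  nT <- config$n_terminals
  region <- config$perfusion_region
  term <- .sample_region(region, nT)
  minsep <- config$min_separation
  if (is.null(minsep)) minsep <- 0.02 * .region_diag(region)
  if (nT > 1) {
    dmin <- min(dist(term))
    if (dmin < minsep) {
      stop(sprintf("infeasible geometry: coincident terminals (min distance %.3g mm < %.3g mm)",
                   dmin, minsep))
    }
  }
  if (any(!is.finite(term))) stop("infeasible geometry: terminal outside region")

  gamma <- config$bifurcation_exponent
  w_exp <- 2 / gamma

  # node/edge representation during growth: node 1 = inlet; edges are straight
  nodes <- rbind(config$inlet_position, term[1, ])
  edges <- matrix(c(1L, 2L), ncol = 2)  # from, to
  term_node <- 2L                        # node index per inserted terminal
  term_flow <- config$terminal_flows[1] # ml/s per terminal node (aligned with term_node)

  edge_flows <- function() {
    # flow through each edge = sum of terminal demand downstream
    nn <- nrow(nodes)
    children <- split(seq_len(nrow(edges)), edges[, 1])
    q_node <- numeric(nn)
    q_node[term_node] <- term_flow
    q_edge <- numeric(nrow(edges))
    rec <- function(e) {
      to <- edges[e, 2]
      kids <- children[[as.character(to)]]
      q <- q_node[to]
      if (!is.null(kids)) for (k in kids) q <- q + rec(k)
      q_edge[e] <<- q
      q
    }
    roots <- which(edges[, 1] == 1L)
    for (e in roots) rec(e)
    q_edge
  }

  bif_volume <- function(x, P, w) sum(w * sqrt(colSums((t(P) - x)^2)))

  # weighted geometric median (Weiszfeld iteration): the minimizer of
  # sum w_k |x - P_k|, i.e. of the total bifurcation volume at fixed radii
  optimize_bif <- function(x0, P, w, iters = 2000, tol = 1e-11) {
    x <- x0
    for (it in seq_len(iters)) {
      d <- sqrt(rowSums(sweep(P, 2, x, "-")^2))
      if (any(d < 1e-9)) {          # sits on an anchor: polish with optim
        res <- optim(x, bif_volume, P = P, w = w, method = "Nelder-Mead",
                     control = list(reltol = 1e-12, maxit = 1000))
        x <- res$par
        break
      }
      wk <- w / d
      xn <- colSums(P * wk) / sum(wk)
      if (sqrt(sum((xn - x)^2)) < tol) { x <- xn; break }
      x <- xn
    }
    # keep the bifurcation strictly off its anchor nodes
    for (k in seq_len(nrow(P))) {
      if (sqrt(sum((x - P[k, ])^2)) < 1e-6) {
        x <- x + 1e-3 * .normalize(colMeans(P) - P[k, ] + 1e-9)
      }
    }
    x
  }

  relax_bifurcations <- function(max_sweeps = 60, tol = 1e-7, iters = 8) {
    qe <- edge_flows()
    w <- qe^w_exp
    deg_out <- tabulate(edges[, 1], nbins = nrow(nodes))
    deg_in <- tabulate(edges[, 2], nbins = nrow(nodes))
    bifs <- which(deg_in == 1L & deg_out == 2L)
    for (sweep in seq_len(max_sweeps)) {
      moved <- 0
      for (v in bifs) {
        ein <- which(edges[, 2] == v)
        eout <- which(edges[, 1] == v)
        anchors <- rbind(nodes[edges[ein, 1], ], nodes[edges[eout[1], 2], ],
                         nodes[edges[eout[2], 2], ])
        wts <- c(w[ein], w[eout[1]], w[eout[2]])
        xn <- optimize_bif(nodes[v, ], anchors, wts, iters = iters, tol = tol / 10)
        moved <- max(moved, sqrt(sum((xn - nodes[v, ])^2)))
        nodes[v, ] <<- xn
      }
      if (moved < tol) break
    }
  }

  for (k in seq_len(nT)[-1]) {
    tpos <- term[k, ]
    # nearest existing segment
    A <- nodes[edges[, 1], , drop = FALSE]
    B <- nodes[edges[, 2], , drop = FALSE]
    D <- B - A
    L2 <- pmax(rowSums(D^2), 1e-300)
    tt <- pmin(pmax(rowSums(sweep(-A, 2, tpos, "+") * D) / L2, 0.1), 0.9)
    prox <- A + D * tt
    d2 <- rowSums(sweep(prox, 2, tpos, "-")^2)
    e <- which.min(d2)
    # split edge e at the projection; connect terminal to the new node
    xnew <- prox[e, ]
    nodes <- rbind(nodes, xnew, tpos)
    vb <- nrow(nodes) - 1L  # bifurcation node
    vt <- nrow(nodes)       # terminal node
    to_old <- edges[e, 2]
    edges[e, 2] <- vb
    edges <- rbind(edges, c(vb, to_old), c(vb, vt))
    term_node <- c(term_node, vt)
    term_flow <- c(term_flow, config$terminal_flows[k])
    relax_bifurcations(max_sweeps = 20, tol = 1e-5)
  }
  relax_bifurcations(max_sweeps = 300, tol = 1e-8, iters = 50)

  qe <- edge_flows()
  q_root <- sum(term_flow)
  # root radius: prescribed, or Poiseuille on the root segment at the budget
  root_edge <- which(edges[, 1] == 1L)[1]
  L_root_m <- sqrt(sum((nodes[edges[root_edge, 2], ] - nodes[1, ])^2)) * 1e-3
  r_root <- config$target_inlet_radius
  if (is.null(r_root)) {
    q_si <- q_root * 1e-6            # ml/s -> m^3/s
    r_root <- (8 * config$viscosity * L_root_m * q_si /
                 (pi * config$pressure_drop))^(1 / 4) * 1e3
  }
  radii <- r_root * (qe / q_root)^(1 / gamma)

  # one centerline per edge, ordered root-first (parents precede children)
  ord <- integer(0)
  queue <- which(edges[, 1] == 1L)
  while (length(queue)) {
    e <- queue[1]; queue <- queue[-1]
    ord <- c(ord, e)
    queue <- c(queue, which(edges[, 1] == edges[e, 2]))
  }
  idx_of <- match(seq_len(nrow(edges)), ord)
  cls <- vector("list", length(ord))
  parent <- rep(NA_integer_, length(ord))
  for (j in seq_along(ord)) {
    e <- ord[j]
    cls[[j]] <- centerline(rbind(nodes[edges[e, 1], ], nodes[edges[e, 2], ]),
                           radii[e])
    up <- which(edges[, 2] == edges[e, 1])
    if (length(up)) parent[j] <- idx_of[up]
  }
  tree <- vessel_tree(cls, parent)
  # per-segment growth bookkeeping (Poiseuille pressure drops at demand flows)
  L_m <- vapply(seq_along(ord), function(j) cls[[j]]$length, 0) * 1e-3
  q_si <- qe[ord] * 1e-6
  dp <- 8 * config$viscosity * L_m * q_si / (pi * (radii[ord] * 1e-3)^4)
  attr(tree, "growth") <- list(flow = qe[ord], pressure_drop = dp,
                               config = config)
  tree
}

#' Growth configuration emulating a 14-outlet renal arterial tree
#'
#' A convenience [growth_config()] for a kidney-type synthetic tree: a single
#' feeding artery entering at the origin along +z, 14 outlets with equal flow
#' demand inside a box-shaped perfusion territory, and a 2.5 mm inlet radius,
#' giving vessel diameters ranging from about 1.5 mm at the smallest outlet
#' to 5 mm at the inlet.
#'
#' @param rng_seed Integer seed for terminal sampling.
#' @param n_terminals Outlet count (default 14).
#' @param inlet_radius Target inlet radius in mm (default 2.5).
#' @return A [growth_config()].
#' @export
calix_config <- function(rng_seed = 1L, n_terminals = 14L, inlet_radius = 2.5) {
  growth_config(
    perfusion_region = list(type = "box",
                            lower = c(-10, -10, 34), upper = c(10, 10, 66)),
    n_terminals = n_terminals,
    terminal_flows = 0.5,
    inlet_position = c(0, 0, 0),
    target_inlet_radius = inlet_radius,
    rng_seed = rng_seed)
}

#' Remodel straight tree segments into smoothly curved vessels
#'
#' Replaces each straight segment by a spline perturbed with low-order sine
#' modes in the two directions orthogonal to the chord, imitating the curved
#' shapes of real vessels.  Endpoints, endpoint radii and connectivity are
#' preserved exactly; the perturbation amplitude of each mode is bounded by
#' `amplitude`, so the curve deviates from the chord by at most twice the
#' requested amplitude.
#'
#' @param tree A [vessel_tree()] whose children attach at parent endpoints
#'   (`s_attach = 1`), as produced by [grow_tree()].
#' @param amplitude Maximum per-mode perturbation in mm (`>= 0`).
#' @param rng_seed Integer seed.
#' @param exclude Integer indices of centerlines left untouched (e.g. the
#'   feeding artery).
#' @param n_interior Number of interior nodes inserted per segment.
#' @return A [vessel_tree()] with the same connectivity.
#' @export
remodel_curved <- function(tree, amplitude, rng_seed = 1L, exclude = integer(0),
                           n_interior = 5L) {
  stopifnot(inherits(tree, "vessel_tree"), amplitude >= 0)
  if (any(tree$s_attach[!is.na(tree$parent)] < 1 - 1e-9)) {
    stop("remodel_curved requires end-attached children (s_attach = 1)")
  }
  if (amplitude == 0) return(tree)
  set.seed(rng_seed)
  cls <- tree$centerlines
  for (i in seq_along(cls)) {
    if (i %in% exclude) next
    cl <- cls[[i]]
    p0 <- cl$nodes[1, ]
    p1 <- cl$nodes[nrow(cl$nodes), ]
    chord <- p1 - p0
    tvec <- .normalize(chord)
    ref <- if (abs(tvec[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- .normalize(.cross3(tvec, ref))
    e2 <- .cross3(tvec, e1)
    s <- seq(0, 1, length.out = n_interior + 2L)
    a <- runif(4, -1, 1) * amplitude / 2
    d <- outer(sin(pi * s), a[1] * e1 + a[2] * e2) +
      outer(sin(2 * pi * s), a[3] * e1 + a[4] * e2)
    pos <- outer(1 - s, p0) + outer(s, p1) + d
    r0 <- eval_radius(cl, s)
    pos[1, ] <- p0
    pos[length(s), ] <- p1
    cls[[i]] <- centerline(pos, r0)
  }
  out <- vessel_tree(cls, tree$parent, tree$s_attach)
  attr(out, "growth") <- attr(tree, "growth")
  out
}
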