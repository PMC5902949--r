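#' Trace flow streamlines through a solved tree
#'
#' Streamline seeds are distributed over the inlet disk proportionally to the
#' local Poiseuille flux (every streamline carries the same flux), then each
#' path is marched along the centerline at arc steps `min(step_max, R/5)`
#' while keeping its relative radial position `rho/R` and azimuth fixed in
#' the parallel-transport frame of the vessel; at a bifurcation the path
#' follows a child chosen with probability proportional to the flow split
#' (seeded RNG), entering at the same relative radial position.  Point speed
#' is the local Poiseuille value `2 v_mean(s) (1 - (rho/R)^2)`.
#'
#' @param solution A [solve_flow()] result on an end-attached tree
#'   (`s_attach = 1` everywhere, as grown by [grow_tree()]).
#' @param n_streamlines Number of streamlines (`>= 1`).
#' @param rng_seed Integer seed (radial seeding and branch choices).
#' @param step_max Maximum arc step in mm (default 0.1).
#' @return An object of class `streamline_set`: list of streamlines, each
#'   with `points` (mm), `speed` (cm/s), `time` (s, cumulative transit time),
#'   `total_time` (s) and a `terminal` flag; plus the per-streamline flux
#'   `q_mm3_s` and the inlet flow.
#' @export
trace_streamlines <- function(solution, n_streamlines, rng_seed = 1L,
                              step_max = 0.1) {
  stopifnot(inherits(solution, "flow_solution"), n_streamlines >= 1)
  tr <- solution$tree
  if (any(tr$s_attach[!is.na(tr$parent)] < 1 - 1e-9)) {
    stop("trace_streamlines requires end-attached children (s_attach = 1)")
  }
  set.seed(rng_seed)
  # flux-proportional radial seeding on the inlet disk:
  # cumulative flux fraction through rho is (rho/R)^2 (2 - (rho/R)^2)
  u <- runif(n_streamlines)
  f_seed <- sqrt(1 - sqrt(1 - u))
  phi_seed <- runif(n_streamlines, 0, 2 * pi)

  kids_of <- lapply(seq_along(tr$centerlines), function(i) .tree_children(tr, i))
  qseg <- segment_flow(solution)                 # ml/s per centerline

  march_one <- function(f, phi) {
    pts <- list(); spd <- list()
    i <- tr$inlet
    e1_prev <- NULL
    truncated <- FALSE
    repeat {
      cl <- tr$centerlines[[i]]
      rmin <- min(cl$radii)
      step <- max(min(step_max, rmin / 5), 1e-4)
      m <- max(4L, ceiling(cl$length / step) + 1L)
      s <- seq(0, 1, length.out = m)
      fr <- .pt_frames(cl, s, e1_init = e1_prev)
      R <- eval_radius(cl, s)
      C <- eval_position(cl, s)
      pl <- solution$polylines[[i]]
      Q <- pl$Q_mm3_s[pmin(findInterval(s, pl$s, all.inside = TRUE),
                           length(pl$Q_mm3_s))]
      vbar <- Q / (pi * R^2)                     # mm/s
      off <- f * R
      P <- C + off * (cos(phi) * fr$e1 + sin(phi) * fr$e2)
      v <- 2 * vbar * (1 - f^2) / 10             # cm/s
      pts[[length(pts) + 1L]] <- P
      spd[[length(spd) + 1L]] <- v
      e1_prev <- fr$e1[m, ]
      kids <- kids_of[[i]]
      if (!length(kids)) break
      pk <- qseg[kids] / sum(qseg[kids])
      i <- kids[sample.int(length(kids), 1L, prob = pk)]
    }
    P <- do.call(rbind, pts)
    v <- unlist(spd)
    # drop duplicated junction points
    keep <- c(TRUE, rowSums((P[-1, , drop = FALSE] -
                               P[-nrow(P), , drop = FALSE])^2) > 1e-16)
    P <- P[keep, , drop = FALSE]
    v <- v[keep]
    dl <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
    vmid <- (v[-1] + v[-length(v)]) / 2 * 10     # mm/s
    tt <- c(0, cumsum(dl / vmid))
    list(points = P, speed = v, time = tt, total_time = tt[length(tt)],
         terminal = TRUE, truncated = truncated)
  }

  sls <- lapply(seq_len(n_streamlines), function(k) march_one(f_seed[k], phi_seed[k]))
  Q_in_mm3 <- .ml_s_to_mm3_s(solution$Q_inlet_ml_s)
  structure(list(streamlines = sls,
                 q_mm3_s = Q_in_mm3 / n_streamlines,
                 Q_inlet_ml_s = solution$Q_inlet_ml_s,
                 f = f_seed, phi = phi_seed,
                 rng_seed = rng_seed),
            class = "streamline_set")
}

#' Rescale the speeds of a streamline set
#'
#' Streamline geometry is flow-invariant in a rigid laminar network; scaling
#' the driving pressure by `factor` scales every speed by `factor` and every
#' transit time by `1/factor`.  Used to sweep inlet-velocity levels without
#' re-tracing.
#'
#' @param sl_set A [trace_streamlines()] result.
#' @param factor Positive scale factor applied to all speeds.
#' @return A `streamline_set`.
#' @export
scale_streamlines <- function(sl_set, factor) {
  stopifnot(inherits(sl_set, "streamline_set"), factor > 0)
  sl_set$streamlines <- lapply(sl_set$streamlines, function(s) {
    s$speed <- s$speed * factor
    s$time <- s$time / factor
    s$total_time <- s$total_time / factor
    s
  })
  sl_set$q_mm3_s <- sl_set$q_mm3_s * factor
  sl_set$Q_inlet_ml_s <- sl_set$Q_inlet_ml_s * factor
  sl_set
}

#' @export
print.streamline_set <- function(x, ...) {
  np <- sum(vapply(x$streamlines, function(s) nrow(s$points), 0L))
  cat(sprintf("<streamline_set> %d streamlines, %d points, q = %.4g mm^3/s each\n",
              length(x$streamlines), np, x$q_mm3_s))
  invisible(x)
}
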