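#' Seed spin isochromat particles on streamlines
#'
#' Populates every streamline along its entire length with particles whose
#' spacing is proportional to the local speed (constant transit-time spacing
#' `dtau = 1 / (density * q)`, with `q` the per-streamline flux).  Because
#' every streamline carries equal flux, this makes the spatial number density
#' stationary under advection — the ensemble is an incompressible tracer of
#' the flow.  Each particle carries a magnetization vector initialized at
#' thermal equilibrium `(0, 0, M0)`.
#'
#' @param sl_set A [trace_streamlines()] result (or a compatible synthetic
#'   set such as [plug_flow_ensemble()] builds internally).
#' @param density Target particle density, particles per mm^3.
#' @param rng_seed Integer seed (per-streamline phase jitter).
#' @param M0 Equilibrium magnetization per particle (proton-density
#'   surrogate, default 1).
#' @param T1,T2 Longitudinal/transverse relaxation times of blood, ms
#'   (defaults 1200 and 250).
#' @param resample_step Maximum spatial spacing (mm) of the uniform-in-time
#'   position tables used by the signal kernel.
#' @return An object of class `particle_ensemble`.
#' @export
seed_particles <- function(sl_set, density, rng_seed = 1L, M0 = 1,
                           T1 = 1200, T2 = 250, resample_step = 0.1) {
  stopifnot(inherits(sl_set, "streamline_set"), density > 0)
  set.seed(rng_seed)
  dtau <- 1 / (density * sl_set$q_mm3_s)       # s between particles
  nsl <- length(sl_set$streamlines)

  # uniform-in-time resampled position tables (linear interp by the kernel)
  tabs <- lapply(sl_set$streamlines, function(s) {
    vmax <- max(s$speed) * 10                  # mm/s
    ns <- as.integer(min(max(32, ceiling(s$total_time * vmax / resample_step) + 1),
                         20000))
    tt <- seq(0, s$total_time, length.out = ns)
    P <- cbind(approx(s$time, s$points[, 1], tt)$y,
               approx(s$time, s$points[, 2], tt)$y,
               approx(s$time, s$points[, 3], tt)$y)
    list(P = P, n = ns, dt = s$total_time / (ns - 1), Ttot = s$total_time)
  })

  sl_idx <- integer(0)
  tau <- numeric(0)
  warned <- FALSE
  for (j in seq_len(nsl)) {
    Ttot <- tabs[[j]]$Ttot
    jit <- runif(1, 0, dtau)
    tj <- seq(jit, Ttot, by = dtau)
    if (!length(tj)) {
      warned <- TRUE
      next
    }
    sl_idx <- c(sl_idx, rep(j, length(tj)))
    tau <- c(tau, tj)
  }
  if (warned) warning("density too low: some streamlines received no particles")
  n <- length(tau)
  if (!n) stop("no particles seeded; increase density")
  structure(list(sl = sl_idx, tau = tau,
                 static_pos = matrix(NA_real_, n, 3),
                 M = cbind(0, 0, rep(M0, n)),
                 M0 = M0, T1 = T1, T2 = T2,
                 density = density, dtau = dtau,
                 tables = tabs, rng_seed = rng_seed),
            class = "particle_ensemble")
}

#' Number of particles in an ensemble
#' @param ensemble A `particle_ensemble`.
#' @return Integer count.
#' @export
n_particles <- function(ensemble) length(ensemble$tau)

#' Current particle positions
#'
#' @param ensemble A `particle_ensemble`.
#' @return Matrix `n x 3` (mm).
#' @export
particle_positions <- function(ensemble) {
  n <- n_particles(ensemble)
  P <- ensemble$static_pos
  mov <- which(!is.na(ensemble$sl))
  for (j in unique(ensemble$sl[mov])) {
    sel <- mov[ensemble$sl[mov] == j]
    tab <- ensemble$tables[[j]]
    u <- ensemble$tau[sel] %% tab$Ttot
    fi <- u / tab$dt
    i0 <- pmin(floor(fi), tab$n - 2)
    w <- fi - i0
    P[sel, ] <- tab$P[i0 + 1, , drop = FALSE] * (1 - w) +
      tab$P[i0 + 2, , drop = FALSE] * w
  }
  P
}

#' Advance a particle ensemble in time
#'
#' Each particle's position moves along its streamline by the local speed
#' times `dt`; a particle passing its trajectory end is recycled to the
#' streamline start with fresh equilibrium magnetization, so the vessel tree
#' stays filled and the particle count is invariant.
#'
#' @param ensemble A `particle_ensemble`.
#' @param dt Time step in ms (`> 0`; `dt = 0` returns the ensemble unchanged).
#' @return The advanced `particle_ensemble`.
#' @export
advance <- function(ensemble, dt) {
  stopifnot(inherits(ensemble, "particle_ensemble"), dt >= 0)
  if (dt == 0) return(ensemble)
  mov <- which(!is.na(ensemble$sl))
  if (length(mov)) {
    Ttot <- vapply(ensemble$tables, `[[`, 0, "Ttot")[ensemble$sl[mov]]
    tau <- ensemble$tau[mov] + dt / 1000
    wrapped <- tau >= Ttot
    tau[wrapped] <- tau[wrapped] %% Ttot[wrapped]
    ensemble$tau[mov] <- tau
    if (any(wrapped)) {
      ensemble$M[mov[wrapped], ] <- rep(c(0, 0, ensemble$M0),
                                        each = sum(wrapped))
    }
  }
  ensemble
}

#' Ensemble of static spin isochromats
#'
#' Builds a `particle_ensemble` of motionless particles, used for stationary
#' tissue phantoms and degenerate-sequence checks.
#'
#' @param positions Matrix `n x 3` (mm).
#' @param M0,T1,T2 Spin parameters as in [seed_particles()].
#' @return A `particle_ensemble`.
#' @export
static_ensemble <- function(positions, M0 = 1, T1 = 1200, T2 = 250) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  structure(list(sl = rep(NA_integer_, n), tau = rep(0, n),
                 static_pos = positions,
                 M = cbind(0, 0, rep(M0, n)),
                 M0 = M0, T1 = T1, T2 = T2,
                 density = NA_real_, dtau = NA_real_,
                 tables = list(), rng_seed = NA_integer_),
            class = "particle_ensemble")
}

#' Merge two particle ensembles
#'
#' @param a,b `particle_ensemble` objects with matching relaxation constants.
#' @return A combined `particle_ensemble`.
#' @export
combine_ensembles <- function(a, b) {
  stopifnot(inherits(a, "particle_ensemble"), inherits(b, "particle_ensemble"))
  if (!isTRUE(all.equal(c(a$T1, a$T2), c(b$T1, b$T2)))) {
    stop("ensembles must share T1/T2 to be combined")
  }
  off <- length(a$tables)
  sl_b <- ifelse(is.na(b$sl), NA_integer_, b$sl + off)
  structure(list(sl = c(a$sl, sl_b), tau = c(a$tau, b$tau),
                 static_pos = rbind(a$static_pos, b$static_pos),
                 M = rbind(a$M, b$M),
                 M0 = a$M0, T1 = a$T1, T2 = a$T2,
                 density = a$density, dtau = a$dtau,
                 tables = c(a$tables, b$tables),
                 rng_seed = a$rng_seed),
            class = "particle_ensemble")
}

#' Plug-flow tube phantom ensemble
#'
#' A straight circular tube along one axis carrying uniform (plug) flow:
#' streamlines are parallel lines seeded uniformly over the disk area (plug
#' flux is uniform), all moving at the same speed.  Useful for verifying the
#' linear phase-velocity relation of the velocity-encoded sequence.
#'
#' @param radius Tube radius (mm).
#' @param length Tube length (mm), centered on `center` along `axis`.
#' @param speed Plug speed (cm/s).
#' @param density Particles per mm^3.
#' @param rng_seed Integer seed.
#' @param axis `"z"`, `"y"` or `"x"`.
#' @param center Tube center (mm).
#' @param n_streamlines Number of parallel streamlines.
#' @param ... Passed to [seed_particles()] (e.g. `M0`, `T1`, `T2`).
#' @return A `particle_ensemble`.
#' @export
plug_flow_ensemble <- function(radius, length, speed, density, rng_seed = 1L,
                               axis = "z", center = c(0, 0, 0),
                               n_streamlines = 200L, ...) {
  stopifnot(radius > 0, length > 0, speed != 0)
  set.seed(rng_seed)
  rr <- radius * sqrt(runif(n_streamlines))
  ph <- runif(n_streamlines, 0, 2 * pi)
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  perp <- setdiff(1:3, ax)
  sgn <- sign(speed)
  speed <- abs(speed)
  v_mm <- speed * 10
  sls <- lapply(seq_len(n_streamlines), function(k) {
    m <- max(8L, ceiling(length / 0.5) + 1L)
    along <- sgn * seq(-length / 2, length / 2, length.out = m)
    P <- matrix(rep(center, each = m), m, 3)
    P[, ax] <- P[, ax] + along
    P[, perp[1]] <- P[, perp[1]] + rr[k] * cos(ph[k])
    P[, perp[2]] <- P[, perp[2]] + rr[k] * sin(ph[k])
    tt <- seq(0, length, length.out = m) / v_mm
    list(points = P, speed = rep(speed, m), time = tt,
         total_time = tt[m], terminal = TRUE, truncated = FALSE)
  })
  Q <- v_mm * pi * radius^2                     # mm^3/s
  set <- structure(list(streamlines = sls, q_mm3_s = Q / n_streamlines,
                        Q_inlet_ml_s = .mm3_s_to_ml_s(Q),
                        f = rr / radius, phi = ph, rng_seed = rng_seed),
                   class = "streamline_set")
  seed_particles(set, density, rng_seed = rng_seed, ...)
}
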