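# Expand one TR's event table into primitive kernel operations.
# Columns of the op matrix: code, dt_s, Gx, Gy, Gz, angle, zmin, zmax, out.
# Gaps between events become gradient-free evolve steps of at most
# max_free_dt; time is continuous from TR start to TR end.
.expand_tr_ops <- function(events, params, out_base, dummy) {
  p <- params
  rows <- vector("list", 64)
  nr <- 0L
  push <- function(m) {
    nr <<- nr + 1L
    rows[[nr]] <<- m
  }
  op <- function(code, dt, G = c(0, 0, 0), angle = 0, zmin = -Inf,
                 zmax = Inf, out = 0) {
    c(code, dt, G[1], G[2], G[3], angle, zmin, zmax, out)
  }
  free_chunks <- function(dur_ms) {
    if (dur_ms <= 1e-9) return(NULL)
    nchunk <- ceiling(dur_ms / 1)               # coarse 1 ms free precession
    dt <- dur_ms / nchunk * 1e-3
    matrix(rep(op(1, dt), nchunk), ncol = 9, byrow = TRUE)
  }
  cursor <- 0
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    g <- free_chunks(e$t_start - cursor)
    if (!is.null(g)) push(g)
    cursor <- max(cursor, e$t_start)
    if (e$type == "rf") {
      dt <- e$duration / e$n_sub * 1e-3
      a <- e$alpha * pi / 180 / e$n_sub
      push(matrix(rep(op(2, dt, angle = a, zmin = e$zmin, zmax = e$zmax),
                      e$n_sub), ncol = 9, byrow = TRUE))
    } else if (e$type == "grad") {
      dt <- e$duration / e$n_sub * 1e-3
      push(matrix(rep(op(1, dt, G = c(e$Gx, e$Gy, e$Gz)), e$n_sub),
                  ncol = 9, byrow = TRUE))
    } else if (e$type == "readout") {
      Nx <- p$matrix_size[1]
      dwell <- p$dwell * 1e-3
      G <- c(e$Gx, e$Gy, e$Gz)
      if (dummy) {
        outs <- rep(0, Nx)
      } else {
        base <- out_base(e$ky)
        outs <- if (e$reversed) base + Nx:1 else base + 1:Nx
      }
      m <- matrix(0, 2L * Nx + 1L, 9)
      m[1, ] <- op(1, dwell / 2, G = G)
      for (n in seq_len(Nx)) {
        m[2L * n, ] <- op(3, 0, out = outs[n])
        m[2L * n + 1L, ] <- if (n < Nx) op(1, dwell, G = G) else
          op(1, dwell / 2, G = G)
      }
      push(m)
    } else if (e$type == "spoil") {
      push(matrix(op(4, 0), 1, 9))
    }
    cursor <- cursor + e$duration
  }
  g <- free_chunks(p$TR - cursor)
  if (!is.null(g)) push(g)
  do.call(rbind, rows[seq_len(nr)])
}

# Build the complete op matrix of one (venc_axis, polarity) acquisition run.
.build_run_ops <- function(params, venc_axis, polarity) {
  p <- params
  sched <- sequence_schedule(p)
  sched <- sched[sched$venc_axis == venc_axis & sched$polarity == polarity, ]
  Nx <- p$matrix_size[1]; Ny <- p$matrix_size[2]
  blocks <- vector("list", nrow(sched))
  for (r in seq_len(nrow(sched))) {
    s <- sched[r, ]
    zi <- if (p$dimension == "3D") s$kz_index else s$slice - 1L
    out_base <- function(ky) (zi * Ny + ky) * Nx
    ev <- build_timeline(p, venc_axis = venc_axis, polarity = polarity,
                         shot = s$shot, kz_index = s$kz_index, slice = s$slice)
    blocks[[r]] <- .expand_tr_ops(ev, p, out_base, s$dummy)
  }
  do.call(rbind, blocks)
}

#' Simulate a PCA acquisition and return raw k-space
#'
#' Runs the full sequence over the particle ensemble: for every encoded axis
#' and both velocity-encoding polarities the sequence is launched from the
#' same pristine ensemble state, every event of every TR is applied to every
#' particle (analytic Bloch updates; adaptive time stepping — RF substeps,
#' gradient substeps, dwell-time steps during readout, coarse 1 ms steps
#' during free precession), particle positions advance continuously along
#' their streamlines with end-of-trajectory recycling, and the acquired
#' signal is the complex sum of transverse magnetization over the ensemble
#' at every readout sample.
#'
#' @param ensemble A `particle_ensemble` ([seed_particles()],
#'   [static_ensemble()], [plug_flow_ensemble()] or a combination).
#' @param params A [sequence_params()].
#' @param rng_seed Seed for the optional measurement noise.
#' @param noise_sd Standard deviation of additive complex Gaussian noise per
#'   sample (0 = noiseless, the default).
#' @return An object of class `kspace_data`: complex array `data` with
#'   dimensions `(Nx, Ny, Nz, axis, polarity)` (Nz = partitions in 3D,
#'   slices in 2D; polarity index 1 = `+`, 2 = `-`), plus `axes`, `params`
#'   and the sample dwell time (ms).
#' @export
acquire <- function(ensemble, params, rng_seed = 1L, noise_sd = 0) {
  stopifnot(inherits(ensemble, "particle_ensemble"),
            inherits(params, "sequence_params"))
  p <- params
  Nx <- p$matrix_size[1]; Ny <- p$matrix_size[2]
  Nz <- if (p$dimension == "3D") p$n_partitions else p$n_slices
  n_samples <- Nx * Ny * Nz
  axes <- p$venc_axes
  data <- array(complex(real = 0, imaginary = 0),
                dim = c(Nx, Ny, Nz, length(axes), 2))

  # streamline tables flattened for the kernel
  ntab <- length(ensemble$tables)
  if (ntab) {
    ns <- vapply(ensemble$tables, `[[`, 0L, "n")
    pos <- do.call(rbind, lapply(ensemble$tables, `[[`, "P"))
    off <- cumsum(c(0L, ns[-ntab]))
    dts <- vapply(ensemble$tables, `[[`, 0, "dt")
    Ts <- vapply(ensemble$tables, `[[`, 0, "Ttot")
  } else {
    pos <- matrix(0, 1, 3); off <- 0L; ns <- 1L; dts <- 1; Ts <- 1
  }
  sl0 <- ifelse(is.na(ensemble$sl), -1L, ensemble$sl - 1L)

  set.seed(rng_seed)
  for (ai in seq_along(axes)) for (pi_ in 1:2) {
    pol <- c(1, -1)[pi_]
    ops <- .build_run_ops(p, axes[ai], pol)
    samples <- pca_kernel(ops, as.integer(sl0), ensemble$tau,
                          ensemble$static_pos, ensemble$M,
                          ensemble$M0, ensemble$T1, ensemble$T2,
                          pos, as.integer(off), as.integer(ns), dts, Ts,
                          GAMMA_PROTON, n_samples)
    if (noise_sd > 0) {
      samples <- samples + complex(real = rnorm(n_samples, 0, noise_sd),
                                   imaginary = rnorm(n_samples, 0, noise_sd))
    }
    data[, , , ai, pi_] <- array(samples, dim = c(Nx, Ny, Nz))
  }
  structure(list(data = data, axes = axes, polarity = c(1, -1),
                 dwell = p$dwell, params = p),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<kspace_data> %dx%dx%d, axes %s, 2 polarities, dwell %.4g ms\n",
              d[1], d[2], d[3], paste(x$axes, collapse = "/"), x$dwell))
  invisible(x)
}
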