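#' Acquisition parameters of a PCA sequence
#'
#' Describes a complete phase-contrast acquisition: timing (TE/TR/t_ACQ),
#' excitation (flip angle, slab geometry), geometry (FOV, matrix, slices or
#' partitions), velocity encoding (VENC, encoded axes) and readout type
#' (conventional Cartesian or echo-planar with `NETL` echoes per excitation).
#' Axes follow the fixed convention SS = z, PE = y, RO = x; slices are axial
#' (oblique orientations are not supported).
#'
#' All gradient lobes are rectangular.  Readout, phase-encode and
#' velocity-encode amplitudes are derived from the FOV/matrix/VENC demands;
#' the constructor verifies that the acquisition window `t_ACQ` allows
#' Nyquist-rate sampling of the FOV within the hardware gradient limit and
#' that all events fit inside TR, and fails with a configuration error
#' naming the offending interval otherwise.
#'
#' @param TE,TR Echo and repetition time, ms (`t_ACQ < TE < TR`).
#' @param FA Flip angle, degrees.
#' @param t_ACQ Acquisition window width, ms.
#' @param FOV In-plane field of view, mm (length 2: x = RO, y = PE).
#' @param matrix_size Acquisition matrix (length 2: Nx, Ny, both `>= 8`).
#' @param slice_thickness Excited slice thickness, mm (2D).
#' @param slice_spacing Spacing between slices (2D) or partitions (3D), mm.
#' @param n_slices Number of 2D slices.
#' @param n_partitions Number of 3D partitions (kz lines).
#' @param VENC Aliasing velocity, cm/s.
#' @param venc_axes Axes carrying velocity encoding: subset of
#'   `c("SS", "PE", "RO")`.  Defaults to `"SS"` in 2D and all three in 3D;
#'   each encoded axis is acquired at both gradient polarities.
#' @param readout `"conventional"` or `"EPI"`.
#' @param NETL Echo train length (EPI only; `Ny` must be divisible by it).
#' @param dimension `"2D"` or `"3D"` (EPI is implemented for 2D only).
#' @param slab_center z coordinate of the slice stack / 3D slab center, mm.
#' @param fov_center In-plane (x, y) center of the field of view, mm
#'   (default the origin).  Off-center FOVs image anatomy away from the
#'   gradient isocenter; with Cartesian sampling this only shifts the voxel
#'   grid the reconstruction evaluates.
#' @param alpha_eff Effective flip angle, degrees (defaults to `FA`,
#'   on-resonance).
#' @param tau_RF RF pulse duration, ms; `rf_substeps` sub-rotations.
#' @param rf_substeps Substeps of the RF rotation.
#' @param T_venc Single-lobe duration of the bipolar pair, ms.
#' @param T_pre Prewinder duration, ms.
#' @param t_blip EPI phase-encode blip duration, ms.
#' @param max_gradient Hardware gradient limit, mT/m.
#' @param n_dummy Dummy excitations before sampling starts (approach to
#'   steady state).
#' @param rf_substeps Number of sub-rotations of each RF pulse.
#' @return An object of class `sequence_params` with derived fields `dwell`
#'   (ms), gradient amplitudes (T/m) and the z positions of slice centers.
#' @export
sequence_params <- function(TE, TR, FA, t_ACQ = 1, FOV = c(64, 64),
                            matrix_size = c(64, 64), slice_thickness = 3,
                            slice_spacing = 3, n_slices = 1L,
                            n_partitions = 1L, VENC = 100,
                            venc_axes = NULL,
                            readout = c("conventional", "EPI"), NETL = 1L,
                            dimension = c("2D", "3D"), slab_center = 0,
                            fov_center = c(0, 0),
                            alpha_eff = FA, tau_RF = 0.2, rf_substeps = 10L,
                            T_venc = 0.4, T_pre = 0.5, t_blip = 0.25,
                            max_gradient = 80, n_dummy = 10L) {
  readout <- match.arg(readout)
  dimension <- match.arg(dimension)
  if (!(t_ACQ < TE && TE < TR)) {
    stop("configuration error: need t_ACQ < TE < TR")
  }
  matrix_size <- as.integer(matrix_size)
  if (any(matrix_size < 8)) stop("matrix dimensions must be >= 8")
  NETL <- as.integer(NETL)
  if (readout == "conventional") NETL <- 1L
  if (readout == "EPI") {
    if (dimension == "3D") stop("EPI readout is implemented for 2D only")
    if (matrix_size[2] %% NETL != 0) {
      stop("configuration error: Ny must be divisible by NETL")
    }
  }
  if (is.null(venc_axes)) {
    venc_axes <- if (dimension == "2D") "SS" else c("SS", "PE", "RO")
  }
  if (!all(venc_axes %in% c("SS", "PE", "RO"))) {
    stop("venc_axes must be a subset of SS, PE, RO")
  }
  if (dimension == "3D") n_slices <- 1L

  Nx <- matrix_size[1]; Ny <- matrix_size[2]
  Nz <- if (dimension == "3D") as.integer(n_partitions) else 1L
  dwell <- t_ACQ / Nx                           # ms
  dk_x <- 1000 / FOV[1]                         # 1/m
  dk_y <- 1000 / FOV[2]
  FOV_z <- if (dimension == "3D") n_partitions * slice_spacing else NA_real_
  dk_z <- if (dimension == "3D") 1000 / FOV_z else 0

  two_pi_gam <- 2 * pi / GAMMA_PROTON           # T s / (1/m)
  G_ro <- two_pi_gam * dk_x / (dwell * 1e-3)
  m_pre_x <- -(Nx + 1) / 2 * dk_x * two_pi_gam  # prewinder moment, T s/m
  G_pre_x <- m_pre_x / (T_pre * 1e-3)
  G_pe_max <- (Ny / 2) * dk_y * two_pi_gam / (T_pre * 1e-3)
  n_shots <- Ny %/% NETL
  G_blip <- n_shots * dk_y * two_pi_gam / (t_blip * 1e-3)
  G_kz_max <- if (dimension == "3D") {
    (Nz / 2) * dk_z * two_pi_gam / (T_pre * 1e-3)
  } else 0
  venc_si <- VENC * 1e-2
  G_venc <- pi / (2 * venc_si * GAMMA_PROTON * (T_venc * 1e-3)^2)

  glim <- max_gradient * 1e-3                   # T/m
  checks <- c(readout_gradient = abs(G_ro), readout_prewinder = abs(G_pre_x),
              phase_encode = G_pe_max, epi_blip = if (NETL > 1) abs(G_blip) else 0,
              partition_encode = G_kz_max, velocity_encode = abs(G_venc))
  bad <- names(checks)[checks > glim]
  if (length(bad)) {
    stop(sprintf(paste0("configuration error: %s amplitude %.1f mT/m exceeds ",
                        "the %.0f mT/m limit; t_ACQ/FOV do not admit ",
                        "Nyquist-rate sampling"),
                 bad[1], checks[[bad[1]]] * 1e3, max_gradient))
  }

  gap <- 0.05
  esp <- t_ACQ + t_blip
  t_pre_end <- tau_RF + gap + 2 * T_venc + gap + T_pre
  t_first_echo_start <- TE - t_ACQ / 2
  if (t_first_echo_start < t_pre_end) {
    stop(sprintf(paste0("configuration error: acquisition window (starts %.2f ms)",
                        " overlaps the prewinder (ends %.2f ms); increase TE"),
                 t_first_echo_start, t_pre_end))
  }
  t_train_end <- TE + (NETL - 1) * esp + t_ACQ / 2
  if (t_train_end + gap > TR) {
    stop(sprintf(paste0("configuration error: echo train (ends %.2f ms) ",
                        "exceeds TR = %.2f ms"), t_train_end, TR))
  }

  sc <- slab_center + (seq_len(n_slices) - (n_slices + 1) / 2) * slice_spacing
  structure(list(TE = TE, TR = TR, FA = FA, alpha_eff = alpha_eff,
                 t_ACQ = t_ACQ, FOV = FOV, matrix_size = c(Nx, Ny),
                 slice_thickness = slice_thickness,
                 slice_spacing = slice_spacing, n_slices = as.integer(n_slices),
                 n_partitions = Nz, VENC = VENC, venc_axes = venc_axes,
                 readout = readout, NETL = NETL, n_shots = n_shots,
                 dimension = dimension, slab_center = slab_center,
                 fov_center = rep_len(as.numeric(fov_center), 2),
                 slice_centers = sc, FOV_z = FOV_z,
                 tau_RF = tau_RF, rf_substeps = as.integer(rf_substeps),
                 T_venc = T_venc, T_pre = T_pre, t_blip = t_blip, gap = gap,
                 dwell = dwell, esp = esp,
                 G_ro = G_ro, G_pre_x = G_pre_x, G_venc = G_venc,
                 dk_x = dk_x, dk_y = dk_y, dk_z = dk_z,
                 two_pi_gam = two_pi_gam,
                 max_gradient = max_gradient, n_dummy = as.integer(n_dummy)),
            class = "sequence_params")
}

#' @export
print.sequence_params <- function(x, ...) {
  cat(sprintf("<sequence_params> %s %s, TE/TR/FA = %g/%g ms/%g deg, %dx%d, VENC %g cm/s",
              x$dimension, x$readout, x$TE, x$TR, x$FA,
              x$matrix_size[1], x$matrix_size[2], x$VENC))
  if (x$readout == "EPI") cat(sprintf(", NETL %d", x$NETL))
  cat("\n")
  invisible(x)
}

.axis_col <- c(RO = 1L, PE = 2L, SS = 3L)

#' Event timeline of one repetition cycle
#'
#' Builds the ordered event list of a single TR: slab-selective RF pulse,
#' bipolar velocity-encoding lobes on the active axis, combined
#' readout/phase-encode (and partition-encode) prewinder, the acquisition
#' window(s) positioned so the first echo peaks at TE — for EPI, `NETL`
#' readouts of alternating polarity interleaved with `NETL - 1` phase-encode
#' blips — and the end-of-cycle spoil event.  A conventional readout is the
#' `NETL = 1` special case of the same construction.
#'
#' @param params A [sequence_params()].
#' @param venc_axis `"SS"`, `"PE"` or `"RO"`.
#' @param polarity `+1` or `-1`.
#' @param shot Shot index, 0-based: in EPI, shot `e` acquires the interleaved
#'   phase-encode lines `e + j * n_shots`; conventionally it is simply the
#'   ky line index.
#' @param kz_index 3D partition index, 0-based (ignored in 2D).
#' @param slice 2D slice number, 1-based.
#' @return A data frame of events ordered in time, with columns `type`
#'   (`rf`/`grad`/`readout`/`spoil`), `t_start`, `duration` (ms), gradient
#'   amplitudes `Gx`, `Gy`, `Gz` (T/m), `alpha` (deg), `n_sub`, `zmin`,
#'   `zmax` (mm), `echo`, `ky` (0-based line), `reversed`.
#' @export
build_timeline <- function(params, venc_axis = params$venc_axes[1],
                           polarity = 1, shot = 0L, kz_index = 0L,
                           slice = 1L) {
  p <- params
  stopifnot(inherits(p, "sequence_params"), polarity %in% c(-1, 1),
            venc_axis %in% c("SS", "PE", "RO"))
  ev <- function(type, t, dur, G = c(0, 0, 0), alpha = 0, n_sub = 1L,
                 zmin = -Inf, zmax = Inf, echo = NA_integer_,
                 ky = NA_integer_, reversed = FALSE) {
    data.frame(type = type, t_start = t, duration = dur,
               Gx = G[1], Gy = G[2], Gz = G[3], alpha = alpha,
               n_sub = as.integer(n_sub), zmin = zmin, zmax = zmax,
               echo = echo, ky = ky, reversed = reversed)
  }
  rows <- list()
  # slab: one slice thickness in 2D, the whole partition stack in 3D
  if (p$dimension == "2D") {
    zc <- p$slice_centers[slice]
    slab <- zc + c(-0.5, 0.5) * p$slice_thickness
  } else {
    slab <- p$slab_center + c(-0.5, 0.5) * p$FOV_z
  }
  rows[[1]] <- ev("rf", 0, p$tau_RF, alpha = p$alpha_eff, n_sub = p$rf_substeps,
                  zmin = slab[1], zmax = slab[2])
  # bipolar pair: (-A, +A) at polarity +1 so that positive velocity along the
  # encoded axis maps to positive reconstructed phase difference
  gv1 <- gv2 <- c(0, 0, 0)
  gv1[.axis_col[[venc_axis]]] <- -polarity * p$G_venc
  gv2[.axis_col[[venc_axis]]] <- +polarity * p$G_venc
  tv0 <- p$tau_RF + p$gap
  rows[[2]] <- ev("grad", tv0, p$T_venc, G = gv1, n_sub = 5L)
  rows[[3]] <- ev("grad", tv0 + p$T_venc, p$T_venc, G = gv2, n_sub = 5L)
  # combined RO/PE(/kz) prewinder
  iy0 <- shot                                   # first ky line of this shot
  ky0 <- (iy0 - p$matrix_size[2] / 2) * p$dk_y
  Gy_pre <- ky0 * p$two_pi_gam / (p$T_pre * 1e-3)
  Gz_pre <- if (p$dimension == "3D") {
    (kz_index - p$n_partitions / 2) * p$dk_z * p$two_pi_gam / (p$T_pre * 1e-3)
  } else 0
  tp0 <- tv0 + 2 * p$T_venc + p$gap
  rows[[4]] <- ev("grad", tp0, p$T_pre, G = c(p$G_pre_x, Gy_pre, Gz_pre),
                  n_sub = 2L)
  # echo train
  for (j in seq_len(p$NETL) - 1L) {
    t_echo <- p$TE + j * p$esp - p$t_ACQ / 2
    rev <- (j %% 2L) == 1L
    rows[[length(rows) + 1L]] <-
      ev("readout", t_echo, p$t_ACQ, G = c(p$G_ro * (if (rev) -1 else 1), 0, 0),
         echo = j, ky = iy0 + j * p$n_shots, reversed = rev)
    if (j < p$NETL - 1L) {
      Gy_blip <- p$n_shots * p$dk_y * p$two_pi_gam / (p$t_blip * 1e-3)
      rows[[length(rows) + 1L]] <-
        ev("grad", t_echo + p$t_ACQ, p$t_blip, G = c(0, Gy_blip, 0))
    }
  }
  t_spoil <- p$TE + (p$NETL - 1) * p$esp + p$t_ACQ / 2 + p$gap
  rows[[length(rows) + 1L]] <- ev("spoil", t_spoil, 0)
  out <- do.call(rbind, rows)
  out[order(out$t_start), , drop = FALSE]
}

#' Shot schedule of a full acquisition
#'
#' Enumerates every TR of one complete k-space acquisition for every encoded
#' axis and both velocity-encoding polarities, including the leading dummy
#' excitations.
#'
#' @param params A [sequence_params()].
#' @return A data frame with one row per TR: `venc_axis`, `polarity`,
#'   `slice`, `kz_index`, `shot`, `dummy`.
#' @export
sequence_schedule <- function(params) {
  p <- params
  out <- list()
  for (ax in p$venc_axes) for (pol in c(1, -1)) {
    if (p$dimension == "2D") {
      for (sl in seq_len(p$n_slices)) {
        dummy <- if (p$n_dummy > 0) {
          data.frame(venc_axis = ax, polarity = pol, slice = sl, kz_index = 0L,
                     shot = 0L, dummy = TRUE)[rep(1, p$n_dummy), ]
        } else NULL
        main <- data.frame(venc_axis = ax, polarity = pol, slice = sl,
                           kz_index = 0L, shot = seq_len(p$n_shots) - 1L,
                           dummy = FALSE)
        out[[length(out) + 1L]] <- rbind(dummy, main)
      }
    } else {
      dummy <- if (p$n_dummy > 0) {
        data.frame(venc_axis = ax, polarity = pol, slice = 1L, kz_index = 0L,
                   shot = 0L, dummy = TRUE)[rep(1, p$n_dummy), ]
      } else NULL
      grid <- expand.grid(shot = seq_len(p$n_shots) - 1L,
                          kz_index = seq_len(p$n_partitions) - 1L)
      main <- data.frame(venc_axis = ax, polarity = pol, slice = 1L,
                         kz_index = grid$kz_index, shot = grid$shot,
                         dummy = FALSE)
      out[[length(out) + 1L]] <- rbind(dummy, main)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
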