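#' Wrap phase to (-pi, pi]
#'
#' @param phi Phase values, rad.
#' @return Wrapped values in `(-pi, pi]` (ties mapped to `+pi`).
#' @export
wrap_phase <- function(phi) {
  w <- -((-phi + pi) %% (2 * pi) - pi)
  w
}

# Centered inverse DFT matrix mapping k samples k_n = (n - N/2)/FOV to voxel
# centers x_i = -FOV/2 + (i + 1/2) * FOV/N (0-based voxel-center convention).
.idft_matrix <- function(N, FOV, x0 = -FOV / 2) {
  n <- seq_len(N) - 1
  k <- (n - N / 2) / FOV
  x <- x0 + (n + 0.5) * FOV / N
  exp(-2i * pi * outer(x, k)) / N
}

.apply_idft <- function(K, W, dim_idx) {
  d <- dim(K)
  perm <- c(dim_idx, setdiff(seq_along(d), dim_idx))
  A <- aperm(K, perm)
  da <- dim(A)
  A <- matrix(A, nrow = da[1])
  A <- W %*% A
  A <- array(A, dim = da)
  aperm(A, order(perm))
}

#' Reconstruct magnitude and phase images from k-space
#'
#' Centered inverse discrete Fourier transform of every fully sampled
#' Cartesian k-space (per slice in 2D, including the partition direction in
#' 3D), returning magnitude and wrapped-phase images per encoded axis and
#' polarity.
#'
#' @param kspace A [acquire()] result (or a compatible `kspace_data`).
#' @return A nested list `recon[[axis]][[polarity]]` (`polarity` names
#'   `"plus"`, `"minus"`) of `image_pair` objects with elements `magnitude`,
#'   `phase`, `complex` and `geometry` (voxel sizes and voxel-center
#'   coordinates, mm).
#' @export
reconstruct <- function(kspace) {
  stopifnot(inherits(kspace, "kspace_data"))
  p <- kspace$params
  d <- dim(kspace$data)
  if (any(!is.finite(Mod(kspace$data)))) stop("incomplete k-space: non-finite samples")
  Nx <- d[1]; Ny <- d[2]; Nz <- d[3]
  fc <- if (is.null(p$fov_center)) c(0, 0) else p$fov_center
  Wx <- .idft_matrix(Nx, p$FOV[1], x0 = fc[1] - p$FOV[1] / 2)
  Wy <- .idft_matrix(Ny, p$FOV[2], x0 = fc[2] - p$FOV[2] / 2)
  geom <- .grid_geometry(p)
  out <- vector("list", length(kspace$axes))
  names(out) <- kspace$axes
  for (ai in seq_along(kspace$axes)) {
    pair <- vector("list", 2)
    names(pair) <- c("plus", "minus")
    for (pi_ in 1:2) {
      K <- kspace$data[, , , ai, pi_, drop = FALSE]
      dim(K) <- c(Nx, Ny, Nz)
      I <- .apply_idft(K, Wx, 1L)
      I <- .apply_idft(I, Wy, 2L)
      if (p$dimension == "3D" && Nz > 1) {
        Wz <- .idft_matrix(Nz, p$FOV_z, x0 = p$slab_center - p$FOV_z / 2)
        I <- .apply_idft(I, Wz, 3L)
      }
      pair[[pi_]] <- structure(list(magnitude = Mod(I),
                                    phase = wrap_phase(Arg(I)),
                                    complex = I, geometry = geom),
                               class = "image_pair")
    }
    out[[ai]] <- pair
  }
  structure(out, class = "pca_recon", params = p)
}

.grid_geometry <- function(p) {
  Nx <- p$matrix_size[1]; Ny <- p$matrix_size[2]
  vx <- p$FOV[1] / Nx; vy <- p$FOV[2] / Ny
  fc <- if (is.null(p$fov_center)) c(0, 0) else p$fov_center
  x <- fc[1] - p$FOV[1] / 2 + (seq_len(Nx) - 0.5) * vx
  y <- fc[2] - p$FOV[2] / 2 + (seq_len(Ny) - 0.5) * vy
  if (p$dimension == "3D") {
    vz <- p$slice_spacing
    z <- p$slab_center - p$FOV_z / 2 + (seq_len(p$n_partitions) - 0.5) * vz
  } else {
    vz <- p$slice_spacing
    z <- p$slice_centers
  }
  list(voxel = c(vx, vy, vz), x = x, y = y, z = z)
}

#' Phase-difference image of two reconstructions
#'
#' `delta_phi = wrap(phi_plus - phi_minus)`, the velocity-encoded phase
#' image of a PCA acquisition pair.
#'
#' @param plus,minus `image_pair` objects on the same grid.
#' @return Array of wrapped phase differences, rad.
#' @export
phase_difference <- function(plus, minus) {
  stopifnot(inherits(plus, "image_pair"), inherits(minus, "image_pair"))
  if (!identical(dim(plus$phase), dim(minus$phase))) {
    stop("grid mismatch between phase images")
  }
  wrap_phase(plus$phase - minus$phase)
}

#' Convert a phase difference to velocity
#'
#' `v = delta_phi * VENC / pi`: a phase difference of `pi` corresponds to
#' the aliasing velocity.
#'
#' @param delta_phi Phase difference(s), rad, in `(-pi, pi]`.
#' @param VENC Aliasing velocity, cm/s.
#' @return Velocity in cm/s (same shape as `delta_phi`).
#' @export
velocity_from_phase <- function(delta_phi, VENC) {
  delta_phi * VENC / pi
}

#' Voxel-wise velocity magnitude
#'
#' `m = sqrt(u^2 + v^2 + w^2)` over co-registered component maps; `NA`
#' components are treated as zero (axes that were not velocity-encoded).
#'
#' @param u,v,w Velocity component arrays, cm/s.
#' @return Array of velocity magnitudes, cm/s.
#' @export
velocity_magnitude <- function(u, v, w) {
  z <- function(a) ifelse(is.na(a), 0, a)
  sqrt(z(u)^2 + z(v)^2 + z(w)^2)
}

#' Mask a velocity map by the magnitude image
#'
#' Voxels whose signal magnitude falls below `threshold_fraction` of the
#' global maximum carry random phase (no spins); their velocities are zeroed
#' and excluded from the validity mask.
#'
#' @param magnitude Magnitude image array.
#' @param vel A `velocity_map` (see [velocity_maps()]).
#' @param threshold_fraction Fraction of the maximum magnitude, normally in
#'   `(0, 1)`; a value above 1 yields an empty mask.
#' @return The masked `velocity_map`.
#' @export
mask_velocity <- function(magnitude, vel, threshold_fraction = 0.1) {
  stopifnot(threshold_fraction > 0)
  mx <- max(magnitude)
  if (mx == 0) {
    warning("all-zero magnitude image: empty mask")
    mask <- array(FALSE, dim(magnitude))
  } else {
    mask <- magnitude > threshold_fraction * mx
  }
  for (f in c("u", "v", "w", "m")) {
    if (!is.null(vel[[f]])) vel[[f]][!mask] <- 0
  }
  vel$mask <- mask
  vel
}

#' Reconstruct velocity maps from a PCA acquisition
#'
#' Full post-processing chain: inverse-Fourier reconstruction of both
#' polarities per encoded axis, phase-difference computation, conversion to
#' velocity components, velocity-magnitude map, and magnitude-image masking.
#'
#' @param kspace A [acquire()] result.
#' @param threshold_fraction Magnitude mask threshold (default 0.1).
#' @return An object of class `velocity_map`: component arrays `u`, `v`, `w`
#'   (cm/s; `NA` for axes that were not encoded), magnitude map `m`,
#'   signal `magnitude`, logical `mask`, `geometry`, and the `VENC` used.
#' @export
velocity_maps <- function(kspace, threshold_fraction = 0.1) {
  rec <- reconstruct(kspace)
  p <- attr(rec, "params")
  dims <- dim(rec[[1]]$plus$magnitude)
  comp <- list(u = NULL, v = NULL, w = NULL)
  ax_map <- c(RO = "u", PE = "v", SS = "w")
  mag_acc <- array(0, dims)
  nacc <- 0
  for (ax in names(rec)) {
    dphi <- phase_difference(rec[[ax]]$plus, rec[[ax]]$minus)
    comp[[ax_map[[ax]]]] <- velocity_from_phase(dphi, p$VENC)
    mag_acc <- mag_acc + rec[[ax]]$plus$magnitude + rec[[ax]]$minus$magnitude
    nacc <- nacc + 2
  }
  magnitude <- mag_acc / nacc
  for (f in c("u", "v", "w")) {
    if (is.null(comp[[f]])) comp[[f]] <- array(NA_real_, dims)
  }
  vel <- structure(list(u = comp$u, v = comp$v, w = comp$w,
                        m = velocity_magnitude(comp$u, comp$v, comp$w),
                        magnitude = magnitude,
                        mask = array(TRUE, dims),
                        geometry = rec[[1]]$plus$geometry,
                        VENC = p$VENC, params = p),
                   class = "velocity_map")
  mask_velocity(magnitude, vel, threshold_fraction)
}

#' @export
print.velocity_map <- function(x, ...) {
  cat(sprintf("<velocity_map> %s, %d in-mask voxels, VENC %g cm/s\n",
              paste(dim(x$m), collapse = "x"), sum(x$mask), x$VENC))
  invisible(x)
}
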