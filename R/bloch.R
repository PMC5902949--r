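#' Spin state of an isochromat
#'
#' @param M Magnetization 3-vector (dimensionless).
#' @param M0 Equilibrium magnitude (proton-density surrogate).
#' @param T1,T2 Relaxation times, ms; requires `T1 >= T2 > 0`.
#' @return An object of class `spin_state`.
#' @export
spin_state <- function(M = c(0, 0, 1), M0 = 1, T1 = 1200, T2 = 250) {
  stopifnot(length(M) == 3, T2 > 0, T1 >= T2)
  structure(list(M = as.numeric(M), M0 = M0, T1 = T1, T2 = T2),
            class = "spin_state")
}

#' Free precession and relaxation of a spin state
#'
#' Analytic Bloch-equation update over a step `dt`:
#' `M <- Rot_z(theta_g) Rot_z(theta_i) R12 M + R1`, where `R12 =
#' diag(exp(-dt/T2), exp(-dt/T2), exp(-dt/T1))` damps the components and the
#' recovery vector `R1 = (0, 0, M0 (1 - exp(-dt/T1)))` restores the
#' longitudinal equilibrium.  `theta_g` is the phase acquired from encoding
#' gradients and `theta_i` from static field inhomogeneity.
#'
#' @param state A [spin_state()].
#' @param dt Time step, ms (`>= 0`).
#' @param theta_g,theta_i Rotation angles about z, rad.
#' @return The updated `spin_state`.
#' @export
free_precess <- function(state, dt, theta_g = 0, theta_i = 0) {
  stopifnot(inherits(state, "spin_state"), dt >= 0)
  e2 <- exp(-dt / state$T2)
  e1 <- exp(-dt / state$T1)
  M <- state$M * c(e2, e2, e1)
  th <- theta_g + theta_i
  ct <- cos(th); st <- sin(th)
  state$M <- c(ct * M[1] - st * M[2],
               st * M[1] + ct * M[2],
               M[3] + state$M0 * (1 - e1))
  state
}

#' Slab-selective RF excitation pulse
#'
#' @param alpha Nominal flip angle, degrees.
#' @param alpha_eff Effective flip angle, degrees; defaults to `alpha`
#'   (on-resonance).  Off-resonance behaviour can be injected by supplying a
#'   different value.
#' @param tau_RF Pulse duration, ms.
#' @param n_substeps Number of sub-rotations the flip is divided into
#'   (`>= 1`); during the pulse the spin rotates by `alpha_eff / n_substeps`
#'   per substep while relaxation is suspended (the pulse is much shorter
#'   than T1/T2).
#' @param slab `c(z_min, z_max)` in mm: only spins currently inside the slab
#'   are excited (slice selection is a geometric membership test; no
#'   slice-selection gradient lobes are played).
#' @return An object of class `rf_pulse`.
#' @export
rf_pulse <- function(alpha, alpha_eff = alpha, tau_RF = 0.2, n_substeps = 10L,
                     slab = c(-Inf, Inf)) {
  stopifnot(n_substeps >= 1, slab[1] < slab[2], tau_RF > 0)
  structure(list(alpha = alpha, alpha_eff = alpha_eff, tau_RF = tau_RF,
                 n_substeps = as.integer(n_substeps), slab = as.numeric(slab)),
            class = "rf_pulse")
}

#' Apply an RF pulse to a spin state
#'
#' Rotates the magnetization about the transverse x axis by the effective
#' flip angle, applied as `n_substeps` successive sub-rotations; a spin whose
#' z position lies outside the slab is untouched.
#'
#' @param state A [spin_state()].
#' @param pulse An [rf_pulse()].
#' @param z Spin z position, mm.
#' @return The updated `spin_state`.
#' @export
apply_rf <- function(state, pulse, z) {
  stopifnot(inherits(state, "spin_state"), inherits(pulse, "rf_pulse"))
  if (z < pulse$slab[1] || z > pulse$slab[2]) return(state)
  a <- pulse$alpha_eff * pi / 180 / pulse$n_substeps
  ca <- cos(a); sa <- sin(a)
  M <- state$M
  for (k in seq_len(pulse$n_substeps)) {
    M <- c(M[1], ca * M[2] + sa * M[3], -sa * M[2] + ca * M[3])
  }
  state$M <- M
  state
}

#' First moment of the bipolar velocity-encoding gradient pair
#'
#' Returns the gradient first moment `M1` such that one acquisition's
#' bipolar pair imparts phase `gamma * M1 * v` on a spin moving with constant
#' velocity `v` along the encoding axis, with `gamma * M1 = pi / (2 VENC)`;
#' the two opposite-polarity acquisitions then differ by
#' `delta_phi = pi * v / VENC`, the phase-velocity gain the velocity map
#' reconstruction inverts.
#'
#' @param VENC Aliasing velocity, cm/s (`> 0`).
#' @return First moment in mT ms^2 / m.
#' @export
bipolar_moment <- function(VENC) {
  if (!is.numeric(VENC) || VENC <= 0) stop("VENC must be positive")
  venc_si <- VENC * 1e-2                        # m/s
  m1_si <- pi / (2 * venc_si * GAMMA_PROTON)    # T s^2 / m
  m1_si * 1e9                                   # mT ms^2 / m
}
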