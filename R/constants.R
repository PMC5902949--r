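#' Gyromagnetic ratio of the proton
#'
#' Angular gyromagnetic ratio used throughout the signal simulation,
#' `2 * pi * 42.577e6` rad s^-1 T^-1.
#'
#' @format A single numeric value.
#' @export
GAMMA_PROTON <- 2 * pi * 42.577e6

# unit helpers: package convention is mm for positions/radii, ms for sequence
# times, cm/s for user-facing velocities, ml/s for flows, Pa for pressures.
# Internal flow computations use mm and mm/s; SI only inside resistances and
# gradient moments.
.cm_s_to_mm_s <- function(v) v * 10
.mm_s_to_cm_s <- function(v) v / 10
.ml_s_to_mm3_s <- function(q) q * 1000
.mm3_s_to_ml_s <- function(q) q / 1000

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}
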