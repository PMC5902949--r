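# separable Gaussian smoothing with replicate padding (FFT-free, direct 1-D
# convolutions along each axis; kernels are truncated at 4 sigma)
.gauss_smooth <- function(arr, sigma_vox) {
  for (a in 1:3) {
    s <- sigma_vox[a]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k <- k / sum(k)
    arr <- .conv_axis(arr, k, a)
  }
  arr
}

.conv_axis <- function(arr, k, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  A <- aperm(arr, perm)
  da <- dim(A)
  n <- da[1]
  r <- (length(k) - 1L) / 2L
  # replicate-pad along the first axis
  Apad <- A[c(rep(1L, r), seq_len(n), rep(n, r)), , , drop = FALSE]
  M <- matrix(Apad, nrow = n + 2L * r)
  out <- matrix(0, n, ncol(M))
  for (j in seq_along(k)) {
    out <- out + k[j] * M[j:(j + n - 1L), , drop = FALSE]
  }
  aperm(array(out, da), order(perm))
}

# central difference along one axis with replicate ends, spacing h (mm)
.cdiff <- function(arr, axis, h) {
  d <- dim(arr)
  n <- d[axis]
  ip <- pmin(seq_len(n) + 1L, n)
  im <- pmax(seq_len(n) - 1L, 1L)
  sel <- function(i) {
    args <- rep(list(quote(expr =)), 3)
    args[[axis]] <- i
    do.call(`[`, c(list(arr), args, list(drop = FALSE)))
  }
  (sel(ip) - sel(im)) / (2 * h)
}

# analytic eigenvalues of symmetric 3x3 matrices, vectorized
# (trigonometric method); returns 3 columns sorted by absolute value
.eig3_sym <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  eig <- matrix(0, length(a11), 3)
  nz <- p > 1e-300
  if (any(!nz)) eig[!nz, ] <- q[!nz]
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]; b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]; b13 <- a13[nz] / p[nz]; b23 <- a23[nz] / p[nz]
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[nz] + 2 * p[nz] * cos(phi)
    e3 <- q[nz] + 2 * p[nz] * cos(phi + 2 * pi / 3)
    e2 <- 3 * q[nz] - e1 - e3
    eig[nz, ] <- cbind(e1, e2, e3)
  }
  # sort rows by |lambda|
  o1 <- abs(eig)
  ord <- t(apply(o1, 1, order))
  cbind(eig[cbind(seq_len(nrow(eig)), ord[, 1])],
        eig[cbind(seq_len(nrow(eig)), ord[, 2])],
        eig[cbind(seq_len(nrow(eig)), ord[, 3])])
}

#' Multi-scale Hessian vesselness filter
#'
#' Enhances bright tubular structures: at every scale the image is smoothed
#' with a Gaussian kernel of that width, the Hessian is computed by central
#' differences (scale-normalized by `sigma^2`), and the eigenvalue-ratio
#' tubularity response is evaluated — large for voxels with two large
#' negative eigenvalues and one near zero (a bright tube), suppressed for
#' plates and blobs.  The voxel response is the maximum over scales.
#'
#' @param img A [volume_image()].
#' @param scales Gaussian scales in mm (default `c(0.5, 1, 2.5, 5)`).
#' @param alpha,beta Plate/blob sensitivity parameters (default 0.5).
#' @param c Second-order structure sensitivity; default half the maximum
#'   Hessian Frobenius norm at each scale.
#' @return A [volume_image()] of vesselness responses in `[0, 1]`.
#' @export
vesselness <- function(img, scales = c(0.5, 1, 2.5, 5), alpha = 0.5,
                       beta = 0.5, c = NULL) {
  stopifnot(inherits(img, "volume_image"), length(scales) >= 1)
  if (any(scales < max(img$voxel_size))) {
    warning("vesselness scale below the voxel size; response may be unreliable")
  }
  d <- dim(img$data)
  best <- array(0, d)
  for (sg in scales) {
    sm <- .gauss_smooth(img$data, sg / img$voxel_size)
    h <- img$voxel_size
    gx <- .cdiff(sm, 1, h[1]); gy <- .cdiff(sm, 2, h[2]); gz <- .cdiff(sm, 3, h[3])
    a11 <- .cdiff(gx, 1, h[1]); a22 <- .cdiff(gy, 2, h[2]); a33 <- .cdiff(gz, 3, h[3])
    a12 <- .cdiff(gx, 2, h[2]); a13 <- .cdiff(gx, 3, h[3]); a23 <- .cdiff(gy, 3, h[3])
    s2 <- sg^2
    lam <- .eig3_sym(as.numeric(a11) * s2, as.numeric(a22) * s2,
                     as.numeric(a33) * s2, as.numeric(a12) * s2,
                     as.numeric(a13) * s2, as.numeric(a23) * s2)
    l1 <- lam[, 1]; l2 <- lam[, 2]; l3 <- lam[, 3]
    S <- sqrt(l1^2 + l2^2 + l3^2)
    cc <- if (is.null(c)) max(S) / 2 else c
    if (cc <= 0) cc <- 1
    RB <- abs(l1) / pmax(sqrt(abs(l2 * l3)), 1e-300)
    RA <- abs(l2) / pmax(abs(l3), 1e-300)
    v <- (1 - exp(-RA^2 / (2 * alpha^2))) * exp(-RB^2 / (2 * beta^2)) *
      (1 - exp(-S^2 / (2 * cc^2)))
    v[l2 > 0 | l3 > 0] <- 0                      # bright-on-dark convention
    best <- pmax(best, array(v, d))
  }
  volume_image(best, img$voxel_size, img$origin)
}
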