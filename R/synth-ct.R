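#' 3D scalar volume on a regular grid
#'
#' @param data 3D numeric array.
#' @param voxel_size Voxel edge lengths, mm (length 3; anisotropy allowed).
#' @param origin Position (mm) of the center of voxel `[1, 1, 1]`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, voxel_size, origin = c(0, 0, 0)) {
  stopifnot(length(dim(data)) == 3, all(voxel_size > 0))
  structure(list(data = data, voxel_size = rep_len(as.numeric(voxel_size), 3),
                 origin = as.numeric(origin)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels of %s mm, range [%.3g, %.3g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

# voxel-center coordinates along each axis
.vol_coords <- function(vol) {
  d <- dim(vol$data)
  lapply(1:3, function(a) vol$origin[a] + (seq_len(d[a]) - 1) * vol$voxel_size[a])
}

# mm position -> fractional 0-based voxel index
.mm_to_index <- function(vol, pts) {
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$voxel_size, "/")
}

#' Synthesize a contrast-enhanced CT-like volume from a tree
#'
#' Voxelizes the vessel lumen on a regular grid: voxels inside any lumen
#' (distance to a centerline below the local spline radius) take the vessel
#' intensity, others the background intensity, with partial-volume handling
#' by supersampled occupancy fractions and optional additive Gaussian noise.
#'
#' @param tree A [vessel_tree()].
#' @param voxel_size Voxel size, mm (scalar or length 3).
#' @param vessel_intensity,background_intensity Distinct intensities
#'   (defaults 200 and 50, emulating contrast-enhanced arteries over soft
#'   tissue).
#' @param noise_sd Gaussian noise standard deviation (`>= 0`).
#' @param rng_seed Integer seed for the noise.
#' @param supersample Subsamples per voxel edge for partial volume
#'   (default 2).
#' @param margin Padding around the tree bounding box, mm.
#' @return A [volume_image()]; the noiseless occupancy fraction is attached
#'   as attribute `"occupancy"` and the ground-truth lumen mask (occupancy
#'   `>= 0.5`) as attribute `"lumen"`.
#' @export
synth_ct <- function(tree, voxel_size = 0.7, vessel_intensity = 200,
                     background_intensity = 50, noise_sd = 0, rng_seed = 1L,
                     supersample = 2L, margin = 3) {
  stopifnot(inherits(tree, "vessel_tree"), noise_sd >= 0)
  if (vessel_intensity == background_intensity) {
    stop("vessel and background intensities must be distinct")
  }
  voxel_size <- rep_len(as.numeric(voxel_size), 3)
  rmin <- min(vapply(tree$centerlines, function(cl) min(cl$radii), 0))
  if (max(voxel_size) > rmin) {
    warning(sprintf("under-resolution: voxel size %.2f mm exceeds the minimum radius %.2f mm",
                    max(voxel_size), rmin))
  }
  bb <- .tree_bbox(tree, margin = margin)
  dims <- pmax(ceiling((bb$hi - bb$lo) / voxel_size), 4)
  origin <- bb$lo + voxel_size / 2
  ss <- as.integer(supersample)
  # supersample offsets within a voxel, in voxel units
  offs <- (seq_len(ss) - 0.5) / ss - 0.5
  occ <- array(0, dims)
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * voxel_size[a])
  # evaluate occupancy plane by plane to bound memory
  for (kz in seq_len(dims[3])) {
    acc <- matrix(0, dims[1], dims[2])
    for (oz in offs) {
      z <- ax[[3]][kz] + oz * voxel_size[3]
      for (oy in offs) for (ox in offs) {
        pts <- cbind(rep(ax[[1]] + ox * voxel_size[1], dims[2]),
                     rep(ax[[2]] + oy * voxel_size[2], each = dims[1]),
                     z)
        acc <- acc + matrix(points_in_lumen(tree, pts), dims[1], dims[2])
      }
    }
    occ[, , kz] <- acc / ss^3
  }
  img <- background_intensity + (vessel_intensity - background_intensity) * occ
  if (noise_sd > 0) {
    set.seed(rng_seed)
    img <- img + array(rnorm(length(img), 0, noise_sd), dims)
  }
  out <- volume_image(img, voxel_size, origin)
  attr(out, "occupancy") <- occ
  attr(out, "lumen") <- occ >= 0.5
  out
}

#' Ground-truth lumen mask of a tree on a volume grid
#'
#' @param tree A [vessel_tree()].
#' @param vol A [volume_image()] providing the grid.
#' @return A `binary_mask` (logical array with the volume geometry).
#' @export
lumen_mask <- function(tree, vol) {
  co <- .vol_coords(vol)
  d <- dim(vol$data)
  pts <- cbind(rep(co[[1]], times = d[2] * d[3]),
               rep(rep(co[[2]], each = d[1]), times = d[3]),
               rep(co[[3]], each = d[1] * d[2]))
  m <- array(points_in_lumen(tree, pts), d)
  binary_mask(m, vol)
}

#' Binary mask sharing a volume's geometry
#'
#' @param data Logical 3D array.
#' @param vol The source [volume_image()] (geometry is copied).
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, vol) {
  stopifnot(identical(dim(data), dim(vol$data)))
  structure(list(data = data, voxel_size = vol$voxel_size,
                 origin = vol$origin),
            class = "binary_mask")
}

#' Read or write a volume as NIfTI
#'
#' Thin wrappers over the RNifti package carrying the voxel size in the
#' header.
#'
#' @param vol A [volume_image()] or `binary_mask`.
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a [volume_image()].
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data * 1)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  volume_image(array(as.numeric(img), dim(img)),
               voxel_size = RNifti::pixdim(img)[1:3])
}
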