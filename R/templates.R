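#' Construct a network template (z-map on a voxel grid)
#'
#' @param z_map 3D numeric array of z-scores.
#' @param affine 4x4 voxel-to-world transform (0-based voxel indices, m).
#' @param name network name.
#' @return object of class `network_template`.
#' @export
network_template <- function(z_map, affine, name = "network") {
  z_map <- as.array(z_map)
  if (length(dim(z_map)) != 3L || any(dim(z_map) < 4L)) {
    abort("`z_map` must be a 3D array with every dimension >= 4.")
  }
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) ||
      abs(det(affine)) < .Machine$double.eps) {
    abort("`affine` must be an invertible 4x4 matrix.")
  }
  structure(list(z_map = z_map, affine = affine, name = name),
            class = "network_template")
}

#' @export
print.network_template <- function(x, ...) {
  cat(sprintf("<network_template> '%s' %s, max z = %.3g\n", x$name,
              paste(dim(x$z_map), collapse = "x"), max(x$z_map)))
  invisible(x)
}

#' Simple scaling affine for a grid centred on the origin
#'
#' Maps 0-based voxel indices to world coordinates with isotropic or
#' per-axis spacing; voxel (0,0,0) maps to `origin` (a voxel centre).
#'
#' @param spacing voxel size per axis (m), length 1 or 3.
#' @param origin world coordinate of the first voxel centre, length 3.
#' @return 4x4 affine matrix.
#' @export
make_affine <- function(spacing, origin) {
  spacing <- rep_len(spacing, 3L)
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  aff
}

voxel_centers_world <- function(dim3, affine) {
  idx <- as.matrix(expand.grid(i = seq_len(dim3[1]) - 1L,
                               j = seq_len(dim3[2]) - 1L,
                               k = seq_len(dim3[3]) - 1L))
  t(affine %*% rbind(t(idx), 1))[, 1:3, drop = FALSE]
}

#' Build a network template from Gaussian blobs
#'
#' The z-map is a sum of isotropic Gaussian bumps at the given world-space
#' centres, rescaled so its maximum equals `peak_z`.
#'
#' @param grid_shape integer length-3 grid dimensions (each >= 4).
#' @param affine 4x4 voxel-to-world transform.
#' @param blob_centers list (or n x 3 matrix) of blob centres in world
#'   coordinates (m); must lie inside the grid.
#' @param blob_sd Gaussian standard deviation (m).
#' @param peak_z maximum z value (> 0).
#' @param name network name.
#' @return a `network_template`.
#' @export
build_dmn_template <- function(grid_shape, affine, blob_centers,
                               blob_sd = 0.012, peak_z = 6, name = "DMN") {
  if (is.list(blob_centers)) blob_centers <- do.call(rbind, blob_centers)
  blob_centers <- matrix(as.numeric(blob_centers), ncol = 3L)
  if (nrow(blob_centers) == 0L) abort("`blob_centers` must be non-empty.")
  stopifnot_scalar_number(peak_z, "peak_z", positive = TRUE)
  stopifnot_scalar_number(blob_sd, "blob_sd", positive = TRUE)
  grid_shape <- as.integer(grid_shape)

  w <- voxel_centers_world(grid_shape, affine)
  inv <- solve(affine)
  vox <- t(inv %*% rbind(t(blob_centers), 1))[, 1:3, drop = FALSE]
  if (any(vox < -0.5) || any(vox > rep(grid_shape, each = nrow(vox)) - 0.5)) {
    abort("all blob centres must lie inside the grid.")
  }

  z <- numeric(nrow(w))
  for (b in seq_len(nrow(blob_centers))) {
    d2 <- rowSums((w - matrix(blob_centers[b, ], nrow(w), 3,
                              byrow = TRUE))^2)
    z <- z + exp(-d2 / (2 * blob_sd^2))
  }
  z <- z / max(z) * peak_z
  network_template(array(z, dim = grid_shape), affine, name = name)
}

#' Default DMN-like template on the toy head
#'
#' Four gray-matter blobs emulating the canonical DMN topology on the toy
#' head: a medial prefrontal node (anterior), a posterior
#' cingulate/precuneus node, and two lateral parietal nodes, all placed
#' within the cortical gray rind of [build_toy_head_mesh()].
#'
#' @param grid_shape grid dimensions (default 16^3 covering the head).
#' @param peak_z maximum z value.
#' @return a `network_template`.
#' @export
default_dmn_template <- function(grid_shape = c(16L, 16L, 16L), peak_z = 6) {
  spacing <- 2 * HEAD_RADIUS * 1.12 / grid_shape   # ~12% margin around head
  origin <- -(grid_shape - 1) / 2 * spacing
  aff <- make_affine(spacing, origin)
  centers <- rbind(
    c(0.000,  0.055, 0.025),   # medial prefrontal
    c(0.000, -0.045, 0.035),   # posterior cingulate / precuneus
    c(0.050, -0.020, 0.040),   # right lateral parietal
    c(-0.050, -0.020, 0.040)   # left lateral parietal
  )
  build_dmn_template(grid_shape, aff, centers, blob_sd = 0.014,
                     peak_z = peak_z, name = "DMN")
}

#' Control templates accompanying the DMN on the toy head
#'
#' Two further network templates (a "visual" posterior-inferior blob pair
#' and a "sensorimotor" dorsal band) used as nuisance networks in the
#' synthetic resting-state cohorts, sharing the DMN template grid.
#'
#' @param grid_shape grid dimensions.
#' @return list of `network_template`s.
#' @export
default_control_templates <- function(grid_shape = c(16L, 16L, 16L)) {
  spacing <- 2 * HEAD_RADIUS * 1.12 / grid_shape
  origin <- -(grid_shape - 1) / 2 * spacing
  aff <- make_affine(spacing, origin)
  vis <- build_dmn_template(grid_shape, aff,
                            rbind(c(0.025, -0.050, -0.020),
                                  c(-0.025, -0.050, -0.020)),
                            blob_sd = 0.014, peak_z = 6, name = "visual")
  smn <- build_dmn_template(grid_shape, aff,
                            rbind(c(0.045, 0.010, 0.045),
                                  c(-0.045, 0.010, 0.045)),
                            blob_sd = 0.014, peak_z = 6, name = "sensorimotor")
  list(vis, smn)
}

#' Binarize a network template at a z threshold
#'
#' `mask = z_map > z_threshold` (strict), the conventional template-mask
#' construction (z = 3.1 corresponding to p = 0.05).
#'
#' @param template a `network_template`.
#' @param z_threshold z cutoff.
#' @return logical 3D array with the template affine as attribute
#'   `"affine"`.
#' @export
binarize_dmn_template <- function(template, z_threshold = 3.1) {
  stopifnot(inherits(template, "network_template"))
  if (any(!is.finite(template$z_map))) abort("template z-map must be finite.")
  mask <- template$z_map > z_threshold
  attr(mask, "affine") <- template$affine
  mask
}

#' Write / read a volume as NIfTI-1
#'
#' Thin wrappers over RNifti carrying the voxel-to-world affine in the
#' sform. Logical masks are written as 0/1 integers.
#'
#' @param volume 3D array (or `network_template`).
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume_nifti` returns `path` invisibly;
#'   `read_volume_nifti` returns the array with attribute `"affine"`.
#' @export
write_volume_nifti <- function(volume, path) {
  affine <- NULL
  if (inherits(volume, "network_template")) {
    affine <- volume$affine
    volume <- volume$z_map
  } else {
    affine <- attr(volume, "affine")
  }
  if (is.logical(volume)) {
    volume <- array(as.integer(volume), dim = dim(volume))
  }
  img <- RNifti::asNifti(volume)
  if (!is.null(affine)) {
    # pixdim must be set first or the writer re-derives unit voxel sizes
    RNifti::pixdim(img) <- sqrt(colSums(affine[1:3, 1:3]^2))
    RNifti::sform(img) <- structure(affine, code = 2L)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim = dim(img))
  attr(vol, "affine") <- unclass(RNifti::xform(img))
  vol
}
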