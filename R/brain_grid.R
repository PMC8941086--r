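# Voxel grid + grey-matter mask defining the analysis space.
#
# A brain_grid holds a 4x4 world-from-voxel affine (0-based voxel indices,
# NIfTI convention), the volume shape, and a logical mask.  All maps handled
# by the package are vectors over the masked voxels in R's native
# column-major order over the volume ("mask order"); downstream statistics
# (Spearman similarity, clustering) are invariant to this ordering.

#' Construct a brain grid from a mask array and affine
#'
#' @param mask logical or numeric 3-D array; numeric data are thresholded at
#'   `>= 0.5` (probabilistic masks).
#' @param affine 4x4 world-from-voxel affine in mm (0-based voxel indices).
#' @return object of class `brain_grid`.
#' @export
brain_grid <- function(mask, affine) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D volume")
  stopifnot(is.matrix(affine), all(dim(affine) == c(4, 4)))
  if (abs(det(affine)) < 1e-12) stop("affine is not invertible")
  m <- array(as.logical(mask >= 0.5), dim = dim(mask))
  n <- sum(m)
  if (n == 0L) stop("mask is empty: no voxel survives thresholding at 0.5")
  structure(list(
    affine = affine,
    inv_affine = solve(affine),
    shape = as.integer(dim(m)),
    mask = m,
    mask_lin = which(m),                 # 1-based linear indices into volume
    n_mask_voxels = as.integer(n),
    voxel_size = sqrt(colSums(affine[1:3, 1:3]^2)),
    voxel_volume_mm3 = abs(det(affine[1:3, 1:3]))
  ), class = "brain_grid")
}

#' @export
print.brain_grid <- function(x, ...) {
  cat("brain_grid: ", paste(x$shape, collapse = " x "),
      " voxels (", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm), ", x$n_mask_voxels, " in mask\n", sep = "")
  invisible(x)
}

#' Default MNI-like affine for a 2 mm synthetic grid
#'
#' Places the world origin at voxel `(shape - 1) / 2` (0-based), axes
#' aligned, isotropic voxels.
#' @param shape integer(3) volume shape.
#' @param voxel_mm voxel edge length in mm.
#' @return 4x4 affine.
#' @export
centered_affine <- function(shape, voxel_mm = 2) {
  origin <- (shape - 1) / 2
  a <- diag(c(rep(voxel_mm, 3), 1))
  a[1:3, 4] <- -voxel_mm * origin
  a
}

#' Built-in synthetic ellipsoid mask
#'
#' An axis-aligned ellipsoid of grey matter centred on the world origin,
#' used as a self-contained stand-in for an ICBM grey-matter mask.  A voxel
#' is in the mask iff its centre lies inside the ellipsoid.
#'
#' @param semiaxes_mm numeric(3) ellipsoid semi-axes in mm.
#' @param voxel_mm voxel size in mm (default 2, the standard analysis grid).
#' @param margin_mm dead space added around the ellipsoid.
#' @return a `brain_grid`.
#' @export
ellipsoid_grid <- function(semiaxes_mm = c(66, 80, 66), voxel_mm = 2,
                           margin_mm = 4) {
  stopifnot(length(semiaxes_mm) == 3, all(semiaxes_mm > 0))
  half <- ceiling((semiaxes_mm + margin_mm) / voxel_mm)
  shape <- 2L * as.integer(half) + 1L
  affine <- centered_affine(shape, voxel_mm)
  ax <- lapply(1:3, function(k) {
    w <- (seq_len(shape[k]) - 1 - (shape[k] - 1) / 2) * voxel_mm
    (w / semiaxes_mm[k])^2
  })
  q <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  brain_grid(q <= 1, affine)
}

#' Load a grey-matter mask
#'
#' @param source path to a NIfTI mask (binary or probabilistic, thresholded
#'   at 0.5), or the string `"ellipsoid"` for the built-in synthetic mask.
#' @param ... passed to [ellipsoid_grid()] when `source == "ellipsoid"`.
#' @return a `brain_grid`.
#' @export
load_mask <- function(source = "ellipsoid", ...) {
  if (identical(source, "ellipsoid")) {
    g <- ellipsoid_grid(...)
  } else {
    nii <- read_nifti(source)
    if (length(nii$dim) != 3L)
      stop("mask must be a 3-D volume, got ", length(nii$dim), "-D")
    g <- brain_grid(nii$data, nii$affine)
  }
  message("mask loaded: ", g$n_mask_voxels, " in-mask voxels")
  g
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' World (mm) to voxel-index conversion and back
#'
#' Voxel indices are 0-based triplets (NIfTI convention).  `world_to_voxel`
#' rounds to the nearest voxel, halves away from zero; indices outside the
#' volume are returned as-is (callers decide how to treat them).
#'
#' @param grid a `brain_grid`.
#' @param xyz numeric(3) or n x 3 matrix of mm coordinates.
#' @return integer matrix (n x 3) of voxel indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind_coords(xyz)
  v <- t(grid$inv_affine %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
  storage.mode(v) <- "double"
  matrix(as.integer(round_half_away(v)), ncol = 3,
         dimnames = list(NULL, c("i", "j", "k")))
}

#' @rdname world_to_voxel
#' @param ijk integer(3) or n x 3 matrix of 0-based voxel indices.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- rbind_coords(ijk)
  w <- t(grid$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
  colnames(w) <- c("x", "y", "z")
  w
}

rbind_coords <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  stopifnot(ncol(x) == 3)
  x
}

in_volume <- function(grid, ijk) {
  ijk[, 1] >= 0 & ijk[, 1] < grid$shape[1] &
  ijk[, 2] >= 0 & ijk[, 2] < grid$shape[2] &
  ijk[, 3] >= 0 & ijk[, 3] < grid$shape[3]
}

# 1-based linear volume index from 0-based ijk matrix (no bounds check)
ijk_to_lin <- function(grid, ijk) {
  1L + ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3])
}

# position of each volume voxel within the mask vector (0 if outside mask)
mask_positions <- function(grid) {
  pos <- integer(prod(grid$shape))
  pos[grid$mask_lin] <- seq_len(grid$n_mask_voxels)
  pos
}

#' Vector over masked voxels
#'
#' @param grid a `brain_grid`.
#' @param values numeric vector of length `grid$n_mask_voxels`.
#' @return object of class `voxel_map`.
#' @export
voxel_map <- function(grid, values) {
  values <- as.double(values)
  if (length(values) != grid$n_mask_voxels)
    stop("values length ", length(values), " != mask voxel count ",
         grid$n_mask_voxels)
  if (any(!is.finite(values))) stop("voxel_map values must be finite")
  structure(list(grid = grid, values = values), class = "voxel_map")
}

#' Write / read a voxel map as NIfTI
#'
#' Out-of-mask voxels are written as 0.  `read_volume` checks that the file's
#' shape and affine match the grid (affine tolerance 1e-4 mm).
#'
#' @param voxmap a `voxel_map`.
#' @param path NIfTI output path (`.nii` or `.nii.gz`).
#' @return `write_volume`: the path, invisibly; `read_volume`: a `voxel_map`.
#' @export
write_volume <- function(voxmap, path) {
  g <- voxmap$grid
  vol <- array(0, dim = g$shape)
  vol[g$mask_lin] <- voxmap$values
  write_nifti(vol, g$affine, path, datatype = "float64")
}

#' @rdname write_volume
#' @param grid the `brain_grid` the file is expected to live on.
#' @export
read_volume <- function(path, grid) {
  nii <- read_nifti(path)
  if (!identical(as.integer(nii$dim), grid$shape))
    stop("volume shape ", paste(nii$dim, collapse = "x"),
         " does not match grid ", paste(grid$shape, collapse = "x"))
  if (max(abs(nii$affine - grid$affine)) > 1e-4)
    stop("volume affine does not match grid affine")
  voxel_map(grid, nii$data[grid$mask_lin])
}
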