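#' Construct a volume grid
#'
#' A `volume_grid` is the package's image substrate: a 3D scalar or integer
#' label array together with a grid-to-world affine. Voxel indices are
#' 0-based and the affine maps homogeneous voxel coordinates `(i, j, k, 1)`
#' to world coordinates in millimetres, following the NIfTI convention.
#'
#' @param values 3D numeric or integer array.
#' @param affine 4x4 grid-to-world matrix; must be invertible. Defaults to an
#'   identity-spacing grid at the world origin.
#' @param label logical; if `TRUE` the volume is treated as a label volume and
#'   values must be non-negative integers (0 = background). If `NULL`
#'   (default) this is inferred from the storage mode.
#' @return An object of class `volume_grid` with fields `values`, `affine`,
#'   `voxel_size` (mm per axis, the column norms of the linear part) and
#'   `label`.
#' @export
volume_grid <- function(values, affine = NULL, label = NULL) {
  if (length(dim(values)) != 3L)
    stop("values must be a 3D array, got ", length(dim(values)), " dimensions")
  if (is.null(affine)) affine <- diag(4)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (abs(det(affine)) < 1e-12)
    stop("affine is not invertible")
  if (is.null(label)) label <- is.integer(values)
  if (label) {
    v <- as.vector(values)
    if (any(v < 0) || any(v != round(v)))
      stop("label volumes must contain non-negative integers")
    storage.mode(values) <- "integer"
  }
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(
    list(values = values, affine = affine, voxel_size = vs, label = label),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf(
    "<volume_grid> %s voxels, voxel size %s mm%s\n",
    paste(dim(x$values), collapse = "x"),
    paste(signif(x$voxel_size, 4), collapse = "x"),
    if (x$label) sprintf(", label volume (%d labels)",
                         length(setdiff(unique(as.vector(x$values)), 0L)))
    else ""
  ))
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' Voxel volume in cubic millimetres
#' @param grid a `volume_grid`.
#' @return scalar, product of voxel sizes.
#' @export
voxel_volume_mm3 <- function(grid) prod(grid$voxel_size)

#' Read a NIfTI volume
#'
#' Reads a `.nii` / `.nii.gz` file into a [volume_grid()]. Volumes stored with
#' an integer datatype are flagged as label volumes.
#'
#' @param path path to a NIfTI file.
#' @return a `volume_grid`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.vector(img), dim = d[1:3])
    storage.mode(img2) <- storage.mode(img)
    aff <- unclass(RNifti::xform(img))[1:4, 1:4]
    return(volume_grid(img2, aff))
  }
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), " dimensions in ", path)
  aff <- unclass(RNifti::xform(img))[1:4, 1:4]
  vals <- array(as.vector(img), dim = d)
  if (storage.mode(img) == "integer") storage.mode(vals) <- "integer"
  volume_grid(vals, aff)
}

#' Write a volume grid to NIfTI
#'
#' @param grid a `volume_grid`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$voxel_size
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 2L))
  dtype <- if (grid$label) "int32" else "double"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Map world-space points to voxel indices
#'
#' Points are assigned to the voxel whose centre is nearest under the
#' half-open convention: a point with continuous voxel coordinate `v` on an
#' axis belongs to index `floor(v + 0.5)`, so a point exactly half a voxel
#' above a centre belongs to the higher-index voxel. Points outside the grid
#' map to `NA`.
#'
#' @param points numeric matrix (n x 3) of world coordinates in mm, or a
#'   length-3 vector for a single point.
#' @param grid a `volume_grid`.
#' @return integer matrix (n x 3) of 0-based voxel indices, with `NA` rows for
#'   points outside the grid.
#' @export
point_to_voxel <- function(points, grid) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  v <- world_to_voxel(points, grid)
  idx <- floor(v + 0.5)
  d <- dim(grid$values)
  bad <- idx[, 1] < 0 | idx[, 1] >= d[1] |
         idx[, 2] < 0 | idx[, 2] >= d[2] |
         idx[, 3] < 0 | idx[, 3] >= d[3]
  idx[bad, ] <- NA_integer_
  storage.mode(idx) <- "integer"
  idx
}

#' Continuous voxel coordinates of world points (0-based)
#' @keywords internal
world_to_voxel <- function(points, grid) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  inv <- solve(grid$affine)
  h <- cbind(points, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

#' World coordinates of (continuous) 0-based voxel coordinates
#' @keywords internal
voxel_to_world <- function(voxels, grid) {
  if (is.null(dim(voxels))) voxels <- matrix(voxels, ncol = 3)
  h <- cbind(voxels, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

#' Convert 0-based voxel index triplets to linear array indices
#' @keywords internal
voxel_linear_index <- function(idx, dims) {
  1L + idx[, 1] + dims[1] * (idx[, 2] + dims[2] * idx[, 3])
}

#' Create a binary lesion mask
#'
#' Wraps a `volume_grid` with values in \{0, 1\}; any nonzero input voxel is
#' treated as lesioned (binarisation is idempotent).
#'
#' @param grid a `volume_grid` (any nonzero value counts as lesion).
#' @return a `lesion_mask`: a `volume_grid` with an added `lesion_volume_cc`
#'   field (voxel count x voxel volume / 1000).
#' @export
lesion_mask <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  vals <- array(as.integer(grid$values != 0), dim = dim(grid$values))
  g <- volume_grid(vals, grid$affine, label = TRUE)
  g$lesion_volume_cc <- sum(vals) * voxel_volume_mm3(g) / 1000
  class(g) <- c("lesion_mask", "volume_grid")
  g
}

#' Lesion volume in cubic centimetres
#' @param mask a `lesion_mask` or binary `volume_grid`.
#' @return lesion volume in cc.
#' @export
lesion_volume_cc <- function(mask) {
  if (!is.null(mask$lesion_volume_cc)) return(mask$lesion_volume_cc)
  sum(mask$values != 0) * voxel_volume_mm3(mask) / 1000
}

#' Check that two grids share shape and affine
#' @keywords internal
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a$values), dim(b$values)) ||
      max(abs(a$affine - b$affine)) > 1e-6)
    stop(what, " are not on the same grid")
  invisible(TRUE)
}
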