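#' Voxels traversed by a streamline
#'
#' Computes the exact set of voxels whose cells are intersected by any
#' segment of the polyline, by incremental grid traversal: each segment is
#' parameterised and every crossing of a voxel face is located analytically,
#' so the visited cell sequence is exact (no sampling). Voxel cells follow the
#' half-open nearest-centre convention of [point_to_voxel()]; voxels of both
#' endpoints are included. Voxels outside the grid are dropped.
#'
#' @param streamline numeric matrix (n x 2+ points x 3) of world-mm points.
#' @param grid a [volume_grid()].
#' @return integer matrix (m x 3) of 0-based voxel indices, unique, in order
#'   of first traversal.
#' @export
streamline_traversal <- function(streamline, grid) {
  streamline <- as.matrix(streamline)
  if (nrow(streamline) < 2L) stop("a streamline needs at least 2 points")
  s <- world_to_voxel(streamline, grid) + 0.5  # cell i occupies [i, i+1)
  d <- dim(grid$values)
  if (any(rowSums(diff(s)^2) == 0))
    warning("zero-length segment skipped")
  cells <- .traverse_cells(s)
  if (nrow(cells) == 0L) return(matrix(integer(0), 0, 3))
  keep <- cells[, 1] >= 0 & cells[, 1] < d[1] &
          cells[, 2] >= 0 & cells[, 2] < d[2] &
          cells[, 3] >= 0 & cells[, 3] < d[3]
  cells <- cells[keep, , drop = FALSE]
  cells <- cells[!duplicated(cells), , drop = FALSE]
  storage.mode(cells) <- "integer"
  cells
}

#' Traversed voxels of every streamline, as linear indices
#'
#' Convenience wrapper used throughout the pipeline: traversals depend only
#' on the (static) tractogram and grid, so they are computed once and reused
#' across lesions.
#'
#' @param trac a [tractogram()].
#' @param grid a [volume_grid()].
#' @return list of integer vectors; element i holds 1-based linear indices
#'   into `grid$values` for streamline i.
#' @export
tractogram_traversal <- function(trac, grid) {
  d <- dim(grid$values)
  lapply(trac$streamlines, function(s) {
    idx <- streamline_traversal(s, grid)
    if (nrow(idx) == 0L) integer(0) else voxel_linear_index(idx, d)
  })
}
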