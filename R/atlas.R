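#' Construct a parcel atlas
#'
#' Bundles a label volume with a parcel table (id, name, world-mm centroid,
#' voxel volume) and named ROI subsets such as a language network. If the
#' parcel table is omitted it is derived from the label volume (centroid =
#' mean world coordinate of member voxels).
#'
#' @param vol a label [volume_grid()] (0 = background).
#' @param parcels optional data.frame with columns `id`, `name`, `cx`, `cy`,
#'   `cz`, `volume_vox`.
#' @param roi_subsets named list of integer vectors of parcel ids.
#' @return an object of class `parcel_atlas`.
#' @export
parcel_atlas <- function(vol, parcels = NULL, roi_subsets = list()) {
  stopifnot(inherits(vol, "volume_grid"))
  if (!vol$label) stop("atlas volume must be a label volume")
  labs <- sort(setdiff(unique(as.vector(vol$values)), 0L))
  if (is.null(parcels)) {
    d <- dim(vol$values)
    idx <- which(vol$values != 0L)
    lab <- vol$values[idx]
    i0 <- (idx - 1L) %% d[1]
    j0 <- ((idx - 1L) %/% d[1]) %% d[2]
    k0 <- (idx - 1L) %/% (d[1] * d[2])
    w <- voxel_to_world(cbind(i0, j0, k0), vol)
    parcels <- data.frame(
      id = labs,
      name = sprintf("parcel_%03d", labs),
      cx = tapply(w[, 1], lab, mean)[as.character(labs)],
      cy = tapply(w[, 2], lab, mean)[as.character(labs)],
      cz = tapply(w[, 3], lab, mean)[as.character(labs)],
      volume_vox = as.integer(table(lab)[as.character(labs)]),
      row.names = NULL
    )
  }
  if (!setequal(parcels$id, labs))
    stop("parcel table does not match the labels present in the volume")
  for (nm in names(roi_subsets)) {
    if (!all(roi_subsets[[nm]] %in% parcels$id))
      stop("ROI subset '", nm, "' references unknown parcel ids")
  }
  structure(list(vol = vol, parcels = parcels, roi_subsets = roi_subsets),
            class = "parcel_atlas")
}

#' @export
print.parcel_atlas <- function(x, ...) {
  cat(sprintf("<parcel_atlas> %d parcels, ROI subsets: %s\n",
              nrow(x$parcels),
              if (length(x$roi_subsets))
                paste(sprintf("%s (%d)", names(x$roi_subsets),
                              lengths(x$roi_subsets)), collapse = ", ")
              else "none"))
  invisible(x)
}

#' Parcel ids of a named ROI subset
#' @param atlas a `parcel_atlas`.
#' @param roi_name subset name, e.g. `"language"`.
#' @return integer vector of parcel ids.
#' @export
roi_parcels <- function(atlas, roi_name) {
  if (!roi_name %in% names(atlas$roi_subsets))
    stop("unknown ROI subset: ", roi_name)
  atlas$roi_subsets[[roi_name]]
}

#' Define a tract
#'
#' A tract couples a name, a binary voxel mask and its member streamlines.
#'
#' @param name tract name (e.g. `"AF"`).
#' @param mask binary [volume_grid()]; must be nonempty.
#' @param streamlines list of streamline matrices belonging to this bundle.
#' @return an object of class `tract_definition`.
#' @export
tract_definition <- function(name, mask, streamlines) {
  stopifnot(inherits(mask, "volume_grid"))
  if (!any(mask$values != 0)) stop("tract '", name, "' has an empty mask")
  structure(list(name = name, mask = mask, streamlines = streamlines),
            class = "tract_definition")
}
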