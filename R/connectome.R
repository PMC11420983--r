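#' Construct a connectome
#'
#' A symmetric non-negative node x node weight matrix tagged by approach
#' (`direct` = from tractography, `indirect` = atlas streamlines filtered by
#' a lesion mask) and scale (`whole` brain or `roi` subset).
#'
#' @param weights symmetric non-negative matrix, zero diagonal; dimnames are
#'   parcel ids.
#' @param approach `"direct"` or `"indirect"`.
#' @param scale `"whole"` or `"roi"`.
#' @return an object of class `connectome`.
#' @export
connectome <- function(weights, approach = c("direct", "indirect"),
                       scale = c("whole", "roi")) {
  approach <- match.arg(approach)
  scale <- match.arg(scale)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weight matrix must be square")
  if (max(abs(weights - t(weights))) > 1e-8)
    stop("weight matrix must be symmetric")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(diag(weights) != 0)) stop("diagonal must be zero")
  weights <- (weights + t(weights)) / 2  # make symmetry exact
  if (is.null(rownames(weights)))
    dimnames(weights) <- list(seq_len(nrow(weights)), seq_len(nrow(weights)))
  structure(list(weights = weights, node_ids = rownames(weights),
                 approach = approach, scale = scale),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d nodes, %s/%s, %d nonzero edges\n",
              nrow(x$weights), x$approach, x$scale,
              sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Assign streamline endpoints to parcels
#'
#' Uses the "end" criterion: each endpoint maps to the atlas label at its
#' voxel (0 or out-of-grid gives `NA`). Streamlines with a missing endpoint
#' or both endpoints in the same parcel contribute to no edge.
#'
#' @param trac a [tractogram()].
#' @param atlas a [parcel_atlas()] on the same grid.
#' @return data.frame with columns `streamline`, `parcel_a`, `parcel_b`.
#' @export
assign_endpoints <- function(trac, atlas) {
  firsts <- t(vapply(trac$streamlines, function(s) s[1, ], numeric(3)))
  lasts <- t(vapply(trac$streamlines, function(s) s[nrow(s), ], numeric(3)))
  lab <- function(pts) {
    idx <- point_to_voxel(pts, atlas$vol)
    ok <- stats::complete.cases(idx)
    out <- rep(NA_integer_, nrow(pts))
    lin <- voxel_linear_index(idx[ok, , drop = FALSE], dim(atlas$vol$values))
    v <- atlas$vol$values[lin]
    v[v == 0L] <- NA_integer_
    out[ok] <- v
    out
  }
  data.frame(streamline = seq_along(trac$streamlines),
             parcel_a = lab(firsts), parcel_b = lab(lasts))
}

# Accumulate streamline counts into a symmetric parcel x parcel matrix.
count_matrix <- function(ends, parcel_ids, keep = NULL) {
  n <- length(parcel_ids)
  W <- matrix(0, n, n, dimnames = list(parcel_ids, parcel_ids))
  sel <- !is.na(ends$parcel_a) & !is.na(ends$parcel_b) &
    ends$parcel_a != ends$parcel_b
  if (!is.null(keep)) sel <- sel & keep
  if (any(sel)) {
    ia <- match(ends$parcel_a[sel], parcel_ids)
    ib <- match(ends$parcel_b[sel], parcel_ids)
    for (s in seq_along(ia)) {
      W[ia[s], ib[s]] <- W[ia[s], ib[s]] + 1
      W[ib[s], ia[s]] <- W[ib[s], ia[s]] + 1
    }
  }
  W
}

#' Direct (tractography-based) parcel connectome
#'
#' Streamline counts per unordered parcel pair, optionally corrected for
#' parcel distance and volume: `w_ij = count_ij * d_ij / sqrt(v_i * v_j)`
#' with `d_ij` the centroid distance in mm and `v` the parcel volume in
#' voxels. The exact correction applied by probabilistic-tractography
#' toolchains is tool-specific, so it is exposed as a switch.
#'
#' @param trac the participant's [tractogram()].
#' @param atlas a [parcel_atlas()] (needs >= 2 parcels).
#' @param correction `"off"` (raw counts), `"full"` (distance and volume) or
#'   `"volume"` (volume only).
#' @return a [connectome()] tagged direct/whole.
#' @export
direct_connectome <- function(trac, atlas,
                              correction = c("off", "full", "volume")) {
  correction <- match.arg(correction)
  if (nrow(atlas$parcels) < 2) stop("atlas needs at least 2 parcels")
  ends <- assign_endpoints(trac, atlas)
  W <- count_matrix(ends, atlas$parcels$id)
  W <- apply_correction(W, atlas, correction)
  connectome(W, "direct", "whole")
}

apply_correction <- function(W, atlas, correction) {
  if (correction == "off") return(W)
  v <- atlas$parcels$volume_vox
  vol_fac <- 1 / sqrt(outer(v, v))
  if (correction == "volume") {
    W <- W * vol_fac
  } else {
    cen <- as.matrix(atlas$parcels[, c("cx", "cy", "cz")])
    d <- as.matrix(stats::dist(cen))
    W <- W * d * vol_fac
  }
  diag(W) <- 0
  W
}

#' Indirect (lesion-filtered) parcel connectome
#'
#' Overlays the lesion on the atlas tractogram, removes every streamline
#' whose traversal passes through the lesion, and counts the preserved
#' streamlines per parcel pair. With an empty lesion this equals the
#' lesion-free count connectome (correction off).
#'
#' @param trac atlas [tractogram()].
#' @param lesion a [lesion_mask()] on the atlas grid.
#' @param atlas a [parcel_atlas()].
#' @param traversal optional precomputed [tractogram_traversal()] list.
#' @param ends optional precomputed [assign_endpoints()] table.
#' @return a [connectome()] tagged indirect/whole.
#' @export
indirect_connectome <- function(trac, lesion, atlas, traversal = NULL,
                                ends = NULL) {
  check_same_grid(atlas$vol, lesion, "atlas and lesion")
  if (is.null(traversal)) traversal <- tractogram_traversal(trac, atlas$vol)
  if (is.null(ends)) ends <- assign_endpoints(trac, atlas)
  lesioned <- lesion$values != 0
  preserved <- vapply(traversal, function(ix) !any(lesioned[ix]), logical(1))
  clsm_log("indirect connectome: %d/%d streamlines preserved",
           sum(preserved), length(preserved))
  W <- count_matrix(ends, atlas$parcels$id, keep = preserved)
  connectome(W, "indirect", "whole")
}

#' Subset a connectome to a named ROI
#'
#' Principal submatrix on the ROI's parcels, order preserved; the scale tag
#' becomes `"roi"`.
#'
#' @param conn a [connectome()].
#' @param atlas the [parcel_atlas()] defining ROI subsets.
#' @param roi_name subset name (e.g. `"language"`).
#' @return a [connectome()] on the ROI nodes.
#' @export
subset_connectome <- function(conn, atlas, roi_name) {
  ids <- as.character(roi_parcels(atlas, roi_name))
  missing_ids <- setdiff(ids, conn$node_ids)
  if (length(missing_ids))
    stop("connectome lacks ROI nodes: ", paste(missing_ids, collapse = ", "))
  keep <- ids[order(match(ids, conn$node_ids))]
  connectome(conn$weights[keep, keep, drop = FALSE], conn$approach, "roi")
}

#' Percent-disconnection matrix
#'
#' Convenience output derived from an indirect connectome: percent of the
#' lesion-free streamline count lost per edge.
#'
#' @param indirect a [connectome()] of preserved counts.
#' @param intact the lesion-free count [connectome()].
#' @return matrix of percents in [0, 100] (`NA` where the intact count is 0).
#' @export
percent_disconnection <- function(indirect, intact) {
  W0 <- intact$weights
  W1 <- indirect$weights
  out <- 100 * (W0 - W1) / W0
  out[W0 == 0] <- NA_real_
  diag(out) <- 0
  out
}
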