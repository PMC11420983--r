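#' Lesion percentage of a tract
#'
#' Percent of the tract's voxels that fall inside the lesion mask.
#'
#' @param tract a [tract_definition()].
#' @param lesion a [lesion_mask()] on the same grid.
#' @return percent in [0, 100].
#' @export
lesion_percentage <- function(tract, lesion) {
  check_same_grid(tract$mask, lesion, "tract mask and lesion")
  n_tract <- sum(tract$mask$values != 0)
  if (n_tract == 0) stop("tract '", tract$name, "' has an empty mask")
  100 * sum(tract$mask$values != 0 & lesion$values != 0) / n_tract
}

#' Disconnection percentage of a tract
#'
#' Percent of the tract's streamlines whose voxel traversal passes through
#' the lesion (binary pass criterion: one lesioned voxel on the path severs
#' the streamline).
#'
#' @param tract a [tract_definition()].
#' @param lesion a [lesion_mask()] on the tract's grid.
#' @param traversal optional precomputed list of linear-index traversals for
#'   the tract's streamlines (from [tractogram_traversal()]); computed here
#'   if missing.
#' @return percent in [0, 100].
#' @export
disconnection_percentage <- function(tract, lesion, traversal = NULL) {
  if (length(tract$streamlines) == 0L)
    stop("tract '", tract$name, "' has no streamlines")
  if (is.null(traversal))
    traversal <- tractogram_traversal(
      tractogram(tract$streamlines), tract$mask)
  lesioned <- lesion$values != 0
  severed <- vapply(traversal, function(ix) any(lesioned[ix]), logical(1))
  100 * sum(severed) / length(severed)
}

#' Mean of a scalar map over a tract
#'
#' Arithmetic mean of the map (FA, MD, AD or RD) over the tract's voxels.
#'
#' @param tract a [tract_definition()].
#' @param scalar_map a [volume_grid()] on the same grid.
#' @return scalar mean.
#' @export
mean_scalar <- function(tract, scalar_map) {
  check_same_grid(tract$mask, scalar_map, "tract mask and scalar map")
  sel <- tract$mask$values != 0
  if (!any(sel)) stop("tract '", tract$name, "' has an empty mask")
  mean(scalar_map$values[sel])
}

#' Tract volume in cubic millimetres
#'
#' Number of tract voxels times the voxel volume.
#'
#' @param tract a [tract_definition()].
#' @return volume in mm^3 (0 for an empty mask).
#' @export
tract_volume <- function(tract) {
  sum(tract$mask$values != 0) * voxel_volume_mm3(tract$mask)
}

#' Tract metric names
#' @keywords internal
TRACT_METRICS <- c("VOL", "SN", "FA", "MD", "AD", "RD", "DP", "LP")

#' Build the participants x (tract, metric) matrix
#'
#' Computes the eight tract metrics — direct VOL (mm^3), SN (streamline
#' count), FA, MD, AD, RD, and indirect DP, LP (percent) — for every
#' participant and tract of a synthetic cohort. Direct metrics emulate
#' per-participant tractography: by default they are measured on the
#' post-lesion bundle (severed streamlines removed, mask recomputed), and are
#' missing (`NA`) where the tract is fully disconnected. Indirect metrics are
#' always present.
#'
#' @param cohort a `clsm_cohort` from [make_cohort()].
#' @param direct_on `"postlesion"` (default: severed streamlines removed
#'   before measuring) or `"atlas"` (measure the intact atlas bundle).
#' @param dp_denominator `"atlas"` (default: the atlas bundle's streamline
#'   count) or `"participant"` (the participant-specific surviving count,
#'   which by construction makes DP 0 or 100 only through full
#'   disconnection).
#' @return data.frame with `participant` plus one numeric column per
#'   `<tract>_<metric>` pair (wide layout; use [metric_long()] to pivot).
#' @export
build_metric_matrix <- function(cohort,
                                direct_on = c("postlesion", "atlas"),
                                dp_denominator = c("atlas", "participant")) {
  direct_on <- match.arg(direct_on)
  dp_denominator <- match.arg(dp_denominator)
  tracts <- cohort$tracts
  grid <- cohort$atlas$vol
  d <- dim(grid$values)
  tr_trav <- lapply(tracts, function(tr)
    cohort$traversal[tr$streamline_idx])
  n <- nrow(cohort$participants)
  cols <- as.vector(outer(TRACT_METRICS, names(tracts),
                          function(m, t) paste0(t, "_", m)))
  out <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  vox_vol <- voxel_volume_mm3(grid)
  for (p in seq_len(n)) {
    lesion <- cohort$lesions[[p]]
    lesioned <- lesion$values != 0
    maps <- make_scalar_maps(tracts, lesion, cohort$spec$scalars,
                             seed = cohort$spec$seed + 1000L + p)
    for (tn in names(tracts)) {
      tr <- tracts[[tn]]
      trav <- tr_trav[[tn]]
      severed <- vapply(trav, function(ix) any(lesioned[ix]), logical(1))
      n_atlas <- length(trav)
      n_kept <- sum(!severed)
      # in the synthetic cohort the participant bundle is the surviving subset,
      # so both denominator conventions give severed + kept = atlas count
      dp_den <- if (dp_denominator == "atlas") n_atlas else sum(severed) + n_kept
      out[p, paste0(tn, "_DP")] <- 100 * sum(severed) / dp_den
      out[p, paste0(tn, "_LP")] <- 100 * sum(lesioned[tr$voxels]) /
        length(tr$voxels)
      if (n_kept == 0L) {
        clsm_log("participant %s: tract %s fully disconnected, direct metrics missing",
                 cohort$participants$id[p], tn)
        next
      }
      # post-lesion bundle: severed streamlines removed, mask recomputed
      kept_vox <- if (direct_on == "postlesion") unique(unlist(trav[!severed]))
                  else tr$voxels
      out[p, paste0(tn, "_SN")] <- if (direct_on == "postlesion") n_kept
                                   else n_atlas
      out[p, paste0(tn, "_VOL")] <- length(kept_vox) * vox_vol
      for (sc in c("FA", "MD", "AD", "RD"))
        out[p, paste0(tn, "_", sc)] <- mean(maps[[sc]]$values[kept_vox])
    }
  }
  data.frame(participant = cohort$participants$id, out,
             check.names = FALSE)
}

#' Pivot a wide metric matrix to long format
#'
#' @param metrics wide data.frame from [build_metric_matrix()].
#' @return data.frame with columns `participant`, `tract`, `metric`, `value`.
#' @export
metric_long <- function(metrics) {
  cols <- setdiff(names(metrics), "participant")
  parts <- strsplit(cols, "_", fixed = TRUE)
  data.frame(
    participant = rep(metrics$participant, times = length(cols)),
    tract = rep(vapply(parts, `[`, "", 1L), each = nrow(metrics)),
    metric = rep(vapply(parts, `[`, "", 2L), each = nrow(metrics)),
    value = unlist(metrics[cols], use.names = FALSE)
  )
}
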