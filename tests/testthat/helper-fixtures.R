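# Shared fixtures. Heavy objects are built lazily and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# anisotropic grid mirroring a realistic DWI protocol voxel size
aniso_grid <- function(dims = c(20L, 20L, 20L)) {
  aff <- diag(c(1.9, 1.9, 2.38, 1))
  aff[1:3, 4] <- c(-9, -9, -11)
  volume_grid(array(0L, dims), aff)
}

unit_grid <- function(dims = c(16L, 16L, 16L)) {
  volume_grid(array(0L, dims), diag(4))
}

# small cohort: cheap enough to build in a couple of seconds
small_spec <- function(seed = 11, n = 10, ...) {
  cohort_spec(n = n, grid_dim = c(32L, 32L, 32L), voxel_size = c(2, 2, 2),
              n_parcels = 24, roi_size = 6, streamlines_per_bundle = 12,
              n_background = 80,
              lesion = list(meanlog = log(12), sdlog = 0.5,
                            range_cc = c(1, 40)),
              seed = seed, ...)
}

small_cohort <- function() {
  cached("small_cohort", function() suppressWarnings(make_cohort(small_spec())))
}

# paper-scale default cohort (n = 50, 166 parcels)
default_cohort <- function() {
  cached("default_cohort",
         function() suppressWarnings(make_cohort(cohort_spec(seed = 42))))
}

# build a tract_definition from explicit voxel triplets (0-based) on a grid
tract_from_voxels <- function(vox, grid, streamlines = NULL, name = "T") {
  vals <- array(0L, dim(grid$values))
  vals[vox[, 1] + 1L + dim(grid$values)[1] *
         (vox[, 2] + dim(grid$values)[2] * vox[, 3])] <- 1L
  if (is.null(streamlines)) {
    p0 <- clsmverse:::voxel_to_world(vox[1, , drop = FALSE], grid)
    streamlines <- list(rbind(p0 - 0.1 * grid$voxel_size,
                              p0 + 0.1 * grid$voxel_size))
  }
  td <- tract_definition(name, volume_grid(vals, grid$affine, label = TRUE),
                         streamlines)
  td$voxels <- clsmverse:::voxel_linear_index(vox, dim(grid$values))
  td
}

# lesion mask from explicit 0-based voxel triplets
lesion_from_voxels <- function(vox, grid) {
  vals <- array(0L, dim(grid$values))
  if (nrow(vox) > 0)
    vals[clsmverse:::voxel_linear_index(vox, dim(grid$values))] <- 1L
  lesion_mask(volume_grid(vals, grid$affine, label = TRUE))
}

# random symmetric non-negative weight matrix with zero diagonal
random_weights <- function(n, density = 0.5, names = TRUE) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  W[ut] <- stats::runif(sum(ut)) * stats::rbinom(sum(ut), 1, density)
  W <- W + t(W)
  if (names) dimnames(W) <- list(seq_len(n), seq_len(n))
  W
}

# supersampling classifier: points every min(voxel)/20 along the segment
supersample_voxels <- function(seg, grid, step_frac = 20) {
  len <- sqrt(sum((seg[2, ] - seg[1, ])^2))
  npt <- max(2L, ceiling(len / (min(grid$voxel_size) / step_frac)))
  t <- seq(0, 1, length.out = npt)
  pts <- cbind(seg[1, 1] + t * (seg[2, 1] - seg[1, 1]),
               seg[1, 2] + t * (seg[2, 2] - seg[1, 2]),
               seg[1, 3] + t * (seg[2, 3] - seg[1, 3]))
  v <- point_to_voxel(pts, grid)
  v <- v[stats::complete.cases(v), , drop = FALSE]
  unique(v)
}

# exact independent oracle: clip the segment against every cell AABB in the
# segment's bounding box (Liang-Barsky in continuous voxel coordinates)
clip_oracle_voxels <- function(seg, grid) {
  s <- clsmverse:::world_to_voxel(seg, grid) + 0.5
  d <- dim(grid$values)
  lo <- pmax(floor(pmin(s[1, ], s[2, ])) - 1, 0)
  hi <- pmin(floor(pmax(s[1, ], s[2, ])) + 1, d - 1)
  if (any(lo > hi)) return(matrix(integer(0), 0, 3))
  cells <- as.matrix(expand.grid(seq.int(lo[1], hi[1]),
                                 seq.int(lo[2], hi[2]),
                                 seq.int(lo[3], hi[3])))
  p0 <- s[1, ]; dir <- s[2, ] - s[1, ]
  keep <- logical(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    t0 <- 0; t1 <- 1; ok <- TRUE
    for (a in 1:3) {
      cmin <- cells[i, a]; cmax <- cells[i, a] + 1
      if (dir[a] == 0) {
        if (p0[a] < cmin || p0[a] >= cmax) { ok <- FALSE; break }
      } else {
        ta <- (cmin - p0[a]) / dir[a]; tb <- (cmax - p0[a]) / dir[a]
        if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
        t0 <- max(t0, ta); t1 <- min(t1, tb)
        if (t0 > t1) { ok <- FALSE; break }
      }
    }
    keep[i] <- ok && t1 > t0
  }
  out <- cells[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  unname(out)
}

sort_rows <- function(m) {
  if (nrow(m) == 0) return(unname(m))
  unname(m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE])
}

# all set partitions of n elements (restricted growth strings)
all_partitions <- function(n) {
  parts <- list()
  rec <- function(s, mx) {
    if (length(s) == n) {
      parts[[length(parts) + 1L]] <<- s
      return(invisible(NULL))
    }
    for (v in seq_len(mx + 1L)) rec(c(s, v), max(mx, v))
  }
  rec(1L, 1L)
  parts
}
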