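test_that("atlas generation packs the requested parcels and is deterministic", {
  spec <- small_spec()
  a1 <- make_atlas(spec)
  labs <- setdiff(unique(as.vector(a1$vol$values)), 0L)
  expect_length(labs, 24)
  expect_setequal(a1$parcels$id, labs)
  expect_length(roi_parcels(a1, "language"), 6)
  a2 <- make_atlas(spec)
  expect_identical(a1$vol$values, a2$vol$values)

  # a 166-parcel atlas (whole-brain scale) fits the default grid
  big <- make_atlas(cohort_spec(seed = 5))
  expect_length(setdiff(unique(as.vector(big$vol$values)), 0L), 166)
  expect_length(roi_parcels(big, "language"), 14)

  # two parcels in a small grid: disjoint by construction
  tiny <- make_atlas(cohort_spec(n = 4, grid_dim = c(20L, 20L, 20L),
                                 n_parcels = 2, roi_size = 2, seed = 3))
  expect_length(setdiff(unique(as.vector(tiny$vol$values)), 0L), 2)

  # impossible packing errors out
  expect_error(make_atlas(cohort_spec(n = 4, grid_dim = c(12L, 12L, 12L),
                                      n_parcels = 500, roi_size = 2,
                                      seed = 1)),
               "packed")
})

test_that("bundle streamlines start and end inside their endpoint parcels", {
  co <- small_cohort()
  ends <- co$endpoints
  for (tn in names(co$tracts)) {
    ix <- co$tracts[[tn]]$streamline_idx
    pair <- co$endpoint_pairs[[tn]]
    expect_true(all(ends$parcel_a[ix] %in% pair))
    expect_true(all(ends$parcel_b[ix] %in% pair))
    expect_true(all(ends$parcel_a[ix] != ends$parcel_b[ix]))
  }
})

test_that("tract masks contain every voxel traversed by member streamlines", {
  co <- small_cohort()
  for (tn in names(co$tracts)) {
    tr <- co$tracts[[tn]]
    trav <- unique(unlist(co$traversal[tr$streamline_idx]))
    expect_true(all(tr$mask$values[trav] == 1L))
  }
})

test_that("lesion-free direct connectome reproduces the bundle design counts", {
  co <- small_cohort()
  conn <- direct_connectome(co$trac, co$atlas, correction = "off")
  for (tn in names(co$tracts)) {
    pair <- as.character(co$endpoint_pairs[[tn]])
    # at least the bundle's own streamlines connect the pair
    expect_gte(conn$weights[pair[1], pair[2]],
               co$spec$streamlines_per_bundle)
  }
  expect_equal(sum(conn$weights) / 2,
               sum(!is.na(co$endpoints$parcel_a) &
                     !is.na(co$endpoints$parcel_b) &
                     co$endpoints$parcel_a != co$endpoints$parcel_b))
})

test_that("synthetic lesions match the analytic sphere volume and are seeded", {
  spec <- small_spec()
  atlas <- make_atlas(spec)
  grid <- atlas$vol
  # a rasterized sphere of radius r >= 5 voxels is within 15% of (4/3) pi r^3
  for (r in c(10, 14, 20)) {
    ix <- clsmverse:::sphere_voxels(c(32, 32, 32), r, grid)
    vol <- length(ix) * voxel_volume_mm3(grid)
    expect_lt(abs(vol - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.15)
  }
  # radius ~0 gives at most one voxel
  expect_lte(length(clsmverse:::sphere_voxels(c(32, 32, 32), 1e-6, grid)), 1)
  l1 <- make_lesion(atlas, spec$lesion, spec, seed = 99)
  l2 <- make_lesion(atlas, spec$lesion, spec, seed = 99)
  expect_identical(l1$values, l2$values)
  expect_gte(lesion_volume_cc(l1), 0)
})

test_that("scalar maps degrade inside the lesion and stay in physical range", {
  spec <- small_spec()
  atlas <- make_atlas(spec)
  bnd <- make_bundles(atlas, spec)
  d <- dim(atlas$vol$values)
  empty <- lesion_from_voxels(matrix(integer(0), 0, 3), atlas$vol)
  maps0 <- make_scalar_maps(bnd$tracts, empty, spec$scalars, seed = 1)
  fa0 <- mean_scalar(bnd$tracts[[1]], maps0$FA)
  # no lesion: tract-mean FA within a few noise SEs of the healthy mean
  n_vox <- length(bnd$tracts[[1]]$voxels)
  expect_lt(abs(fa0 - spec$scalars$FA$healthy),
            4 * spec$scalars$FA$sd / sqrt(n_vox))
  # lesion covering the tract: FA drops, MD rises
  all_vox <- which(bnd$tracts[[1]]$mask$values == 1L)
  vals <- array(0L, d); vals[all_vox] <- 1L
  cover <- lesion_mask(volume_grid(vals, atlas$vol$affine, label = TRUE))
  maps1 <- make_scalar_maps(bnd$tracts, cover, spec$scalars, seed = 2)
  expect_lt(mean_scalar(bnd$tracts[[1]], maps1$FA), fa0)
  expect_gt(mean_scalar(bnd$tracts[[1]], maps1$MD),
            mean_scalar(bnd$tracts[[1]], maps0$MD))
  expect_true(all(maps1$FA$values >= 0 & maps1$FA$values <= 1))
  expect_true(all(maps1$MD$values >= 0))
})

test_that("cohort generation is a pure function of the spec and seed", {
  co1 <- small_cohort()
  co2 <- suppressWarnings(make_cohort(small_spec()))
  expect_identical(co1$participants, co2$participants)
  expect_identical(co1$metrics, co2$metrics)
  expect_identical(co1$lesions[[3]]$values, co2$lesions[[3]]$values)
  # writing a cohort produces a complete text/NIfTI directory
  dir <- withr::local_tempdir()
  write_cohort(co1, dir)
  expect_true(file.exists(file.path(dir, "participants.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  expect_true(file.exists(file.path(dir, "atlas.nii.gz")))
  tsv <- read.delim(file.path(dir, "participants.tsv"))
  expect_equal(nrow(tsv), 10)
  back <- read_volume(file.path(dir, "lesions", "sub-03_lesion.nii.gz"))
  expect_identical(back$values, co1$lesions[[3]]$values)
})

test_that("a null cohort decorrelates the target metric residual from behaviour", {
  # beta = 0: after regressing out lesion size and scanner, the metric
  # carries no information about naming
  # small-grid lesions are small in cc, so steepen the volume slope to keep
  # the lesion-behaviour confound visible at this scale
  co <- suppressWarnings(make_cohort(small_spec(
    seed = 31, n = 60,
    # the intercept is the expected score at the 91 cc reference volume;
    # with ~12 cc lesions this puts the cohort mean near 35
    behavior = list(naming = list(mean = -60, b_size = -1.2, sd = 10,
                                  max = 60)))))
  p <- co$participants
  expect_lt(cor(p$lesion_cc, p$naming), -0.1)
  m <- co$metrics$AF_LP
  rm_ <- residualize(m, p$lesion_cc, p$scanner)
  ry <- residualize(p$naming, p$lesion_cc, p$scanner)
  expect_lt(abs(cor(rm_, ry)), 0.35)  # ~2.6 SE at n = 60
})

test_that("cohort configs load from YAML and JSON with defaults preserved", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n: 12", "n_parcels: 30", "roi_size: 5", "seed: 9"), f)
  sp <- read_cohort_config(f)
  expect_s3_class(sp, "cohort_spec")
  expect_equal(sp$n, 12L)
  expect_equal(sp$n_parcels, 30L)
  expect_equal(sp$seed, 9L)
  expect_equal(sp$tract_names, c("AF", "FAT", "SLF3", "ILF", "IFOF", "UF"))
  sp2 <- read_cohort_config(f, seed = 77)
  expect_equal(sp2$seed, 77L)
  fj <- withr::local_tempfile(fileext = ".json")
  writeLines('{"n": 8, "streamlines_per_bundle": 7}', fj)
  spj <- read_cohort_config(fj)
  expect_equal(spj$streamlines_per_bundle, 7L)
  fb <- withr::local_tempfile(fileext = ".yaml")
  writeLines("nonsense_field: 3", fb)
  expect_error(read_cohort_config(fb), "unknown config fields")
})

test_that("an effect spec naming an unknown metric errors", {
  co <- small_cohort()
  expect_error(
    resample_behavior(co, seed = 1,
                      effect = list(target = "XX_FA", outcome = "naming",
                                    partial_r2 = 0.1)),
    "unknown metric")
})
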