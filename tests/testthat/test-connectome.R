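test_that("endpoint assignment follows the end criterion", {
  co <- small_cohort()
  atlas <- co$atlas
  cen <- atlas$parcels[, c("cx", "cy", "cz")]
  # a streamline ending inside parcels (a, b) is an edge candidate
  a <- atlas$parcels$id[3]; b <- atlas$parcels$id[7]
  s <- rbind(unlist(cen[3, ]), (unlist(cen[3, ]) + unlist(cen[7, ])) / 2,
             unlist(cen[7, ]))
  ends <- assign_endpoints(tractogram(list(s)), atlas)
  expect_equal(ends$parcel_a, a)
  expect_equal(ends$parcel_b, b)
  # an endpoint in background contributes nothing
  bgpt <- c(1, 1, 1)  # grid corner: outside every parcel
  s2 <- rbind(bgpt, unlist(cen[3, ]))
  ends2 <- assign_endpoints(tractogram(list(s2)), atlas)
  expect_true(is.na(ends2$parcel_a))
})

test_that("endpoint assignment matches a per-point label-lookup oracle", {
  set.seed(8)
  co <- small_cohort()
  atlas <- co$atlas
  d <- dim(atlas$vol$values)
  sl <- replicate(500, matrix(runif(6, 0, 63), 2, 3), simplify = FALSE)
  ends <- assign_endpoints(tractogram(sl), atlas)
  for (i in sample(500, 60)) {
    for (side in 1:2) {
      pt <- sl[[i]][if (side == 1) 1 else 2, ]
      vx <- point_to_voxel(pt, atlas$vol)
      lab <- if (any(is.na(vx))) NA_integer_ else {
        l <- atlas$vol$values[vx[1] + 1, vx[2] + 1, vx[3] + 1]
        if (l == 0L) NA_integer_ else l
      }
      got <- if (side == 1) ends$parcel_a[i] else ends$parcel_b[i]
      expect_identical(got, lab)
    }
  }
})

test_that("direct connectome counts streamlines and applies the correction", {
  # toy atlas: two parcels, 5 streamlines between them
  g <- volume_grid(array(0L, c(20, 20, 20)), diag(4))
  vals <- array(0L, c(20, 20, 20))
  vals[3:5, 3:5, 3:5] <- 1L; vals[13:15, 3:5, 3:5] <- 2L
  atlas <- parcel_atlas(volume_grid(vals, diag(4), label = TRUE))
  p1 <- c(4, 4, 4); p2 <- c(14, 4, 4)
  sl <- replicate(5, rbind(p1 + runif(3, -0.4, 0.4),
                           p2 + runif(3, -0.4, 0.4)), simplify = FALSE)
  conn <- direct_connectome(tractogram(sl), atlas, correction = "off")
  expect_equal(conn$weights["1", "2"], 5)
  expect_equal(conn$weights["2", "1"], 5)
  expect_true(all(diag(conn$weights) == 0))
  # correction: w = count * d / sqrt(v1 * v2); here d = 10 mm, v = 27 voxels
  connc <- direct_connectome(tractogram(sl), atlas, correction = "full")
  expect_equal(connc$weights["1", "2"], 5 * 10 / sqrt(27 * 27),
               tolerance = 1e-9)
  conn_v <- direct_connectome(tractogram(sl), atlas, correction = "volume")
  expect_equal(conn_v$weights["1", "2"], 5 / sqrt(27 * 27), tolerance = 1e-9)
})

test_that("indirect connectome equals a per-streamline filter oracle", {
  set.seed(13)
  co <- small_cohort()
  atlas <- co$atlas
  lesion <- co$lesions[[1]]
  got <- indirect_connectome(co$trac, lesion, atlas,
                             traversal = co$traversal, ends = co$endpoints)
  # empty lesion: identical to the lesion-free count connectome
  empty <- lesion_from_voxels(matrix(integer(0), 0, 3), atlas$vol)
  free <- indirect_connectome(co$trac, empty, atlas,
                              traversal = co$traversal, ends = co$endpoints)
  count0 <- direct_connectome(co$trac, atlas, correction = "off")
  expect_equal(free$weights, count0$weights)
  # brute-force filter oracle
  lesioned <- lesion$values != 0
  ids <- atlas$parcels$id
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(co$trac$streamlines)) {
    trav <- streamline_traversal(co$trac$streamlines[[i]], atlas$vol)
    lin <- clsmverse:::voxel_linear_index(trav, dim(atlas$vol$values))
    if (any(lesioned[lin])) next
    a <- co$endpoints$parcel_a[i]; b <- co$endpoints$parcel_b[i]
    if (is.na(a) || is.na(b) || a == b) next
    W[as.character(a), as.character(b)] <- W[as.character(a), as.character(b)] + 1
    W[as.character(b), as.character(a)] <- W[as.character(b), as.character(a)] + 1
  }
  expect_equal(got$weights, W)
  # preserved counts never exceed the intact counts
  expect_true(all(got$weights <= free$weights))
})

test_that("indirect weights never increase under lesion growth", {
  co <- small_cohort()
  atlas <- co$atlas
  d <- dim(atlas$vol$values)
  for (i in 1:10) {
    small <- make_lesion(atlas, co$spec$lesion, co$spec, seed = 70 + i)
    extra <- make_lesion(atlas, co$spec$lesion, co$spec, seed = 170 + i)
    big <- lesion_mask(volume_grid(array(pmax(small$values, extra$values), d),
                                   atlas$vol$affine, label = TRUE))
    w_small <- indirect_connectome(co$trac, small, atlas, co$traversal,
                                   co$endpoints)$weights
    w_big <- indirect_connectome(co$trac, big, atlas, co$traversal,
                                 co$endpoints)$weights
    expect_true(all(w_big <= w_small))
  }
})

test_that("ROI subsetting preserves order, tags and nests", {
  co <- small_cohort()
  conn <- indirect_connectome(co$trac, co$lesions[[2]], co$atlas,
                              co$traversal, co$endpoints)
  sub <- subset_connectome(conn, co$atlas, "language")
  ids <- as.character(roi_parcels(co$atlas, "language"))
  expect_equal(sub$node_ids, ids)
  expect_equal(sub$scale, "roi")
  expect_equal(sub$weights, conn$weights[ids, ids])
  expect_error(subset_connectome(conn, co$atlas, "nope"), "unknown ROI")
  # subsetting with all nodes is the identity
  atlas_all <- co$atlas
  atlas_all$roi_subsets$all <- atlas_all$parcels$id
  sub_all <- subset_connectome(conn, atlas_all, "all")
  expect_equal(sub_all$weights, conn$weights)
})

test_that("vectorized edge counts match the network sizes of both scales", {
  W14 <- random_weights(14)
  expect_length(upper_tri_vec(W14), 91)
  W166 <- random_weights(166, density = 0.1)
  expect_length(upper_tri_vec(W166), 13695)
  c14 <- connectome(W14, "indirect", "roi")
  expect_length(upper_tri_vec(c14$weights), 91)
})
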