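#' Specification of a synthetic stroke cohort
#'
#' Collects every parameter of the synthetic cohort generator. The defaults
#' emulate a typical chronic left-hemisphere stroke aphasia sample: n = 50
#' participants scanned under three protocols (25/18/7), lesion volumes
#' lognormal with mean ~91 cc truncated to 2-263 cc, naming scores with mean
#' 34 (max 60) and comprehension (Token) scores with mean 24 (max 45), both
#' strongly negatively correlated with lesion volume, six language-related
#' tract bundles (AF, FAT, SLF3, ILF, IFOF, UF), a 166-parcel atlas with a
#' 14-parcel language subset, and diffusion scalar maps degraded inside the
#' lesion.
#'
#' @param n number of participants (>= 4, for 4-fold cross-validation).
#' @param grid_dim,voxel_size image grid (voxels) and spacing (mm).
#' @param n_parcels,roi_size atlas parcels and language-subset size.
#' @param tract_names names of the tract bundles.
#' @param streamlines_per_bundle streamlines per tract.
#' @param n_background additional atlas streamlines between random parcel
#'   pairs (the non-bundle part of the whole-brain tractogram).
#' @param bundle_spread corridor width of a bundle (mm, jitter SD of the
#'   mid-course control point).
#' @param lesion list: `meanlog`, `sdlog` (lognormal target volume in cc),
#'   `range_cc` truncation, `center_sd` (mm), `n_blobs` spheres per lesion.
#' @param scanner list: `levels` and sampling `prob`.
#' @param behavior per-outcome intercept/slope/noise/maximum and scanner
#'   offsets; `b_size` is points per cc of lesion.
#' @param scalars per-scalar healthy mean, voxel noise SD and multiplicative
#'   lesion factor (FA drops, MD/RD rise).
#' @param effect `NULL` for a null cohort, or a list with `target` (a metric
#'   column such as `"UF_FA"`), `outcome` (`"naming"` or `"token"`) and either
#'   `partial_r2` (planted partial R-squared over the covariate-adjusted
#'   outcome) or `beta` (raw slope per metric unit).
#' @param direct_noise_sd lognormal SD of per-edge tractography variability
#'   used when simulating participant-level direct connectomes.
#' @param direct_bg background intensity of spurious streamlines in the
#'   simulated direct connectome (probabilistic tractography produces dense
#'   connectomes): expected spurious count at zero distance, decaying with
#'   centroid distance over 30 mm.
#' @param seed integer; every generated object is a pure function of the
#'   spec including this seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 50,
                        grid_dim = c(64L, 64L, 64L),
                        voxel_size = c(2, 2, 2),
                        n_parcels = 166,
                        roi_size = 14,
                        tract_names = c("AF", "FAT", "SLF3", "ILF", "IFOF", "UF"),
                        streamlines_per_bundle = 50,
                        n_background = 1200,
                        bundle_spread = 3,
                        lesion = list(),
                        scanner = list(),
                        behavior = list(),
                        scalars = list(),
                        effect = NULL,
                        direct_noise_sd = 0.8,
                        direct_bg = 3,
                        seed = 1L) {
  if (n < 4) stop("n must be >= 4 (4-fold cross-validation)")
  if (roi_size < 2 || roi_size > n_parcels)
    stop("need n_parcels >= roi_size >= 2")
  cv <- 65 / 91  # lesion volume: mean 91 cc, SD 65 cc
  lesion <- utils::modifyList(list(
    meanlog = log(91) - 0.5 * log(1 + cv^2),
    sdlog = sqrt(log(1 + cv^2)),
    range_cc = c(2, 263),
    center_sd = 22,
    n_blobs = 3L
  ), lesion)
  scanner <- utils::modifyList(list(
    levels = c("achieva", "allegra", "prisma"),
    prob = c(25, 18, 7) / 50
  ), scanner)
  behavior <- utils::modifyList(list(
    naming = list(mean = 34, b_size = -0.185, sd = 15, max = 60),
    token = list(mean = 24, b_size = -0.13, sd = 9.5, max = 45),
    scanner_naming = c(0, 3, -3),
    scanner_token = c(0, 2, -2)
  ), behavior)
  scalars <- utils::modifyList(list(
    FA = list(healthy = 0.45, sd = 0.04, lesion_factor = 0.45),
    MD = list(healthy = 8e-4, sd = 5e-5, lesion_factor = 1.8),
    AD = list(healthy = 1.2e-3, sd = 8e-5, lesion_factor = 1.15),
    RD = list(healthy = 6e-4, sd = 5e-5, lesion_factor = 2.0)
  ), scalars)
  if (!is.null(effect)) {
    if (is.null(effect$target)) stop("effect spec needs a target metric")
    effect$outcome <- if (is.null(effect$outcome)) "naming" else effect$outcome
    if (is.null(effect$partial_r2) && is.null(effect$beta))
      stop("effect spec needs partial_r2 or beta")
  }
  structure(list(
    n = as.integer(n), grid_dim = as.integer(grid_dim),
    voxel_size = as.numeric(voxel_size),
    n_parcels = as.integer(n_parcels), roi_size = as.integer(roi_size),
    tract_names = tract_names,
    streamlines_per_bundle = as.integer(streamlines_per_bundle),
    n_background = as.integer(n_background),
    bundle_spread = bundle_spread,
    lesion = lesion, scanner = scanner, behavior = behavior,
    scalars = scalars, effect = effect,
    direct_noise_sd = direct_noise_sd, direct_bg = direct_bg,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Read a cohort specification from a YAML or JSON config file
#'
#' The file holds any subset of [cohort_spec()]'s arguments (tract list, ROI
#' size, lesion model, thresholds, seed, ...); unspecified fields keep their
#' defaults. A `--seed` style override can be passed through `seed`.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @param seed optional seed overriding the file's value.
#' @return a `cohort_spec`.
#' @export
read_cohort_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    # keep y/n-style keys (e.g. the field "n") as strings, not booleans
    yaml::read_yaml(path, handlers = list("bool#yes" = function(v) v,
                                          "bool#no" = function(v) v))
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json: ", path)
  if (!is.null(seed)) cfg$seed <- seed
  known <- names(formals(cohort_spec))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(cohort_spec, cfg)
}

# World-space geometry of the synthetic brain: an ellipsoid filling most of
# the grid, with a "language zone" off-centre (the synthetic stand-in for the
# left peri-sylvian region where both the bundles and the lesions live).
brain_geometry <- function(spec) {
  extent <- spec$grid_dim * spec$voxel_size
  centre <- extent / 2
  semi <- 0.46 * extent
  list(centre = centre, semi = semi,
       language_centre = centre + c(-0.28, 0.12, 0.08) * semi)
}

inside_ellipsoid <- function(pts, geom, shrink = 1) {
  u <- sweep(sweep(pts, 2, geom$centre), 2, geom$semi * shrink, "/")
  rowSums(u^2) <= 1
}

# Linear indices of voxels whose centre lies within radius_mm of a world
# point. Distances are measured in world mm, so anisotropic grids work.
sphere_voxels <- function(centre, radius_mm, grid) {
  d <- dim(grid$values)
  cv <- world_to_voxel(matrix(centre, 1), grid)[1, ]
  rv <- radius_mm / grid$voxel_size
  lo <- pmax(ceiling(cv - rv - 0.5), 0)
  hi <- pmin(floor(cv + rv + 0.5), d - 1)
  if (any(lo > hi)) return(integer(0))
  ii <- seq.int(lo[1], hi[1]); jj <- seq.int(lo[2], hi[2])
  kk <- seq.int(lo[3], hi[3])
  box <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  w <- voxel_to_world(box, grid)
  keep <- rowSums(sweep(w, 2, centre)^2) <= radius_mm^2
  if (!any(keep)) return(integer(0))
  voxel_linear_index(box[keep, , drop = FALSE], d)
}

#' Generate a synthetic parcel atlas
#'
#' Packs `n_parcels` disjoint spherical parcels onto a jittered lattice
#' inside an ellipsoidal brain volume and designates the `roi_size` parcels
#' nearest the language zone as the `"language"` subset.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional seed (defaults to `spec$seed`).
#' @return a [parcel_atlas()]; the language-zone centre is attached as field
#'   `language_centre`.
#' @export
make_atlas <- function(spec, seed = spec$seed) {
  geom <- brain_geometry(spec)
  grid0 <- volume_grid(array(0L, spec$grid_dim),
                       diag(c(spec$voxel_size, 1)))
  parcel_r <- 2.2 * min(spec$voxel_size)   # mm
  spacing <- 6 * min(spec$voxel_size)      # lattice spacing, mm
  with_seed(seed, {
    ax <- lapply(1:3, function(a)
      seq(spacing / 2, spec$grid_dim[a] * spec$voxel_size[a] - spacing / 2,
          by = spacing))
    sites <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
    sites <- sites[inside_ellipsoid(sites, geom, shrink = 0.92), , drop = FALSE]
    if (nrow(sites) < spec$n_parcels)
      stop("parcels cannot be packed into the grid (",
           nrow(sites), " sites for ", spec$n_parcels, " parcels)")
    # keep the language-zone sites, fill the rest at random
    dlang <- sqrt(rowSums(sweep(sites, 2, geom$language_centre)^2))
    ord <- order(dlang)
    lang_sites <- ord[seq_len(spec$roi_size)]
    others <- sample(setdiff(ord, lang_sites),
                     spec$n_parcels - spec$roi_size)
    chosen <- sites[c(lang_sites, others), , drop = FALSE]
    chosen <- chosen + matrix(stats::runif(length(chosen), -0.5, 0.5) *
                                min(spec$voxel_size), ncol = 3)
    vals <- array(0L, spec$grid_dim)
    for (p in seq_len(nrow(chosen))) {
      ix <- sphere_voxels(chosen[p, ], parcel_r, grid0)
      vals[ix] <- p
    }
    vol <- volume_grid(vals, grid0$affine, label = TRUE)
    atlas <- parcel_atlas(vol,
                          roi_subsets = list(language = seq_len(spec$roi_size)))
    atlas$language_centre <- geom$language_centre
    atlas
  })
}

# Quadratic Bezier sampled roughly every `step` mm.
bezier_points <- function(p0, ctrl, p1, step) {
  len <- sqrt(sum((p1 - p0)^2)) +
    sqrt(sum((ctrl - p0)^2)) + sqrt(sum((p1 - ctrl)^2))
  npts <- max(3L, ceiling(len / 2 / step) + 1L)
  t <- seq(0, 1, length.out = npts)
  b <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), ctrl) + outer(t^2, p1)
  b[!duplicated(round(b, 9)), , drop = FALSE]
}

#' Generate the tract bundles and whole-brain atlas tractogram
#'
#' Each tract is a bundle of streamlines between two distinct language
#' parcels, arching around a shared mid-course control point so the bundle
#' forms a compact corridor; the tract's voxel mask is the union of voxels
#' traversed by its member streamlines. Background streamlines between
#' random parcel pairs (distance-decaying preference) complete the
#' whole-brain tractogram.
#'
#' @param atlas a [parcel_atlas()] from [make_atlas()].
#' @param spec the [cohort_spec()].
#' @param seed optional seed (defaults to `spec$seed + 1`).
#' @return list with `tracts` (named [tract_definition()]s carrying
#'   `streamline_idx` into the tractogram), `trac` (the full [tractogram()])
#'   and `endpoint_pairs` (tract name -> parcel ids).
#' @export
make_bundles <- function(atlas, spec, seed = spec$seed + 1L) {
  grid <- atlas$vol
  lang <- roi_parcels(atlas, "language")
  if (length(spec$tract_names) > choose(length(lang), 2))
    stop("not enough language parcel pairs for the requested tracts")
  cen <- as.matrix(atlas$parcels[, c("cx", "cy", "cz")])
  parcel_r <- 2.2 * min(spec$voxel_size)
  with_seed(seed, {
    pairs <- utils::combn(lang, 2)
    # prefer mid-range pairs so bundles have room to arch
    dd <- sqrt(rowSums((cen[pairs[1, ], , drop = FALSE] -
                          cen[pairs[2, ], , drop = FALSE])^2))
    sel <- sample(ncol(pairs), length(spec$tract_names),
                  prob = dd / sum(dd))
    streamlines <- list(); bundles <- character(0)
    tracts <- list()
    pair_tab <- list()
    for (ti in seq_along(spec$tract_names)) {
      tn <- spec$tract_names[ti]
      a <- pairs[1, sel[ti]]; b <- pairs[2, sel[ti]]
      if (a == b) stop("endpoint parcels of tract ", tn, " are identical")
      pair_tab[[tn]] <- c(a, b)
      ca <- cen[match(a, atlas$parcels$id), ]
      cb <- cen[match(b, atlas$parcels$id), ]
      mid <- (ca + cb) / 2
      # per-tract arching: some bundles hug the lesion epicentre, others bow
      # away from it, so severance rates vary across tracts
      arch <- stats::rnorm(3, 0, 6) +
        (mid - brain_geometry(spec)$centre) * stats::runif(1, 0.2, 1.3)
      idx0 <- length(streamlines)
      for (s in seq_len(spec$streamlines_per_bundle)) {
        p0 <- ca + runif_ball(0.55 * parcel_r)
        p1 <- cb + runif_ball(0.55 * parcel_r)
        ctrl <- mid + arch + stats::rnorm(3, 0, spec$bundle_spread)
        streamlines[[length(streamlines) + 1L]] <-
          bezier_points(p0, ctrl, p1, min(spec$voxel_size))
        bundles <- c(bundles, tn)
      }
      tracts[[tn]] <- list(idx = idx0 + seq_len(spec$streamlines_per_bundle))
    }
    # background streamlines between random parcel pairs
    np <- nrow(atlas$parcels)
    if (spec$n_background > 0) {
      d_all <- as.matrix(stats::dist(cen))
      ut <- which(upper.tri(d_all))
      w <- exp(-d_all[ut] / 40)
      picks <- sample(ut, spec$n_background, replace = TRUE, prob = w)
      ai <- row(d_all)[picks]; bi <- col(d_all)[picks]
      for (s in seq_len(spec$n_background)) {
        p0 <- cen[ai[s], ] + runif_ball(0.55 * parcel_r)
        p1 <- cen[bi[s], ] + runif_ball(0.55 * parcel_r)
        ctrl <- (p0 + p1) / 2 + stats::rnorm(3, 0, 4)
        streamlines[[length(streamlines) + 1L]] <-
          bezier_points(p0, ctrl, p1, min(spec$voxel_size))
        bundles <- c(bundles, "other")
      }
    }
    trac <- tractogram(streamlines, bundles)
    trav <- tractogram_traversal(trac, grid)
    d <- dim(grid$values)
    out_tracts <- list()
    for (tn in names(tracts)) {
      ix <- tracts[[tn]]$idx
      vox <- unique(unlist(trav[ix]))
      mvals <- array(0L, d); mvals[vox] <- 1L
      td <- tract_definition(tn, volume_grid(mvals, grid$affine, label = TRUE),
                             trac$streamlines[ix])
      td$streamline_idx <- ix
      td$voxels <- vox  # cached linear indices of the mask
      out_tracts[[tn]] <- td
    }
    list(tracts = out_tracts, trac = trac, traversal = trav,
         endpoint_pairs = pair_tab)
  })
}

runif_ball <- function(r) {
  repeat {
    x <- stats::runif(3, -1, 1)
    if (sum(x^2) <= 1) return(x * r)
  }
}

#' Generate a synthetic lesion
#'
#' A connected blob built as a union of overlapping spheres around a centre
#' drawn near the language zone, with total volume drawn from a truncated
#' lognormal targeting the 2-263 cc range. Lesions are clipped to the brain
#' ellipsoid; an empty lesion (volume 0) is allowed.
#'
#' @param atlas a [parcel_atlas()] from [make_atlas()].
#' @param model the `lesion` component of a [cohort_spec()].
#' @param spec the [cohort_spec()] (for the brain geometry).
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return a [lesion_mask()].
#' @export
make_lesion <- function(atlas, model, spec, seed = NULL) {
  grid <- atlas$vol
  geom <- brain_geometry(spec)
  with_seed(seed, {
    target_cc <- stats::rlnorm(1, model$meanlog, model$sdlog)
    target_cc <- min(max(target_cc, model$range_cc[1]), model$range_cc[2])
    centre <- atlas$language_centre + stats::rnorm(3, 0, model$center_sd)
    for (try in 1:20) {
      if (inside_ellipsoid(matrix(centre, 1), geom, shrink = 0.85)) break
      centre <- geom$centre + (centre - geom$centre) * 0.8
    }
    v_mm3 <- target_cc * 1000
    r0 <- (3 * v_mm3 * 0.9 / (4 * pi))^(1 / 3)
    ix <- sphere_voxels(centre, r0, grid)
    for (b in seq_len(max(model$n_blobs - 1L, 0L))) {
      off <- stats::rnorm(3); off <- off / sqrt(sum(off^2)) * 0.9 * r0
      ix <- c(ix, sphere_voxels(centre + off, 0.62 * r0, grid))
    }
    ix <- unique(ix)
    # clip to brain
    d <- dim(grid$values)
    i0 <- (ix - 1L) %% d[1]
    j0 <- ((ix - 1L) %/% d[1]) %% d[2]
    k0 <- (ix - 1L) %/% (d[1] * d[2])
    w <- voxel_to_world(cbind(i0, j0, k0), grid)
    ix <- ix[inside_ellipsoid(w, geom)]
    vals <- array(0L, d)
    vals[ix] <- 1L
    lesion_mask(volume_grid(vals, grid$affine, label = TRUE))
  })
}

#' Generate diffusion scalar maps for one participant
#'
#' FA, MD, AD and RD maps: spatially uncorrelated voxel noise around a
#' healthy mean, with lesioned voxels scaled by the per-scalar lesion factor
#' (FA reduced, MD/RD elevated). FA is clipped to [0, 1], the diffusivities
#' to non-negative values. The degradation model is a configurable stand-in,
#' not a biophysical claim.
#'
#' @param tracts named list of [tract_definition()]s (used only for the
#'   grid).
#' @param lesion a [lesion_mask()].
#' @param model the `scalars` component of a [cohort_spec()].
#' @param seed optional seed.
#' @return named list of `volume_grid`s: `FA`, `MD`, `AD`, `RD`.
#' @export
make_scalar_maps <- function(tracts, lesion, model, seed = NULL) {
  grid <- lesion
  d <- dim(grid$values)
  nvox <- prod(d)
  lesioned <- grid$values != 0
  with_seed(seed, {
    out <- list()
    for (sc in c("FA", "MD", "AD", "RD")) {
      m <- model[[sc]]
      mu <- rep(m$healthy, nvox)
      mu[lesioned] <- m$healthy * m$lesion_factor
      vals <- array(mu + stats::rnorm(nvox, 0, m$sd), d)
      vals[vals < 0] <- 0
      if (sc == "FA") vals[vals > 1] <- 1
      out[[sc]] <- volume_grid(vals, grid$affine, label = FALSE)
    }
    out
  })
}

#' Generate a full synthetic cohort
#'
#' Runs the whole generator: atlas, bundles and whole-brain tractogram
#' (with cached voxel traversals and endpoint assignments), per-participant
#' lesions, the tract metric matrix, and behaviour scores following
#'
#' `score = intercept + b_size * (lesion_cc - 91) + scanner_offset +
#'   effect + noise`,
#'
#' clipped to the test range (a warning is raised if more than 10% of scores
#' clip). A planted effect adds `c * z` to the chosen outcome, where `z` is
#' the standardized residual of the target metric after regressing out
#' lesion volume and scanner, and `c = sd_noise * sqrt(pr2 / (1 - pr2))`, so
#' the expected partial R-squared over the covariate-only model is
#' `partial_r2`. Tracts with every streamline severed are flagged fully
#' disconnected and their direct metrics are missing.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `clsm_cohort`: fields `spec`, `atlas`,
#'   `tracts`, `trac`, `traversal`, `endpoints`, `participants` (with
#'   behaviour), `lesions`, `metrics` (wide matrix from
#'   [build_metric_matrix()]) and `ground_truth`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  atlas <- make_atlas(spec)
  bnd <- make_bundles(atlas, spec)
  ends <- assign_endpoints(bnd$trac, atlas)
  cohort <- structure(list(
    spec = spec, atlas = atlas, tracts = bnd$tracts, trac = bnd$trac,
    traversal = bnd$traversal, endpoints = ends,
    endpoint_pairs = bnd$endpoint_pairs
  ), class = "clsm_cohort")
  with_seed(spec$seed + 2L, {
    ids <- sprintf("sub-%02d", seq_len(spec$n))
    scanner <- factor(
      sample(spec$scanner$levels, spec$n, replace = TRUE,
             prob = spec$scanner$prob),
      levels = spec$scanner$levels)
    lesions <- lapply(seq_len(spec$n), function(p)
      make_lesion(atlas, spec$lesion, spec))
    cohort$participants <- data.frame(
      id = ids, scanner = scanner,
      lesion_cc = vapply(lesions, lesion_volume_cc, numeric(1)))
    cohort$lesions <- lesions
  })
  cohort$metrics <- build_metric_matrix(cohort)
  cohort <- resample_behavior(cohort, seed = spec$seed + 3L)
  cohort
}

#' Redraw behaviour for an existing cohort
#'
#' Regenerates the naming and Token scores (and the planted effect) from the
#' stored lesions and metric matrix without touching the imaging stage.
#' Used for behaviour-level replication loops (power, calibration).
#'
#' @param cohort a `clsm_cohort`.
#' @param seed seed for the behaviour draw.
#' @param effect optional effect spec overriding `cohort$spec$effect`.
#' @return the cohort with `participants$naming` / `token` and
#'   `ground_truth` updated.
#' @export
resample_behavior <- function(cohort, seed = NULL, effect = cohort$spec$effect) {
  spec <- cohort$spec
  n <- spec$n
  lesion_cc <- cohort$participants$lesion_cc
  scanner_i <- as.integer(cohort$participants$scanner)
  with_seed(seed, {
    scores <- list()
    planted <- NULL
    for (oc in c("naming", "token")) {
      bh <- spec$behavior[[oc]]
      offs <- spec$behavior[[paste0("scanner_", oc)]][scanner_i]
      lin <- bh$mean + bh$b_size * (lesion_cc - 91) + offs
      eff_term <- numeric(n)
      if (!is.null(effect) && identical(effect$outcome, oc)) {
        m <- cohort$metrics[[effect$target]]
        if (is.null(m)) stop("effect spec names unknown metric: ",
                             effect$target)
        ok <- !is.na(m)
        z <- numeric(n)
        base <- stats::lm(m[ok] ~ lesion_cc[ok] + factor(scanner_i[ok]))
        r <- stats::resid(base)
        if (stats::sd(r) > 0) z[ok] <- r / stats::sd(r)
        cc <- if (!is.null(effect$beta)) effect$beta * stats::sd(r)
              else bh$sd * sqrt(effect$partial_r2 / (1 - effect$partial_r2))
        eff_term <- cc * z
        planted <- list(target = effect$target, outcome = oc,
                        coef_per_sd = cc,
                        partial_r2 = effect$partial_r2)
      }
      eps <- stats::rnorm(n, 0, bh$sd)
      raw <- lin + eff_term + eps
      frac_clip <- mean(raw < -0.5 | raw > bh$max + 0.5)
      if (!is.null(effect) && identical(effect$outcome, oc) &&
          is.null(effect$beta) && frac_clip > 0) {
        # clipped scores are insensitive to the planted effect, which would
        # attenuate the delivered partial R-squared below its target;
        # compensate the coefficient for the clipped fraction
        eff_term <- eff_term / sqrt(max(1 - frac_clip, 0.5))
        planted$coef_per_sd <- planted$coef_per_sd /
          sqrt(max(1 - frac_clip, 0.5))
        raw <- lin + eff_term + eps
      }
      clipped <- pmin(pmax(round(raw), 0), bh$max)
      if (frac_clip > 0.1)
        warning(sprintf("%.0f%% of %s scores clipped to [0, %d]",
                        100 * frac_clip, oc, bh$max))
      scores[[oc]] <- list(score = clipped, linpred = lin + eff_term)
    }
    cohort$participants$naming <- scores$naming$score
    cohort$participants$token <- scores$token$score
    fully_disc <- is.na(
      as.matrix(cohort$metrics[paste0(names(cohort$tracts), "_SN")]))
    colnames(fully_disc) <- names(cohort$tracts)
    cohort$ground_truth <- list(
      seed = spec$seed, behavior_seed = seed,
      planted = planted,
      linpred_naming = scores$naming$linpred,
      linpred_token = scores$token$linpred,
      fully_disconnected = fully_disc,
      healthy_scalar_means = vapply(spec$scalars, `[[`, 0, "healthy")
    )
    cohort
  })
}

#' @export
print.clsm_cohort <- function(x, ...) {
  cat(sprintf(
    "<clsm_cohort> n=%d, %d parcels (%d-language ROI), %d tracts, %d streamlines\n",
    nrow(x$participants), nrow(x$atlas$parcels),
    length(roi_parcels(x$atlas, "language")), length(x$tracts),
    length(x$trac)))
  invisible(x)
}

#' Participant-level parcel connectomes
#'
#' Builds the four connectomes of one participant. The indirect pair
#' overlays the lesion on the atlas tractogram (preserved streamline
#' counts). The direct pair emulates participant tractography: per-edge
#' counts are Poisson draws around the lesion-filtered atlas counts with
#' lognormal anatomical/tracking variability (`spec$direct_noise_sd`),
#' then distance/volume corrected.
#'
#' @param cohort a `clsm_cohort`.
#' @param p participant index.
#' @param correction correction mode for the direct connectome (see
#'   [direct_connectome()]).
#' @param seed optional seed for the direct-connectome noise (default
#'   derived from the cohort seed and `p`).
#' @return list `direct_whole`, `indirect_whole`, `direct_roi`,
#'   `indirect_roi`.
#' @export
participant_connectomes <- function(cohort, p, correction = "full",
                                    seed = cohort$spec$seed + 5000L + p) {
  atlas <- cohort$atlas
  indirect <- indirect_connectome(cohort$trac, cohort$lesions[[p]], atlas,
                                  traversal = cohort$traversal,
                                  ends = cohort$endpoints)
  W0 <- indirect$weights
  direct <- with_seed(seed, {
    noise <- matrix(0, nrow(W0), ncol(W0))
    ut <- upper.tri(W0)
    noise[ut] <- stats::rnorm(sum(ut), 0, cohort$spec$direct_noise_sd)
    noise <- noise + t(noise)
    cen <- as.matrix(atlas$parcels[, c("cx", "cy", "cz")])
    dmat <- as.matrix(stats::dist(cen))
    lam <- W0 * exp(noise) + cohort$spec$direct_bg * exp(-dmat / 30)
    diag(lam) <- 0
    Wd <- matrix(0, nrow(W0), ncol(W0), dimnames = dimnames(W0))
    Wd[ut] <- stats::rpois(sum(ut), lam[ut])
    Wd <- Wd + t(Wd)
    connectome(apply_correction(Wd, atlas, correction), "direct", "whole")
  })
  list(direct_whole = direct,
       indirect_whole = indirect,
       direct_roi = subset_connectome(direct, atlas, "language"),
       indirect_roi = subset_connectome(indirect, atlas, "language"))
}

#' Write a cohort to a directory
#'
#' Writes `participants.tsv`, `metrics.tsv`, `ground_truth.json`, the atlas
#' label volume, the atlas tractogram (jsonl dialect) and per-participant
#' lesion masks.
#'
#' @param cohort a `clsm_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "lesions"), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$participants, file.path(dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$metrics, file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gt <- cohort$ground_truth
  gt$fully_disconnected <- as.data.frame(gt$fully_disconnected)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_volume(cohort$atlas$vol, file.path(dir, "atlas.nii.gz"))
  write_tractogram(cohort$trac, file.path(dir, "tractogram.jsonl"))
  for (p in seq_len(nrow(cohort$participants)))
    write_volume(cohort$lesions[[p]],
                 file.path(dir, "lesions",
                           paste0(cohort$participants$id[p], "_lesion.nii.gz")))
  invisible(dir)
}
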