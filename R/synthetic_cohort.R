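# run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-subject seed from the master seed
#'
#' Deterministic splitting rule (a multiplicative hash of the subject index
#' and a stream index), so a cohort can be extended with new subjects
#' without changing the subjects already generated.
#'
#' @param master master seed (integer).
#' @param subject subject index, >= 1.
#' @param stream sub-stream index (1 = bundle, 2 = cavity, 3 = scores,
#'   4 = maps).
#' @return an integer seed in \[1, 2^31).
#' @export
subject_seed <- function(master, subject, stream = 1L) {
  m <- 2147483563
  s <- (as.double(master) %% m) * 48271 + subject * 69621 + stream * 30269
  as.integer(s %% m + 1)
}

#' Configuration of the synthetic cohort generator
#'
#' Defines the study conditions emulated by the generator: a tube-like
#' fibre bundle (a fan whose streamlines start at varying arc positions
#' along a curved centerline, mimicking fibres peeling off a trunk), an
#' ellipsoidal anterior resection cavity whose posterior extent varies
#' across subjects (so transection fractions spread over most of 0-100%),
#' scanner-batch offsets on FA/MD, and three-timepoint memory z-scores whose
#' postoperative change depends linearly on transection fraction, age at
#' surgery, resection volume and timepoint plus Gaussian noise and a
#' subject-level random intercept.
#'
#' @param n_subjects cohort size.
#' @param grid_shape voxel grid dimensions.
#' @param voxel_size voxel edge lengths in mm.
#' @param control_points centerline control points (mm), anterior to
#'   posterior.
#' @param n_streamlines streamlines per bundle.
#' @param n_points points per streamline.
#' @param tube_radius bundle tube radius in mm.
#' @param jitter_sd per-knot spatial jitter SD in mm (truncated at 2.5 SD).
#' @param subject_shift_sd SD (mm) of the rigid inter-subject bundle shift.
#' @param start_spread streamline start positions are uniform on
#'   \[0, start_spread\] of centerline arc length (the fan).
#' @param cavity_anterior_y anterior reference edge of the cavity (mm).
#' @param cavity_radii cavity semi-axes (mm); the whole cavity is scaled by
#'   the size jitter, decoupling cavity volume from posterior reach.
#' @param cavity_center_xz cavity center in x and z (mm).
#' @param cavity_size_jitter uniform range of the per-subject multiplicative
#'   cavity size factor.
#' @param posterior_extent_range uniform range (mm) of the cavity's extra
#'   posterior displacement: larger extents reach deeper into the fan and
#'   transect more streamlines at near-constant volume.
#' @param icv_center,icv_radii intracranial-volume ellipsoid (mm).
#' @param beta_transect named change in z-score per unit transection
#'   fraction (0-1), one per task.
#' @param beta_time change at 12 months relative to 3 months (recovery).
#' @param beta_age change per year of age at surgery.
#' @param beta_resvol change per unit normalized resection volume.
#' @param beta0 intercept of the change model.
#' @param noise_sd residual SD of the change scores.
#' @param subject_sd SD of the per-subject random intercept.
#' @param missing_rate probability a postoperative timepoint is missing.
#' @param batch_prob probability of scanner batch "B".
#' @param fa_batch_offset,md_batch_offset additive batch-B shifts.
#' @param fa_bundle,fa_background,fa_noise_sd FA map composition.
#' @param md_bundle,md_background,md_noise_sd MD map composition (mm^2/s).
#' @param ilae_beta0,ilae_beta_frac logistic model of seizure freedom on
#'   transection fraction.
#' @param seed master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 80L,
                       grid_shape = c(32L, 40L, 32L),
                       voxel_size = c(1, 1, 1),
                       control_points = rbind(c(16, 14, 10),
                                              c(15, 19, 12),
                                              c(14, 24, 13.5),
                                              c(15, 29, 15),
                                              c(16, 34, 17)),
                       n_streamlines = 50L,
                       n_points = 40L,
                       tube_radius = 3,
                       jitter_sd = 0.4,
                       subject_shift_sd = 0.75,
                       start_spread = 0.8,
                       cavity_anterior_y = 8,
                       cavity_radii = c(9, 6, 9),
                       cavity_center_xz = c(16, 11),
                       cavity_size_jitter = c(0.85, 1.15),
                       posterior_extent_range = c(-6, 14),
                       icv_center = c(16, 20, 16),
                       icv_radii = c(15, 19, 15),
                       beta_transect = c(encoding = -0.5, retrieval = -0.5),
                       beta_time = 0.25,
                       beta_age = -0.01,
                       beta_resvol = -1,
                       beta0 = 0.2,
                       noise_sd = 0.25,
                       subject_sd = 0.2,
                       missing_rate = 0.08,
                       batch_prob = 0.5,
                       fa_batch_offset = 0.05,
                       md_batch_offset = -5e-5,
                       fa_bundle = 0.5, fa_background = 0.2,
                       fa_noise_sd = 0.02,
                       md_bundle = 7e-4, md_background = 8.5e-4,
                       md_noise_sd = 2e-5,
                       ilae_beta0 = 0.25, ilae_beta_frac = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_subjects < 1L) stop("n_subjects must be >= 1", call. = FALSE)
  if (cfg$n_streamlines < 1L) stop("n_streamlines must be >= 1", call. = FALSE)
  if (cfg$tube_radius <= 0) stop("tube radius must be positive", call. = FALSE)
  sds <- c(cfg$jitter_sd, cfg$subject_shift_sd, cfg$noise_sd, cfg$subject_sd,
           cfg$fa_noise_sd, cfg$md_noise_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  structure(cfg, class = "sim_config")
}

sim_affine <- function(config) {
  diag(c(config$voxel_size, 1))
}

# interpolation matrix of a natural cubic spline: maps n_knots values at
# uniform parameters to n_out values at uniform parameters (the map is
# linear and identical for every streamline, so it is built once per bundle)
natural_spline_matrix <- function(n_knots, n_out) {
  xout <- seq(1, n_knots, length.out = n_out)
  vapply(seq_len(n_knots), function(j) {
    e <- numeric(n_knots); e[j] <- 1
    stats::spline(seq_len(n_knots), e, xout = xout, method = "natural")$y
  }, numeric(n_out))
}

# natural cubic spline through 3-D knots, parameterized by cumulative chord
# length; returns a function of arc fraction in [0, 1]
spline_curve <- function(knots) {
  d <- sqrt(rowSums(diff(knots)^2))
  t <- c(0, cumsum(d)) / sum(d)
  fx <- stats::splinefun(t, knots[, 1], method = "natural")
  fy <- stats::splinefun(t, knots[, 2], method = "natural")
  fz <- stats::splinefun(t, knots[, 3], method = "natural")
  function(u) cbind(fx(u), fy(u), fz(u))
}

#' Generate one subject's synthetic fibre bundle
#'
#' Smooth streamlines (cubic splines through jittered knots) inside a tube
#' around a common centerline; the whole bundle is rigidly shifted by a
#' subject-level random offset, and each streamline starts at a random arc
#' position (a fan), so an anterior cavity transects a graded fraction of
#' the bundle. The generating centerline (densely sampled) is attached as
#' attribute `"centerline"`.
#'
#' @param config a [sim_config()].
#' @param seed streamline-level seed (see [subject_seed()]).
#' @return a [tract_bundle()].
#' @export
gen_bundle <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  if (config$tube_radius <= 0) stop("tube radius must be positive", call. = FALSE)
  with_local_seed(seed, {
    shift <- stats::rnorm(3, 0, config$subject_shift_sd)
    center <- spline_curve(sweep(config$control_points, 2, shift, "+"))
    n_knots <- 8L
    interp <- natural_spline_matrix(n_knots, config$n_points)
    sl <- lapply(seq_len(config$n_streamlines), function(i) {
      t0 <- stats::runif(1, 0, config$start_spread)
      # radial offset: uniform in the tube's cross-sectional ball
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      off <- dir * config$tube_radius * stats::runif(1)^(1 / 3)
      tk <- seq(t0, 1, length.out = n_knots)
      k <- center(tk)
      jd <- matrix(stats::rnorm(3L * n_knots), n_knots, 3L)
      jd <- jd / sqrt(rowSums(jd^2))
      jmag <- pmin(abs(stats::rnorm(n_knots, 0, config$jitter_sd)),
                   2.5 * config$jitter_sd)
      jit <- jd * jmag
      interp %*% (k + matrix(off, n_knots, 3, byrow = TRUE) + jit)
    })
    b <- tract_bundle(sl)
    attr(b, "centerline") <- center(seq(0, 1, length.out = 400L))
    b
  })
}

# world coordinates of all voxel centers, as three arrays on the grid
voxel_center_arrays <- function(shape, affine) {
  i <- array(rep(seq_len(shape[1]) - 1, times = shape[2] * shape[3]), shape)
  j <- array(rep(rep(seq_len(shape[2]) - 1, each = shape[1]), shape[3]), shape)
  k <- array(rep(seq_len(shape[3]) - 1, each = shape[1] * shape[2]), shape)
  list(x = affine[1, 1] * i + affine[1, 2] * j + affine[1, 3] * k + affine[1, 4],
       y = affine[2, 1] * i + affine[2, 2] * j + affine[2, 3] * k + affine[2, 4],
       z = affine[3, 1] * i + affine[3, 2] * j + affine[3, 3] * k + affine[3, 4])
}

ellipsoid_mask <- function(shape, affine, center, radii) {
  if (any(radii <= 0))
    stop("ellipsoid radii must be positive (zero-extent cavity)", call. = FALSE)
  cc <- voxel_center_arrays(shape, affine)
  inside <- ((cc$x - center[1]) / radii[1])^2 +
    ((cc$y - center[2]) / radii[2])^2 +
    ((cc$z - center[3]) / radii[3])^2 <= 1
  binary_mask(array(as.numeric(inside), dim = shape), affine)
}

#' Generate one subject's resection cavity mask
#'
#' An ellipsoidal cavity whose posterior reach is drawn uniformly from
#' `posterior_extent_range` (deeper reach transects more of the fibre fan)
#' while its volume varies only through an independent size factor,
#' emulating anterior temporal resections whose posterior extent — not
#' their volume — governs how much of the bundle is removed. The drawn
#' extent is attached as attribute `"posterior_extent"`.
#'
#' @param config a [sim_config()].
#' @param seed cavity-level seed.
#' @return a `binary_mask` on the configured grid.
#' @export
gen_resection_mask <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  affine <- sim_affine(config)
  with_local_seed(seed, {
    ext <- stats::runif(1, config$posterior_extent_range[1],
                        config$posterior_extent_range[2])
    size <- stats::runif(1, config$cavity_size_jitter[1],
                         config$cavity_size_jitter[2])
    radii <- config$cavity_radii * size
    center <- c(config$cavity_center_xz[1],
                config$cavity_anterior_y + radii[2] + ext,
                config$cavity_center_xz[2])
    world_max <- drop(sim_affine(config) %*% c(config$grid_shape - 1, 1))[1:3]
    world_min <- sim_affine(config)[1:3, 4]
    if (any(center < world_min) || any(center > world_max))
      stop("resection cavity center lies outside the grid", call. = FALSE)
    m <- ellipsoid_mask(config$grid_shape, affine, center, radii)
    if (sum(m$data) == 0)
      stop("resection cavity contains no voxel (zero extent)", call. = FALSE)
    attr(m, "posterior_extent") <- ext
    m
  })
}

# FA/MD-like maps: background + bundle compartment + batch shift + noise
gen_scalar_maps <- function(config, bundle, batch, seed) {
  affine <- sim_affine(config)
  grid <- volume_grid(array(0, config$grid_shape), affine)
  vis <- streamline_visitation(bundle, grid)
  in_bundle <- vis$data > 0
  with_local_seed(seed, {
    fa <- array(config$fa_background, config$grid_shape)
    fa[in_bundle] <- config$fa_bundle
    fa <- fa + stats::rnorm(length(fa), 0, config$fa_noise_sd)
    if (batch == "B") fa <- fa + config$fa_batch_offset
    fa <- pmin(pmax(fa, 0), 1)
    md <- array(config$md_background, config$grid_shape)
    md[in_bundle] <- config$md_bundle
    md <- md + stats::rnorm(length(md), 0, config$md_noise_sd)
    if (batch == "B") md <- md + config$md_batch_offset
    md <- pmax(md, 1e-6)
    list(fa = volume_grid(array(fa, config$grid_shape), affine),
         md = volume_grid(array(md, config$grid_shape), affine))
  })
}

#' Generate a complete synthetic cohort with known ground truth
#'
#' For each subject: a fibre bundle, a resection cavity, the geometric true
#' transection fraction, FA/MD maps with scanner-batch offsets, demographics
#' and three-timepoint memory scores following the linear change model
#' `dz = beta0 + beta_time * I(12m) + beta_age * age_surgery +
#' beta_resvol * resvol + beta_transect * fraction + b_subject + noise`.
#' Raw scores are obtained by inverting the package's synthetic normative
#' table. With `dir` set, the cohort is written to disk in the formats the
#' pipeline reads (TCK bundles, NIfTI masks and maps, manifest CSV and a
#' ground-truth JSON sidecar holding every simulated component).
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; created if missing.
#' @param with_maps generate FA/MD maps (the slowest part); turn off for
#'   score-model simulations that only need geometry and scores.
#' @return a `synthetic_cohort` list: `manifest` (demographics + raw/z
#'   scores), `metrics` (true percent_cut and resection volume), `truth`
#'   (all generating parameters and per-subject components), `bundles`,
#'   `masks`, `fa`, `md`, `icv_mask`, `config`, `dir`.
#' @export
gen_cohort <- function(config = sim_config(), dir = NULL, with_maps = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  affine <- sim_affine(config)
  icv <- ellipsoid_mask(config$grid_shape, affine,
                        config$icv_center, config$icv_radii)
  icv_vol <- sum(icv$data) * voxel_volume(icv)
  norms <- default_normative_table()
  tasks <- names(config$beta_transect)
  task_max <- c(encoding = 75, retrieval = 15)

  n <- config$n_subjects
  bundles <- masks <- fa <- md <- vector("list", n)
  rows <- vector("list", n)
  subj_truth <- vector("list", n)

  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)

  for (i in seq_len(n)) {
    id <- sprintf("sub-%03d", i)
    bundles[[i]] <- gen_bundle(config, subject_seed(config$seed, i, 1L))
    masks[[i]] <- gen_resection_mask(config, subject_seed(config$seed, i, 2L))
    tf <- transection_fraction(bundles[[i]], masks[[i]])
    frac <- tf$percent_cut / 100
    resvol <- sum(masks[[i]]$data) * voxel_volume(masks[[i]]) / icv_vol

    sc <- with_local_seed(subject_seed(config$seed, i, 3L), {
      age_onset <- stats::runif(1, 5, 30)
      age_surgery <- min(70, max(18, age_onset + stats::runif(1, 5, 30)))
      batch <- if (stats::runif(1) < config$batch_prob) "B" else "A"
      rtype <- if (stats::runif(1) < 0.7) "ATLR" else "limited"
      free <- stats::rbinom(1, 1,
                            stats::plogis(config$ilae_beta0 +
                                            config$ilae_beta_frac * frac))
      ilae <- if (free == 1) 1L else sample(2:4, 1L)
      per_task <- lapply(tasks, function(task) {
        b_i <- stats::rnorm(1, 0, config$subject_sd)
        eps <- stats::rnorm(2, 0, config$noise_sd)
        pre_z <- stats::rnorm(1, -0.3, 1)
        ch <- config$beta0 + config$beta_time * c(0, 1) +
          config$beta_age * age_surgery +
          config$beta_resvol * resvol +
          config$beta_transect[[task]] * frac + b_i + eps
        miss <- stats::runif(2) < config$missing_rate
        list(b = b_i, eps = eps, pre_z = pre_z,
             change = ch, miss = miss)
      })
      names(per_task) <- tasks
      list(age_onset = age_onset, age_surgery = age_surgery, batch = batch,
           rtype = rtype, ilae = ilae, per_task = per_task)
    })

    if (with_maps) {
      mp <- gen_scalar_maps(config, bundles[[i]], sc$batch,
                            subject_seed(config$seed, i, 4L))
      fa[[i]] <- mp$fa; md[[i]] <- mp$md
    }

    band_raw <- function(task, z) {
      nb <- norms[norms$task == task &
                    norms$age_low <= sc$age_surgery &
                    sc$age_surgery <= norms$age_high, ][1, ]
      pmin(pmax(nb$mean + z * nb$sd, 0), task_max[[task]])
    }
    score_cols <- list()
    for (task in tasks) {
      pt <- sc$per_task[[task]]
      z3 <- if (pt$miss[1]) NA_real_ else pt$pre_z + pt$change[1]
      z12 <- if (pt$miss[2]) NA_real_ else pt$pre_z + pt$change[2]
      zz <- c(pre = pt$pre_z, m3 = z3, m12 = z12)
      for (tp in names(zz)) {
        score_cols[[paste0(task, "_raw_", tp)]] <-
          if (is.na(zz[[tp]])) NA_real_ else band_raw(task, zz[[tp]])
        score_cols[[paste0(task, "_z_", tp)]] <- zz[[tp]]
      }
    }

    rows[[i]] <- data.frame(subject_id = id,
                            age_onset = sc$age_onset,
                            age_surgery = sc$age_surgery,
                            scanner_batch = sc$batch,
                            resection_type = sc$rtype,
                            resection_volume = resvol,
                            ilae_12m = sc$ilae,
                            percent_cut = tf$percent_cut,
                            as.data.frame(score_cols),
                            stringsAsFactors = FALSE)
    subj_truth[[i]] <- list(subject_id = id,
                            transection_fraction = frac,
                            resection_volume = resvol,
                            posterior_extent = attr(masks[[i]],
                                                    "posterior_extent"),
                            per_task = sc$per_task)

    if (!is.null(dir)) {
      write_tractogram(bundles[[i]], file.path(dir, paste0(id, "_bundle.tck")))
      write_volume(masks[[i]], file.path(dir, paste0(id, "_resection.nii.gz")))
      if (with_maps) {
        write_volume(fa[[i]], file.path(dir, paste0(id, "_fa.nii.gz")))
        write_volume(md[[i]], file.path(dir, paste0(id, "_md.nii.gz")))
      }
    }
  }

  manifest <- do.call(rbind, rows)
  metrics <- manifest[, c("subject_id", "percent_cut", "resection_volume")]
  truth <- list(parameters = config[c("beta_transect", "beta_time", "beta_age",
                                      "beta_resvol", "beta0", "noise_sd",
                                      "subject_sd", "seed")],
                subjects = subj_truth)
  cohort <- structure(list(config = config, manifest = manifest,
                           metrics = metrics, truth = truth,
                           bundles = bundles, masks = masks,
                           fa = fa, md = md, icv_mask = icv, dir = dir),
                      class = "synthetic_cohort")
  if (!is.null(dir)) {
    write_volume(icv, file.path(dir, "icv.nii.gz"))
    man <- manifest
    man$bundle_file <- paste0(man$subject_id, "_bundle.tck")
    man$resection_file <- paste0(man$subject_id, "_resection.nii.gz")
    if (with_maps) {
      man$fa_file <- paste0(man$subject_id, "_fa.nii.gz")
      man$md_file <- paste0(man$subject_id, "_md.nii.gz")
    }
    utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects, grid %s%s\n",
              x$config$n_subjects,
              paste(x$config$grid_shape, collapse = "x"),
              if (is.null(x$dir)) " (in memory)" else paste0(" at ", x$dir)))
  invisible(x)
}

#' Long-format analysis table for the mixed models
#'
#' One row per subject, task and postoperative timepoint with the change
#' score, baseline z-score, covariates and the transection fraction
#' (`transection`, 0-1 scale).
#'
#' @param cohort a [gen_cohort()] result, or its manifest merged with a
#'   metrics table carrying `percent_cut`.
#' @param tasks tasks to include.
#' @return long-format data.frame.
#' @export
cohort_long <- function(cohort, tasks = NULL) {
  man <- if (inherits(cohort, "synthetic_cohort")) cohort$manifest else cohort
  if (is.null(tasks)) {
    tasks <- unique(sub("_z_pre$", "", grep("_z_pre$", names(man),
                                            value = TRUE)))
  }
  out <- list()
  for (task in tasks) {
    for (tp in c("3m", "12m")) {
      post <- man[[paste0(task, "_z_", if (tp == "3m") "m3" else "m12")]]
      pre <- man[[paste0(task, "_z_pre")]]
      out[[paste(task, tp)]] <- data.frame(
        subject_id = man$subject_id,
        task = task,
        timepoint = tp,
        pre_z = pre,
        change_z = change_score(pre, post),
        age_surgery = man$age_surgery,
        age_onset = man$age_onset,
        resection_volume = man$resection_volume,
        transection = man$percent_cut / 100,
        scanner_batch = man$scanner_batch,
        resection_type = man$resection_type,
        ilae_12m = man$ilae_12m,
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, out)
  rownames(d) <- NULL
  d$timepoint <- factor(d$timepoint, levels = c("3m", "12m"))
  d
}
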