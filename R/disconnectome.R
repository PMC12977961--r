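# 0-based voxel indices of the resampled points of one streamline that fall
# inside the grid, as unique 1-based linear indices into the data array
streamline_voxels <- function(points, grid, step, inv = solve(grid$affine)) {
  q <- resample_polyline(points, step)
  ijk <- floor(cbind(q, 1) %*% t(inv) + 0.5)[, 1:3, drop = FALSE]
  sh <- grid$shape
  ok <- ijk[, 1] >= 0 & ijk[, 1] < sh[1] &
        ijk[, 2] >= 0 & ijk[, 2] < sh[2] &
        ijk[, 3] >= 0 & ijk[, 3] < sh[3]
  if (!any(ok)) return(integer(0))
  ijk <- ijk[ok, , drop = FALSE]
  unique(1L + as.integer(ijk[, 1] + sh[1] * (ijk[, 2] + sh[2] * ijk[, 3])))
}

#' Per-voxel streamline visitation counts
#'
#' Each streamline is resampled to an arc-length spacing of at most `step`
#' mm; a voxel's count is the number of distinct streamlines with at least
#' one resampled point mapping to it (nearest-voxel rule). Points outside
#' the grid contribute nothing. The default step, half the smallest voxel
#' dimension, prevents a segment stepping diagonally over a voxel.
#'
#' @param bundle a [tract_bundle()], non-empty.
#' @param grid a `volume_grid` defining the target voxel lattice.
#' @param step resampling spacing in mm; default half the smallest voxel
#'   dimension.
#' @return a `volume_grid` of integer counts on `grid`'s lattice.
#' @export
streamline_visitation <- function(bundle, grid, step = default_step(grid)) {
  stopifnot(inherits(bundle, "tract_bundle"), inherits(grid, "volume_grid"))
  if (bundle$count == 0L)
    stop("bundle is empty: visitation map undefined", call. = FALSE)
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be a single positive number (mm)", call. = FALSE)
  counts <- array(0L, dim = grid$shape)
  inv <- solve(grid$affine)
  for (s in bundle$streamlines) {
    v <- streamline_voxels(s, grid, step, inv)
    counts[v] <- counts[v] + 1L
  }
  volume_grid(counts, grid$affine)
}

#' Half the smallest voxel dimension of a grid, in mm
#' @param grid a `volume_grid`.
#' @export
default_step <- function(grid) {
  min(sqrt(colSums(grid$affine[1:3, 1:3]^2))) / 2
}

#' Bundle probability map
#'
#' Visitation counts divided by the number of streamlines: the fraction of
#' the bundle's streamlines visiting each voxel, in \[0, 1\].
#'
#' @inheritParams streamline_visitation
#' @return a `volume_grid` with values in \[0, 1\].
#' @export
bundle_probability_map <- function(bundle, grid, step = default_step(grid)) {
  vis <- streamline_visitation(bundle, grid, step)
  volume_grid(vis$data / bundle$count, grid$affine)
}

#' Threshold a probability map into a binary mask
#'
#' Values below `threshold` are zeroed; the rest become 1. Used both to
#' trim spurious low-probability voxels from bundle maps (default 0.01) and
#' to binarize bundle masks.
#'
#' @param map a `volume_grid` with values in \[0, 1\].
#' @param threshold retention cut; voxels with value >= threshold survive.
#' @return a `binary_mask`.
#' @export
threshold_probability_map <- function(map, threshold = 0.01) {
  stopifnot(inherits(map, "volume_grid"))
  binary_mask(array(as.numeric(map$data >= threshold), dim = map$shape),
              map$affine, threshold = 0.5)
}

#' Virtual-lesion streamline transection
#'
#' Treats the resection cavity as an exclusion mask: a streamline is cut iff
#' any of its resampled points (spacing <= `step` mm) falls in a set voxel
#' of the mask. The surviving streamlines are a proxy for postoperative
#' tractography; `percent_cut` is the percentage of streamlines removed.
#'
#' @param bundle a [tract_bundle()], non-empty.
#' @param resection a `binary_mask` co-registered with the bundle.
#' @param step resampling spacing in mm.
#' @return a `transection_result`: list with `n_pre`, `n_post`,
#'   `percent_cut` (0-100), `cut` (logical per streamline) and `remaining`
#'   (the surviving [tract_bundle()]).
#' @export
transection_fraction <- function(bundle, resection,
                                 step = default_step(resection)) {
  stopifnot(inherits(bundle, "tract_bundle"), inherits(resection, "binary_mask"))
  if (bundle$count == 0L)
    stop("bundle is empty: transection fraction undefined", call. = FALSE)
  inv <- solve(resection$affine)
  cut <- vapply(bundle$streamlines, function(s) {
    v <- streamline_voxels(s, resection, step, inv)
    any(resection$data[v] == 1)
  }, logical(1))
  n_pre <- bundle$count
  n_post <- n_pre - sum(cut)
  structure(list(n_pre = n_pre,
                 n_post = n_post,
                 percent_cut = 100 * (n_pre - n_post) / n_pre,
                 cut = cut,
                 remaining = tract_bundle(bundle$streamlines[!cut])),
            class = "transection_result")
}

#' @export
print.transection_result <- function(x, ...) {
  cat(sprintf("<transection_result> %d/%d streamlines cut (%.1f%%)\n",
              x$n_pre - x$n_post, x$n_pre, x$percent_cut))
  invisible(x)
}

#' Build a probabilistic tract atlas from subject bundle masks
#'
#' Binary bundle masks on a common grid are combined and rescaled to
#' \[0, 1\]: the value at a voxel is the fraction of subjects whose mask
#' covers it (1 = overlap of all subjects, 0 = no overlap).
#'
#' @param masks list of `binary_mask` objects on one common grid.
#' @return a `probabilistic_atlas` (a `volume_grid` with values that are
#'   exact multiples of 1/n) with field `n_subjects`.
#' @export
build_atlas <- function(masks) {
  if (!is.list(masks) || length(masks) < 1L)
    stop("need at least one mask to build an atlas", call. = FALSE)
  lapply(masks, function(m) stopifnot(inherits(m, "binary_mask")))
  for (i in seq_along(masks)[-1L])
    check_same_grid(masks[[1L]], masks[[i]],
                    sprintf("masks 1 and %d", i))
  n <- length(masks)
  tally <- Reduce(`+`, lapply(masks, `[[`, "data"))
  structure(list(data = tally / n, affine = masks[[1L]]$affine,
                 shape = masks[[1L]]$shape, n_subjects = n),
            class = c("probabilistic_atlas", "volume_grid"))
}

#' Atlas-based disconnection probability (Tractotron rule)
#'
#' The probability that the resection disconnects the bundle is the maximum
#' atlas value over the resected voxels — independent of how many resected
#' voxels intersect the bundle, so a single resected voxel meeting 50% of
#' the bundle suffices for a 50% disconnection probability. The probability
#' is then binarized at `threshold` (default 0.5, i.e. 50%); a tie at the
#' threshold counts as disconnected.
#'
#' @param resection a `binary_mask` on the atlas grid.
#' @param atlas a `probabilistic_atlas` (or any `volume_grid` in \[0, 1\]).
#' @param threshold binarization threshold on the probability.
#' @return a `disconnection_result`: list with `probability` (0-1),
#'   `disconnected` (0/1) and `threshold`.
#' @export
disconnection_probability <- function(resection, atlas, threshold = 0.5) {
  stopifnot(inherits(resection, "binary_mask"), inherits(atlas, "volume_grid"))
  check_same_grid(resection, atlas, "resection mask and atlas")
  vals <- atlas$data[resection$data == 1]
  prob <- if (length(vals)) max(vals) else 0
  structure(list(probability = prob,
                 disconnected = as.integer(prob >= threshold),
                 threshold = threshold),
            class = "disconnection_result")
}

#' @export
print.disconnection_result <- function(x, ...) {
  cat(sprintf("<disconnection_result> p = %.3f (threshold %.2f): %s\n",
              x$probability, x$threshold,
              if (x$disconnected) "disconnected" else "preserved"))
  invisible(x)
}

#' Tract volume normalized to intracranial volume
#'
#' @param bundle_mask `binary_mask` of the tract.
#' @param icv_mask `binary_mask` of the intracranial volume (non-empty).
#' @return unitless ratio tract volume / ICV.
#' @export
normalized_tract_volume <- function(bundle_mask, icv_mask) {
  stopifnot(inherits(bundle_mask, "binary_mask"), inherits(icv_mask, "binary_mask"))
  icv <- sum(icv_mask$data) * voxel_volume(icv_mask)
  if (icv <= 0)
    stop("intracranial volume mask is empty", call. = FALSE)
  sum(bundle_mask$data) * voxel_volume(bundle_mask) / icv
}

#' Min-max rescale a cohort of values to \[0, 1\]
#'
#' Maps the cohort minimum to 0 and maximum to 1 linearly; `NA`s are
#' preserved. A constant cohort has no spread to rescale: all values become
#' 0, with a warning.
#'
#' @param values numeric vector.
#' @return rescaled vector in \[0, 1\].
#' @export
cohort_rescale <- function(values) {
  rng <- range(values, na.rm = TRUE)
  if (!all(is.finite(rng)))
    stop("no finite values to rescale", call. = FALSE)
  if (diff(rng) == 0) {
    warning("cohort values are constant; rescaled values set to 0")
    out <- values
    out[!is.na(out)] <- 0
    return(out)
  }
  (values - rng[1]) / diff(rng)
}

#' Median scalar-map value over a bundle's visited voxels
#'
#' The median (robust to outlier voxels) of the scalar map over the set of
#' distinct voxels visited by the bundle; each visited voxel contributes
#' once regardless of how many streamlines or points pass through it.
#'
#' @param bundle a [tract_bundle()], non-empty.
#' @param scalar_map a `volume_grid` (e.g. an FA or MD map) co-registered
#'   with the bundle.
#' @param step resampling spacing in mm.
#' @return the median map value over visited voxels.
#' @export
tract_median_metric <- function(bundle, scalar_map,
                                step = default_step(scalar_map)) {
  vis <- streamline_visitation(bundle, scalar_map, step)
  vox <- which(vis$data > 0L)
  if (!length(vox))
    stop("bundle visits no in-bounds voxel of the scalar map", call. = FALSE)
  stats::median(scalar_map$data[vox])
}
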