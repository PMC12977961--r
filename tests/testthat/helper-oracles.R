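# Independent brute-force oracles and small fixture builders used across the
# geometric tests. The oracles sample every polyline segment densely (default
# 0.01 mm) and tally voxel visits point by point through a separate code path
# (explicit per-streamline data-frame tallies), so they share no machinery
# with the package's accumulation route.

make_grid <- function(shape = c(16L, 16L, 16L), affine = diag(4)) {
  volume_grid(array(0, shape), affine)
}

# dense per-segment samples at arc positions seq(0, L, by = spacing) + L
oracle_samples <- function(s, spacing = 0.01) {
  out <- vector("list", nrow(s) - 1L)
  for (i in seq_len(nrow(s) - 1L)) {
    p0 <- s[i, ]
    p1 <- s[i + 1L, ]
    L <- sqrt(sum((p1 - p0)^2))
    if (L == 0) next
    t <- c(seq(0, L, by = spacing), L)
    out[[i]] <- cbind(p0[1] + t / L * (p1[1] - p0[1]),
                      p0[2] + t / L * (p1[2] - p0[2]),
                      p0[3] + t / L * (p1[3] - p0[3]))
  }
  do.call(rbind, out)
}

# 0-based in-bounds voxel rows (unique) visited by one streamline
oracle_streamline_voxels <- function(s, grid, spacing = 0.01) {
  pts <- oracle_samples(s, spacing)
  inv <- solve(grid$affine)
  h <- inv %*% rbind(t(pts), 1)
  ijk <- floor(t(h)[, 1:3, drop = FALSE] + 0.5)
  sh <- grid$shape
  keep <- ijk[, 1] >= 0 & ijk[, 1] < sh[1] &
    ijk[, 2] >= 0 & ijk[, 2] < sh[2] &
    ijk[, 3] >= 0 & ijk[, 3] < sh[3]
  unique(ijk[keep, , drop = FALSE])
}

oracle_visitation <- function(bundle, grid, spacing = 0.01) {
  counts <- array(0L, grid$shape)
  for (s in bundle$streamlines) {
    v <- oracle_streamline_voxels(s, grid, spacing)
    if (nrow(v)) {
      idx <- v + 1L
      counts[idx] <- counts[idx] + 1L
    }
  }
  counts
}

oracle_transection <- function(bundle, mask, spacing = 0.01) {
  cut <- vapply(bundle$streamlines, function(s) {
    v <- oracle_streamline_voxels(s, mask, spacing)
    nrow(v) > 0 && any(mask$data[v + 1L] == 1)
  }, logical(1))
  100 * sum(cut) / length(cut)
}

oracle_median_metric <- function(bundle, map, spacing = 0.01) {
  counts <- oracle_visitation(bundle, map, spacing)
  stats::median(map$data[counts > 0])
}

# random piecewise-linear bundle inside a margin of the grid
random_bundle <- function(grid, n_streamlines = 10L, n_waypoints = 5L,
                         margin = 2) {
  lo <- margin
  hi <- voxel_to_world(grid$shape - 1L, grid) - margin
  origin <- voxel_to_world(c(0L, 0L, 0L), grid) + margin
  sl <- lapply(seq_len(n_streamlines), function(i) {
    start <- runif(3, origin, hi)
    steps <- matrix(runif(3 * (n_waypoints - 1), -6, 6),
                    n_waypoints - 1L, 3L)
    p <- rbind(start, start + apply(steps, 2L, cumsum))
    # clamp to the sampled region so geometry stays mostly in-grid
    p[, 1] <- pmin(pmax(p[, 1], origin[1] - 4), hi[1] + 4)
    p[, 2] <- pmin(pmax(p[, 2], origin[2] - 4), hi[2] + 4)
    p[, 3] <- pmin(pmax(p[, 3], origin[3] - 4), hi[3] + 4)
    p
  })
  tract_bundle(sl)
}

# random blob mask: union of 1-2 ellipsoids evaluated at voxel centers
random_blob_mask <- function(grid, n_blobs = 2L) {
  sh <- grid$shape
  idx <- as.matrix(expand.grid(i = 0:(sh[1] - 1), j = 0:(sh[2] - 1),
                               k = 0:(sh[3] - 1)))
  w <- voxel_to_world(idx, grid)
  inside <- rep(FALSE, nrow(w))
  for (b in seq_len(n_blobs)) {
    cen <- runif(3, voxel_to_world(c(0, 0, 0), grid) + 3,
                 voxel_to_world(sh - 1L, grid) - 3)
    rad <- runif(3, 2, 6)
    inside <- inside |
      (((w[, 1] - cen[1]) / rad[1])^2 +
         ((w[, 2] - cen[2]) / rad[2])^2 +
         ((w[, 3] - cen[3]) / rad[3])^2 <= 1)
  }
  binary_mask(array(as.numeric(inside), sh), grid$affine)
}

# straight streamline along +x at a given (y, z), in world mm
straight_streamline <- function(x0, x1, y, z, n = 2L) {
  cbind(seq(x0, x1, length.out = n), rep(y, n), rep(z, n))
}
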