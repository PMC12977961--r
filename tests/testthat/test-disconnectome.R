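test_that("visitation counts distinct streamlines per voxel", {
  g <- make_grid(c(8, 8, 8))
  s <- straight_streamline(0, 4, 2, 2)      # through voxels x = 0..4
  b <- tract_bundle(list(s))
  vis <- streamline_visitation(b, g, step = 0.5)
  expect_equal(sum(vis$data), 5)
  expect_equal(as.numeric(vis$data[1:5, 3, 3]), rep(1, 5))

  # a duplicated streamline doubles counts exactly on its support
  b2 <- tract_bundle(list(s, s))
  vis2 <- streamline_visitation(b2, g, step = 0.5)
  expect_equal(max(vis2$data), 2)
  expect_identical(vis2$data == 2L, vis$data == 1L)

  expect_error(streamline_visitation(tract_bundle(list()), g), "empty")
  expect_error(streamline_visitation(b, g, step = -1), "positive")
})

test_that("probability maps normalize by streamline count and threshold", {
  g <- make_grid(c(8, 8, 8))
  sl <- c(list(straight_streamline(0, 4, 2, 2)),
          replicate(9, straight_streamline(0, 4, 5, 5), simplify = FALSE))
  b <- tract_bundle(sl)
  pm <- bundle_probability_map(b, g, step = 0.5)
  expect_equal(pm$data[3, 3, 3], 0.1)   # visited by 1 of 10
  expect_equal(pm$data[3, 6, 6], 0.9)   # visited by 9 of 10
  expect_equal(max(pm$data), 0.9)

  thr <- threshold_probability_map(
    volume_grid(array(c(0.005, 0.02, rep(0, 6)), c(8, 1, 1)), diag(4)),
    threshold = 0.01)
  expect_identical(as.numeric(thr$data[1:2, 1, 1]), c(0, 1))
})

test_that("transection fraction counts streamlines traversing the cavity", {
  g <- make_grid(c(12, 12, 12))
  # 10 parallel streamlines at y = 0..9; mask covers the corridor y in [0,3]
  b <- tract_bundle(lapply(0:9, function(y) straight_streamline(0, 10, y, 5)))
  a <- array(0, c(12, 12, 12)); a[, 1:4, ] <- 1
  mask <- binary_mask(a, diag(4))
  tr <- transection_fraction(b, mask, step = 0.5)
  expect_equal(tr$percent_cut, 40)
  expect_equal(tr$n_pre, 10L)
  expect_equal(tr$n_post, 6L)
  expect_equal(tr$remaining$count, 6L)

  empty <- binary_mask(array(0, c(12, 12, 12)), diag(4))
  tr0 <- transection_fraction(b, empty, step = 0.5)
  expect_equal(tr0$percent_cut, 0)
  expect_equal(tr0$n_post, tr0$n_pre)
  expect_error(transection_fraction(tract_bundle(list()), mask), "empty")
})

test_that("geometric operations agree with the dense-sampling oracle", {
  set.seed(1234)
  for (rep in 1:10) {
    aff <- diag(c(runif(1, 0.8, 1.4), runif(1, 0.8, 1.4),
                  runif(1, 0.8, 1.4), 1))
    aff[1:3, 4] <- runif(3, -3, 3)
    g <- make_grid(c(14L, 14L, 14L), aff)
    b <- random_bundle(g, n_streamlines = 6L, n_waypoints = 4L)
    vis <- streamline_visitation(b, g, step = 0.01)
    expect_identical(as.integer(vis$data), as.integer(oracle_visitation(b, g)))
    m <- random_blob_mask(g)
    tr <- transection_fraction(b, m, step = 0.01)
    expect_equal(tr$percent_cut, oracle_transection(b, m))
    map <- volume_grid(array(runif(prod(g$shape)), g$shape), aff)
    expect_equal(tract_median_metric(b, map, step = 0.01),
                 oracle_median_metric(b, map))
  }
})

test_that("atlas construction tallies mask overlap as exact fractions", {
  a1 <- array(0, c(6, 6, 6)); a1[2:3, 2:3, 2] <- 1
  m1 <- binary_mask(a1, diag(4))
  atl <- build_atlas(list(m1, m1))
  expect_identical(atl$data, m1$data)
  expect_equal(atl$n_subjects, 2L)

  a2 <- array(0, c(6, 6, 6)); a2[3, 3, 2] <- 1; a2[5, 5, 5] <- 1
  m2 <- binary_mask(a2, diag(4))
  atl2 <- build_atlas(list(m1, m2))
  expect_equal(atl2$data[3, 3, 2], 1)          # shared voxel
  expect_equal(atl2$data[2, 2, 2], 0.5)        # only mask 1
  expect_equal(atl2$data[5, 5, 5], 0.5)        # only mask 2
  expect_equal(atl2$data[1, 1, 1], 0)

  # 7 random masks: per-voxel value equals an independent tally / 7
  set.seed(9)
  masks <- lapply(1:7, function(i)
    binary_mask(array(as.numeric(runif(6^3) < 0.3), c(6, 6, 6)), diag(4)))
  atl7 <- build_atlas(masks)
  tally <- array(0, c(6, 6, 6))
  for (m in masks) for (v in which(m$data == 1)) tally[v] <- tally[v] + 1
  expect_equal(atl7$data, tally / 7)
  expect_true(all(abs(atl7$data * 7 - round(atl7$data * 7)) < 1e-12))

  g2 <- binary_mask(array(0, c(5, 5, 5)), diag(4))
  expect_error(build_atlas(list(m1, g2)), "different grids")
})

test_that("disconnection probability is the maximum atlas value over the cavity", {
  a <- array(0, c(8, 8, 8))
  a[2, 2, 2] <- 0.20; a[3, 3, 3] <- 0.35; a[4, 4, 4] <- 0.50
  a[6, 6, 6] <- 0.90
  atlas <- volume_grid(a, diag(4))

  r <- array(0, c(8, 8, 8)); r[2, 2, 2] <- r[3, 3, 3] <- r[4, 4, 4] <- 1
  res <- binary_mask(r, diag(4))
  d <- disconnection_probability(res, atlas)
  expect_equal(d$probability, 0.5)
  expect_equal(d$disconnected, 1L)   # a tie at the threshold disconnects

  r2 <- array(0, c(8, 8, 8)); r2[8, 8, 8] <- 1
  expect_equal(disconnection_probability(binary_mask(r2, diag(4)),
                                         atlas)$probability, 0)
  expect_equal(disconnection_probability(binary_mask(r2, diag(4)),
                                         atlas)$disconnected, 0L)

  r3 <- array(0, c(8, 8, 8)); r3[2, 2, 2] <- r3[6, 6, 6] <- 1
  expect_equal(disconnection_probability(binary_mask(r3, diag(4)),
                                         atlas)$probability, 0.9)

  # adding overlap voxels below the maximum changes nothing
  r4 <- r3; r4[3, 3, 3] <- r4[4, 4, 4] <- 1
  expect_equal(disconnection_probability(binary_mask(r4, diag(4)),
                                         atlas)$probability, 0.9)
})

test_that("tract volumes normalize to ICV and rescale across the cohort", {
  aff <- diag(c(2, 2, 2, 1))
  bm <- array(0, c(50, 50, 50)); bm[1:10, 1:10, 1] <- 1   # 100 voxels x 8 mm3
  bundle_mask <- binary_mask(bm, aff)
  icv <- binary_mask(array(1, c(50, 50, 50)), aff)        # 1e6 mm3
  expect_equal(normalized_tract_volume(bundle_mask, icv), 8e-4)
  expect_error(normalized_tract_volume(bundle_mask,
                                       binary_mask(array(0, c(50, 50, 50)),
                                                   aff)),
               "empty")

  expect_equal(cohort_rescale(c(0.2, 0.5, 0.8)), c(0, 0.5, 1))
  expect_warning(out <- cohort_rescale(c(0.4, 0.4, 0.4)), "constant")
  expect_equal(out, c(0, 0, 0))
})

test_that("median tract metric is over distinct visited voxels", {
  g <- make_grid(c(8, 8, 8))
  b <- tract_bundle(list(straight_streamline(0, 4, 2, 2)))
  uni <- volume_grid(array(0.7, c(8, 8, 8)), diag(4))
  expect_equal(tract_median_metric(b, uni, step = 0.5), 0.7)

  # exactly two visited voxels valued 0.2 and 0.8 -> median 0.5
  m <- array(0, c(8, 8, 8)); m[1, 3, 3] <- 0.2; m[2, 3, 3] <- 0.8
  map <- volume_grid(m, diag(4))
  b2 <- tract_bundle(list(straight_streamline(0, 1, 2, 2)))
  expect_equal(tract_median_metric(b2, map, step = 0.25), 0.5)

  # a bundle entirely out of bounds fails
  far <- tract_bundle(list(straight_streamline(100, 110, 50, 50)))
  expect_error(tract_median_metric(far, uni), "no in-bounds voxel")
})

test_that("enlarging the resection never decreases cut fraction or probability", {
  set.seed(77)
  g <- make_grid(c(14, 14, 14))
  for (rep in 1:8) {
    b <- random_bundle(g, n_streamlines = 8L)
    small <- random_blob_mask(g)
    big <- dilate_mask(small, 1.5)
    expect_gte(transection_fraction(b, big)$percent_cut,
               transection_fraction(b, small)$percent_cut)
    atlas <- bundle_probability_map(b, g)
    expect_gte(disconnection_probability(big, atlas)$probability,
               disconnection_probability(small, atlas)$probability)
  }
  # full-support mask cuts everything
  b <- random_bundle(g, n_streamlines = 5L)
  all_mask <- binary_mask(array(1, g$shape), g$affine)
  expect_equal(transection_fraction(b, all_mask)$percent_cut, 100)
})
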