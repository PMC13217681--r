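shifted_cube_pair <- function() {
  list(a = cube_mask(), b = cube_mask(from = c(11, 6, 6)))
}

test_that("overlap metrics reproduce hand-countable cases", {
  p <- shifted_cube_pair()
  expect_equal(dice(p$a, p$a), 1.0)
  expect_equal(dice(p$a, p$b), 0.5) # overlap 500 of 1000+1000
  expect_equal(conformity_index(p$a, p$b), 500 / 1500)
  expect_equal(inclusion_index(p$a, p$b), 0.5)
  expect_equal(relative_volume_difference(p$a, p$b), 0.0)
  disjoint <- cube_mask(dim = c(40, 20, 20), from = c(25, 6, 6))
  base <- cube_mask(dim = c(40, 20, 20))
  expect_equal(dice(base, disjoint), 0.0)
  expect_equal(inclusion_index(base, disjoint), 0.0)
})

test_that("inclusion and rvd follow their definitions", {
  ref <- cube_mask()
  superset <- cube_mask(from = c(5, 5, 5), size = 12)
  expect_equal(inclusion_index(superset, ref), 1.0)
  expect_equal(relative_volume_difference(superset, ref), 12^3 / 10^3 - 1)
  half <- cube_mask(dim = c(20, 20, 20), from = c(6, 6, 6), size = 10)
  half$occupancy[11:15, , ] <- FALSE
  expect_equal(relative_volume_difference(half, ref), -0.5)
})

test_that("empty masks raise undefined-metric errors instead of sentinels", {
  e <- voxel_mask(array(FALSE, c(10, 10, 10)), c(1, 1, 1))
  f <- cube_mask(dim = c(10, 10, 10), from = c(3, 3, 3), size = 4)
  expect_error(dice(e, e), class = "ce_undefined_metric")
  expect_error(inclusion_index(f, e), class = "ce_undefined_metric")
  expect_error(relative_volume_difference(f, e), class = "ce_undefined_metric")
  expect_error(surface_points(e), class = "ce_undefined_metric")
  expect_error(directed_surface_distances(f, e), class = "ce_undefined_metric")
  expect_error(centroid_distance(e, f), class = "ce_undefined_metric")
  expect_error(metric_set(e, f), class = "ce_undefined_metric")
  expect_error(metric_set(f, e), class = "ce_undefined_metric")
})

test_that("surface extraction matches the 6-neighbour definition", {
  s1 <- single_voxel_mask(c(5, 5, 5), c(3, 3, 3))
  expect_equal(surface_points(s1), matrix(c(2, 2, 2), 1), ignore_attr = TRUE)
  s3 <- voxel_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  expect_equal(nrow(surface_points(s3)), 26)
  s5 <- voxel_mask(array(TRUE, c(5, 5, 5)), c(1, 1, 1))
  expect_equal(nrow(surface_points(s5)), 98) # brute-force count over 125 voxels
  set.seed(101)
  for (i in 1:5) {
    m <- random_mask(c(9, 8, 7), p = 0.35, spacing = c(1.5, 1, 2))
    got <- surface_points(m)
    want <- bf_surface_coords(m)
    expect_equal(got[order(got[, 1], got[, 2], got[, 3]), ],
                 want[order(want[, 1], want[, 2], want[, 3]), ])
  }
})

test_that("single-voxel distances are exact", {
  a <- single_voxel_mask(c(9, 9, 9), c(2, 5, 5))
  b <- single_voxel_mask(c(9, 9, 9), c(5, 5, 5))
  expect_equal(directed_surface_distances(a, b), 3.0)
  expect_equal(average_surface_distance(a, b), 3.0)
  expect_equal(hausdorff_percentile(a, b, 95), 3.0)
  expect_equal(centroid_distance(a, b), 3.0)
})

test_that("surface distances match the exhaustive all-pairs oracle", {
  set.seed(202)
  for (i in 1:8) {
    sp <- c(sample(c(1, 1.25, 2.5), 1), 1, sample(c(1, 2), 1))
    a <- random_mask(c(12, 12, 12), p = 0.25, spacing = sp)
    b <- random_mask(c(12, 12, 12), p = 0.25, spacing = sp)
    got_ab <- sort(directed_surface_distances(a, b))
    want_ab <- sort(bf_directed(a, b))
    expect_equal(got_ab, want_ab, tolerance = 1e-12)
    expect_equal(average_surface_distance(a, b),
                 mean(c(bf_directed(a, b), bf_directed(b, a))),
                 tolerance = 1e-12)
    expect_equal(hausdorff_percentile(a, b, 100),
                 max(c(max(bf_directed(a, b)), max(bf_directed(b, a)))),
                 tolerance = 1e-12)
    expect_equal(centroid_distance(a, b), bf_centroid_distance(a, b),
                 tolerance = 1e-12)
  }
})

test_that("centroid distance reproduces a 3-4-5 translation", {
  base <- cube_mask(dim = c(20, 30, 30), from = c(6, 6, 6))
  moved <- cube_mask(dim = c(20, 30, 30), from = c(9, 10, 6))
  expect_equal(centroid_distance(base, moved), 5.0)
})

test_that("hausdorff percentile validates p", {
  p <- shifted_cube_pair()
  expect_error(hausdorff_percentile(p$a, p$b, 0), class = "ce_invalid_parameter")
  expect_error(hausdorff_percentile(p$a, p$b, 101), class = "ce_invalid_parameter")
  expect_equal(hausdorff_percentile(p$a, p$a, 50), 0.0)
})

test_that("metric_set agrees with the standalone metrics", {
  set.seed(303)
  a <- random_mask(c(12, 12, 12), p = 0.3, spacing = c(2.5, 1, 1))
  b <- random_mask(c(12, 12, 12), p = 0.3, spacing = c(2.5, 1, 1))
  ms <- metric_set(a, b)
  expect_equal(ms$dsc, dice(a, b))
  expect_equal(ms$ci, conformity_index(a, b))
  expect_equal(ms$inclusion, inclusion_index(a, b))
  expect_equal(ms$rvd, relative_volume_difference(a, b))
  expect_equal(ms$asd, average_surface_distance(a, b))
  expect_equal(ms$dc, centroid_distance(a, b))
  expect_equal(ms$hd95, hausdorff_percentile(a, b, 95))
  expect_equal(ms$volume, mask_volume(a))
  identical_ms <- metric_set(a, a)
  expect_equal(identical_ms$dsc, 1)
  expect_equal(identical_ms$ci, 1)
  expect_equal(identical_ms$inclusion, 1)
  expect_equal(identical_ms$rvd, 0)
  expect_equal(identical_ms$asd, 0)
  expect_equal(identical_ms$dc, 0)
  expect_equal(identical_ms$hd95, 0)
})

test_that("symmetric metrics are invariant under argument swap", {
  set.seed(404)
  for (i in 1:4) {
    a <- random_mask(c(10, 11, 9), p = 0.3, spacing = c(1.25, 1.25, 5))
    b <- random_mask(c(10, 11, 9), p = 0.3, spacing = c(1.25, 1.25, 5))
    expect_equal(dice(a, b), dice(b, a))
    expect_equal(conformity_index(a, b), conformity_index(b, a))
    expect_equal(average_surface_distance(a, b), average_surface_distance(b, a))
    expect_equal(hausdorff_percentile(a, b, 95), hausdorff_percentile(b, a, 95))
    expect_equal(centroid_distance(a, b), centroid_distance(b, a))
  }
})

test_that("Dice-Jaccard identity holds on random pairs", {
  set.seed(505)
  for (i in 1:10) {
    a <- random_mask(c(11, 10, 9), p = 0.35)
    b <- random_mask(c(11, 10, 9), p = 0.35)
    dsc <- dice(a, b)
    expect_equal(conformity_index(a, b), dsc / (2 - dsc), tolerance = 1e-12)
  }
})

test_that("metrics are invariant under joint integer-voxel translation", {
  set.seed(606)
  a <- random_mask(c(10, 10, 10), p = 0.4, spacing = c(1, 2, 1.25))
  b <- random_mask(c(10, 10, 10), p = 0.4, spacing = c(1, 2, 1.25))
  shift <- function(m, k) {
    d <- dim(m$occupancy) + k
    occ <- array(FALSE, d)
    occ[(k[1] + 1):d[1], (k[2] + 1):d[2], (k[3] + 1):d[3]] <- m$occupancy
    voxel_mask(occ, m$spacing, m$origin)
  }
  k <- c(3, 2, 4)
  a2 <- shift(a, k); b2 <- shift(b, k)
  expect_equal(metric_set(a2, b2)[], metric_set(a, b)[])
})

test_that("distances scale linearly and volume cubically with spacing", {
  set.seed(707)
  occ_a <- array(runif(1000) < 0.3, c(10, 10, 10))
  occ_b <- array(runif(1000) < 0.3, c(10, 10, 10))
  k <- 2.5
  a1 <- voxel_mask(occ_a, c(1, 1.5, 2)); b1 <- voxel_mask(occ_b, c(1, 1.5, 2))
  a2 <- voxel_mask(occ_a, k * c(1, 1.5, 2)); b2 <- voxel_mask(occ_b, k * c(1, 1.5, 2))
  m1 <- metric_set(a1, b1); m2 <- metric_set(a2, b2)
  expect_equal(m2$asd, k * m1$asd)
  expect_equal(m2$dc, k * m1$dc)
  expect_equal(m2$hd95, k * m1$hd95)
  expect_equal(m2$volume, k^3 * m1$volume)
  expect_equal(m2$dsc, m1$dsc)
  expect_equal(m2$ci, m1$ci)
  expect_equal(m2$inclusion, m1$inclusion)
  expect_equal(m2$rvd, m1$rvd)
})

test_that("dilating the test mask toward the reference never decreases inclusion", {
  ref <- make_reference_mask(reference_shape(semi_axes = c(25, 22, 20)),
                             grid_spec(dim = c(16, 50, 50),
                                       spacing = c(5, 1.25, 1.25)))
  test <- perturb_mask(ref, perturbation_spec(boundary_growth = -6, seed = 9))
  incl <- vapply(c(-6, -4, -2, 0, 2), function(g)
    inclusion_index(perturb_mask(ref, perturbation_spec(boundary_growth = g,
                                                        seed = 9)), ref),
    numeric(1))
  expect_true(all(diff(incl) >= 0))
  expect_lt(inclusion_index(test, ref), 1)
})
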