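#' Overlap and boundary-accuracy metrics for contour pairs
#'
#' These functions implement the standard battery used to score observer
#' delineations against a reference volume: spatial overlap and consistency
#' (Dice similarity coefficient, Jaccard conformity index, inclusion index,
#' relative volume difference) and geometric boundary accuracy (average
#' surface distance, centroid distance, percentile Hausdorff distance), plus
#' the structure volume itself. Surface distances are computed between voxel
#' centres via an exact Euclidean distance transform that honours anisotropic
#' spacing.
#'
#' @name contour_metrics
NULL

intersection_count <- function(a, b) sum(a$occupancy & b$occupancy)

#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical masks, 0 for disjoint masks.
#' Undefined (an error) when both masks are empty.
#'
#' @param a,b [voxel_mask] objects on the same grid.
#' @return Unitless value in \[0, 1\].
#' @export
dice <- function(a, b) {
  assert_mask(a, "a"); assert_mask(b, "b")
  assert_same_grid(a, b)
  na <- n_foreground(a); nb <- n_foreground(b)
  if (na + nb == 0)
    err_undefined_metric("dice is undefined for two empty masks")
  2 * intersection_count(a, b) / (na + nb)
}

#' Conformity index (Jaccard)
#'
#' `|A n B| / |A u B|`. Related to the Dice coefficient by
#' `CI = DSC / (2 - DSC)`.
#'
#' @inheritParams dice
#' @return Unitless value in \[0, 1\].
#' @export
conformity_index <- function(a, b) {
  assert_mask(a, "a"); assert_mask(b, "b")
  assert_same_grid(a, b)
  na <- n_foreground(a); nb <- n_foreground(b)
  if (na + nb == 0)
    err_undefined_metric("conformity index is undefined for two empty masks")
  inter <- intersection_count(a, b)
  inter / (na + nb - inter)
}

#' Inclusion index
#'
#' Fraction of the reference volume covered by the test contour:
#' `|test n ref| / |ref|`.
#'
#' @param test,ref [voxel_mask] objects on the same grid; `ref` non-empty.
#' @return Unitless value in \[0, 1\].
#' @export
inclusion_index <- function(test, ref) {
  assert_mask(test, "test"); assert_mask(ref, "ref")
  assert_same_grid(test, ref)
  nr <- n_foreground(ref)
  if (nr == 0)
    err_undefined_metric("inclusion index is undefined for an empty reference")
  intersection_count(test, ref) / nr
}

#' Relative volume difference
#'
#' `(V_test - V_ref) / V_ref`: negative when the test contour is smaller
#' than the reference.
#'
#' @inheritParams inclusion_index
#' @return Signed unitless fraction.
#' @export
relative_volume_difference <- function(test, ref) {
  assert_mask(test, "test"); assert_mask(ref, "ref")
  assert_same_grid(test, ref)
  vr <- mask_volume(ref)
  if (vr == 0)
    err_undefined_metric("relative volume difference is undefined for an empty reference")
  (mask_volume(test) - vr) / vr
}

# logical array marking foreground voxels with >=1 background 6-neighbour
# (out-of-bounds counts as background)
surface_voxels <- function(occ) {
  d <- dim(occ)
  bg <- !occ
  any_bg <- array(FALSE, d)
  shift_bg <- function(axis, dir) {
    s <- array(TRUE, d) # OOB neighbours are background
    if (d[axis] > 1) {
      src <- lapply(d, seq_len)
      dst <- lapply(d, seq_len)
      if (dir > 0) { dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis] }
      else         { dst[[axis]] <- 2:d[axis];       src[[axis]] <- 1:(d[axis] - 1) }
      s[dst[[1]], dst[[2]], dst[[3]]] <- bg[src[[1]], src[[2]], src[[3]]]
    }
    s
  }
  for (axis in 1:3) for (dir in c(-1, 1)) any_bg <- any_bg | shift_bg(axis, dir)
  occ & any_bg
}

#' Surface points of a mask
#'
#' Physical coordinates (mm) of the centres of surface voxels: foreground
#' voxels with at least one background 6-neighbour (the grid boundary counts
#' as background). These points are the support of all surface-distance
#' metrics.
#'
#' @param mask A non-empty [voxel_mask].
#' @return An n x 3 numeric matrix of coordinates, mm.
#' @export
surface_points <- function(mask) {
  assert_mask(mask)
  if (n_foreground(mask) == 0)
    err_undefined_metric("surface is undefined for an empty mask")
  voxel_coords(mask, which(surface_voxels(mask$occupancy)))
}

#' Directed surface distances
#'
#' For every surface point of `src`, the Euclidean distance (mm, honouring
#' anisotropic spacing) to the nearest surface point of `dst`, computed with
#' an exact distance transform seeded at the surface of `dst`.
#'
#' @param src,dst Non-empty [voxel_mask] objects on the same grid.
#' @return Numeric vector of length `nrow(surface_points(src))`.
#' @export
directed_surface_distances <- function(src, dst) {
  assert_mask(src, "src"); assert_mask(dst, "dst")
  assert_same_grid(src, dst)
  if (n_foreground(src) == 0 || n_foreground(dst) == 0)
    err_undefined_metric("surface distances are undefined for an empty mask")
  surf_src <- surface_voxels(src$occupancy)
  surf_dst <- surface_voxels(dst$occupancy)
  dsq <- edt_sq(surf_dst, src$spacing)
  sqrt(dsq[which(surf_src)])
}

#' Average surface distance
#'
#' Symmetric: the mean of the pooled list concatenating the directed
#' distances a to b and b to a. Zero iff the two surfaces coincide.
#'
#' @inheritParams dice
#' @return Distance in mm.
#' @export
average_surface_distance <- function(a, b) {
  mean(c(directed_surface_distances(a, b), directed_surface_distances(b, a)))
}

#' Percentile Hausdorff distance
#'
#' The maximum of the p-th percentiles (linear-interpolation quantile) of the
#' two directed surface-distance lists. `p = 100` recovers the classical
#' Hausdorff distance; `p = 95` is the robust variant conventional in
#' medical image segmentation.
#'
#' @inheritParams dice
#' @param p Percentile in (0, 100].
#' @return Distance in mm.
#' @export
hausdorff_percentile <- function(a, b, p = 95) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 100)
    err_invalid_parameter("percentile p must lie in (0, 100]")
  dab <- directed_surface_distances(a, b)
  dba <- directed_surface_distances(b, a)
  max(quantile(dab, p / 100, names = FALSE, type = 7),
      quantile(dba, p / 100, names = FALSE, type = 7))
}

#' Distance between centres of mass
#'
#' Euclidean distance (mm) between the physical-space centroids of the two
#' masks (unweighted mean of foreground voxel centres).
#'
#' @inheritParams dice
#' @return Distance in mm.
#' @export
centroid_distance <- function(a, b) {
  assert_mask(a, "a"); assert_mask(b, "b")
  assert_same_grid(a, b)
  if (n_foreground(a) == 0 || n_foreground(b) == 0)
    err_undefined_metric("centroid is undefined for an empty mask")
  ca <- colMeans(voxel_coords(a))
  cb <- colMeans(voxel_coords(b))
  sqrt(sum((ca - cb)^2))
}

#' Full metric set for one contour pair
#'
#' Computes all eight per-pair quality numbers in one pass (sharing the
#' directed-distance lists): `dsc`, `ci`, `inclusion`, `rvd`, `asd` (mm),
#' `dc` (mm), `hd95` (mm, at the requested percentile) and `volume` (cm^3,
#' of the test contour). Each field equals the corresponding standalone
#' function's value.
#'
#' @inheritParams inclusion_index
#' @param hd_p Percentile for the Hausdorff distance (default 95).
#' @return A `metric_set` object (named list of the eight values).
#' @export
metric_set <- function(test, ref, hd_p = 95) {
  assert_mask(test, "test"); assert_mask(ref, "ref")
  assert_same_grid(test, ref)
  if (n_foreground(ref) == 0)
    err_undefined_metric("metric set is undefined for an empty reference mask")
  if (n_foreground(test) == 0)
    err_undefined_metric("metric set (dsc/asd/hd95/...) is undefined for an empty test mask")
  if (!is.numeric(hd_p) || length(hd_p) != 1L || is.na(hd_p) || hd_p <= 0 || hd_p > 100)
    err_invalid_parameter("percentile hd_p must lie in (0, 100]")
  dsc <- dice(test, ref)
  d_tr <- directed_surface_distances(test, ref)
  d_rt <- directed_surface_distances(ref, test)
  structure(list(
    dsc = dsc,
    ci = conformity_index(test, ref),
    inclusion = inclusion_index(test, ref),
    rvd = relative_volume_difference(test, ref),
    asd = mean(c(d_tr, d_rt)),
    dc = centroid_distance(test, ref),
    hd95 = max(quantile(d_tr, hd_p / 100, names = FALSE, type = 7),
               quantile(d_rt, hd_p / 100, names = FALSE, type = 7)),
    volume = mask_volume(test)
  ), class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(paste0(
    "<metric_set> dsc %.3f | ci %.3f | inclusion %.3f | rvd %+.3f | ",
    "asd %.2f mm | dc %.2f mm | hd95 %.2f mm | volume %.2f cm^3\n"),
    x$dsc, x$ci, x$inclusion, x$rvd, x$asd, x$dc, x$hd95, x$volume))
  invisible(x)
}

# one tidy row per metric_set, with the CSV column names of the cohort table
metric_row <- function(ms) {
  tibble::tibble(dsc = ms$dsc, ci = ms$ci, inclusion = ms$inclusion,
                 rvd = ms$rvd, asd_mm = ms$asd, dc_mm = ms$dc,
                 hd95_mm = ms$hd95, volume_cm3 = ms$volume)
}
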