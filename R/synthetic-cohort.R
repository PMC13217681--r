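#' Grid specification for synthetic masks
#'
#' Default grid echoes a pelvic planning CT rasterisation: 5 mm slices with
#' 1.25 mm in-plane resolution (axis 1 = slice axis), 40 x 160 x 160 voxels
#' (200 x 200 x 200 mm extent).
#'
#' @param dim Integer length-3 voxel counts per axis.
#' @param spacing Numeric length-3 voxel size per axis, mm.
#' @param origin Physical coordinate of the first voxel centre, mm.
#' @return A `grid_spec` list.
#' @export
grid_spec <- function(dim = c(40, 160, 160), spacing = c(5, 1.25, 1.25),
                      origin = c(0, 0, 0)) {
  dim <- as.integer(dim); spacing <- as.numeric(spacing)
  if (length(dim) != 3L || any(is.na(dim)) || any(dim < 1))
    err_invalid_geometry("grid dim must be three positive integers")
  if (length(spacing) != 3L || any(is.na(spacing)) || any(spacing <= 0))
    err_invalid_geometry("grid spacing must be three positive values (mm)")
  structure(list(dim = dim, spacing = spacing, origin = as.numeric(origin)),
            class = "grid_spec")
}

#' Reference-shape specification
#'
#' An axis-aligned ellipsoid (optionally with unioned spherical side-lobes,
#' e.g. nodal regions) standing in for an expert reference clinical target
#' volume. The default semi-axes (60, 50, 52) mm give an analytic volume of
#' ~654 cm^3, the scale of a definitive-radiotherapy cervical-cancer CTV.
#'
#' @param semi_axes Numeric length-3 ellipsoid semi-axes, mm (all > 0).
#' @param center Physical centre, mm; default the grid centre.
#' @param lobes Optional list of spherical lobes, each a list with
#'   `offset` (mm, relative to the centre) and `radius` (mm).
#' @return A `reference_shape` list.
#' @export
reference_shape <- function(semi_axes = c(60, 50, 52), center = NULL,
                            lobes = NULL) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) != 3L || any(is.na(semi_axes)) || any(semi_axes <= 0))
    err_invalid_geometry("semi_axes must be three strictly positive values (mm)")
  structure(list(semi_axes = semi_axes, center = center, lobes = lobes),
            class = "reference_shape")
}

#' Rasterise a reference mask
#'
#' Deterministically rasterises the reference shape on the grid: a voxel is
#' foreground when its centre lies inside the ellipsoid (or any lobe). The
#' shape must fit inside the grid's physical extent.
#'
#' @param shape A [reference_shape()].
#' @param grid A [grid_spec()].
#' @return A [voxel_mask].
#' @export
make_reference_mask <- function(shape = reference_shape(), grid = grid_spec()) {
  if (!inherits(shape, "reference_shape")) shape <- do.call(reference_shape, shape)
  if (!inherits(grid, "grid_spec")) grid <- do.call(grid_spec, grid)
  extent <- (grid$dim - 1) * grid$spacing
  center <- shape$center
  if (is.null(center)) center <- grid$origin + extent / 2
  lo <- center - shape$semi_axes - grid$origin
  hi <- center + shape$semi_axes - grid$origin
  if (any(lo < -1e-9) || any(hi > extent + 1e-9))
    err_invalid_geometry("reference shape does not fit inside the grid")
  ax <- lapply(1:3, function(a)
    grid$origin[a] + (seq_len(grid$dim[a]) - 1) * grid$spacing[a])
  u <- lapply(1:3, function(a) ((ax[[a]] - center[a]) / shape$semi_axes[a])^2)
  occ <- outer(outer(u[[1]], u[[2]], `+`), u[[3]], `+`) <= 1
  if (!is.null(shape$lobes)) {
    for (lb in shape$lobes) {
      cc <- center + lb$offset
      v <- lapply(1:3, function(a) (ax[[a]] - cc[a])^2)
      occ <- occ | (outer(outer(v[[1]], v[[2]], `+`), v[[3]], `+`) <= lb$radius^2)
    }
  }
  voxel_mask(occ, spacing = grid$spacing, origin = grid$origin)
}

#' Perturbation severity specification
#'
#' Parameters of the stochastic observer-contour model: a rigid translation
#' (per-axis normal, `translation_sd` mm, quantised to whole voxels), a
#' uniform boundary growth/erosion whose magnitude is drawn per realisation
#' from `N(boundary_growth, growth_sd)` mm (positive = dilation), and a
#' spatially correlated radial jitter of the boundary with pointwise
#' standard deviation `surface_noise_sd` mm and correlation length
#' `noise_corr_len` mm. The three ingredients map onto the failure modes the
#' quality metrics separate: translation moves the centroid (DC), net growth
#' changes volume (RVD, and drives interobserver volume dispersion), and
#' jitter roughens the boundary (ASD, 95%HD, DSC).
#'
#' @param translation_sd Per-axis SD of the rigid shift, mm (>= 0).
#' @param boundary_growth Mean uniform growth, mm (signed; < 0 erodes).
#' @param growth_sd SD of the per-realisation growth draw, mm (>= 0).
#' @param surface_noise_sd SD of the radial boundary jitter, mm (>= 0).
#' @param noise_corr_len Correlation length of the jitter field, mm (> 0).
#' @param seed Optional integer; fixing it makes [perturb_mask()] bitwise
#'   reproducible.
#' @return A `perturbation_spec` list.
#' @export
perturbation_spec <- function(translation_sd = 0, boundary_growth = 0,
                              growth_sd = 0, surface_noise_sd = 0,
                              noise_corr_len = 25, seed = NULL) {
  for (v in c(translation_sd, growth_sd, surface_noise_sd))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      err_invalid_parameter("severities must be non-negative scalars")
  if (!is.numeric(noise_corr_len) || noise_corr_len <= 0)
    err_invalid_parameter("noise_corr_len must be positive (mm)")
  structure(list(translation_sd = translation_sd,
                 boundary_growth = boundary_growth, growth_sd = growth_sd,
                 surface_noise_sd = surface_noise_sd,
                 noise_corr_len = noise_corr_len, seed = seed),
            class = "perturbation_spec")
}

# smooth Gaussian random field sampled at arbitrary physical points:
# white noise on a coarse lattice (node pitch = correlation length) spanning
# [lo, hi], trilinearly interpolated. Returns a sampler closure.
make_noise_field <- function(lo, hi, sd, corr_len) {
  nc <- pmax(2L, as.integer(ceiling((hi - lo) / corr_len)) + 2L)
  coarse <- array(rnorm(prod(nc), 0, sd), dim = nc)
  function(points) {
    n <- nrow(points)
    val <- numeric(n)
    pos <- lapply(1:3, function(a) {
      t <- (points[, a] - lo[a]) / corr_len
      pmin(pmax(t, 0), nc[a] - 1 - 1e-9)
    })
    i0 <- lapply(pos, floor)
    w <- lapply(1:3, function(a) pos[[a]] - i0[[a]])
    for (da in 0:1) for (db in 0:1) for (dc in 0:1) {
      wa <- if (da) w[[1]] else 1 - w[[1]]
      wb <- if (db) w[[2]] else 1 - w[[2]]
      wc <- if (dc) w[[3]] else 1 - w[[3]]
      idx <- cbind(i0[[1]] + 1 + da, i0[[2]] + 1 + db, i0[[3]] + 1 + dc)
      val <- val + coarse[idx] * wa * wb * wc
    }
    val
  }
}

# integer-voxel shift of a 3D logical array; exposed voxels become FALSE
shift_array <- function(occ, k) {
  d <- dim(occ)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (abs(k[a]) >= d[a]) return(out)
    if (k[a] >= 0) { dst[[a]] <- (1 + k[a]):d[a]; src[[a]] <- 1:(d[a] - k[a]) }
    else           { dst[[a]] <- 1:(d[a] + k[a]); src[[a]] <- (1 - k[a]):d[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- occ[src[[1]], src[[2]], src[[3]]]
  out
}

#' Stochastically perturb a mask into an observer contour
#'
#' Applies, in order: a rigid translation drawn per axis from
#' `N(0, translation_sd)` and rounded to whole voxels; then a signed-distance
#' reshaping that combines the uniform growth draw `g ~ N(boundary_growth,
#' growth_sd)` with the correlated radial jitter field `f` — the output
#' keeps every voxel whose signed distance to the (shifted) boundary
#' satisfies `s(x) - f(x) <= g`. A spec with all severities zero returns the
#' input mask unchanged; a fixed `seed` makes the output bitwise
#' reproducible.
#'
#' @param ref A non-empty [voxel_mask].
#' @param spec A [perturbation_spec()].
#' @return A [voxel_mask] on the same grid.
#' @export
perturb_mask <- function(ref, spec) {
  assert_mask(ref, "ref")
  if (!inherits(spec, "perturbation_spec")) spec <- do.call(perturbation_spec, spec)
  if (n_foreground(ref) == 0)
    err_undefined_metric("cannot perturb an empty mask")
  runner <- function() {
    occ <- ref$occupancy
    if (spec$translation_sd > 0) {
      off <- rnorm(3, 0, spec$translation_sd)
      occ <- shift_array(occ, as.integer(round(off / ref$spacing)))
    }
    g <- spec$boundary_growth
    if (spec$growth_sd > 0) g <- g + rnorm(1, 0, spec$growth_sd)
    if (g != 0 || spec$surface_noise_sd > 0) {
      if (!any(occ)) err_degenerate_output("perturbation emptied the mask")
      # signed distance to the rasterised boundary: distances are measured
      # to the occupied voxel *region*, so the zero level sits on the true
      # voxel faces rather than half a voxel inside
      cap <- abs(g) + 6 * spec$surface_noise_sd + 2 * max(ref$spacing)
      d_out <- sqrt(region_dt_sq(occ, ref$spacing, cap))  # 0 inside
      d_in <- sqrt(region_dt_sq(!occ, ref$spacing, cap))  # 0 outside
      signed <- array(d_out - d_in, dim(occ))
      keep <- signed <= g
      if (spec$surface_noise_sd > 0) {
        # radial jitter: the noise is constant along rays from the centroid
        # (sampled where the ray pierces the mean-radius sphere), so the
        # boundary moves coherently in and out without spawning islands
        tmp <- voxel_mask(occ, ref$spacing, ref$origin)
        cen <- colMeans(voxel_coords(tmp))
        r0 <- (3 * mask_volume(tmp) * 1000 / (4 * pi))^(1 / 3)
        fband <- 6 * spec$surface_noise_sd
        idx <- which(signed > g - fband & signed < g + fband)
        if (length(idx)) {
          co <- voxel_coords(tmp, idx)
          dvec <- sweep(co, 2, cen)
          r <- pmax(sqrt(rowSums(dvec^2)), 1e-6)
          proj <- sweep(dvec * (r0 / r), 2, cen, `+`)
          lo <- ref$origin
          hi <- ref$origin + (dim(occ) - 1) * ref$spacing
          field <- make_noise_field(lo, hi, spec$surface_noise_sd,
                                    spec$noise_corr_len)
          # centre the field over directions (Fibonacci sphere) so jitter
          # reshapes the boundary without a net-volume mode; volume
          # dispersion is then governed by growth_sd alone
          k <- seq_len(512)
          zs <- 1 - (2 * k - 1) / 512
          th <- pi * (1 + sqrt(5)) * k
          dirs <- cbind(sqrt(1 - zs^2) * cos(th), sqrt(1 - zs^2) * sin(th), zs)
          fbar <- mean(field(sweep(dirs * r0, 2, cen, `+`)))
          keep[idx] <- (signed[idx] - (field(proj) - fbar)) <= g
        }
      }
      occ <- array(keep, dim(occ))
    }
    if (!any(occ)) err_degenerate_output("perturbation emptied the mask")
    voxel_mask(occ, spacing = ref$spacing, origin = ref$origin)
  }
  if (is.null(spec$seed)) runner() else with_local_seed(spec$seed, runner())
}

# evaluate expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Cohort-simulation specification
#'
#' Bundles everything needed to emulate a structured-training contouring
#' study: the reference shape and grid, the pre- and post-training
#' perturbation severities (post < pre under the default training scenario),
#' and the latent parameters of the 5-point Likert questionnaire (a shared
#' per-observer aptitude, item noise, and a positive post-training shift;
#' latent values are rounded and clipped to 1..5). The default severities
#' are calibrated so that a default-grid cohort lands in the reported range
#' of a pelvic CTV study: mean volume ~650-680 cm^3 with SD of tens of cm^3,
#' pre-training Dice ~0.78-0.82 improving post-training.
#'
#' @param n_observers Number of observers (>= 2).
#' @param pre,post [perturbation_spec()] for each phase.
#' @param shape,grid Reference geometry, see [reference_shape()] and
#'   [grid_spec()].
#' @param likert_items Character vector of questionnaire item labels.
#' @param likert_pre_mean Latent pre-training mean score.
#' @param likert_shift Latent post-training improvement.
#' @param likert_person_sd SD of the shared per-observer aptitude.
#' @param likert_item_sd SD of the per-item noise.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_observers = 19,
                        pre = perturbation_spec(translation_sd = 3,
                                                boundary_growth = -1.2,
                                                growth_sd = 1.9,
                                                surface_noise_sd = 12),
                        post = perturbation_spec(translation_sd = 2,
                                                 boundary_growth = -0.8,
                                                 growth_sd = 1.35,
                                                 surface_noise_sd = 10),
                        shape = reference_shape(),
                        grid = grid_spec(),
                        likert_items = c("confidence", "principles", "CTV-U",
                                         "CTV-C", "CTV-Np", "CTV-Na"),
                        likert_pre_mean = 3.4, likert_shift = 0.85,
                        likert_person_sd = 0.55, likert_item_sd = 0.65) {
  if (!is.numeric(n_observers) || n_observers < 2)
    err_invalid_parameter("n_observers must be >= 2")
  if (!inherits(pre, "perturbation_spec")) pre <- do.call(perturbation_spec, pre)
  if (!inherits(post, "perturbation_spec")) post <- do.call(perturbation_spec, post)
  structure(list(n_observers = as.integer(n_observers), pre = pre, post = post,
                 shape = shape, grid = grid, likert_items = likert_items,
                 likert_pre_mean = likert_pre_mean, likert_shift = likert_shift,
                 likert_person_sd = likert_person_sd,
                 likert_item_sd = likert_item_sd),
            class = "cohort_spec")
}

# counter-based sub-seed: adding observers never reshuffles earlier ones
sub_seed <- function(master, i, counter) {
  (as.numeric(master) %% 500009) * 4000 + i * 8 + counter
}

#' Simulate a complete contouring cohort
#'
#' Generates the reference mask, one pre- and one post-training contour per
#' observer (each from an independent counter-derived sub-seed of the master
#' seed, so the cohort is bitwise reproducible and earlier observers are
#' unaffected by later ones), and a paired Likert questionnaire with a
#' positive latent post-training shift.
#'
#' @param spec A [cohort_spec()].
#' @param seed Master integer seed.
#' @return List with `reference` ([voxel_mask]), `cohort` (tibble
#'   `observer_id`, `case_id`, `phase`, `structure`, `mask` list-column) and
#'   `likert` (tibble `observer_id`, `item_id`, `pre`, `post`).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed) {
  if (!inherits(spec, "cohort_spec")) err_invalid_parameter("spec must be a cohort_spec")
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    err_invalid_parameter("a single integer master seed is required")
  ref <- make_reference_mask(spec$shape, spec$grid)
  rows <- list()
  for (i in seq_len(spec$n_observers)) {
    oid <- sprintf("obs%02d", i)
    for (phase in c("pre", "post")) {
      ps <- if (phase == "pre") spec$pre else spec$post
      ps$seed <- sub_seed(seed, i, if (phase == "pre") 0 else 1)
      m <- tryCatch(perturb_mask(ref, ps), error = function(e)
        ce_error(sprintf("observer %s (%s): %s", oid, phase,
                         conditionMessage(e)), class(e)[1]))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        observer_id = oid, case_id = "case1", phase = phase,
        structure = "CTV", mask = list(m))
    }
  }
  likert <- list()
  for (i in seq_len(spec$n_observers)) {
    oid <- sprintf("obs%02d", i)
    sc <- with_local_seed(sub_seed(seed, i, 2), {
      aptitude <- rnorm(1, 0, spec$likert_person_sd)
      pre_lat <- spec$likert_pre_mean + aptitude +
        rnorm(length(spec$likert_items), 0, spec$likert_item_sd)
      post_lat <- pre_lat + spec$likert_shift +
        rnorm(length(spec$likert_items), 0, spec$likert_item_sd / 2)
      list(pre = pmin(5L, pmax(1L, as.integer(round(pre_lat)))),
           post = pmin(5L, pmax(1L, as.integer(round(post_lat)))))
    })
    likert[[length(likert) + 1L]] <- tibble::tibble(
      observer_id = oid, item_id = spec$likert_items,
      pre = sc$pre, post = sc$post)
  }
  list(reference = ref, cohort = dplyr::bind_rows(rows),
       likert = dplyr::bind_rows(likert))
}
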