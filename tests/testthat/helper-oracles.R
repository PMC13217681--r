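# mask builders -------------------------------------------------------------

cube_mask <- function(dim = c(20, 20, 20), from = c(6, 6, 6), size = 10,
                      spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  occ <- array(FALSE, dim)
  occ[from[1]:(from[1] + size - 1),
      from[2]:(from[2] + size - 1),
      from[3]:(from[3] + size - 1)] <- TRUE
  voxel_mask(occ, spacing = spacing, origin = origin)
}

random_mask <- function(dim, p = 0.3, spacing = c(1, 1, 1)) {
  occ <- array(runif(prod(dim)) < p, dim)
  if (!any(occ)) occ[ceiling(prod(dim) / 2)] <- TRUE
  voxel_mask(occ, spacing = spacing)
}

single_voxel_mask <- function(dim, at, spacing = c(1, 1, 1)) {
  occ <- array(FALSE, dim)
  occ[at[1], at[2], at[3]] <- TRUE
  voxel_mask(occ, spacing = spacing)
}

# brute-force oracles --------------------------------------------------------

# surface voxels by explicit 6-neighbour check
bf_surface_coords <- function(mask) {
  occ <- mask$occupancy
  d <- dim(occ)
  idx <- which(occ)
  ijk <- arrayInd(idx, d)
  on_surface <- vapply(seq_len(nrow(ijk)), function(r) {
    p <- ijk[r, ]
    for (a in 1:3) for (s in c(-1L, 1L)) {
      q <- p; q[a] <- q[a] + s
      if (q[a] < 1 || q[a] > d[a]) return(TRUE)
      if (!occ[q[1], q[2], q[3]]) return(TRUE)
    }
    FALSE
  }, logical(1))
  co <- sweep(sweep(ijk[on_surface, , drop = FALSE] - 1, 2, mask$spacing, `*`),
              2, mask$origin, `+`)
  co
}

# all-pairs directed nearest-surface distances
bf_directed <- function(src, dst) {
  a <- bf_surface_coords(src)
  b <- bf_surface_coords(dst)
  vapply(seq_len(nrow(a)), function(i)
    min(sqrt(colSums((t(b) - a[i, ])^2))), numeric(1))
}

bf_centroid_distance <- function(a, b) {
  ca <- colMeans(sweep(sweep(arrayInd(which(a$occupancy), dim(a$occupancy)) - 1,
                             2, a$spacing, `*`), 2, a$origin, `+`))
  cb <- colMeans(sweep(sweep(arrayInd(which(b$occupancy), dim(b$occupancy)) - 1,
                             2, b$spacing, `*`), 2, b$origin, `+`))
  sqrt(sum((ca - cb)^2))
}

# exact two-sided Wilcoxon signed-rank p by enumerating all sign assignments
# (ranks of |d| held fixed, ties kept as averaged ranks)
bf_wilcoxon_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# exact two-sided mid-p (half weight on the observed atom), the quantity the
# uncorrected normal approximation estimates
bf_wilcoxon_exact_midp <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
  w_all <- as.vector(signs %*% r)
  lo <- mean(w_all < w_obs) + 0.5 * mean(w_all == w_obs)
  hi <- mean(w_all > w_obs) + 0.5 * mean(w_all == w_obs)
  min(1, 2 * min(lo, hi))
}

# cohort scales used by simulation-heavy suites ------------------------------

demo_grid <- function() grid_spec(dim = c(30, 60, 60), spacing = c(5, 2.5, 2.5))

demo_cohort_spec <- function(n = 19) cohort_spec(n_observers = n, grid = demo_grid())

tiny_grid <- function() grid_spec(dim = c(20, 40, 40), spacing = c(5, 2.5, 2.5))

tiny_shape <- function() reference_shape(semi_axes = c(38, 33, 35))

# small synthetic cohort with one injected instance of each QC problem
qc_test_cohort <- function() {
  ref <- make_reference_mask(tiny_shape(), tiny_grid())
  spec <- cohort_spec(n_observers = 6, grid = tiny_grid(), shape = tiny_shape())
  sim <- simulate_cohort(spec, seed = 99)
  cohort <- sim$cohort
  likert <- sim$likert
  # obs02: drop the post contour
  cohort <- cohort[!(cohort$observer_id == "obs02" & cohort$phase == "post"), ]
  # obs03: make pre and post identical
  i_pre <- which(cohort$observer_id == "obs03" & cohort$phase == "pre")
  i_post <- which(cohort$observer_id == "obs03" & cohort$phase == "post")
  cohort$mask[[i_post]] <- cohort$mask[[i_pre]]
  # obs04: unreadable mask
  cohort$mask[which(cohort$observer_id == "obs04" & cohort$phase == "pre")] <-
    list(NULL)
  # obs05: questionnaire ceiling
  likert$pre[likert$observer_id == "obs05"] <- 5L
  list(reference = ref, cohort = cohort, likert = likert, sim = sim)
}

# per-observer Dice of each phase against the reference, as a wide table
dice_by_phase <- function(sim) {
  pre <- sim$cohort[sim$cohort$phase == "pre", ]
  post <- sim$cohort[sim$cohort$phase == "post", ]
  post <- post[match(pre$observer_id, post$observer_id), ]
  list(pre = vapply(pre$mask, dice, numeric(1), b = sim$reference),
       post = vapply(post$mask, dice, numeric(1), b = sim$reference))
}
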