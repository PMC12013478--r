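# Shared fixtures and independent oracles, all built in code.

# single-voxel mask helper
point_mask <- function(shape, at, spacing = c(1, 1, 1)) {
  a <- array(FALSE, shape)
  a[at[1], at[2], at[3]] <- TRUE
  binary_mask(a, spacing)
}

# Brute-force oracle for mm-metric dilation: all-pairs center distances.
brute_force_dilate <- function(mask, radius_mm) {
  d <- dim(mask$data)
  sp <- mask$spacing
  idx <- which(mask$data, arr.ind = TRUE)
  if (nrow(idx) == 0) return(mask$data)
  ctrue <- sweep(idx - 1, 2, sp, "*")
  out <- array(FALSE, d)
  all_idx <- which(array(TRUE, d), arr.ind = TRUE)
  call <- sweep(all_idx - 1, 2, sp, "*")
  for (v in seq_len(nrow(all_idx))) {
    d2 <- (call[v, 1] - ctrue[, 1])^2 + (call[v, 2] - ctrue[, 2])^2 +
      (call[v, 3] - ctrue[, 3])^2
    out[all_idx[v, 1], all_idx[v, 2], all_idx[v, 3]] <- any(d2 <= radius_mm^2)
  }
  out
}

# Brute-force Gaussian smoothing at interior voxels (reflective borders are
# irrelevant there), independent of the package's convolution path.
brute_force_smooth <- function(arr, sigma_vox) {
  d <- dim(arr)
  radius <- vapply(sigma_vox, function(s) max(1L, as.integer(ceiling(4 * s))),
                   integer(1))
  kern <- lapply(1:3, function(a) {
    t <- seq.int(-radius[a], radius[a])
    g <- exp(-t^2 / (2 * sigma_vox[a]^2))
    g / sum(g)
  })
  out <- array(NA_real_, d)
  for (i in (radius[1] + 1):(d[1] - radius[1]))
    for (j in (radius[2] + 1):(d[2] - radius[2]))
      for (k in (radius[3] + 1):(d[3] - radius[3])) {
        block <- arr[i + seq.int(-radius[1], radius[1]),
                     j + seq.int(-radius[2], radius[2]),
                     k + seq.int(-radius[3], radius[3])]
        w <- outer(outer(kern[[1]], kern[[2]]), kern[[3]])
        out[i, j, k] <- sum(block * w)
      }
  out
}

# Gaussian-profile cylinder along z: in-plane std `s` voxels, isotropic grid.
gaussian_cylinder <- function(n = 41, nz = 21, s = 1.5) {
  x <- seq_len(n) - (n + 1) / 2
  prof <- exp(-outer(x^2, x^2, "+") / (2 * s^2))
  image_volume(array(rep(prof, nz), c(n, n, nz)), c(1, 1, 1))
}

# eigen_field with constant eigenvalues, for closed-form response checks
const_eigen_field <- function(l1, l2, l3, shape = c(2, 2, 2)) {
  structure(list(l1 = array(l1, shape), l2 = array(l2, shape),
                 l3 = array(l3, shape), spacing = c(1, 1, 1),
                 sigma_voxels = 1, sigma_mm = 1),
            class = "eigen_field")
}

# standard noiseless isotropic recovery phantom used across tests
recovery_phantom <- function(shape = c(64, 64, 64), n_tubes = 5, seed = 7,
                             n_wmh = 0, n_ich = 0) {
  generate_phantom(phantom_spec(
    shape = shape, spacing = c(1, 1, 1), n_tubes = n_tubes,
    tube_radius_range = c(1, 1.5), tube_length_range = c(12, 22),
    orientation = "uniform-random", noise_sigma = 0,
    n_wmh = n_wmh, n_ich = n_ich, seed = seed))
}

# full pipeline on a phantom: sweep thresholds, pick best Dice vs truth
phantom_recovery <- function(ph, thresholds = seq(0.05, 0.95, by = 0.05)) {
  roi <- suppressWarnings(build_nawm_roi(ph$brain_mask, ph$csf_mask, 2.5,
                                         lesion_mask = ph$lesion_mask))
  norm <- normalize_histogram(ph$image)
  vmap <- suppressWarnings(frangi_vesselness(norm, roi))
  sw <- sweep_thresholds(vmap, roi, thresholds)
  dice <- vapply(sw$threshold, function(t)
    dice_coefficient(threshold_vesselness(vmap, roi, t), ph$pvs_truth_mask),
    numeric(1))
  best <- which.max(dice)
  list(roi = roi, vmap = vmap, sweep = sw, dice = dice,
       best_threshold = sw$threshold[best], best_dice = dice[best],
       best_pvs_vf = sw$pvs_vf[best])
}

write_tmp_mask <- function(mask, name = "m.nii.gz") {
  f <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  write_mask(mask, f)
  f
}
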