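#' Specification of a synthetic PVS phantom
#'
#' Describes a ground-truthed T2-like test volume: an ellipsoidal
#' "brain" of white matter wrapped in a one-voxel bright CSF rim,
#' containing straight bright tubes that mimic perivascular spaces,
#' optional bright WMH-like and dark hemorrhage-like spherical lesions,
#' and Rician magnitude noise. The default grid uses the anisotropic
#' 0.50 x 0.56 x 3.60 mm voxels of a typical multi-slice T2 acquisition.
#' Intensities are arbitrary units obeying the T2 brightness ordering
#' (CSF and tubes brighter than white matter, hemorrhage darker).
#'
#' @param shape integer length-3 grid dimensions.
#' @param spacing voxel spacing in mm.
#' @param n_tubes number of PVS-like tubes.
#' @param tube_radius_range tube radius interval in mm.
#' @param tube_length_range tube length interval in mm.
#' @param orientation `"uniform-random"` or `"axis-aligned"`.
#' @param wm_intensity,csf_intensity,tube_intensity white matter / CSF /
#'   tube signal (arbitrary units; `csf`, `tube` > `wm`).
#' @param n_wmh,n_ich counts of bright (WMH-like) and dark (ICH-like)
#'   spherical lesions.
#' @param wmh_intensity,ich_intensity lesion signal (`ich` < `wm`).
#' @param lesion_radius_range lesion radius interval in mm.
#' @param noise_sigma Rician channel standard deviation (intensity units).
#' @param seed mandatory RNG seed; generation is fully deterministic
#'   given the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         spacing = c(0.50, 0.56, 3.60),
                         n_tubes = 10,
                         tube_radius_range = c(0.3, 1.5),
                         tube_length_range = c(10, 25),
                         orientation = c("uniform-random", "axis-aligned"),
                         wm_intensity = 100,
                         csf_intensity = 200,
                         tube_intensity = 180,
                         n_wmh = 0, n_ich = 0,
                         wmh_intensity = 160,
                         ich_intensity = 40,
                         lesion_radius_range = c(2, 5),
                         noise_sigma = 5,
                         seed) {
  orientation <- match.arg(orientation)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("a numeric seed is mandatory")
  shape <- as.integer(shape)
  spacing <- check_spacing(spacing)
  if (length(shape) != 3 || any(shape < 8))
    stop("shape must be three dimensions of at least 8 voxels")
  if (any(tube_radius_range <= 0) || diff(tube_radius_range) < 0)
    stop("tube_radius_range must be a positive increasing interval")
  if (any(tube_length_range <= 0) || diff(tube_length_range) < 0)
    stop("tube_length_range must be a positive increasing interval")
  ints <- c(wm_intensity, csf_intensity, tube_intensity,
            wmh_intensity, ich_intensity)
  if (any(ints < 0)) stop("intensities must be >= 0")
  if (csf_intensity <= wm_intensity || tube_intensity <= wm_intensity)
    stop("T2 ordering violated: csf and tube intensity must exceed wm")
  if (ich_intensity >= wm_intensity)
    stop("T2 ordering violated: ich intensity must be below wm")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(shape = shape, spacing = spacing, n_tubes = n_tubes,
                 tube_radius_range = tube_radius_range,
                 tube_length_range = tube_length_range,
                 orientation = orientation,
                 wm_intensity = wm_intensity, csf_intensity = csf_intensity,
                 tube_intensity = tube_intensity, n_wmh = n_wmh,
                 n_ich = n_ich, wmh_intensity = wmh_intensity,
                 ich_intensity = ich_intensity,
                 lesion_radius_range = lesion_radius_range,
                 noise_sigma = noise_sigma, seed = seed),
            class = "phantom_spec")
}

#' Add Rician magnitude noise to a volume
#'
#' Magnitude-MRI noise: `out = sqrt((v + n1)^2 + n2^2)` with `n1`, `n2`
#' independent zero-mean Gaussians of standard deviation `sigma`. The
#' output is non-negative everywhere; `sigma = 0` returns the input
#' unchanged. At high SNR the model reduces to additive Gaussian noise;
#' on zero signal it yields a Rayleigh field with mean
#' `sigma * sqrt(pi/2)`.
#'
#' @param volume an [image_volume].
#' @param sigma channel standard deviation (>= 0), intensity units.
#' @param seed RNG seed; the caller's RNG state is left untouched.
#' @return A noisy [image_volume].
#' @export
rician_noise <- function(volume, sigma, seed) {
  stopifnot(inherits(volume, "image_volume"))
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(volume)
  with_local_seed(seed, {
    image_volume(rician_corrupt(volume$data, sigma),
                 volume$spacing, volume$affine)
  })
}

# Rician corruption drawing from the current RNG stream.
rician_corrupt <- function(arr, sigma) {
  n <- length(arr)
  array(sqrt((arr + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2), dim(arr))
}

#' Generate a ground-truthed synthetic phantom
#'
#' Builds the volume described by a [phantom_spec] together with every
#' mask the pipeline consumes and the analytic ground truth. Tubes are
#' straight cylinders (a voxel belongs to a tube iff its center lies
#' within the radius of the axis segment), placed fully inside the white
#' matter at least `2.5 mm + radius` away from the CSF so they survive
#' the standard ROI construction, and non-overlapping with each other
#' and with lesions. Lesions are spheres placed after the tubes, so a
#' given seed yields identical tubes whether or not lesions are
#' requested. The NAWM mask is built with [build_nawm_roi()] (2.5 mm
#' CSF dilation, lesion exclusion). The true PVS volume is the analytic
#' `sum(pi r^2 L)` over tubes; the true volume fraction divides it by
#' the NAWM volume.
#'
#' @param spec a [phantom_spec].
#' @return An object of class `phantom_truth`: `image`, `brain_mask`,
#'   `csf_mask`, `lesion_mask`, `pvs_truth_mask`, `nawm_mask`, `tubes`
#'   (data.frame of placed tubes), `true_pvs_volume_mm3`, `true_pvs_vf`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  d <- spec$shape; sp <- spec$spacing
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - 1) * sp[a])
  ctr <- vapply(1:3, function(a) (d[a] - 1) * sp[a] / 2, numeric(1))
  semi <- ctr - sp # one-voxel margin of background

  # voxel center coordinate arrays
  X <- array(ax[[1]], d)
  Y <- array(rep(ax[[2]], each = d[1]), d)
  Z <- array(rep(ax[[3]], each = d[1] * d[2]), d)

  brain <- ((X - ctr[1]) / semi[1])^2 + ((Y - ctr[2]) / semi[2])^2 +
    ((Z - ctr[3]) / semi[3])^2 <= 1
  csf <- brain & !erode_face6(brain)
  wm <- brain & !csf

  # mm distance from each voxel to the nearest non-WM voxel: placement margin
  din <- sqrt(.edt_sq_cpp(as.vector(!wm), d, sp))
  din <- array(din, d)

  pvs <- array(FALSE, d)
  tubes <- data.frame()
  n_placed <- 0
  attempts <- 0
  max_attempts <- 200 * max(1, spec$n_tubes)
  while (n_placed < spec$n_tubes) {
    if ((attempts <- attempts + 1) > max_attempts)
      stop("tube placement failed after ", max_attempts,
           " attempts (overcrowded phantom spec)")
    r <- runif(1, spec$tube_radius_range[1], spec$tube_radius_range[2])
    L <- runif(1, spec$tube_length_range[1], spec$tube_length_range[2])
    u <- if (spec$orientation == "axis-aligned") {
      diag(3)[sample.int(3, 1), ]
    } else {
      v <- rnorm(3); v / sqrt(sum(v^2))
    }
    # tube must clear the CSF dilation zone along its whole axis
    margin <- r + 2.5 + max(sp)
    cand <- which(din >= margin)
    if (length(cand) == 0) next
    cidx <- cand[sample.int(length(cand), 1)]
    cc <- c(X[cidx], Y[cidx], Z[cidx])
    p0 <- cc - u * L / 2
    p1 <- cc + u * L / 2
    tt <- seq(0, 1, by = min(sp) / L)
    pts <- cbind(p0[1] + tt * (p1[1] - p0[1]), p0[2] + tt * (p1[2] - p0[2]),
                 p0[3] + tt * (p1[3] - p0[3]))
    vi <- cbind(pmin(pmax(round(pts[, 1] / sp[1]), 0), d[1] - 1) + 1,
                pmin(pmax(round(pts[, 2] / sp[2]), 0), d[2] - 1) + 1,
                pmin(pmax(round(pts[, 3] / sp[3]), 0), d[3] - 1) + 1)
    if (any(din[vi] < margin)) next
    vox <- rasterize_tube(p0, p1, r, X, Y, Z, sp, d)
    if (any(pvs[vox])) next # tubes must not merge
    pvs[vox] <- TRUE
    tubes <- rbind(tubes, data.frame(
      cx = cc[1], cy = cc[2], cz = cc[3], ux = u[1], uy = u[2], uz = u[3],
      radius_mm = r, length_mm = L))
    n_placed <- n_placed + 1
  }

  lesions <- array(FALSE, d)
  place_spheres <- function(n, lesions) {
    placed <- 0; tries <- 0
    while (placed < n) {
      if ((tries <- tries + 1) > 200 * n)
        stop("lesion placement failed (overcrowded phantom spec)")
      r <- runif(1, spec$lesion_radius_range[1], spec$lesion_radius_range[2])
      cand <- which(din >= r + 1)
      if (length(cand) == 0) stop("no room for a lesion of radius ", r)
      cidx <- cand[sample.int(length(cand), 1)]
      cc <- c(X[cidx], Y[cidx], Z[cidx])
      sph <- (X - cc[1])^2 + (Y - cc[2])^2 + (Z - cc[3])^2 <= r^2
      if (any(sph & pvs)) next # lesions keep clear of the PVS truth
      lesions[sph] <- TRUE
      placed <- placed + 1
    }
    lesions
  }
  wmh <- if (spec$n_wmh > 0) place_spheres(spec$n_wmh, array(FALSE, d))
         else array(FALSE, d)
  ich <- if (spec$n_ich > 0) place_spheres(spec$n_ich, array(FALSE, d))
         else array(FALSE, d)
  lesions <- wmh | ich

  img <- array(0, d)
  img[wm] <- spec$wm_intensity
  img[csf] <- spec$csf_intensity
  img[wmh] <- spec$wmh_intensity
  img[ich] <- spec$ich_intensity
  img[pvs] <- spec$tube_intensity
  if (spec$noise_sigma > 0) img <- rician_corrupt(img, spec$noise_sigma)

  brain_m <- binary_mask(brain, sp)
  csf_m <- binary_mask(csf, sp)
  lesion_m <- binary_mask(lesions, sp)
  pvs_m <- binary_mask(pvs, sp)
  nawm <- suppressWarnings(build_nawm_roi(brain_m, csf_m, 2.5,
                                          lesion_mask = lesion_m))
  true_vol <- if (nrow(tubes)) sum(pi * tubes$radius_mm^2 * tubes$length_mm) else 0
  structure(list(image = image_volume(img, sp),
                 brain_mask = brain_m, csf_mask = csf_m,
                 lesion_mask = lesion_m, pvs_truth_mask = pvs_m,
                 nawm_mask = nawm, tubes = tubes,
                 true_pvs_volume_mm3 = true_vol,
                 true_pvs_vf = true_vol / mask_volume_mm3(nawm),
                 spec = spec),
            class = "phantom_truth")
}

# voxels whose center lies inside the finite cylinder of radius r around
# segment p0-p1 (flat ends: axial projection within the segment)
rasterize_tube <- function(p0, p1, r, X, Y, Z, sp, d) {
  lo <- pmin(p0, p1) - r - sp
  hi <- pmax(p0, p1) + r + sp
  box <- X >= lo[1] & X <= hi[1] & Y >= lo[2] & Y <= hi[2] &
    Z >= lo[3] & Z <= hi[3]
  idx <- which(box)
  w1 <- X[idx] - p0[1]; w2 <- Y[idx] - p0[2]; w3 <- Z[idx] - p0[3]
  v <- p1 - p0
  L2 <- sum(v^2)
  t <- (w1 * v[1] + w2 * v[2] + w3 * v[3]) / L2
  dx <- w1 - t * v[1]; dy <- w2 - t * v[2]; dz <- w3 - t * v[3]
  idx[t >= 0 & t <= 1 & dx^2 + dy^2 + dz^2 <= r^2]
}

# logical array shifted by one voxel along `ax`; vacated slice is FALSE
shift_logical <- function(m, ax, by) {
  d <- dim(m)
  n <- d[ax]
  out <- array(FALSE, d)
  idx_dst <- lapply(d, seq_len)
  idx_src <- idx_dst
  if (by > 0) { idx_dst[[ax]] <- seq_len(n - 1); idx_src[[ax]] <- 2:n }
  else        { idx_dst[[ax]] <- 2:n; idx_src[[ax]] <- seq_len(n - 1) }
  vals <- do.call(`[`, c(list(m), idx_src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), idx_dst, list(value = vals)))
}

# 6-connectivity erosion: keep voxels whose face neighbors are all TRUE
erode_face6 <- function(m) {
  out <- m
  for (ax in 1:3)
    out <- out & shift_logical(m, ax, 1L) & shift_logical(m, ax, -1L)
  out
}
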