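#' Parameters of the multi-scale Frangi vesselness filter
#'
#' Defaults follow the standard bright-tube configuration used for PVS
#' segmentation on T2-weighted images: 10 scales linearly spaced from
#' sigma = 1 to 3.5 (in-plane voxel units), plate/line sensitivity
#' `alpha = 0.5`, blob sensitivity `beta = 0.5`, adaptive structure-ness
#' constant `c` (half the maximum Hessian Frobenius norm at each scale),
#' and scale normalization exponent `gamma = 2` so responses are
#' comparable across scales. Polarity is bright-on-dark: PVS are
#' CSF-bright tubes on T2.
#'
#' @param scales strictly increasing positive sigmas in in-plane voxel
#'   units.
#' @param alpha plate-vs-line sensitivity (> 0).
#' @param beta blob sensitivity (> 0).
#' @param c `"adaptive"` or a fixed positive structure-ness constant.
#' @param gamma scale-normalization exponent (>= 0).
#' @param polarity `"bright"` (tubes brighter than background, the
#'   physiological case) or `"dark"` (exposed for testing).
#' @return An object of class `vesselness_params`.
#' @export
vesselness_params <- function(scales = seq(1, 3.5, length.out = 10),
                              alpha = 0.5, beta = 0.5, c = "adaptive",
                              gamma = 2, polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  scales <- as.numeric(scales)
  if (length(scales) == 0 || any(scales <= 0) || is.unsorted(scales, strictly = TRUE))
    stop("scales must be non-empty, positive and strictly increasing")
  if (!is.numeric(alpha) || alpha <= 0 || !is.numeric(beta) || beta <= 0)
    stop("alpha and beta must be positive")
  if (!identical(c, "adaptive") && (!is.numeric(c) || length(c) != 1 || c <= 0))
    stop("c must be \"adaptive\" or a single positive number")
  if (!is.numeric(gamma) || gamma < 0) stop("gamma must be >= 0")
  structure(list(scales = scales, alpha = alpha, beta = beta, c = c,
                 gamma = gamma, polarity = polarity),
            class = "vesselness_params")
}

# Sampled Gaussian derivative kernels (correlation form) at scale `sigma`
# in index units, normalized to be exact on polynomials of degree <= 2:
# sum(g0) = 1, sum(t * g1) = 1, sum(g2) = 0 and sum(t^2 * g2) = 2.
# For sub-voxel sigma the second-derivative kernel degenerates gracefully
# to the central finite difference [1, -2, 1].
gaussian_derivative_kernels <- function(sigma) {
  radius <- max(1L, as.integer(ceiling(4 * sigma)))
  t <- seq.int(-radius, radius)
  g <- exp(-t^2 / (2 * sigma^2))
  g0 <- g / sum(g)
  m1 <- sum(t^2 * g)
  g1 <- if (m1 > 0) t * g / m1 else c(-0.5, 0, 0.5)
  g2 <- (t^2 - sigma^2) * g
  g2 <- g2 - sum(g2) / sum(g) * g            # enforce zero DC response
  m2 <- sum(t^2 * g2)
  if (m2 <= .Machine$double.xmin * 1e6) {
    g2 <- numeric(length(t))
    g2[radius + c(0L, 1L, 2L)] <- c(1, -2, 1) # degenerate: central difference
  } else {
    g2 <- 2 * g2 / m2
  }
  list(g0, g1, g2)
}

#' Gaussian second-derivative (Hessian) field at one scale
#'
#' Computes the six unique components of the scale-space Hessian of a
#' volume at physical scale `sigma_mm = sigma_voxels * mean in-plane
#' spacing`. The Gaussian kernel is isotropic in mm: the per-axis
#' derivative width is `sigma_mm / spacing\[axis\]` voxels, so thick
#' slices receive a deliberately sub-voxel through-plane kernel.
#' Derivatives are expressed per mm^2 and multiplied by `sigma_mm^gamma`
#' (gamma-normalization) so single-scale responses are comparable across
#' scales. Borders are handled by reflective image extension.
#'
#' @param volume an [image_volume].
#' @param sigma_voxels scale in in-plane voxel units (> 0).
#' @param gamma scale-normalization exponent.
#' @param warn_underresolved warn when `sigma_mm / spacing < 0.4` on some
#'   axis (kernel under-resolved; common and intended on thick slices).
#' @return An object of class `hessian_field`: list with arrays `xx`,
#'   `yy`, `zz`, `xy`, `xz`, `yz` plus the geometry and scale metadata.
#' @export
hessian_at_scale <- function(volume, sigma_voxels, gamma = 2,
                             warn_underresolved = TRUE) {
  stopifnot(inherits(volume, "image_volume"))
  if (!is.numeric(sigma_voxels) || sigma_voxels <= 0)
    stop("sigma_voxels must be positive")
  sp <- volume$spacing
  sigma_mm <- sigma_voxels * mean(sp[1:2])
  sigma_vox <- sigma_mm / sp
  if (warn_underresolved && any(sigma_vox < 0.4))
    warning(sprintf(
      "under-resolved derivative kernel on axis %s (sigma %.2f voxels < 0.4)",
      paste(which(sigma_vox < 0.4), collapse = ","), min(sigma_vox)))

  kern <- lapply(sigma_vox, gaussian_derivative_kernels)
  dims <- dim(volume$data)
  x <- as.vector(volume$data)
  # separable correlation: orders[axis] selects smoothing (0), first (1)
  # or second (2) derivative kernel on that axis
  deriv <- function(orders) {
    out <- x
    for (ax in 1:3)
      out <- .conv_axis_cpp(out, dims, kern[[ax]][[orders[ax] + 1L]], ax,
                            orders[ax] > 0L)
    scale <- prod(sp^orders) # index-space derivative -> per-mm
    array(out / scale * sigma_mm^gamma, dims)
  }
  structure(list(xx = deriv(c(2, 0, 0)), yy = deriv(c(0, 2, 0)),
                 zz = deriv(c(0, 0, 2)), xy = deriv(c(1, 1, 0)),
                 xz = deriv(c(1, 0, 1)), yz = deriv(c(0, 1, 1)),
                 spacing = sp, sigma_voxels = sigma_voxels,
                 sigma_mm = sigma_mm, gamma = gamma),
            class = "hessian_field")
}

#' Per-voxel Hessian eigenvalues sorted by absolute value
#'
#' Solves the symmetric 3x3 eigenproblem at every voxel and orders the
#' three real eigenvalues so that `|l1| <= |l2| <= |l3|` — the ordering
#' on which the Frangi ratios are defined.
#'
#' @param hessian a `hessian_field` from [hessian_at_scale()].
#' @return An object of class `eigen_field`: arrays `l1`, `l2`, `l3`.
#' @export
eigenvalues_sorted <- function(hessian) {
  stopifnot(inherits(hessian, "hessian_field"))
  comp <- hessian[c("xx", "yy", "zz", "xy", "xz", "yz")]
  if (!all(vapply(comp, function(a) all(is.finite(a)), logical(1))))
    stop("non-finite Hessian components")
  dims <- dim(hessian$xx)
  ev <- .eig3_sym_cpp(as.vector(hessian$xx), as.vector(hessian$yy),
                      as.vector(hessian$zz), as.vector(hessian$xy),
                      as.vector(hessian$xz), as.vector(hessian$yz))
  structure(list(l1 = array(ev[, 1], dims), l2 = array(ev[, 2], dims),
                 l3 = array(ev[, 3], dims), spacing = hessian$spacing,
                 sigma_voxels = hessian$sigma_voxels,
                 sigma_mm = hessian$sigma_mm),
            class = "eigen_field")
}

#' Single-scale Frangi vesselness response
#'
#' Evaluates the tubularity measure from ordered Hessian eigenvalues.
#' For bright tubes the response is zero wherever `l2 > 0` or `l3 > 0`
#' (dark-structure sign pattern) and otherwise
#' `V = (1 - exp(-Ra^2 / 2 alpha^2)) * exp(-Rb^2 / 2 beta^2) *
#' (1 - exp(-S^2 / 2 c^2))` with `Ra = |l2|/|l3|`,
#' `Rb = |l1|/sqrt(|l2 l3|)` and `S = sqrt(l1^2 + l2^2 + l3^2)`.
#' With `c = "adaptive"`, `c` is set to half the maximum of `S` (over
#' `c_reference_mask` if given, else the whole field); an identically
#' zero `S` field yields an all-zero response.
#'
#' @param eig an `eigen_field` from [eigenvalues_sorted()].
#' @param params a [vesselness_params] object (only `alpha`, `beta`,
#'   `c`, `polarity` are used at a single scale).
#' @param c_reference_mask optional [binary_mask] over which the adaptive
#'   `c` maximum is taken.
#' @return An [image_volume] with values in \[0, 1\].
#' @export
frangi_response_single_scale <- function(eig, params = vesselness_params(),
                                         c_reference_mask = NULL) {
  stopifnot(inherits(eig, "eigen_field"), inherits(params, "vesselness_params"))
  l1 <- eig$l1; l2 <- eig$l2; l3 <- eig$l3
  if (identical(params$polarity, "dark")) { # sign-flip reduces to bright case
    l1 <- -l1; l2 <- -l2; l3 <- -l3
  }
  S2 <- l1^2 + l2^2 + l3^2
  cval <- params$c
  if (identical(cval, "adaptive")) {
    S2ref <- if (is.null(c_reference_mask)) S2 else S2[c_reference_mask$data]
    smax <- sqrt(max(S2ref))
    if (smax == 0)
      return(image_volume(array(0, dim(l1)), eig$spacing))
    cval <- smax / 2
  }
  if (cval <= 0) stop("c must be positive")

  v <- array(0, dim(l1))
  ok <- l2 < 0 & l3 < 0 # bright-tube sign gate; l3 = 0 stays 0
  if (any(ok)) {
    a2 <- abs(l2[ok]); a3 <- abs(l3[ok])
    Ra2 <- (a2 / a3)^2
    Rb2 <- l1[ok]^2 / (a2 * a3)
    v[ok] <- (1 - exp(-Ra2 / (2 * params$alpha^2))) *
      exp(-Rb2 / (2 * params$beta^2)) *
      (1 - exp(-S2[ok] / (2 * cval^2)))
  }
  out <- image_volume(v, eig$spacing)
  attr(out, "c") <- cval
  out
}

#' Multi-scale Frangi vesselness map
#'
#' Computes the per-voxel maximum of the single-scale Frangi responses
#' over all scales in `params$scales`, restricted to the ROI (voxels
#' outside the ROI are exactly zero). This is the pre-threshold
#' vesselness map from which the PVS segmentation is cut.
#'
#' @param volume an [image_volume] (typically histogram-normalized).
#' @param roi a non-empty [binary_mask] on the same grid.
#' @param params a [vesselness_params] object.
#' @return An [image_volume] in \[0, 1\] with attribute `"scales"`.
#' @export
frangi_vesselness <- function(volume, roi, params = vesselness_params()) {
  stopifnot(inherits(volume, "image_volume"), inherits(roi, "binary_mask"),
            inherits(params, "vesselness_params"))
  if (!same_grid(volume, roi)) stop_grid_mismatch("volume and roi")
  if (!any(roi$data)) stop("empty ROI")

  sig_mm <- params$scales * mean(volume$spacing[1:2])
  minvox <- min(outer(sig_mm, volume$spacing, "/"))
  if (minvox < 0.4)
    warning(sprintf(paste0("some scales are under-resolved on the coarsest ",
                           "axis (min sigma %.2f voxels); through-plane ",
                           "sensitivity is reduced"), minvox))

  vmax <- array(0, dim(volume$data))
  for (s in params$scales) {
    h <- hessian_at_scale(volume, s, gamma = params$gamma,
                          warn_underresolved = FALSE)
    e <- eigenvalues_sorted(h)
    v <- frangi_response_single_scale(e, params, c_reference_mask = roi)
    vmax <- pmax(vmax, v$data)
  }
  vmax[!roi$data] <- 0
  vmax[vmax < 0] <- 0
  vmax[vmax > 1] <- 1
  out <- image_volume(vmax, volume$spacing, volume$affine)
  attr(out, "scales") <- params$scales
  out
}
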