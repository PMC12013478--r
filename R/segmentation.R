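#' Threshold a vesselness map within the ROI
#'
#' A voxel enters the PVS segmentation iff it lies inside the ROI and its
#' vesselness strictly exceeds the threshold, so threshold 1 yields the
#' empty segmentation and threshold 0 the full positive support. An
#' optional minimum 26-connected component size can prune speckle; it
#' defaults to 0 (no pruning), matching the protocol's plain manual
#' threshold.
#'
#' @param map vesselness [image_volume] with values in \[0, 1\].
#' @param roi a [binary_mask] on the same grid.
#' @param threshold scalar in \[0, 1\]; per-subject choice.
#' @param min_component_voxels drop 26-connected components smaller than
#'   this many voxels (default 0).
#' @return The PVS segmentation as a [binary_mask].
#' @export
threshold_vesselness <- function(map, roi, threshold,
                                 min_component_voxels = 0) {
  stopifnot(inherits(map, "image_volume"), inherits(roi, "binary_mask"))
  if (!same_grid(map, roi)) stop_grid_mismatch("map and roi")
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1]")
  seg <- roi$data & (map$data > threshold)
  if (min_component_voxels > 0 && any(seg)) {
    lab <- .label_cc26_cpp(as.vector(seg), dim(seg))
    sizes <- tabulate(lab, nbins = attr(lab, "n"))
    keep <- which(sizes >= min_component_voxels)
    seg <- array(lab %in% keep, dim(seg))
  }
  binary_mask(seg, map$spacing, map$affine)
}

#' Count 26-connected components of a mask
#' @param mask a [binary_mask].
#' @return Integer component count.
#' @export
count_components <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$data)) return(0L)
  attr(.label_cc26_cpp(as.vector(mask$data), dim(mask$data)), "n")
}

#' PVS volume and volume fraction within the NAWM ROI
#'
#' Volumes are voxel counts times the voxel volume `sx * sy * sz`;
#' the volume fraction is the segmented PVS volume divided by the NAWM
#' ROI volume, which normalizes for the amount of white matter in which
#' PVS were segmented. Segmented voxels outside the ROI are dropped with
#' a warning.
#'
#' @param pvs_mask PVS segmentation as a [binary_mask].
#' @param roi non-empty NAWM ROI [binary_mask] on the same grid.
#' @param threshold optional: the vesselness cutoff that produced
#'   `pvs_mask`, recorded in the result.
#' @return An object of class `pvs_result`: `pvs_volume_mm3`,
#'   `nawm_volume_mm3`, `pvs_vf`, `threshold`, `n_components`.
#' @export
compute_pvs_vf <- function(pvs_mask, roi, threshold = NA_real_) {
  stopifnot(inherits(pvs_mask, "binary_mask"), inherits(roi, "binary_mask"))
  if (!same_grid(pvs_mask, roi)) stop_grid_mismatch("pvs_mask and roi")
  if (!any(roi$data)) stop("empty ROI")
  seg <- pvs_mask$data
  outside <- sum(seg & !roi$data)
  if (outside > 0) {
    warning(outside, " segmented voxels outside the ROI were dropped")
    seg <- seg & roi$data
  }
  vox <- voxel_volume_mm3(roi)
  n_pvs <- sum(seg)
  n_roi <- sum(roi$data)
  seg_mask <- binary_mask(seg, roi$spacing, roi$affine)
  structure(list(pvs_volume_mm3 = n_pvs * vox,
                 nawm_volume_mm3 = n_roi * vox,
                 pvs_vf = n_pvs / n_roi,
                 threshold = threshold,
                 n_components = count_components(seg_mask)),
            class = "pvs_result")
}

#' @export
print.pvs_result <- function(x, ...) {
  cat(sprintf(paste0("PVS result: volume %.2f mm^3 in NAWM %.2f mm^3 -> ",
                     "PVSvf %.5f (threshold %s, %d components)\n"),
              x$pvs_volume_mm3, x$nawm_volume_mm3, x$pvs_vf,
              format(x$threshold), x$n_components))
  invisible(x)
}

#' Sweep segmentation thresholds
#'
#' Evaluates the segmentation at each threshold in an ascending list and
#' tabulates the resulting volume fraction and component count —
#' decision support for the per-subject threshold choice that the
#' semi-automated protocol leaves to the assessor. The volume fraction
#' is non-increasing along the sweep by construction.
#'
#' @param map vesselness [image_volume].
#' @param roi NAWM ROI [binary_mask].
#' @param thresholds ascending thresholds in \[0, 1\].
#' @return A data.frame of class `threshold_sweep` with columns
#'   `threshold`, `pvs_vf`, `pvs_volume_mm3`, `n_components`.
#' @export
sweep_thresholds <- function(map, roi,
                             thresholds = seq(0.05, 0.95, by = 0.05)) {
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) == 0 || is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  rows <- lapply(thresholds, function(t) {
    r <- compute_pvs_vf(threshold_vesselness(map, roi, t), roi, threshold = t)
    data.frame(threshold = t, pvs_vf = r$pvs_vf,
               pvs_volume_mm3 = r$pvs_volume_mm3,
               n_components = r$n_components)
  })
  out <- do.call(rbind, rows)
  stopifnot(!is.unsorted(rev(out$pvs_vf))) # non-increasing, by construction
  class(out) <- c("threshold_sweep", "data.frame")
  out
}

#' Dice overlap coefficient between two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty masks count as perfect
#' agreement (Dice 1).
#'
#' @param a,b [binary_mask]s on one grid.
#' @return Scalar in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(inherits(a, "binary_mask"), inherits(b, "binary_mask"))
  if (!same_grid(a, b)) stop_grid_mismatch("a and b")
  na <- sum(a$data); nb <- sum(b$data)
  if (na + nb == 0) return(1)
  2 * sum(a$data & b$data) / (na + nb)
}
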