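#' Histogram-based intensity normalization
#'
#' Rescales a T2-weighted volume to the dimensionless range \[0, 1\]
#' using robust percentiles of its intensity histogram:
#' `clip((v - P_low) / (P_high - P_low), 0, 1)`. The percentiles are
#' computed over the whole volume or, if `reference_mask` is given,
#' over the voxels inside it. Percentiles use linear interpolation
#' between order statistics (position `1 + p(n-1)`), the same quantile
#' convention used throughout the package. The default (1st, 99th)
#' window guards against hyperintense outliers such as hemorrhage rims,
#' and makes a single vesselness threshold meaningful across subjects
#' regardless of scanner gain.
#'
#' @param volume an [image_volume] with finite intensities.
#' @param low_percentile lower percentile in \[0, 100) (default 1).
#' @param high_percentile upper percentile in (low, 100\] (default 99).
#' @param reference_mask optional [binary_mask] restricting the histogram.
#' @return An [image_volume] with values in \[0, 1\].
#' @export
normalize_histogram <- function(volume, low_percentile = 1,
                                high_percentile = 99,
                                reference_mask = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  if (!is.numeric(low_percentile) || !is.numeric(high_percentile) ||
      low_percentile < 0 || high_percentile > 100 ||
      low_percentile >= high_percentile)
    stop("percentiles must satisfy 0 <= low < high <= 100")
  vals <- volume$data
  if (!is.null(reference_mask)) {
    stopifnot(inherits(reference_mask, "binary_mask"))
    if (!same_grid(volume, reference_mask))
      stop_grid_mismatch("volume and reference_mask")
    if (!any(reference_mask$data)) stop("reference_mask is empty")
    vals <- volume$data[reference_mask$data]
  }
  p <- quantile(as.vector(vals), c(low_percentile, high_percentile) / 100,
                type = 7, names = FALSE)
  if (p[2] <= p[1])
    stop(sprintf(paste0("degenerate intensity percentiles: P%.3g = P%.3g = %g ",
                        "(constant or near-constant image)"),
                 low_percentile, high_percentile, p[1]))
  out <- (volume$data - p[1]) / (p[2] - p[1])
  out[out < 0] <- 0
  out[out > 1] <- 1
  res <- image_volume(out, volume$spacing, volume$affine)
  attr(res, "percentile_values") <- p
  res
}
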